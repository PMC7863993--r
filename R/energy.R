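# Relative conformer-energy agreement. All energies are in kcal/mol and all
# relative energies are anchored at the group's reference conformer — the
# one with the lowest QM energy — so any constant offset between a force
# field's energy scale and the QM scale cancels:
#   ddE_i = [FF(i) - FF(0)] - [QM(i) - QM(0)]

#' Relative energy differences (ddE) for one molecule group and force field
#'
#' For every conformer `i` of the group: `dE_QM = QM(i) - QM(0)`,
#' `dE_FF = FF(i) - FF(0)`, `ddE = dE_FF - dE_QM`, with conformer 0 the
#' group's reference (lowest QM energy). The reference row is flagged and has
#' `ddE = 0` exactly. Rows with a non-finite FF energy, or with `|ddE|` at or
#' beyond `pathological_cutoff` (hydrogen-collapse-type failures), are flagged
#' pathological: excluded from summaries but retained for the extrema report.
#'
#' @param group a `molecule_group`.
#' @param ff_id force-field identifier present in every member's
#'   `ff_results`.
#' @param pathological_cutoff absolute ddE at or above which a finite row is
#'   still considered pathological (default `1e4` kcal/mol).
#' @return data frame (one row per conformer): `key`, `title`, `i`,
#'   `ff`, `qm_energy`, `ff_energy`, `de_qm`, `de_ff`, `dde`,
#'   `is_reference`, `pathological`.
#' @export
dde <- function(group, ff_id, pathological_cutoff = 1e4) {
  stopifnot(inherits(group, "molecule_group"))
  nrec <- length(group$records)
  ref <- group$reference_index
  qm_e <- vapply(group$records, function(r) r$qm$energy, numeric(1))
  ff_e <- vapply(group$records, function(r) {
    cf <- r$ff_results[[ff_id]]
    if (is.null(cf)) stop("force field ", ff_id, " absent from group member")
    cf$energy
  }, numeric(1))

  de_qm <- qm_e - qm_e[ref]
  de_ff <- ff_e - ff_e[ref]
  d <- de_ff - de_qm
  d[ref] <- 0 # exact by construction

  patho <- !is.finite(ff_e) | (is.finite(d) & abs(d) >= pathological_cutoff)
  data.frame(
    key = group$key,
    title = group$titles,
    i = seq_len(nrec) - 1L,
    ff = ff_id,
    qm_energy = qm_e,
    ff_energy = ff_e,
    de_qm = de_qm,
    de_ff = de_ff,
    dde = d,
    is_reference = seq_len(nrec) == ref,
    pathological = patho,
    stringsAsFactors = FALSE
  )
}

#' Mean signed deviation (MSD) of matched relative conformer energies
#'
#' `MSD = (1 / (N - 1)) * sum(dE_FF - dE_QM)` over a molecule's `N - 1`
#' non-reference matched conformers. The reference conformer (dE = 0) is
#' excluded by the caller; `values` are the non-reference
#' `dE_FF - dE_QM` terms (equal to their ddE values).
#'
#' @param values numeric vector of `N - 1` signed deviations (kcal/mol).
#' @param n total matched conformer count `N` (including the reference);
#'   default `length(values) + 1`.
#' @return MSD in kcal/mol, or `NA` (with a message) when `n < 2`.
#' @export
msd <- function(values, n = length(values) + 1L) {
  if (n < 2L) {
    message("MSD undefined for fewer than 2 conformers; molecule skipped")
    return(NA_real_)
  }
  if (length(values) != n - 1L) {
    stop("expected n - 1 non-reference values, got ", length(values))
  }
  sum(values) / (n - 1L)
}

#' Fraction of conformers with |ddE| within a threshold
#'
#' @param dde_values non-reference ddE values (kcal/mol).
#' @param threshold energy window, default 1 kcal/mol.
#' @return list with `fraction` and binomial `se = sqrt(p(1-p)/n)`.
#' @export
fraction_within <- function(dde_values, threshold = 1) {
  stopifnot(threshold > 0)
  v <- dde_values[is.finite(dde_values)]
  if (length(v) == 0L) stop("no finite ddE values")
  p <- mean(abs(v) <= threshold)
  list(fraction = p, se = sqrt(p * (1 - p) / length(v)))
}

#' Per-force-field ddE extrema and pathological listing
#'
#' Minimum and maximum ddE per force field over non-reference,
#' non-pathological rows, plus a listing of every pathological row (the
#' hydrogen-collapse analogue report) with its molecule key.
#'
#' @param energy_tables named list (per force field) of [dde()] tables, or
#'   one combined data frame.
#' @return list with `summary` (data frame: `ff`, `min_dde`, `max_dde`,
#'   `n_pathological`) and `pathological` (data frame of flagged rows).
#' @export
extrema_summary <- function(energy_tables) {
  tab <- if (is.data.frame(energy_tables)) energy_tables
         else do.call(rbind, unname(energy_tables))
  ffs <- unique(tab$ff)
  rows <- lapply(ffs, function(f) {
    sub <- tab[tab$ff == f & !tab$is_reference & !tab$pathological, ,
               drop = FALSE]
    npath <- sum(tab$ff == f & tab$pathological)
    data.frame(
      ff = f,
      min_dde = if (nrow(sub)) min(sub$dde) else NA_real_,
      max_dde = if (nrow(sub)) max(sub$dde) else NA_real_,
      n_pathological = npath,
      stringsAsFactors = FALSE
    )
  })
  list(
    summary = do.call(rbind, rows),
    pathological = tab[tab$pathological, , drop = FALSE]
  )
}
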