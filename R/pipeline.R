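# Pipeline orchestration: SDF ensembles -> molecule groups -> geometry and
# energy metrics -> conformer matching -> summaries -> (optional) parameter
# enrichment, bundled as plain tables. Everything is deterministic given the
# inputs; every dropped structure is accounted for.

#' Per-structure geometry metrics for all force fields
#'
#' Symmetry-aware RMSD and TFD of every member's force-field conformer
#' against its own QM conformer. Automorphisms and torsion sets are computed
#' once per group. Structures whose graph has no torsion entries get
#' `NA` TFD.
#'
#' @param groups list of `molecule_group`.
#' @param ff_ids force-field ids to evaluate (default: all on record 1).
#' @return data frame: `key`, `title`, `ff`, `rmsd`, `tfd`.
#' @export
geometry_metric_table <- function(groups, ff_ids = NULL) {
  rows <- list()
  for (g in groups) {
    graph <- g$records[[1L]]$graph
    autos <- enumerate_automorphisms(graph)
    tset <- build_torsion_set(graph)
    has_torsions <- length(tset$entries) > 0L
    ids <- ff_ids
    if (is.null(ids)) ids <- names(g$records[[1L]]$ff_results)
    for (i in seq_along(g$records)) {
      rec <- g$records[[i]]
      for (f in ids) {
        cf <- rec$ff_results[[f]]
        if (is.null(cf)) next
        rows[[length(rows) + 1L]] <- data.frame(
          key = g$key, title = g$titles[i], ff = f,
          rmsd = as.numeric(best_rmsd(graph, rec$qm, cf,
                                      automorphisms = autos)),
          tfd = if (has_torsions) {
            suppressWarnings(tfd(tset, rec$qm, cf))
          } else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(key = character(), title = character(),
                      ff = character(), rmsd = numeric(), tfd = numeric()))
  }
  do.call(rbind, rows)
}

#' Histogram table with centered bins
#'
#' Bin edges at integer multiples of `bin_width`, bins reported by center
#' (`(k + 0.5) * bin_width`). Reference-conformer entries are excluded when
#' `drop_reference` is set; counts always sum to the retained values.
#'
#' @param values numeric vector.
#' @param bin_width bin width (> 0).
#' @param is_reference optional logical vector marking reference entries.
#' @param drop_reference drop entries flagged in `is_reference`.
#' @return data frame `center`, `count`.
#' @export
histogram_export <- function(values, bin_width = 1, is_reference = NULL,
                             drop_reference = TRUE) {
  stopifnot(bin_width > 0)
  v <- values
  if (drop_reference && !is.null(is_reference)) v <- v[!is_reference]
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(data.frame(center = numeric(),
                                         count = integer()))
  centers <- (floor(v / bin_width) + 0.5) * bin_width
  tab <- table(centers)
  data.frame(center = as.numeric(names(tab)),
             count = as.integer(tab))
}

#' ddE-vs-TFD scatter table with local density
#'
#' Each (ddE, TFD) point annotated with a 2-D Gaussian kernel density
#' estimate at the point (product kernel, Scott's-rule bandwidth
#' `sd_j * n^(-1/6)` per coordinate). Densities are positive and finite.
#'
#' @param dde_values,tfd_values equal-length numeric vectors.
#' @return data frame `dde`, `tfd`, `density`.
#' @export
scatter_density_export <- function(dde_values, tfd_values) {
  if (length(dde_values) != length(tfd_values)) {
    stop("dde and tfd vectors must have equal length")
  }
  n <- length(dde_values)
  if (n == 0L) return(data.frame(dde = numeric(), tfd = numeric(),
                                 density = numeric()))
  x <- as.numeric(dde_values); y <- as.numeric(tfd_values)
  hx <- sd(x) * n^(-1 / 6); hy <- sd(y) * n^(-1 / 6)
  if (!is.finite(hx) || hx <= 0) hx <- 1
  if (!is.finite(hy) || hy <= 0) hy <- 1
  dens <- vapply(seq_len(n), function(i) {
    mean(exp(-((x - x[i])^2 / (2 * hx^2) + (y - y[i])^2 / (2 * hy^2)))) /
      (2 * pi * hx * hy)
  }, numeric(1))
  data.frame(dde = x, tfd = y, density = dens)
}

#' Run the full benchmark pipeline
#'
#' Reads the QM and per-force-field SDF ensembles (or takes pre-built
#' records), groups structures into molecules, computes energy tables,
#' geometry metrics, conformer matching, per-molecule MSDs, summaries, and
#' — when an assignment table is supplied — the parameter-enrichment report
#' for `enrichment_ff` (default: first force field).
#'
#' @param qm QM SDF path, or a list of `structure_record` (then `ff` is
#'   ignored).
#' @param ff named character vector of force-field SDF paths.
#' @param assignments optional `parameter_assignment` or path to an
#'   assignment table.
#' @param energy_tag SDF energy tag name.
#' @param rmsd_threshold conformer-matching threshold in Angstrom.
#' @param tfd_cutoff high-TFD subset cutoff.
#' @param within fraction-within energy window (kcal/mol).
#' @param alpha enrichment significance level.
#' @param min_subset_count enrichment small-sample exclusion bound.
#' @param enrichment_ff force field analyzed for enrichment.
#' @param match_method `"greedy"` or `"optimal"`.
#' @param use_stereo passed to grouping.
#' @param out_dir optional directory for the CSV/JSON report bundle.
#' @param seed recorded in metadata (the pipeline itself is deterministic).
#' @return `report_bundle` list; see fields in the implementation or the
#'   written bundle.
#' @export
run_pipeline <- function(qm, ff = NULL, assignments = NULL,
                         energy_tag = "ENERGY_KCAL",
                         rmsd_threshold = 1.0, tfd_cutoff = 0.12,
                         within = 1.0, alpha = 0.05,
                         min_subset_count = 21L,
                         enrichment_ff = NULL,
                         match_method = "greedy",
                         use_stereo = TRUE,
                         out_dir = NULL, seed = NULL) {
  if (is.character(qm)) {
    if (is.null(ff) || is.null(names(ff))) {
      stop("ff must be a named vector of force-field SDF paths")
    }
    qm_entries <- read_conformer_sdf(qm, energy_tag, source = "QM")
    ff_entries <- lapply(names(ff), function(nm) {
      read_conformer_sdf(ff[[nm]], energy_tag, source = nm)
    })
    names(ff_entries) <- names(ff)
    records <- build_records(qm_entries, ff_entries)
  } else {
    records <- qm
  }
  if (is.character(assignments)) assignments <- read_assignments(assignments)

  groups <- group_by_identity(records, use_stereo = use_stereo)
  dropped <- attr(groups, "dropped")
  ff_ids <- attr(groups, "ff_ids")
  if (length(groups) == 0L) stop("no analyzable molecule groups")
  if (is.null(enrichment_ff)) enrichment_ff <- ff_ids[1L]

  # --- energy tables
  energy_tables <- lapply(ff_ids, function(f) {
    do.call(rbind, lapply(groups, dde, ff_id = f))
  })
  names(energy_tables) <- ff_ids
  energy_table <- do.call(rbind, unname(energy_tables))

  # --- geometry metrics
  metric_table <- geometry_metric_table(groups, ff_ids)

  # --- matching + per-molecule MSD (matched, reference excluded)
  match_rows <- list()
  msd_rows <- list()
  for (g in groups) {
    graph <- g$records[[1L]]$graph
    autos <- enumerate_automorphisms(graph)
    nrec <- length(g$records)
    for (f in ff_ids) {
      rmat <- matrix(NA_real_, nrec, nrec)
      for (i in seq_len(nrec)) {
        for (j in seq_len(nrec)) {
          rmat[i, j] <- best_rmsd(graph, g$records[[i]]$qm,
                                  g$records[[j]]$ff_results[[f]],
                                  automorphisms = autos)
        }
      }
      mr <- match_from_matrix(rmat, rmsd_threshold, match_method)
      match_rows[[length(match_rows) + 1L]] <- data.frame(
        key = g$key, ff = f,
        qm_title = c(g$titles[mr$pairs$qm],
                     g$titles[mr$dropped_qm],
                     rep(NA_character_, nrow(mr$dropped_ff))),
        ff_title = c(g$titles[mr$pairs$ff],
                     rep(NA_character_, length(mr$dropped_qm)),
                     g$titles[mr$dropped_ff$index]),
        rmsd = c(mr$pairs$rmsd,
                 rep(NA_real_, length(mr$dropped_qm) + nrow(mr$dropped_ff))),
        disposition = c(rep("matched", nrow(mr$pairs)),
                        rep("dropped-qm", length(mr$dropped_qm)),
                        mr$dropped_ff$reason),
        stringsAsFactors = FALSE
      )

      # MSD over matched, non-reference conformers: ddE of the matched FF
      # conformer against the dE of its QM partner
      et <- energy_tables[[f]]
      et <- et[et$key == g$key, , drop = FALSE]
      pair <- mr$pairs
      vals <- numeric()
      for (k in seq_len(nrow(pair))) {
        qi <- pair$qm[k]; fj <- pair$ff[k]
        if (qi == g$reference_index && fj == g$reference_index) next
        v <- et$de_ff[fj] - et$de_qm[qi]
        if (is.finite(v) && !et$pathological[fj]) vals <- c(vals, v)
      }
      n_matched <- nrow(pair)
      msd_rows[[length(msd_rows) + 1L]] <- data.frame(
        key = g$key, ff = f, n_matched = n_matched,
        msd = if (n_matched >= 2L && length(vals) >= 1L) {
          sum(vals) / length(vals)
        } else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  match_table <- do.call(rbind, match_rows)
  msd_table <- do.call(rbind, msd_rows)

  # --- summaries
  extrema <- extrema_summary(energy_tables)
  within_rows <- lapply(ff_ids, function(f) {
    et <- energy_tables[[f]]
    ok <- !et$is_reference & !et$pathological & is.finite(et$dde)
    fw <- fraction_within(et$dde[ok], within)
    data.frame(ff = f, threshold = within, fraction = fw$fraction,
               se = fw$se, n = sum(ok), stringsAsFactors = FALSE)
  })
  within_table <- do.call(rbind, within_rows)

  dde_histograms <- lapply(ff_ids, function(f) {
    et <- energy_tables[[f]]
    ok <- !et$pathological & is.finite(et$dde)
    histogram_export(et$dde[ok], bin_width = 1,
                     is_reference = et$is_reference[ok],
                     drop_reference = TRUE)
  })
  names(dde_histograms) <- ff_ids

  scatter <- lapply(ff_ids, function(f) {
    et <- energy_tables[[f]]
    mt <- metric_table[metric_table$ff == f, , drop = FALSE]
    idx <- match(paste(et$key, et$title), paste(mt$key, mt$title))
    ok <- !et$is_reference & !et$pathological & is.finite(et$dde) &
      !is.na(idx) & !is.na(mt$tfd[idx])
    scatter_density_export(et$dde[ok], mt$tfd[idx[ok]])
  })
  names(scatter) <- ff_ids

  # --- enrichment (optional)
  enrichment <- NULL
  high_tfd_keys <- NULL
  if (!is.null(assignments)) {
    mt <- metric_table[metric_table$ff == enrichment_ff, , drop = FALSE]
    high_tfd_keys <- select_high_tfd_molecules(mt, tfd_cutoff)
    full_keys <- vapply(groups, function(g) g$key, character(1))
    full_keys <- intersect(full_keys, names(assignments))
    high_tfd_keys <- intersect(high_tfd_keys, full_keys)
    enrichment <- enrichment_report(assignments, high_tfd_keys, full_keys,
                                    alpha = alpha,
                                    min_subset_count = min_subset_count)
  }

  bundle <- structure(list(
    groups = groups,
    manifest = group_manifest(groups),
    dropped_records = dropped,
    ff_ids = ff_ids,
    energy_table = energy_table,
    metric_table = metric_table,
    match_table = match_table,
    msd_table = msd_table,
    extrema = extrema,
    within_table = within_table,
    dde_histograms = dde_histograms,
    scatter = scatter,
    enrichment = enrichment,
    high_tfd_keys = high_tfd_keys,
    metadata = list(
      rmsd_threshold = rmsd_threshold, tfd_cutoff = tfd_cutoff,
      within = within, alpha = alpha,
      min_subset_count = min_subset_count,
      enrichment_ff = enrichment_ff, match_method = match_method,
      seed = seed, n_records = length(records),
      package_version = as.character(utils::packageVersion("ffbench"))
    )
  ), class = "report_bundle")

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(paste0("<report_bundle> %d group(s), %d force field(s); ",
                     "%d energy rows, %d dropped record(s)\n"),
              length(x$groups), length(x$ff_ids), nrow(x$energy_table),
              nrow(x$dropped_records)))
  invisible(x)
}

#' Write a report bundle as CSV tables plus JSON metadata
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory (created if needed).
#' @return named vector of written file paths, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    files[[name]] <<- p
  }
  put(bundle$manifest, "groups.csv")
  put(bundle$dropped_records, "dropped_records.csv")
  put(bundle$energy_table, "energy_table.csv")
  put(bundle$metric_table, "geometry_metrics.csv")
  put(bundle$match_table, "match_report.csv")
  put(bundle$msd_table, "msd_per_molecule.csv")
  put(bundle$extrema$summary, "dde_extrema.csv")
  put(bundle$extrema$pathological, "pathological_rows.csv")
  put(bundle$within_table, "fraction_within.csv")
  for (f in bundle$ff_ids) {
    put(bundle$dde_histograms[[f]], sprintf("dde_histogram_%s.csv", f))
    put(bundle$scatter[[f]], sprintf("dde_tfd_scatter_%s.csv", f))
  }
  if (!is.null(bundle$enrichment)) {
    put(bundle$enrichment, "enrichment_report.csv")
    put(data.frame(key = bundle$high_tfd_keys), "high_tfd_molecules.csv")
  }
  meta_path <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(bundle$metadata, meta_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files[["metadata.json"]] <- meta_path
  invisible(files)
}
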