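# Parameter overrepresentation analysis: which force-field parameters are
# applied disproportionately often among molecules whose geometries deviate
# most from the QM reference (high TFD)? Proportions are compared with a
# one-sample Z-test, the full-set representation ratio playing the role of
# the population proportion.

#' Read a parameter-assignment table
#'
#' CSV with columns `molecule_key`, `parameter_id`, `class` (class in
#' bond / angle / proper torsion / improper torsion / vdW), or a JSON object
#' mapping molecule key to an array of `{id, class}` entries. Per-molecule
#' parameter sets are deduplicated: a parameter applied many times to one
#' molecule counts once for that molecule.
#'
#' @param path CSV or JSON file path.
#' @return object of class `parameter_assignment`: named list
#'   molecule key -> character vector of parameter ids, with attribute
#'   `classes` (named character vector parameter id -> class).
#' @export
read_assignments <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    df <- do.call(rbind, lapply(names(raw), function(k) {
      data.frame(
        molecule_key = k,
        parameter_id = vapply(raw[[k]], function(e) e$id, character(1)),
        class = vapply(raw[[k]], function(e) e$class, character(1)),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("molecule_key", "parameter_id", "class")
  if (!all(need %in% names(df))) {
    stop("assignment table needs columns: ", paste(need, collapse = ", "))
  }
  parameter_assignment(df)
}

#' Build a parameter assignment from a long data frame
#'
#' @param df data frame with columns `molecule_key`, `parameter_id`,
#'   `class`.
#' @return a `parameter_assignment` (see [read_assignments()]).
#' @export
parameter_assignment <- function(df) {
  classes <- tapply(df$class, df$parameter_id, function(x) x[1L])
  sets <- lapply(split(df$parameter_id, df$molecule_key), unique)
  structure(sets, classes = classes, class = "parameter_assignment")
}

#' Select molecules with high torsion fingerprint deviation
#'
#' A molecule enters the high-TFD subset when at least one of its analyzed
#' structures has TFD strictly above the cutoff (molecule-level TFD = max
#' over its structures). Keys are connectivity-distinct by construction.
#'
#' @param tfd_table data frame with columns `key` and `tfd` (one row per
#'   analyzed structure; pre-filter to one force field if desired).
#' @param cutoff TFD cutoff, default 0.12.
#' @return character vector of molecule keys.
#' @export
select_high_tfd_molecules <- function(tfd_table, cutoff = 0.12) {
  if (is.null(tfd_table) || nrow(tfd_table) == 0L) return(character())
  v <- tfd_table$tfd
  keep <- !is.na(v) & v > cutoff
  sort(unique(tfd_table$key[keep]))
}

#' Representation ratio of a parameter in a molecule set
#'
#' Fraction of molecules in the set that apply the parameter at least once;
#' multiplicity within a molecule is ignored.
#'
#' @param parameter_id parameter identifier.
#' @param keys molecule keys forming the set (non-empty).
#' @param assignment a `parameter_assignment`.
#' @return proportion in [0, 1].
#' @export
representation_ratio <- function(parameter_id, keys, assignment) {
  if (length(keys) == 0L) stop("empty molecule set")
  hits <- vapply(keys, function(k) parameter_id %in% assignment[[k]],
                 logical(1))
  mean(hits)
}

#' One-sample Z-test for a proportion
#'
#' `z = (p_hat - p0) / sqrt(p0 (1 - p0) / n)`, two-sided p-value from the
#' standard normal, and a Wald 95% (or `1 - alpha`) confidence interval
#' `p_hat +/- z_crit * sqrt(p_hat (1 - p_hat) / n)`.
#'
#' @param p_hat sample proportion.
#' @param p0 population proportion under the null (must be strictly inside
#'   (0, 1)).
#' @param n sample size.
#' @param alpha significance level for the confidence interval.
#' @return list `z`, `p_value`, `ci_low`, `ci_high`.
#' @export
proportion_z_test <- function(p_hat, p0, n, alpha = 0.05) {
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 1)
  if (p0 <= 0 || p0 >= 1) stop("degenerate null proportion p0")
  z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / n)
  half <- qnorm(1 - alpha / 2) * sqrt(p_hat * (1 - p_hat) / n)
  list(z = z,
       p_value = 2 * pnorm(-abs(z)),
       ci_low = p_hat - half,
       ci_high = p_hat + half)
}

#' Parameter enrichment report over a high-TFD subset
#'
#' For every parameter occurring in the full molecule set: the full-set
#' representation ratio (`p0`), the subset ratio (`p_hat`), the Z statistic
#' with two-sided p-value and Wald CI. Parameters applied by
#' `min_subset_count - 1` (default 20) or fewer subset molecules are
#' excluded from significance calls (`excluded_small_sample`). A parameter
#' is `significant` iff it is not excluded, its p-value is below `alpha`,
#' and it is overrepresented (`p_hat > p0`).
#'
#' @param assignment a `parameter_assignment`.
#' @param subset_keys high-TFD molecule keys (subset of `full_keys`).
#' @param full_keys all molecule keys in the analysis.
#' @param alpha significance level.
#' @param min_subset_count minimum number of subset molecules applying a
#'   parameter for it to be eligible (default 21, i.e. exclude at <= 20).
#' @return data frame: `parameter_id`, `class`, `ratio_full`,
#'   `ratio_subset`, `n_subset`, `n_applied_subset`, `z`, `p_value`,
#'   `ci_low`, `ci_high`, `excluded_small_sample`, `significant`.
#' @export
enrichment_report <- function(assignment, subset_keys, full_keys,
                              alpha = 0.05, min_subset_count = 21L) {
  if (!all(subset_keys %in% full_keys)) {
    stop("subset keys must be a subset of the full key set")
  }
  if (length(full_keys) == 0L) stop("empty full molecule set")
  params <- sort(unique(unlist(assignment[
    names(assignment) %in% full_keys])))
  classes <- attr(assignment, "classes")
  n_sub <- length(subset_keys)

  rows <- lapply(params, function(pid) {
    p0 <- representation_ratio(pid, full_keys, assignment)
    applied_sub <- if (n_sub > 0L) {
      sum(vapply(subset_keys, function(k) pid %in% assignment[[k]],
                 logical(1)))
    } else 0L
    p_hat <- if (n_sub > 0L) applied_sub / n_sub else NA_real_
    excluded <- applied_sub < min_subset_count
    if (!excluded && p0 > 0 && p0 < 1) {
      zt <- proportion_z_test(p_hat, p0, n_sub, alpha)
      signif <- !excluded && zt$p_value < alpha && p_hat > p0
    } else {
      zt <- list(z = NA_real_, p_value = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_)
      signif <- FALSE
      if (!excluded) excluded <- FALSE # degenerate p0: tested nowhere
    }
    data.frame(
      parameter_id = pid,
      class = unname(classes[pid]),
      ratio_full = p0,
      ratio_subset = p_hat,
      n_subset = n_sub,
      n_applied_subset = applied_sub,
      z = zt$z, p_value = zt$p_value,
      ci_low = zt$ci_low, ci_high = zt$ci_high,
      excluded_small_sample = excluded,
      significant = signif,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Default substructure outlier patterns
#'
#' Labeled-subgraph queries for moieties repeatedly found among benchmark
#' outliers: an N-N single bond and an azetidine ring (saturated 4-ring with
#' exactly one nitrogen).
#'
#' @return named list of `molecular_graph` patterns.
#' @export
default_substructure_patterns <- function() {
  list(
    "N-N" = molecular_graph(
      elements = c("N", "N"),
      bonds = data.frame(a1 = 1L, a2 = 2L, order = "1"),
      title = "N-N single bond"
    ),
    azetidine = molecular_graph(
      elements = c("N", "C", "C", "C"),
      bonds = data.frame(a1 = c(1L, 2L, 3L, 4L), a2 = c(2L, 3L, 4L, 1L),
                         order = "1"),
      title = "azetidine ring"
    )
  )
}

#' Tag molecules containing given substructures
#'
#' Subgraph-isomorphism search (VF2) on element and bond-order labels;
#' formal charges are ignored for pattern matching. Matches are non-induced:
#' the pattern's bonds must embed, extra bonds in the target are allowed.
#'
#' @param groups list of `molecule_group` objects (or of `molecular_graph`).
#' @param patterns named list of `molecular_graph` patterns; default
#'   [default_substructure_patterns()].
#' @return named list: molecule key (or graph title) -> character vector of
#'   matching pattern names (possibly empty).
#' @export
flag_substructures <- function(groups, patterns = NULL) {
  if (is.null(patterns)) patterns <- default_substructure_patterns()
  if (is.null(names(patterns)) || any(!nzchar(names(patterns)))) {
    stop("patterns must be a named list")
  }
  for (nm in names(patterns)) {
    if (!inherits(patterns[[nm]], "molecular_graph")) {
      stop("malformed pattern: ", nm)
    }
  }
  out <- list()
  for (g in groups) {
    graph <- if (inherits(g, "molecule_group")) g$records[[1L]]$graph else g
    key <- if (inherits(g, "molecule_group")) g$key else graph$title
    tags <- character()
    for (nm in names(patterns)) {
      if (has_substructure(graph, patterns[[nm]])) tags <- c(tags, nm)
    }
    out[[key]] <- tags
  }
  out
}

# element-only vertex colors from a dictionary shared by pattern and target
has_substructure <- function(graph, pattern) {
  dict <- sort(unique(c(graph$atoms$element, pattern$atoms$element)))
  if (!all(pattern$atoms$element %in% graph$atoms$element)) return(FALSE)
  vc_t <- match(graph$atoms$element, dict)
  vc_p <- match(pattern$atoms$element, dict)
  ec_t <- match(graph$bonds$order, .BOND_ORDERS)
  ec_p <- match(pattern$bonds$order, .BOND_ORDERS)
  igraph::subgraph_isomorphic(
    as_igraph(pattern), as_igraph(graph),
    method = "vf2",
    vertex.color1 = vc_t, vertex.color2 = vc_p,
    edge.color1 = ec_t, edge.color2 = ec_p
  )
}
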