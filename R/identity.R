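# Molecular identity: a canonical key for labeled graphs, record assembly
# from per-file ensembles, and grouping of structures into molecules.
# Tautomers differ in bond orders / H placement, hence get different keys and
# are analyzed as distinct molecules.

#' Canonical identity key of a molecular graph
#'
#' A text key invariant under atom relabeling: two graphs receive the same key
#' if and only if they are isomorphic as element / formal-charge /
#' bond-order(/stereo) labeled graphs. Built by canonical labeling (BLISS via
#' igraph) of an auxiliary colored graph in which every bond is subdivided by
#' a vertex colored with its order, so edge labels participate in the
#' canonical form.
#'
#' @param graph a `molecular_graph`.
#' @param use_stereo include per-atom stereo flags in the identity when any
#'   are set (`TRUE`, default, mirrors an isomeric-SMILES identity); `FALSE`
#'   ignores stereo flags entirely.
#' @return character scalar key.
#' @export
canonical_graph_key <- function(graph, use_stereo = TRUE) {
  stopifnot(inherits(graph, "molecular_graph"))
  if (!graph_is_connected(graph)) {
    stop("disconnected graph: multi-molecule records unsupported")
  }
  n <- n_atoms(graph)
  b <- graph$bonds
  m <- nrow(b)

  stereo <- graph$atoms$stereo
  if (!use_stereo || all(is.na(stereo))) stereo <- rep("", n)
  stereo[is.na(stereo)] <- ""
  atom_lab <- paste0("A:", graph$atoms$element, ":", graph$atoms$charge,
                     ":", stereo)
  bond_lab <- if (m > 0L) paste0("B:", b$order) else character()
  labels <- c(atom_lab, bond_lab)

  # auxiliary graph: atoms 1..n, bond-vertex n+k adjacent to its endpoints
  if (m > 0L) {
    edges <- rbind(cbind(b$a1, n + seq_len(m)), cbind(b$a2, n + seq_len(m)))
  } else {
    edges <- matrix(integer(), ncol = 2L)
  }
  g <- igraph::make_empty_graph(n = n + m, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))

  # color integers by rank of the label string: isomorphic graphs share the
  # label multiset, so ranks are consistent across graphs
  colors <- as.integer(factor(labels, levels = sort(unique(labels))))
  cp <- igraph::canonical_permutation(g, colors = colors)
  gc <- igraph::permute(g, cp$labeling)

  lab_c <- character(n + m)
  lab_c[cp$labeling] <- labels
  el <- igraph::as_edgelist(gc, names = FALSE)
  el <- el[order(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L])), ,
           drop = FALSE]
  paste0(
    paste(lab_c, collapse = "|"), "||",
    paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]),
          sep = "-", collapse = ",")
  )
}

#' Assemble structure records from QM and per-force-field ensembles
#'
#' Aligns one QM ensemble with one ensemble per force field. Alignment is by
#' record title when titles are unique on both sides, falling back to record
#' order when every file has the same length; any other situation is an
#' error, not a guess. FF files may omit records (a structure that failed for
#' that force field) only under title alignment.
#'
#' @param qm_entries list from [read_conformer_sdf()] for the QM file.
#' @param ff_entries named list (one element per force field) of lists from
#'   [read_conformer_sdf()].
#' @return list of `structure_record`.
#' @export
build_records <- function(qm_entries, ff_entries) {
  stopifnot(is.list(ff_entries))
  if (length(ff_entries) > 0L && is.null(names(ff_entries))) {
    stop("ff_entries must be a named list (force-field id -> entries)")
  }
  qm_titles <- vapply(qm_entries, function(e) e$graph$title, character(1))
  by_title <- !anyDuplicated(qm_titles) && all(nzchar(qm_titles))

  records <- vector("list", length(qm_entries))
  for (i in seq_along(qm_entries)) {
    qe <- qm_entries[[i]]
    ff <- list()
    for (nm in names(ff_entries)) {
      fe <- ff_entries[[nm]]
      if (by_title) {
        ft <- vapply(fe, function(e) e$graph$title, character(1))
        if (anyDuplicated(ft[nzchar(ft)])) {
          stop("duplicate titles in force-field file ", nm)
        }
        j <- match(qm_titles[i], ft)
      } else {
        if (length(fe) != length(qm_entries)) {
          stop("cannot align force-field file ", nm,
               ": titles unusable and record counts differ")
        }
        j <- i
      }
      if (!is.na(j)) {
        cf <- fe[[j]]$conformer
        cf$source <- nm
        ff[[nm]] <- cf
      }
    }
    qc <- qe$conformer
    qc$source <- "QM"
    records[[i]] <- structure_record(qe$graph, qc, ff)
  }
  records
}

#' Group structure records into molecules by canonical identity
#'
#' Partitions records by [canonical_graph_key()] of the graph attached to the
#' QM-optimized geometry. Records whose `ff_results` lack any dataset-wide
#' force field are dropped and reported (the benchmark analyzes only
#' structures with results for all force fields). Each group's reference
#' conformer is the member with minimal QM energy (ties broken by lowest
#' input index).
#'
#' @param records list of `structure_record`.
#' @param ff_ids dataset-wide force-field ids; default: union over records.
#' @param use_stereo passed to [canonical_graph_key()].
#' @return list of `molecule_group` objects (fields `key`, `records`,
#'   `titles`, `reference_index`, `indices` into the input), with attribute
#'   `dropped`: data frame of dropped record indices and the missing ids.
#' @export
group_by_identity <- function(records, ff_ids = NULL, use_stereo = TRUE) {
  if (length(records) == 0L) {
    out <- list()
    attr(out, "dropped") <- data.frame(index = integer(),
                                       missing = character())
    return(out)
  }
  if (is.null(ff_ids)) {
    ff_ids <- sort(unique(unlist(lapply(records,
                                        function(r) names(r$ff_results)))))
  }
  missing <- vapply(records, function(r) {
    paste(setdiff(ff_ids, names(r$ff_results)), collapse = ";")
  }, character(1))
  keep <- !nzchar(missing)
  dropped <- data.frame(index = which(!keep), missing = missing[!keep],
                        stringsAsFactors = FALSE)

  kept_idx <- which(keep)
  keys <- vapply(records[kept_idx],
                 function(r) canonical_graph_key(r$graph, use_stereo),
                 character(1))
  out <- list()
  for (k in unique(keys)) {
    sel <- kept_idx[keys == k]
    qm_e <- vapply(records[sel], function(r) r$qm$energy, numeric(1))
    ref <- which.min(qm_e) # which.min takes the first on ties
    out[[length(out) + 1L]] <- structure(
      list(key = k,
           records = records[sel],
           titles = vapply(records[sel], function(r) r$graph$title,
                           character(1)),
           reference_index = ref,
           indices = sel),
      class = "molecule_group"
    )
  }
  attr(out, "dropped") <- dropped
  attr(out, "ff_ids") <- ff_ids
  out
}

#' @export
print.molecule_group <- function(x, ...) {
  cat(sprintf("<molecule_group> %d record(s), reference #%d (%s)\n",
              length(x$records), x$reference_index,
              x$titles[x$reference_index]))
  invisible(x)
}

#' Export a molecule-group manifest
#'
#' @param groups result of [group_by_identity()].
#' @param path optional CSV output path.
#' @return data frame with columns `key`, `n_records`, `reference_title`.
#' @export
group_manifest <- function(groups, path = NULL) {
  df <- data.frame(
    key = vapply(groups, function(g) g$key, character(1)),
    n_records = vapply(groups, function(g) length(g$records), integer(1)),
    reference_title = vapply(groups,
                             function(g) g$titles[g$reference_index],
                             character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
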