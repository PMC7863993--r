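# Torsion fingerprint deviation (TFD): a weighted, normalized torsion-angle
# disagreement between two conformers of one graph, in [0, 1]. The recipe —
# torsion selection, symmetry periods, ring pseudo-torsions, Gaussian
# distance weights — is fully fixed here and documented in the vignette;
# published TFD implementations differ in these choices, so numeric equality
# with them is not claimed.

#' Build the torsion set of a molecular graph
#'
#' One dihedral entry per non-ring, non-terminal bond (representative end
#' atoms picked by highest atomic number, ties by lowest index) and one
#' ring pseudo-torsion entry per ring system (fused rings sharing bonds form
#' one system). Each entry carries a symmetry period: `360 / k` degrees when
#' one end of the central bond bears `k >= 2` identical terminal substituents
#' (e.g. 120 for a methyl), else 360; ring entries use 360. Weights are
#' Gaussian in the topological distance of the entry's central bond from the
#' center of the bond graph (line graph), `w ~ exp(-d^2 / (2 sigma^2))` with
#' `sigma = max(1, bond-graph radius)`, normalized to sum to 1.
#'
#' @param graph a `molecular_graph`.
#' @return object of class `torsion_set`: list of entries (`type`,
#'   `quad`/`quads`, `period`, `weight`, `central_bond`). Empty (zero
#'   entries) for graphs without torsions; TFD is then undefined.
#' @export
build_torsion_set <- function(graph) {
  n <- n_atoms(graph)
  b <- graph$bonds
  deg <- graph_degrees(graph)
  nb <- graph_neighbors(graph)
  g <- as_igraph(graph)

  m <- nrow(b)
  entries <- list()
  if (m > 0L) {
    bridge_ids <- as.integer(igraph::bridges(g))
    is_ring_bond <- !(seq_len(m) %in% bridge_ids)

    # --- dihedral entries: non-ring bonds with both ends non-terminal
    for (k in which(!is_ring_bond)) {
      u <- b$a1[k]; v <- b$a2[k]
      if (deg[u] < 2L || deg[v] < 2L) next
      a_end <- pick_end_atom(graph, nb, u, exclude = v)
      d_end <- pick_end_atom(graph, nb, v, exclude = u)
      entries[[length(entries) + 1L]] <- list(
        type = "dihedral",
        quad = c(a_end, u, v, d_end),
        period = torsion_period(graph, nb, deg, u, v),
        central_bond = k
      )
    }

    # --- ring pseudo-torsion entries: one per ring system
    if (any(is_ring_bond)) {
      rg <- igraph::subgraph_from_edges(g, which(is_ring_bond),
                                        delete.vertices = FALSE)
      comp <- igraph::components(rg)
      ring_atom_sets <- split(seq_len(n), comp$membership)
      ring_atom_sets <- Filter(function(s) length(s) >= 3L, ring_atom_sets)
      for (atoms in ring_atom_sets) {
        quads <- ring_system_quads(b, is_ring_bond, atoms)
        if (length(quads) == 0L) next
        sys_bonds <- which(is_ring_bond &
                             b$a1 %in% atoms & b$a2 %in% atoms)
        entries[[length(entries) + 1L]] <- list(
          type = "ring",
          quads = quads,
          period = 360,
          central_bond = sys_bonds # representative chosen at weighting time
        )
      }
    }
  }

  if (length(entries) == 0L) {
    return(structure(list(entries = list(), graph = graph),
                     class = "torsion_set"))
  }

  # --- Gaussian weights in bond-graph (line-graph) topological distance
  lg <- igraph::make_line_graph(g)
  dmat <- igraph::distances(lg)
  ecc <- apply(dmat, 1L, max)
  radius <- min(ecc)
  centers <- which(ecc == radius)
  sigma <- max(1, radius)
  w <- vapply(entries, function(e) {
    d <- min(dmat[e$central_bond, centers, drop = FALSE])
    exp(-d^2 / (2 * sigma^2))
  }, numeric(1))
  w <- w / sum(w)
  for (i in seq_along(entries)) entries[[i]]$weight <- w[i]

  structure(list(entries = entries, graph = graph), class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("<torsion_set> %d entr%s\n", length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies"))
  invisible(x)
}

# representative end atom: highest atomic number, then lowest index
pick_end_atom <- function(graph, nb, atom, exclude) {
  cand <- setdiff(nb[[atom]], exclude)
  z <- atomic_number(graph$atoms$element[cand])
  cand[order(-z, cand)][1L]
}

# symmetry period of the torsion about bond u-v from terminal-group topology:
# k identical terminal substituents on one end give a 360/k-degree period
torsion_period <- function(graph, nb, deg, u, v) {
  fold_of <- function(center, partner) {
    subs <- setdiff(nb[[center]], partner)
    if (length(subs) < 2L) return(1L)
    if (any(deg[subs] != 1L)) return(1L)
    lab <- paste0(graph$atoms$element[subs], ":", graph$atoms$charge[subs])
    if (length(unique(lab)) == 1L) length(subs) else 1L
  }
  fold <- max(fold_of(u, v), fold_of(v, u))
  360 / fold
}

# all a-b-c-d quadruples whose three consecutive bonds are ring bonds of one
# ring system, deduplicated against reversal
ring_system_quads <- function(bonds, is_ring_bond, atoms) {
  rb <- bonds[is_ring_bond & bonds$a1 %in% atoms & bonds$a2 %in% atoms, ,
              drop = FALSE]
  adj <- list()
  for (k in seq_len(nrow(rb))) {
    u <- as.character(rb$a1[k]); v <- as.character(rb$a2[k])
    adj[[u]] <- c(adj[[u]], rb$a2[k])
    adj[[v]] <- c(adj[[v]], rb$a1[k])
  }
  quads <- list()
  seen <- character()
  for (bidx in seq_len(nrow(rb))) {
    bb <- rb$a1[bidx]; cc <- rb$a2[bidx]
    for (aa in setdiff(adj[[as.character(bb)]], cc)) {
      for (dd in setdiff(adj[[as.character(cc)]], bb)) {
        if (aa == dd) next
        key <- paste(min(aa, dd), bb, cc, max(aa, dd))
        rkey <- paste(min(aa, dd), cc, bb, max(aa, dd))
        if (key %in% seen || rkey %in% seen) next
        seen <- c(seen, key)
        quads[[length(quads) + 1L]] <- c(aa, bb, cc, dd)
      }
    }
  }
  quads
}

#' Torsion fingerprint deviation between two conformers
#'
#' `sum_i w_i * dev_i` with, for a dihedral entry of period `P`,
#' `dev = min(|dtheta| mod P, P - |dtheta| mod P) / (P / 2)` where `dtheta`
#' is the wrapped angle difference; for a ring entry the mean signed wrapped
#' deviation over the ring system's internal dihedrals is treated the same
#' way with `P = 360`. The score lies in [0, 1], is 0 for identical internal
#' torsions, and is invariant to rigid motions. Colinear (degenerate)
#' quadruples contribute deviation 0 with a warning.
#'
#' @param torsion_set result of [build_torsion_set()].
#' @param conf_a,conf_b `conformer` objects or N x 3 matrices on the set's
#'   graph.
#' @return TFD score in [0, 1].
#' @export
tfd <- function(torsion_set, conf_a, conf_b) {
  stopifnot(inherits(torsion_set, "torsion_set"))
  if (length(torsion_set$entries) == 0L) {
    stop("TFD undefined: torsion set is empty")
  }
  a <- if (inherits(conf_a, "conformer")) conf_a$coords else as.matrix(conf_a)
  b <- if (inherits(conf_b, "conformer")) conf_b$coords else as.matrix(conf_b)
  n <- n_atoms(torsion_set$graph)
  if (nrow(a) != n || nrow(b) != n) stop("conformer atom count mismatch")

  degen <- FALSE
  score <- 0
  for (e in torsion_set$entries) {
    if (e$type == "dihedral") {
      ta <- dihedral_angle(a, e$quad)
      tb <- dihedral_angle(b, e$quad)
      if (is.na(ta) || is.na(tb)) { degen <- TRUE; next }
      dev <- periodic_deviation(ta - tb, e$period)
    } else {
      ds <- vapply(e$quads, function(q) {
        ta <- dihedral_angle(a, q)
        tb <- dihedral_angle(b, q)
        if (is.na(ta) || is.na(tb)) NA_real_ else wrap_angle(ta - tb)
      }, numeric(1))
      if (anyNA(ds)) { degen <- TRUE; ds <- ds[!is.na(ds)] }
      if (length(ds) == 0L) next
      dev <- periodic_deviation(mean(ds), 360)
    }
    score <- score + e$weight * dev
  }
  if (degen) {
    warning("degenerate (colinear) torsion quadruple; contributed 0")
  }
  min(max(score, 0), 1)
}

# normalized periodic deviation in [0, 1]
periodic_deviation <- function(dtheta, period) {
  r <- abs(dtheta) %% period
  min(r, period - r) / (period / 2)
}
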