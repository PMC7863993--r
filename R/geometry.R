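# Geometric agreement between conformers of one graph: least-squares rigid
# superposition (Kabsch, proper rotations only) minimized over the graph's
# automorphism group.

#' Least-squares rigid superposition of two point sets
#'
#' Kabsch algorithm: the optimal proper rotation and translation aligning
#' `coords_b` onto `coords_a` under a fixed atom correspondence. Reflections
#' are excluded.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom).
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3), `translation`
#'   (length 3); `coords_b %*% rotation` then adding `translation` rowwise
#'   reproduces the alignment.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L) {
    stop("coordinate matrices must be N x 3 with equal atom counts")
  }
  n <- nrow(a)
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2L, ca); bc <- sweep(b, 2L, cb)
  s <- svd(crossprod(bc, ac)) # t(bc) %*% ac
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  resid <- ac - bc %*% rot
  list(
    rmsd = sqrt(sum(resid^2) / n),
    rotation = rot,
    translation = ca - as.vector(cb %*% rot)
  )
}

# integer colors shared across both sides of an isomorphism test; computed
# from label ranks (consistent for graphs with equal label multisets)
.atom_colors <- function(graph) {
  lab <- paste0(graph$atoms$element, ":", graph$atoms$charge)
  as.integer(factor(lab, levels = sort(unique(lab))))
}

.bond_colors <- function(graph) {
  if (nrow(graph$bonds) == 0L) return(integer())
  as.integer(factor(graph$bonds$order, levels = .BOND_ORDERS))
}

#' Enumerate graph automorphisms
#'
#' All atom permutations preserving element, formal charge and bond order
#' (VF2). The identity permutation is always first. If more than `cap`
#' automorphisms exist, the result is truncated and carries attribute
#' `truncated = TRUE`; the identity is retained so downstream minima remain
#' valid upper bounds.
#'
#' @param graph a `molecular_graph`.
#' @param cap maximum number of permutations returned (default 10000).
#' @return list of integer permutations `p` (atom `i` maps to `p[i]`), with
#'   attribute `truncated`.
#' @export
enumerate_automorphisms <- function(graph, cap = 10000L) {
  stopifnot(cap >= 1L)
  n <- n_atoms(graph)
  g <- as_igraph(graph)
  vc <- .atom_colors(graph)
  ec <- .bond_colors(graph)
  isos <- igraph::graph.get.isomorphisms.vf2(
    g, g,
    vertex.color1 = vc, vertex.color2 = vc,
    edge.color1 = ec, edge.color2 = ec
  )
  perms <- lapply(isos, function(p) as.integer(p))
  is_id <- vapply(perms, function(p) all(p == seq_len(n)), logical(1))
  perms <- c(perms[is_id], perms[!is_id])
  truncated <- length(perms) > cap
  if (truncated) perms <- perms[seq_len(cap)]
  attr(perms, "truncated") <- truncated
  perms
}

#' Symmetry-aware minimum RMSD between two conformers
#'
#' Minimum over the graph's automorphisms of the Kabsch RMSD, i.e. the lowest
#' possible RMSD over rigid motions and symmetry-related atom relabelings.
#' Hydrogens are included by default.
#'
#' @param graph shared `molecular_graph`.
#' @param conf_a,conf_b `conformer` objects (or bare N x 3 matrices) on
#'   `graph`.
#' @param include_hydrogens include hydrogen atoms (default `TRUE`).
#' @param automorphisms optional precomputed result of
#'   [enumerate_automorphisms()] (cache across calls on the same graph).
#' @param cap automorphism cap when enumerating here.
#' @return RMSD in Angstrom; attribute `upper_bound = TRUE` when the
#'   automorphism enumeration was truncated.
#' @export
best_rmsd <- function(graph, conf_a, conf_b, include_hydrogens = TRUE,
                      automorphisms = NULL, cap = 10000L) {
  a <- if (inherits(conf_a, "conformer")) conf_a$coords else as.matrix(conf_a)
  b <- if (inherits(conf_b, "conformer")) conf_b$coords else as.matrix(conf_b)
  n <- n_atoms(graph)
  if (nrow(a) != n || nrow(b) != n) {
    stop("conformer atom count does not match graph")
  }
  if (is.null(automorphisms)) {
    automorphisms <- enumerate_automorphisms(graph, cap = cap)
  }
  sel <- if (include_hydrogens) seq_len(n) else
    which(graph$atoms$element != "H")
  if (length(sel) == 0L) stop("no atoms selected")

  m <- length(automorphisms)
  if (m <= 8L) {
    best <- Inf
    for (p in automorphisms) {
      # under p, the counterpart of atom i in conf_b is atom p[i]
      r <- kabsch_superpose(a[sel, , drop = FALSE],
                            b[p[sel], , drop = FALSE])
      if (r$rmsd < best) best <- r$rmsd
    }
  } else {
    # screen all automorphisms with a vectorized closed-form Kabsch RMSD
    # (analytic singular values of the 3x3 cross-covariances), then settle
    # the leaders with the exact SVD path
    approx <- rmsd_over_perms(a, b, automorphisms, sel)
    ord <- order(approx)
    cand <- ord[approx[ord] <= approx[ord[1L]] + 1e-6]
    cand <- cand[seq_len(min(length(cand), 16L))]
    best <- Inf
    for (ci in cand) {
      p <- automorphisms[[ci]]
      r <- kabsch_superpose(a[sel, , drop = FALSE],
                            b[p[sel], , drop = FALSE])
      if (r$rmsd < best) best <- r$rmsd
    }
  }
  if (isTRUE(attr(automorphisms, "truncated"))) {
    attr(best, "upper_bound") <- TRUE
  }
  best
}

# Kabsch RMSD of a[sel,] against b[p[sel],] for every permutation p at once.
# Automorphisms map the selected (element-preserved) atom subset onto itself,
# so the centroid of the permuted b-subset is constant and the
# cross-covariance C_p can be assembled for all p with 9 matrix-vector
# products. Singular values come from the trigonometric closed form for the
# eigenvalues of the symmetric 3x3 C^T C.
rmsd_over_perms <- function(a, b, perms, sel) {
  ns <- length(sel)
  ac <- sweep(a[sel, , drop = FALSE], 2L,
              colMeans(a[sel, , drop = FALSE]))
  ssa <- sum(ac^2)
  bc <- sweep(b, 2L, colMeans(b[sel, , drop = FALSE]))
  ssb <- sum(bc[sel, , drop = FALSE]^2)
  m <- length(perms)
  P <- matrix(0L, m, ns)
  for (i in seq_len(m)) P[i, ] <- perms[[i]][sel]

  cc <- vector("list", 9L) # cc[[3*(i-1)+j]] = C_p[i, j] across p
  for (i in 1:3) {
    Xi <- matrix(bc[, i][P], m, ns)
    for (j in 1:3) cc[[3L * (i - 1L) + j]] <- as.vector(Xi %*% ac[, j])
  }
  c11 <- cc[[1]]; c12 <- cc[[2]]; c13 <- cc[[3]]
  c21 <- cc[[4]]; c22 <- cc[[5]]; c23 <- cc[[6]]
  c31 <- cc[[7]]; c32 <- cc[[8]]; c33 <- cc[[9]]

  detC <- c11 * (c22 * c33 - c23 * c32) -
    c12 * (c21 * c33 - c23 * c31) +
    c13 * (c21 * c32 - c22 * c31)

  # M = C^T C (symmetric): column dot products
  m11 <- c11^2 + c21^2 + c31^2
  m22 <- c12^2 + c22^2 + c32^2
  m33 <- c13^2 + c23^2 + c33^2
  m12 <- c11 * c12 + c21 * c22 + c31 * c32
  m13 <- c11 * c13 + c21 * c23 + c31 * c33
  m23 <- c12 * c13 + c22 * c23 + c32 * c33

  q <- (m11 + m22 + m33) / 3
  p2 <- (m11 - q)^2 + (m22 - q)^2 + (m33 - q)^2 +
    2 * (m12^2 + m13^2 + m23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  safe_p <- ifelse(p > 0, p, 1)
  b11 <- (m11 - q) / safe_p; b22 <- (m22 - q) / safe_p
  b33 <- (m33 - q) / safe_p
  b12 <- m12 / safe_p; b13 <- m13 / safe_p; b23 <- m23 / safe_p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  s1 <- sqrt(pmax(l1, 0)); s2 <- sqrt(pmax(l2, 0)); s3 <- sqrt(pmax(l3, 0))
  trace <- s1 + s2 + sign(detC) * s3 # s3 is the smallest
  sqrt(pmax(0, (ssa + ssb - 2 * trace) / ns))
}

#' Dihedral angle of four points
#'
#' Signed torsion angle about the b-c axis, in degrees wrapped to
#' (-180, 180]. Colinear quadruples (undefined dihedral) return `NA`.
#'
#' @param coords N x 3 matrix.
#' @param quad integer vector of four atom indices (a, b, c, d).
#' @return angle in degrees, or `NA` for a degenerate quadruple.
#' @export
dihedral_angle <- function(coords, quad) {
  p <- coords[quad, , drop = FALSE]
  b1 <- p[2L, ] - p[1L, ]
  b2 <- p[3L, ] - p[2L, ]
  b3 <- p[4L, ] - p[3L, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# wrap to (-180, 180]
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}
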