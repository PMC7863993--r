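# Fixture builders and independent brute-force oracles. The oracles never
# share code paths with the implementation they check: automorphisms come
# from filtering all n! permutations, isomorphism from exhaustive search,
# and the symmetry-aware RMSD oracle from looping the exact Kabsch
# superposition over the brute-force automorphism list.

# ---- toy molecules -------------------------------------------------------

water_graph <- function() {
  molecular_graph(c("O", "H", "H"),
                  data.frame(a1 = 1L, a2 = 2:3, order = "1"),
                  title = "water")
}

ethane_graph <- function() {
  molecular_graph(c("C", "C", rep("H", 6)),
                  data.frame(a1 = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
                             a2 = c(2L, 3L, 4L, 5L, 6L, 7L, 8L),
                             order = "1"),
                  title = "ethane")
}

ethane_coords <- function() {
  # staggered-ish geometry, bond lengths roughly physical
  rbind(c(0, 0, 0), c(1.54, 0, 0),
        c(-0.5, 1.0, 0), c(-0.5, -0.5, 0.9), c(-0.5, -0.5, -0.9),
        c(2.04, 1.0, 0), c(2.04, -0.5, 0.9), c(2.04, -0.5, -0.9))
}

benzene_graph <- function() {
  molecular_graph(c(rep("C", 6), rep("H", 6)),
                  rbind(data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = "ar"),
                        data.frame(a1 = 1:6, a2 = 7:12, order = "1")),
                  title = "benzene")
}

benzene_coords <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  rbind(cbind(1.4 * cos(ang), 1.4 * sin(ang), 0),
        cbind(2.4 * cos(ang), 2.4 * sin(ang), 0))
}

# heavy-atom butane chain: exactly one torsion entry (period 360)
butane_chain <- function() {
  molecular_graph(rep("C", 4),
                  data.frame(a1 = 1:3, a2 = 2:4, order = "1"),
                  title = "butane-chain")
}

butane_coords <- function(theta = 60) {
  # dihedral about the 2-3 bond equals theta degrees (theta = 0 is cis)
  th <- theta * pi / 180
  rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0),
        c(1.5, cos(th), sin(th)))
}

# keto and enol tautomers of the same formula (C2H4O)
keto_graph <- function() {
  molecular_graph(c("C", "O", "C", "H", "H", "H", "H"),
                  data.frame(a1 = c(1L, 1L, 3L, 3L, 3L, 1L),
                             a2 = c(2L, 3L, 4L, 5L, 6L, 7L),
                             order = c("2", "1", "1", "1", "1", "1")),
                  title = "keto")
}

enol_graph <- function() {
  molecular_graph(c("C", "O", "C", "H", "H", "H", "H"),
                  data.frame(a1 = c(1L, 1L, 3L, 3L, 2L, 1L),
                             a2 = c(2L, 3L, 4L, 5L, 6L, 7L),
                             order = c("1", "2", "1", "1", "1", "1")),
                  title = "enol")
}

hydrazine_graph <- function() {
  molecular_graph(c("N", "N", "H", "H", "H", "H"),
                  data.frame(a1 = c(1L, 1L, 1L, 2L, 2L),
                             a2 = c(2L, 3L, 4L, 5L, 6L),
                             order = "1"),
                  title = "hydrazine")
}

azetidine_toy_graph <- function() {
  # azetidine ring with a methyl substituent (heavy atoms only)
  molecular_graph(c("N", "C", "C", "C", "C"),
                  data.frame(a1 = c(1L, 2L, 3L, 4L, 2L),
                             a2 = c(2L, 3L, 4L, 1L, 5L),
                             order = "1"),
                  title = "azetidine-toy")
}

# ---- random structures ---------------------------------------------------

random_labeled_graph <- function(n, elements = c("C", "N", "O", "S"),
                                 extra_edge_prob = 0.4) {
  el <- sample(elements, n, replace = TRUE)
  bonds <- data.frame(
    a1 = vapply(seq_len(n - 1L), function(i) sample.int(i, 1L), integer(1)),
    a2 = 2:n,
    order = sample(c("1", "2"), n - 1L, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (n >= 4L && runif(1L) < extra_edge_prob) {
    have <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    cand <- which(upper.tri(diag(n)), arr.ind = TRUE)
    cand <- cand[!(paste(cand[, 1L], cand[, 2L]) %in% have), , drop = FALSE]
    if (nrow(cand) > 0L) {
      k <- sample.int(nrow(cand), 1L)
      bonds <- rbind(bonds, data.frame(a1 = cand[k, 1L], a2 = cand[k, 2L],
                                       order = "1"))
    }
  }
  molecular_graph(el, bonds)
}

relabel_graph <- function(graph, perm) {
  # perm maps old index -> new index
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  b <- graph$bonds
  molecular_graph(graph$atoms$element[inv],
                  data.frame(a1 = perm[b$a1], a2 = perm[b$a2],
                             order = b$order),
                  charges = graph$atoms$charge[inv],
                  stereo = graph$atoms$stereo[inv],
                  title = graph$title)
}

random_conformer_coords <- function(n) {
  matrix(rnorm(n * 3, sd = 2), n, 3L)
}

random_rigid_transform <- function(coords) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  sweep(coords %*% q, 2L, rnorm(3, sd = 5), "+")
}

# ---- brute-force oracles -------------------------------------------------

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# adjacency code matrix: entry (i, j) = bond-order code, 0 if unbonded
adjacency_codes <- function(graph) {
  n <- n_atoms(graph)
  B <- matrix(0L, n, n)
  code <- match(graph$bonds$order, c("1", "2", "3", "ar"))
  B[cbind(graph$bonds$a1, graph$bonds$a2)] <- code
  B[cbind(graph$bonds$a2, graph$bonds$a1)] <- code
  B
}

brute_automorphisms <- function(graph) {
  n <- n_atoms(graph)
  P <- all_perms(n)
  lab <- paste0(graph$atoms$element, ":", graph$atoms$charge)
  li <- as.integer(factor(lab))
  B <- adjacency_codes(graph)
  keep <- vapply(seq_len(nrow(P)), function(r) {
    p <- P[r, ]
    all(li[p] == li) && all(B[p, p] == B)
  }, logical(1))
  lapply(which(keep), function(r) as.integer(P[r, ]))
}

brute_isomorphic <- function(g1, g2) {
  n <- n_atoms(g1)
  if (n_atoms(g2) != n) return(FALSE)
  lab1 <- paste0(g1$atoms$element, ":", g1$atoms$charge)
  lab2 <- paste0(g2$atoms$element, ":", g2$atoms$charge)
  if (!identical(sort(lab1), sort(lab2))) return(FALSE)
  l1 <- as.integer(factor(lab1, levels = sort(unique(c(lab1, lab2)))))
  l2 <- as.integer(factor(lab2, levels = sort(unique(c(lab1, lab2)))))
  B1 <- adjacency_codes(g1)
  B2 <- adjacency_codes(g2)
  P <- all_perms(n)
  for (r in seq_len(nrow(P))) {
    p <- P[r, ] # map g1 atom i -> g2 atom p[i]
    if (all(l2[p] == l1) && all(B2[p, p] == B1)) return(TRUE)
  }
  FALSE
}

oracle_best_rmsd <- function(graph, a, b) {
  min(vapply(brute_automorphisms(graph), function(p) {
    kabsch_superpose(a, b[p, , drop = FALSE])$rmsd
  }, numeric(1)))
}

# small record builder: shared graph/coords, chosen energies
make_energy_group <- function(qm_energies, ff_energies, ff_id = "ffx") {
  g <- water_graph()
  co <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  recs <- lapply(seq_along(qm_energies), function(i) {
    gi <- g
    gi$title <- sprintf("rec%02d", i)
    ffs <- lapply(ff_energies, function(fe) {
      conformer(co, fe[i], source = ff_id, allow_nonfinite = TRUE)
    })
    structure_record(gi, conformer(co, qm_energies[i]), ffs)
  })
  groups <- group_by_identity(recs)
  groups[[1L]]
}
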