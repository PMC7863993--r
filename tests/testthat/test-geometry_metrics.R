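# Kabsch superposition, automorphism enumeration, symmetry-aware RMSD, TFD

test_that("kabsch_superpose satisfies identity, rigid invariance, hand case", {
  set.seed(1)
  a <- random_conformer_coords(6)
  expect_equal(kabsch_superpose(a, a)$rmsd, 0, tolerance = 1e-10)
  b <- random_rigid_transform(a)
  r <- kabsch_superpose(a, b)
  expect_lt(r$rmsd, 1e-6)
  # returned transform reproduces the alignment
  realigned <- sweep(b %*% r$rotation, 2L, r$translation, "+")
  expect_equal(sqrt(sum((a - realigned)^2) / nrow(a)), r$rmsd,
               tolerance = 1e-9)
  # hand-derived: two points 2 apart vs 4 apart -> rmsd exactly 1
  expect_equal(kabsch_superpose(rbind(c(0, 0, 0), c(2, 0, 0)),
                                rbind(c(0, 0, 0), c(4, 0, 0)))$rmsd,
               1.0, tolerance = 1e-12)
  expect_error(kabsch_superpose(a, a[1:3, ]), "equal atom counts")
})

test_that("automorphism enumeration matches the brute-force oracle", {
  # oracle: filter all n! permutations on labels and adjacency codes
  expect_length(enumerate_automorphisms(water_graph()), 2L)
  expect_length(brute_automorphisms(water_graph()), 2L)

  benz_core <- molecular_graph(rep("C", 6),
                               data.frame(a1 = 1:6, a2 = c(2:6, 1L),
                                          order = "ar"))
  expect_length(enumerate_automorphisms(benz_core), 12L)
  expect_length(brute_automorphisms(benz_core), 12L)

  chain <- molecular_graph(c("C", "N", "O"),
                           data.frame(a1 = 1:2, a2 = 2:3, order = "1"))
  expect_length(enumerate_automorphisms(chain), 1L)

  set.seed(33)
  for (i in 1:10) {
    g <- random_labeled_graph(sample(4:7, 1L))
    got <- enumerate_automorphisms(g)
    want <- brute_automorphisms(g)
    expect_identical(
      sort(vapply(got, paste, character(1), collapse = ",")),
      sort(vapply(want, paste, character(1), collapse = ","))
    )
    expect_identical(got[[1L]], seq_len(n_atoms(g))) # identity first
  }
})

test_that("automorphism cap truncates with identity retained", {
  full <- enumerate_automorphisms(ethane_graph())
  expect_length(full, 72L) # 2 (C swap) x 3! x 3! hydrogen permutations
  capped <- enumerate_automorphisms(ethane_graph(), cap = 5L)
  expect_length(capped, 5L)
  expect_true(attr(capped, "truncated"))
  expect_identical(capped[[1L]], 1:8)
  r <- best_rmsd(ethane_graph(), ethane_coords(),
                 ethane_coords() + 0.1, automorphisms = capped)
  expect_true(isTRUE(attr(r, "upper_bound")))
})

test_that("best_rmsd absorbs symmetry swaps and matches the oracle", {
  g <- ethane_graph()
  co <- ethane_coords()
  swapped <- co[c(1, 2, 4, 3, 5, 6, 7, 8), ] # swap two equivalent hydrogens
  expect_lt(best_rmsd(g, co, swapped), 1e-9)

  set.seed(44)
  for (i in 1:5) {
    pert <- co + matrix(rnorm(24, 0, 0.2), 8, 3)
    expect_equal(as.numeric(best_rmsd(g, co, pert)),
                 oracle_best_rmsd(g, co, pert), tolerance = 1e-8)
  }

  # asymmetric molecule: symmetry-aware equals plain Kabsch
  chain <- molecular_graph(c("C", "N", "O"),
                           data.frame(a1 = 1:2, a2 = 2:3, order = "1"))
  a <- random_conformer_coords(3)
  b <- random_conformer_coords(3)
  expect_equal(as.numeric(best_rmsd(chain, a, b)),
               kabsch_superpose(a, b)$rmsd, tolerance = 1e-12)
})

test_that("best_rmsd is symmetric, bounded by fixed-correspondence Kabsch", {
  set.seed(55)
  for (i in 1:8) {
    g <- random_labeled_graph(sample(4:7, 1L))
    a <- random_conformer_coords(n_atoms(g))
    b <- random_conformer_coords(n_atoms(g))
    r_ab <- as.numeric(best_rmsd(g, a, b))
    r_ba <- as.numeric(best_rmsd(g, b, a))
    expect_gte(r_ab, 0)
    expect_equal(r_ab, r_ba, tolerance = 1e-8)
    expect_lte(r_ab, kabsch_superpose(a, b)$rmsd + 1e-12)
  }
})

test_that("torsion sets follow the documented selection and period rules", {
  # ethane: one entry, threefold terminal symmetry each side, weight 1
  ts <- build_torsion_set(ethane_graph())
  expect_length(ts$entries, 1L)
  expect_identical(ts$entries[[1L]]$period, 120)
  expect_identical(ts$entries[[1L]]$weight, 1)

  # heavy-atom butane chain: single dihedral, period 360
  ts2 <- build_torsion_set(butane_chain())
  expect_length(ts2$entries, 1L)
  expect_identical(ts2$entries[[1L]]$period, 360)

  # chain + ring: one dihedral + one ring pseudo-torsion; weights sum to 1
  # (the ring must have >= 4 atoms: a 3-ring has no internal dihedral)
  g3 <- molecular_graph(rep("C", 6),
                        data.frame(a1 = c(1L, 2L, 3L, 4L, 4L, 5L),
                                   a2 = c(2L, 3L, 4L, 1L, 5L, 6L),
                                   order = "1"))
  ts3 <- build_torsion_set(g3)
  types <- sort(vapply(ts3$entries, function(e) e$type, character(1)))
  expect_identical(types, c("dihedral", "ring"))
  expect_equal(sum(vapply(ts3$entries, function(e) e$weight, numeric(1))),
               1, tolerance = 1e-12)

  # diatomic: no torsions, TFD undefined downstream
  di <- molecular_graph(c("C", "O"),
                        data.frame(a1 = 1L, a2 = 2L, order = "3"))
  expect_length(build_torsion_set(di)$entries, 0L)
  expect_error(tfd(build_torsion_set(di), matrix(0, 2, 3),
                   matrix(0, 2, 3)), "undefined")
})

test_that("tfd evaluates the stated deviation formula", {
  ts <- build_torsion_set(butane_chain())
  ref <- butane_coords(0)
  expect_equal(tfd(ts, ref, ref), 0, tolerance = 1e-12)
  expect_equal(tfd(ts, ref, butane_coords(180)), 1.0, tolerance = 1e-9)
  expect_equal(tfd(ts, ref, butane_coords(90)), 0.5, tolerance = 1e-9)
  # rigid motions leave internal torsions unchanged
  set.seed(66)
  moved <- random_rigid_transform(butane_coords(47))
  expect_lt(tfd(ts, butane_coords(47), moved), 1e-9)
})

test_that("tfd is monotone in a single torsion's deviation", {
  ts <- build_torsion_set(butane_chain())
  ref <- butane_coords(0)
  scores <- vapply(seq(0, 180, by = 5), function(th) {
    tfd(ts, ref, butane_coords(th))
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("dihedral angles wrap to (-180, 180] and flag degeneracy", {
  # signed, antisymmetric under mirroring; magnitude matches construction
  expect_equal(abs(dihedral_angle(butane_coords(90), 1:4)), 90,
               tolerance = 1e-9)
  expect_equal(dihedral_angle(butane_coords(90), 1:4),
               -dihedral_angle(butane_coords(-90), 1:4), tolerance = 1e-9)
  expect_equal(dihedral_angle(butane_coords(180), 1:4), 180,
               tolerance = 1e-9) # wrapped to +180, never -180
  colinear <- cbind(0:3, 0, 0)
  expect_true(is.na(dihedral_angle(colinear, 1:4)))
})
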