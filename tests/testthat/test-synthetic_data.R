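# Synthetic benchmark generator: determinism, planted features, perturbation

small_cfg <- function(seed = 7L, ...) {
  synth_config(n_molecules = 12L, conformers = c(2L, 4L),
               ff = list(ffx = list(bias = 0.5, energy_sd = 0.3,
                                    cart_sigma = 0.05, kick_sd = 3)),
               high_kick_fraction = 0.25, tautomer_rate = 0.15,
               collapse_rate = 0.1, seed = seed, ...)
}

test_that("generation is deterministic given config and seed", {
  d1 <- generate_benchmark(small_cfg())
  d2 <- generate_benchmark(small_cfg())
  expect_identical(d1, d2)
  # and file outputs are byte-identical
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  generate_benchmark(small_cfg(), out_dir = o1)
  generate_benchmark(small_cfg(), out_dir = o2)
  for (f in list.files(o1)) {
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)), info = f)
  }
  # different seed, different data
  d3 <- generate_benchmark(small_cfg(seed = 8L))
  expect_false(identical(d1$records, d3$records))
})

test_that("seed is mandatory and infeasible configs are rejected", {
  expect_error(synth_config(), "seed")
  expect_error(synth_config(heavy_atoms = c(1L, 2L), seed = 1L))
  expect_error(synth_config(tautomer_rate = 2, seed = 1L))
})

test_that("emitted records are valid and grouped as planted", {
  d <- generate_benchmark(small_cfg())
  expect_true(all(vapply(d$records, inherits, logical(1),
                         "structure_record")))
  groups <- group_by_identity(d$records)
  nflip <- length(d$truth$tautomer_flips)
  expect_identical(length(groups), 12L + nflip)
  # flipped records are singleton groups under their flipped key
  for (fl in d$truth$tautomer_flips) {
    grp <- Filter(function(g) g$key == fl$flipped_key, groups)
    expect_length(grp, 1L)
    expect_identical(grp[[1L]]$titles, fl$title)
  }
})

test_that("planted collapses surface in the pathological listing", {
  d <- generate_benchmark(small_cfg())
  groups <- group_by_identity(d$records)
  tabs <- list(ffx = do.call(rbind, lapply(groups, dde, ff_id = "ffx")))
  ex <- extrema_summary(tabs)
  got <- sort(ex$pathological$title)
  want <- sort(vapply(d$truth$collapse, function(x) x$title, character(1)))
  expect_identical(got, want)
  expect_gt(length(want), 0L) # the fixture world does plant collapses
  # collapse geometry: an H within 0.1 A of its parent atom
  fl <- d$truth$collapse[[1L]]
  rec <- d$records[[which(vapply(d$records, function(r) r$graph$title,
                                 character(1)) == fl$title)]]
  co <- rec$ff_results[[fl$ff]]$coords
  dmin <- min(dist(co))
  expect_lt(dmin, 0.1)
  expect_identical(rec$ff_results[[fl$ff]]$energy, -1e6)
})

test_that("perturb_conformer honours zero noise and grows with sigma", {
  g <- butane_chain()
  co <- butane_coords(30)
  expect_identical(perturb_conformer(g, co, sigma = 0, kick_sd = 0), co)
  set.seed(31)
  r_small <- replicate(50, {
    kabsch_superpose(co, perturb_conformer(g, co, sigma = 0.02))$rmsd
  })
  r_large <- replicate(50, {
    kabsch_superpose(co, perturb_conformer(g, co, sigma = 0.2))$rmsd
  })
  expect_lt(mean(r_small), mean(r_large))
  expect_error(perturb_conformer(g, co, sigma = -1), "sigma")
})

test_that("a 180-degree torsion kick on a one-torsion molecule gives tfd 1", {
  g <- butane_chain()
  ts <- build_torsion_set(g)
  co <- butane_coords(10)
  rot <- ffbench:::graph_rotors(g)
  expect_length(rot, 1L)
  kicked <- ffbench:::rotate_torsion(co, rot[[1L]], 180)
  expect_equal(tfd(ts, co, kicked), 1.0, tolerance = 1e-9)
})

test_that("sigma = 0.05 A noise keeps best_rmsd below 0.3 A almost surely", {
  # asymmetric chain: single automorphism, so the check is pure Kabsch
  g <- molecular_graph(c("C", "N", "O", "S"),
                       data.frame(a1 = 1:3, a2 = 2:4, order = "1"))
  co <- butane_coords(45)
  set.seed(32)
  r <- replicate(1000, {
    as.numeric(best_rmsd(g, co, perturb_conformer(g, co, sigma = 0.05)))
  })
  expect_gte(mean(r < 0.3), 0.99)
})

test_that("tautomer-flipped graphs are valence-consistent keto/enol pairs", {
  d <- generate_benchmark(small_cfg())
  nflip <- length(d$truth$tautomer_flips)
  expect_gt(nflip, 0L) # the fixture world does plant flips
  for (fl in d$truth$tautomer_flips) {
    rec <- d$records[[which(vapply(d$records, function(r) r$graph$title,
                                   character(1)) == fl$title)]]
    b <- rec$graph$bonds
    # enol signature: a C=C double bond next to an O-H
    expect_true(any(b$order == "2"))
    expect_false(canonical_graph_key(rec$graph) == fl$base_key)
    expect_identical(canonical_graph_key(rec$graph), fl$flipped_key)
  }
})
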