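# Representation ratios, proportion Z-test, enrichment report, substructures

test_that("high-TFD molecule selection applies the strict cutoff per key", {
  tab <- data.frame(key = c("a", "a", "b", "c"),
                    tfd = c(0.05, 0.20, 0.10, NA))
  expect_identical(select_high_tfd_molecules(tab), "a")
  expect_identical(select_high_tfd_molecules(tab, cutoff = 0.09),
                   c("a", "b"))
  # strictly greater than the cutoff
  expect_identical(select_high_tfd_molecules(
    data.frame(key = "x", tfd = 0.12)), character())
  expect_identical(select_high_tfd_molecules(
    data.frame(key = character(), tfd = numeric())), character())
  # default cutoff is 0.12
  expect_identical(formals(select_high_tfd_molecules)$cutoff, 0.12)
})

test_that("representation ratio counts molecules, not applications", {
  df <- data.frame(
    molecule_key = c("m1", "m1", "m1", "m2", "m3", "m4"),
    parameter_id = c("p1", "p1", "p1", "p2", "p1", "p2"),
    class = "bond"
  )
  a <- parameter_assignment(df)
  # p1 applied three times in m1 still counts once
  expect_equal(representation_ratio("p1", c("m1", "m2"), a), 0.5)
  expect_equal(representation_ratio("p1", c("m1", "m2", "m3", "m4"), a),
               0.5)
  expect_equal(representation_ratio("p2", c("m2", "m4"), a), 1.0)
  expect_error(representation_ratio("p1", character(), a), "empty")
})

test_that("proportion Z-test reproduces the closed form", {
  zt <- proportion_z_test(0.5, 0.2, 25)
  expect_equal(zt$z, 3.75, tolerance = 1e-12)
  null <- proportion_z_test(0.37, 0.37, 50)
  expect_equal(null$z, 0, tolerance = 1e-12)
  expect_equal(null$p_value, 1, tolerance = 1e-12)
  # z grows as sqrt(n)
  z25 <- proportion_z_test(0.4, 0.2, 25)$z
  z100 <- proportion_z_test(0.4, 0.2, 100)$z
  expect_equal(z100 / z25, 2, tolerance = 1e-12)
  expect_error(proportion_z_test(0.5, 0, 10), "degenerate")
  expect_error(proportion_z_test(0.5, 1, 10), "degenerate")
  # Wald CI on the sample proportion
  expect_equal(zt$ci_high - zt$ci_low,
               2 * qnorm(0.975) * sqrt(0.5 * 0.5 / 25), tolerance = 1e-12)
})

test_that("enrichment report flags planted signal, excludes small samples", {
  set.seed(21)
  full <- sprintf("m%03d", 1:200)
  subset <- full[1:60]
  rows <- list()
  add <- function(k, p) rows[[length(rows) + 1L]] <<- data.frame(
    molecule_key = k, parameter_id = p, class = "proper torsion")
  for (k in full) {
    # planted: 80% in subset, ~17% elsewhere (full-set ratio ~0.3)
    if (k %in% subset) {
      if (runif(1) < 0.8) add(k, "planted")
    } else if (runif(1) < 0.17) add(k, "planted")
    if (runif(1) < 0.5) add(k, "background")
    if (k %in% subset[1:20]) add(k, "rare") # exactly 20 subset molecules
  }
  a <- parameter_assignment(do.call(rbind, rows))
  rep_ <- enrichment_report(a, subset, full)
  planted <- rep_[rep_$parameter_id == "planted", ]
  expect_true(planted$significant)
  expect_false(planted$excluded_small_sample)
  expect_gt(planted$ratio_subset, planted$ratio_full)

  rare <- rep_[rep_$parameter_id == "rare", ]
  expect_identical(rare$n_applied_subset, 20L)
  expect_true(rare$excluded_small_sample)
  expect_false(rare$significant)

  # disposition accounting: every parameter is excluded, significant, or
  # tested-not-significant
  expect_identical(
    sum(rep_$excluded_small_sample) +
      sum(rep_$significant) +
      sum(!rep_$excluded_small_sample & !rep_$significant),
    nrow(rep_)
  )
})

test_that("underrepresented parameters are never significant", {
  full <- sprintf("m%02d", 1:80)
  subset <- full[1:40]
  # applied by every non-subset molecule, few subset molecules
  df <- data.frame(molecule_key = c(full[41:80], subset[1:25]),
                   parameter_id = "depleted", class = "vdW")
  rep_ <- enrichment_report(parameter_assignment(df), subset, full)
  expect_false(rep_$excluded_small_sample) # 25 > 20 applications
  expect_false(rep_$significant) # p_hat < p0, one-sided rule
  expect_lt(rep_$ratio_subset, rep_$ratio_full)
})

test_that("substructure flags find N-N bonds and azetidine, not benzene", {
  tags <- flag_substructures(list(hydrazine_graph(), azetidine_toy_graph(),
                                  benzene_graph()))
  expect_identical(tags[["hydrazine"]], "N-N")
  expect_identical(tags[["azetidine-toy"]], "azetidine")
  expect_length(tags[["benzene"]], 0L)
  # azo N=N must not match the N-N single-bond pattern
  azo <- molecular_graph(c("N", "N", "C", "C"),
                         data.frame(a1 = c(1L, 1L, 2L), a2 = c(2L, 3L, 4L),
                                    order = c("2", "1", "1")),
                         title = "azo")
  expect_length(flag_substructures(list(azo))[["azo"]], 0L)
  expect_error(flag_substructures(list(benzene_graph()),
                                  patterns = list(bad = "not-a-graph")),
               "malformed")
})

test_that("assignment tables read from CSV and JSON agree", {
  df <- data.frame(molecule_key = c("m1", "m1", "m2"),
                   parameter_id = c("p1", "p2", "p1"),
                   class = c("bond", "angle", "bond"))
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, pcsv, row.names = FALSE)
  a1 <- read_assignments(pcsv)
  pjson <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    m1 = list(list(id = "p1", class = "bond"),
              list(id = "p2", class = "angle")),
    m2 = list(list(id = "p1", class = "bond"))
  ), auto_unbox = TRUE), pjson)
  a2 <- read_assignments(pjson)
  expect_identical(a1[["m1"]], a2[["m1"]])
  expect_identical(a1[["m2"]], a2[["m2"]])
  expect_identical(attr(a1, "classes")[["p2"]], "angle")
})
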