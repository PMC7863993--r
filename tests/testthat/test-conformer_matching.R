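# Threshold matching of FF conformers to QM references

test_that("the stated two-by-two example resolves as specified", {
  # m1: 0.3 to q1, 1.5 to q2; m2: 0.5 to q1, 1.2 to q2
  m <- rbind(c(0.3, 0.5), c(1.5, 1.2)) # rows QM, cols FF
  res <- match_from_matrix(m, threshold = 1.0)
  expect_identical(nrow(res$pairs), 1L)
  expect_identical(res$pairs$qm, 1L)
  expect_identical(res$pairs$ff, 1L)
  expect_equal(res$pairs$rmsd, 0.3, tolerance = 1e-12)
  expect_identical(res$dropped_ff$index, 2L)
  expect_identical(res$dropped_ff$reason, "duplicate-superseded")
  expect_identical(res$dropped_qm, 2L)
})

test_that("identical ensembles pair perfectly; empty FF set is valid", {
  m <- matrix(1, 4, 4) + diag(-1, 4) # zeros on the diagonal
  res <- match_from_matrix(m, threshold = 0.5)
  expect_identical(res$pairs$qm, 1:4)
  expect_identical(res$pairs$ff, 1:4)
  expect_length(res$dropped_qm, 0L)
  expect_identical(nrow(res$dropped_ff), 0L)

  empty <- match_from_matrix(matrix(numeric(), 3, 0), threshold = 1)
  expect_identical(nrow(empty$pairs), 0L)
  expect_identical(empty$dropped_qm, 1:3)
})

test_that("counting identities hold on random ensembles for both methods", {
  set.seed(9)
  for (i in 1:200) {
    n_qm <- sample(1:7, 1L); n_ff <- sample(1:7, 1L)
    m <- matrix(runif(n_qm * n_ff, 0, 2), n_qm, n_ff)
    for (method in c("greedy", "optimal")) {
      res <- match_from_matrix(m, threshold = 1.0, method = method)
      expect_identical(nrow(res$pairs) + nrow(res$dropped_ff), n_ff)
      expect_identical(nrow(res$pairs) + length(res$dropped_qm), n_qm)
      expect_false(anyDuplicated(res$pairs$qm) > 0)
      expect_false(anyDuplicated(res$pairs$ff) > 0)
      expect_true(all(res$pairs$rmsd <= 1.0))
    }
  }
})

test_that("pair count is monotone non-decreasing in the threshold", {
  set.seed(10)
  for (i in 1:40) {
    m <- matrix(runif(30, 0, 2), 5, 6)
    counts <- vapply(c(0.3, 0.6, 1.0, 1.5, 2.1), function(th) {
      nrow(match_from_matrix(m, threshold = th)$pairs)
    }, integer(1))
    expect_true(all(diff(counts) >= 0L))
  }
})

test_that("optimal assignment matches a brute-force matching oracle", {
  # oracle: enumerate all injective FF->QM maps under the threshold,
  # maximize cardinality then minimize total rmsd
  brute_best <- function(m, th) {
    n_qm <- nrow(m); n_ff <- ncol(m)
    best <- list(card = -1L, cost = Inf)
    assign_next <- function(j, used, cost, card) {
      if (j > n_ff) {
        if (card > best$card ||
            (card == best$card && cost < best$cost - 1e-12)) {
          best <<- list(card = card, cost = cost)
        }
        return(invisible())
      }
      assign_next(j + 1L, used, cost, card) # leave j unmatched
      for (q in seq_len(n_qm)) {
        if (!used[q] && m[q, j] <= th) {
          used[q] <- TRUE
          assign_next(j + 1L, used, cost + m[q, j], card + 1L)
          used[q] <- FALSE
        }
      }
    }
    assign_next(1L, rep(FALSE, n_qm), 0, 0L)
    best
  }
  set.seed(11)
  for (i in 1:25) {
    n_qm <- sample(2:4, 1L); n_ff <- sample(2:4, 1L)
    m <- matrix(runif(n_qm * n_ff, 0, 1.6), n_qm, n_ff)
    res <- match_from_matrix(m, threshold = 1.0, method = "optimal")
    want <- brute_best(m, 1.0)
    expect_identical(nrow(res$pairs), want$card)
    expect_equal(sum(res$pairs$rmsd), want$cost, tolerance = 1e-9)
  }
})

test_that("match_conformers runs on a real group with symmetry-aware rmsd", {
  co <- ethane_coords()
  g <- ethane_graph()
  mk <- function(title, qm_co, ff_co) {
    gi <- g; gi$title <- title
    structure_record(gi, conformer(qm_co, -10),
                     list(ffx = conformer(ff_co, -9, source = "ffx")))
  }
  set.seed(12)
  far <- co + 5 # rigid shift: rmsd 0 after superposition -> still pairs
  recs <- list(mk("c1", co, co + matrix(rnorm(24, 0, 0.02), 8, 3)),
               mk("c2", far, far + matrix(rnorm(24, 0, 0.02), 8, 3)))
  res <- match_conformers(group_by_identity(recs)[[1L]], "ffx")
  expect_identical(nrow(res$pairs) + nrow(res$dropped_ff), 2L)
  expect_true(all(res$pairs$rmsd < 0.1))
})
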