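# Conformer matching: pair each force-field-minimized conformer with a QM
# reference under an RMSD threshold, as described procedurally — nearest
# reference, then lowest-RMSD deduplication — with an optimal bipartite
# assignment available behind a flag.

#' Match force-field conformers to QM reference conformers
#'
#' Distances are symmetry-aware [best_rmsd()] values (hydrogens included).
#' Under the default greedy procedure each FF conformer is assigned to its
#' nearest QM reference if that distance is at or below `threshold`, else
#' dropped (`no-reference-within-threshold`); when several FF conformers
#' claim one QM reference only the lowest-RMSD claimant survives, the others
#' are dropped (`duplicate-superseded`, ties to the lower FF index). QM
#' references left without a partner are listed in `dropped_qm`. With
#' `method = "optimal"` a maximum-cardinality minimum-cost assignment under
#' the threshold is used instead.
#'
#' @param group a `molecule_group`; its QM conformers are the references and
#'   its members' `ff_results[[ff_id]]` conformers are the candidates.
#' @param ff_id force-field identifier.
#' @param threshold RMSD threshold in Angstrom (default 1.0).
#' @param method `"greedy"` (default, the stated procedure) or `"optimal"`.
#' @param rmsd_matrix optional precomputed matrix (QM rows x FF columns) of
#'   symmetry-aware RMSDs; computed here when absent.
#' @return object of class `match_result`: `pairs` (data frame `qm`, `ff`,
#'   `rmsd`), `dropped_qm` (integer indices), `dropped_ff` (data frame
#'   `index`, `reason`), plus `n_qm`, `n_ff`.
#' @export
match_conformers <- function(group, ff_id, threshold = 1.0,
                             method = c("greedy", "optimal"),
                             rmsd_matrix = NULL) {
  method <- match.arg(method)
  stopifnot(threshold > 0)
  if (is.null(rmsd_matrix)) {
    autos <- enumerate_automorphisms(group$records[[1L]]$graph)
    nrec <- length(group$records)
    rmsd_matrix <- matrix(NA_real_, nrec, nrec)
    for (i in seq_len(nrec)) {
      for (j in seq_len(nrec)) {
        cf <- group$records[[j]]$ff_results[[ff_id]]
        if (is.null(cf)) stop("force field ", ff_id, " absent from member ", j)
        rmsd_matrix[i, j] <- best_rmsd(group$records[[i]]$graph,
                                       group$records[[i]]$qm, cf,
                                       automorphisms = autos)
      }
    }
  }
  match_from_matrix(rmsd_matrix, threshold, method)
}

#' Match conformers from a precomputed RMSD matrix
#'
#' Core of [match_conformers()], usable directly on any QM x FF distance
#' matrix.
#'
#' @inheritParams match_conformers
#' @param rmsd_matrix numeric matrix, rows = QM references, columns = FF
#'   conformers.
#' @return a `match_result` (see [match_conformers()]).
#' @export
match_from_matrix <- function(rmsd_matrix, threshold = 1.0,
                              method = c("greedy", "optimal")) {
  method <- match.arg(method)
  n_qm <- nrow(rmsd_matrix); n_ff <- ncol(rmsd_matrix)
  pairs <- data.frame(qm = integer(), ff = integer(), rmsd = numeric())
  dropped_ff <- data.frame(index = integer(), reason = character(),
                           stringsAsFactors = FALSE)

  if (n_ff > 0L && n_qm > 0L) {
    if (method == "greedy") {
      nearest <- apply(rmsd_matrix, 2L, which.min)
      ndist <- rmsd_matrix[cbind(nearest, seq_len(n_ff))]
      out_of_reach <- ndist > threshold
      for (j in which(out_of_reach)) {
        dropped_ff <- rbind(dropped_ff, data.frame(
          index = j, reason = "no-reference-within-threshold"))
      }
      for (q in sort(unique(nearest[!out_of_reach]))) {
        claimants <- which(nearest == q & !out_of_reach)
        keep <- claimants[order(ndist[claimants], claimants)][1L]
        pairs <- rbind(pairs, data.frame(qm = q, ff = keep,
                                         rmsd = ndist[keep]))
        for (j in setdiff(claimants, keep)) {
          dropped_ff <- rbind(dropped_ff, data.frame(
            index = j, reason = "duplicate-superseded"))
        }
      }
    } else {
      asg <- hungarian_assign(rmsd_matrix, threshold)
      for (j in seq_len(n_ff)) {
        q <- asg[j]
        if (is.na(q)) {
          reason <- if (min(rmsd_matrix[, j]) > threshold)
            "no-reference-within-threshold" else "duplicate-superseded"
          dropped_ff <- rbind(dropped_ff,
                              data.frame(index = j, reason = reason))
        } else {
          pairs <- rbind(pairs, data.frame(qm = q, ff = j,
                                           rmsd = rmsd_matrix[q, j]))
        }
      }
      pairs <- pairs[order(pairs$qm), , drop = FALSE]
    }
  } else if (n_ff > 0L) {
    dropped_ff <- data.frame(index = seq_len(n_ff),
                             reason = "no-reference-within-threshold")
  }

  structure(
    list(pairs = pairs,
         dropped_qm = setdiff(seq_len(n_qm), pairs$qm),
         dropped_ff = dropped_ff,
         n_qm = n_qm, n_ff = n_ff),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair(s), %d QM dropped, %d FF dropped\n",
              nrow(x$pairs), length(x$dropped_qm), nrow(x$dropped_ff)))
  invisible(x)
}

# maximum-cardinality, minimum-total-RMSD assignment of FF conformers
# (columns) to QM references (rows), pairs above threshold forbidden.
# Square Hungarian algorithm on a padded cost matrix with a big-M penalty
# for forbidden / dummy cells so cardinality dominates total cost.
hungarian_assign <- function(rmsd_matrix, threshold) {
  n_qm <- nrow(rmsd_matrix); n_ff <- ncol(rmsd_matrix)
  n <- max(n_qm, n_ff)
  big <- (sum(pmin(rmsd_matrix, threshold)) + threshold + 1) * (n + 1)
  cost <- matrix(big, n, n)
  cost[seq_len(n_qm), seq_len(n_ff)] <- ifelse(rmsd_matrix <= threshold,
                                               rmsd_matrix, big)
  a <- solve_hungarian(cost) # a[row] = assigned column
  asg <- rep(NA_integer_, n_ff)
  for (r in seq_len(n_qm)) {
    cc <- a[r]
    if (cc <= n_ff && cost[r, cc] < big) asg[cc] <- r
  }
  asg
}

# O(n^3) Hungarian algorithm (Jonker-style shortest augmenting paths).
# Returns for each row its assigned column.
solve_hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L) # p[col] = row matched to col (0 = none), col 1..n+1
  way <- integer(n + 1L)
  INF <- Inf
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L # columns are offset by 1: j0 = 1 is the virtual column
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}
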