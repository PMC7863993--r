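# Synthetic benchmark generator: molecules, QM conformer ensembles,
# per-force-field minimized conformers and energies, and parameter
# assignments, all with known ground truth. Geometric realism is
# deliberately minimal (a toy spring/repulsion potential): the generator
# exists to exercise the analysis contracts, not to model chemistry.
#
# Every molecule is grown around a keto fragment O=C-C(H) so that a
# tautomer flip (keto -> enol: move the alpha H onto the oxygen, swap the
# C=O / C-C bond orders) is always well defined and valence-legal.

.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L)

#' Synthetic benchmark configuration
#'
#' Defaults describe the stated world of the package's tests: 200 molecules
#' of 4-8 heavy atoms with 2-10 conformers each; three force fields with
#' planted energy biases of -1, 0 and +2 kcal/mol and energy noise 0.5
#' kcal/mol; Cartesian geometry noise 0.05 Angstrom with small (3 degrees)
#' torsion kicks, except for a planted high-deviation fraction of molecules
#' (30%) that receives large (60 degrees) kicks and therefore high TFD;
#' tautomer-flip and hydrogen-collapse rates of 2%; and parameter
#' assignments in which three planted parameter ids appear in 80% of
#' high-deviation molecules but only 30% of the rest, against 25 background
#' parameters assigned at 30% everywhere.
#'
#' @param n_molecules number of base molecules.
#' @param heavy_atoms length-2 range of heavy-atom counts.
#' @param conformers length-2 range of conformers per molecule.
#' @param ff named list per force field: `bias`, `energy_sd` (kcal/mol),
#'   `cart_sigma` (Angstrom), `kick_sd` (degrees).
#' @param high_kick_fraction fraction of molecules given large torsion
#'   kicks (the planted high-TFD set).
#' @param high_kick_sd torsion-kick sd (degrees) for that set.
#' @param tautomer_rate per-record probability of a planted tautomer flip
#'   (at most one per molecule, never the only record of a molecule).
#' @param collapse_rate per-record probability of a hydrogen-collapse
#'   pathology (never the molecule's QM-minimum record).
#' @param collapse_ff force field receiving the collapse (default: first).
#' @param n_background_parameters,background_prop background parameter pool
#'   size and per-molecule assignment probability.
#' @param planted_parameters planted (enriched) parameter ids.
#' @param target_prop,base_prop planted-parameter assignment probability in
#'   high-deviation vs other molecules.
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_molecules = 200L,
                         heavy_atoms = c(4L, 8L),
                         conformers = c(2L, 10L),
                         ff = list(
                           ff_a = list(bias = -1, energy_sd = 0.5,
                                       cart_sigma = 0.05, kick_sd = 3),
                           ff_b = list(bias = 0, energy_sd = 0.5,
                                       cart_sigma = 0.05, kick_sd = 3),
                           ff_c = list(bias = 2, energy_sd = 0.5,
                                       cart_sigma = 0.05, kick_sd = 3)
                         ),
                         high_kick_fraction = 0.3,
                         high_kick_sd = 60,
                         tautomer_rate = 0.02,
                         collapse_rate = 0.02,
                         collapse_ff = NULL,
                         n_background_parameters = 25L,
                         background_prop = 0.3,
                         planted_parameters = c("t_planted_1", "t_planted_2",
                                                "t_planted_3"),
                         target_prop = 0.8,
                         base_prop = 0.3,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(heavy_atoms[1L] >= 3L, heavy_atoms[2L] >= heavy_atoms[1L],
            conformers[1L] >= 1L,
            tautomer_rate >= 0, tautomer_rate <= 1,
            collapse_rate >= 0, collapse_rate <= 1,
            all(vapply(ff, function(f) f$cart_sigma >= 0 &&
                         f$energy_sd >= 0, logical(1))))
  if (is.null(collapse_ff)) collapse_ff <- names(ff)[1L]
  structure(as.list(environment()), class = "synth_config")
}

# deterministic substream seeds, all below 2^31
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483629)
}

#' Generate a complete synthetic benchmark dataset
#'
#' Emits structure records (QM conformer + per-force-field minimized
#' conformers and energies), a parameter-assignment table, and the ground
#' truth behind every planted feature. With `out_dir`, writes `qm.sdf`, one
#' `ff_<id>.sdf` per force field, `assignments.csv` and `truth.json`.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @return list with `records` (list of `structure_record`),
#'   `assignments` (a `parameter_assignment`), `assignment_df` (long data
#'   frame), `truth` (ground-truth list), and `files` (named paths when
#'   `out_dir` was given).
#' @export
generate_benchmark <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config

  # --- molecules, with unique canonical keys
  set.seed(substream(cfg$seed, 1L))
  mols <- list()
  keys <- character()
  tries <- 0L
  while (length(mols) < cfg$n_molecules) {
    tries <- tries + 1L
    if (tries > cfg$n_molecules * 50L) {
      stop("infeasible config: could not generate distinct molecules")
    }
    nh <- sample(cfg$heavy_atoms[1L]:cfg$heavy_atoms[2L], 1L)
    m <- random_molecule(nh)
    k <- canonical_graph_key(m$graph)
    if (k %in% keys) next
    keys <- c(keys, k)
    m$key <- k
    m$rotors <- graph_rotors(m$graph)
    mols[[length(mols) + 1L]] <- m
  }

  # --- planted high-deviation (large torsion kick) molecules
  set.seed(substream(cfg$seed, 2L))
  n_high <- round(cfg$high_kick_fraction * cfg$n_molecules)
  high_idx <- sort(sample.int(cfg$n_molecules, n_high))

  # --- QM conformers and energies
  set.seed(substream(cfg$seed, 3L))
  for (i in seq_along(mols)) {
    ncf <- sample(cfg$conformers[1L]:cfg$conformers[2L], 1L)
    # rigid molecules (no rotatable bonds) have exactly one conformer:
    # torsional sampling cannot distinguish more, and a non-redundant
    # ensemble must not carry duplicate geometries
    if (length(mols[[i]]$rotors) == 0L) ncf <- 1L
    base_e <- runif(1L, -80, -20)
    # reject near-duplicate geometries: the emulated ensemble is
    # non-redundant, so conformers must be mutually distinguishable
    confs <- list()
    for (j in seq_len(ncf)) {
      for (try in 1:10) {
        cc <- make_conformer_geometry(mols[[i]])
        dmin <- if (length(confs) == 0L) Inf else
          min(vapply(confs, function(cf) {
            kabsch_superpose(cf$coords, cc)$rmsd
          }, numeric(1)))
        if (dmin > 0.25) break
        cc <- NULL
      }
      if (is.null(cc)) next
      confs[[length(confs) + 1L]] <-
        conformer(cc, base_e + runif(1L, 0, 8), source = "QM")
    }
    mols[[i]]$qm_conformers <- confs
  }

  # --- tautomer flips: at most one per molecule, only molecules with >= 2
  # conformers, flipped key must not collide with any existing key
  set.seed(substream(cfg$seed, 4L))
  flips <- list()
  all_keys <- keys
  for (i in seq_along(mols)) {
    ncf <- length(mols[[i]]$qm_conformers)
    if (ncf < 2L) next
    if (runif(1L) >= cfg$tautomer_rate * ncf) next
    j <- sample.int(ncf, 1L)
    fl <- tautomer_flip(mols[[i]], j)
    fk <- canonical_graph_key(fl$graph)
    if (fk %in% all_keys) next
    all_keys <- c(all_keys, fk)
    flips[[length(flips) + 1L]] <- list(mol = i, conf = j, graph = fl$graph,
                                        coords = fl$coords, key = fk,
                                        rotors = graph_rotors(fl$graph))
  }
  flip_by_mol <- if (length(flips)) {
    setNames(flips, vapply(flips, function(f) as.character(f$mol),
                           character(1)))
  } else list()

  # --- assemble records with per-ff perturbed geometries and energies
  records <- list()
  rec_meta <- list()
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    fl <- flip_by_mol[[as.character(i)]]
    for (j in seq_along(m$qm_conformers)) {
      title <- sprintf("mol%04d_conf%02d", i, j)
      flipped <- !is.null(fl) && fl$conf == j
      if (flipped) {
        graph <- fl$graph
        qm_coords <- fl$coords
      } else {
        graph <- m$graph
        qm_coords <- m$qm_conformers[[j]]$coords
      }
      graph$title <- title
      qm <- conformer(qm_coords, m$qm_conformers[[j]]$energy, source = "QM")
      records[[length(records) + 1L]] <- structure_record(graph, qm, list())
      rec_meta[[length(rec_meta) + 1L]] <-
        list(mol = i, conf = j, flipped = flipped,
             key = if (flipped) fl$key else m$key,
             rotors = if (flipped) fl$rotors else m$rotors)
    }
  }

  # per-ff geometries/energies. The energy bias is planted on the RELATIVE
  # energies: with reference r(k) = the lowest-QM-energy record of each
  # molecule key k,
  #   FF(i) = QM(i) + C_mol + (b + eps_i) * [i != r(k)]
  # so that dE_FF,i = dE_QM,i + b + eps_i for non-reference conformers and
  # per-molecule MSD estimates b. The per-molecule constant C_mol cancels in
  # every relative quantity.
  ff_ids <- names(cfg$ff)
  rec_keys <- vapply(rec_meta, function(x) x$key, character(1))
  qm_e_all <- vapply(records, function(r) r$qm$energy, numeric(1))
  ref_of_key <- vapply(split(seq_along(records), rec_keys), function(idx) {
    idx[which.min(qm_e_all[idx])]
  }, integer(1))
  is_ref <- seq_along(records) %in% ref_of_key

  set.seed(substream(cfg$seed, 5L))
  c_mol <- matrix(rnorm(length(mols) * length(ff_ids), 0, 5),
                  length(mols), length(ff_ids),
                  dimnames = list(NULL, ff_ids))
  for (r in seq_along(records)) {
    meta <- rec_meta[[r]]
    kick <- if (meta$mol %in% high_idx) cfg$high_kick_sd else NULL
    for (f in ff_ids) {
      p <- cfg$ff[[f]]
      kick_sd <- if (is.null(kick)) p$kick_sd else kick
      coords <- perturb_coords(records[[r]]$graph, records[[r]]$qm$coords,
                               p$cart_sigma, kick_sd, rotors = meta$rotors)
      energy <- records[[r]]$qm$energy + c_mol[meta$mol, f] +
        if (is_ref[r]) 0 else p$bias + rnorm(1L, 0, p$energy_sd)
      records[[r]]$ff_results[[f]] <- conformer(coords, energy, source = f)
    }
  }

  # --- hydrogen-collapse pathologies (never a molecule's reference record,
  # so the energy anchor of its group stays sane)
  set.seed(substream(cfg$seed, 6L))
  key_size <- table(rec_keys)
  collapse <- integer()
  for (r in seq_along(records)) {
    if (is_ref[r] || key_size[[rec_keys[r]]] < 2L) next
    if (runif(1L) < cfg$collapse_rate) collapse <- c(collapse, r)
  }
  for (r in collapse) {
    records[[r]] <- apply_collapse(records[[r]], cfg$collapse_ff)
  }

  # --- parameter assignments
  set.seed(substream(cfg$seed, 7L))
  high_keys <- vapply(mols[high_idx], function(m) m$key, character(1))
  # flipped singletons inherit their base molecule's deviation status
  flip_keys_high <- vapply(flips, function(f) f$mol %in% high_idx,
                           logical(1))
  molecule_keys <- c(vapply(mols, function(m) m$key, character(1)),
                     vapply(flips, function(f) f$key, character(1)))
  is_high <- c(seq_along(mols) %in% high_idx, flip_keys_high)

  classes <- c("bond", "angle", "proper torsion", "improper torsion", "vdW")
  bg_ids <- sprintf("param_%03d", seq_len(cfg$n_background_parameters))
  bg_classes <- classes[(seq_along(bg_ids) - 1L) %% length(classes) + 1L]
  rows <- list()
  for (ki in seq_along(molecule_keys)) {
    k <- molecule_keys[ki]
    pp <- if (is_high[ki]) cfg$target_prop else cfg$base_prop
    for (pid in cfg$planted_parameters) {
      if (runif(1L) < pp) {
        rows[[length(rows) + 1L]] <- data.frame(
          molecule_key = k, parameter_id = pid, class = "proper torsion",
          stringsAsFactors = FALSE)
      }
    }
    on <- runif(length(bg_ids)) < cfg$background_prop
    for (b in which(on)) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_key = k, parameter_id = bg_ids[b], class = bg_classes[b],
        stringsAsFactors = FALSE)
    }
  }
  assignment_df <- do.call(rbind, rows)
  assignments <- parameter_assignment(assignment_df)

  truth <- list(
    ff = lapply(cfg$ff, function(p) p[c("bias", "energy_sd", "cart_sigma",
                                        "kick_sd")]),
    molecule_keys = vapply(mols, function(m) m$key, character(1)),
    high_kick_keys = high_keys,
    tautomer_flips = lapply(flips, function(f) list(
      title = sprintf("mol%04d_conf%02d", f$mol, f$conf),
      base_key = mols[[f$mol]]$key, flipped_key = f$key)),
    collapse = lapply(collapse, function(r) list(
      title = records[[r]]$graph$title, key = rec_meta[[r]]$key,
      ff = cfg$collapse_ff)),
    planted_parameters = cfg$planted_parameters,
    seed = cfg$seed
  )

  out <- list(records = records, assignments = assignments,
              assignment_df = assignment_df, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(qm = file.path(out_dir, "qm.sdf"))
    write_conformer_sdf(
      lapply(records, function(r) list(graph = r$graph, conformer = r$qm)),
      files[["qm"]]
    )
    for (f in ff_ids) {
      pf <- file.path(out_dir, paste0("ff_", f, ".sdf"))
      write_conformer_sdf(
        lapply(records, function(r) list(graph = r$graph,
                                         conformer = r$ff_results[[f]])),
        pf
      )
      files[[paste0("ff_", f)]] <- pf
    }
    files[["assignments"]] <- file.path(out_dir, "assignments.csv")
    write.csv(assignment_df, files[["assignments"]], row.names = FALSE)
    files[["truth"]] <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$files <- files
  }
  out
}

# --- molecule construction ------------------------------------------------

# grow a random valence-legal molecule around a keto fragment O=C1-C2;
# returns graph (H-completed), base 3-D coordinates, and the tautomer site
random_molecule <- function(n_heavy, ring_prob = 0.25) {
  elements <- c("C", "O", "C")
  bonds <- data.frame(a1 = c(1L, 1L), a2 = c(2L, 3L),
                      order = c("2", "1"), stringsAsFactors = FALSE)
  used <- c(3L, 2L, 2L) # bond-order sums so far (C1: =O + -C2, O: =C1, C2)
  used[3L] <- 1L
  pool <- c("C", "N", "O", "S", "F", "Cl")
  pw <- c(0.55, 0.15, 0.12, 0.06, 0.06, 0.06)

  free <- function() .VALENCE[elements] - used
  while (length(elements) < n_heavy) {
    # keep one slot on C2 for its alpha hydrogen
    cand <- which(free() > 0L)
    cand <- setdiff(cand, if (free()[3L] <= 1L) 3L else integer())
    if (length(cand) == 0L) break
    at <- if (length(cand) == 1L) cand else sample(cand, 1L)
    el <- sample(pool, 1L, prob = pw)
    elements <- c(elements, el)
    new <- length(elements)
    bonds <- rbind(bonds, data.frame(a1 = at, a2 = new, order = "1"))
    used[at] <- used[at] + 1L
    used <- c(used, 1L)
  }

  # optional single ring closure between atoms at graph distance 3..5
  if (runif(1L) < ring_prob && length(elements) >= 5L) {
    g <- igraph::graph_from_data_frame(bonds[, 1:2], directed = FALSE,
                                       vertices = data.frame(
                                         name = seq_along(elements)))
    dm <- igraph::distances(g)
    fr <- free()
    ok <- which(fr > 0L & seq_along(elements) != 3L)
    cand <- list()
    if (length(ok) >= 2L) {
      for (u in ok) for (v in ok) {
        if (u < v && dm[u, v] >= 3 && dm[u, v] <= 5) {
          cand[[length(cand) + 1L]] <- c(u, v)
        }
      }
    }
    if (length(cand) > 0L) {
      pick <- cand[[sample.int(length(cand), 1L)]]
      bonds <- rbind(bonds, data.frame(a1 = pick[1L], a2 = pick[2L],
                                       order = "1"))
      used[pick] <- used[pick] + 1L
    }
  }

  # hydrogen completion; remember one alpha hydrogen on C2
  n_heavy_final <- length(elements)
  alpha_h <- NA_integer_
  for (i in seq_len(n_heavy_final)) {
    nh <- .VALENCE[elements[i]] - used[i]
    for (k in seq_len(max(nh, 0L))) {
      elements <- c(elements, "H")
      new <- length(elements)
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = new, order = "1"))
      if (i == 3L && is.na(alpha_h)) alpha_h <- new
    }
  }
  stopifnot(!is.na(alpha_h)) # C2 always keeps at least one H slot

  graph <- molecular_graph(elements, bonds)
  list(graph = graph, coords = embed_graph(graph),
       site = list(o = 2L, c1 = 1L, c2 = 3L, h = alpha_h))
}

# initial placement along the bond tree, then toy spring/repulsion relaxation
embed_graph <- function(graph, n_iter = 200L) {
  n <- n_atoms(graph)
  b <- graph$bonds
  is_h <- graph$atoms$element == "H"
  target <- ifelse(is_h[b$a1] | is_h[b$a2], 1.05, 1.5)

  coords <- matrix(0, n, 3L)
  placed <- rep(FALSE, n)
  placed[1L] <- TRUE
  nb <- graph_neighbors(graph)
  queue <- 1L
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in nb[[u]]) {
      if (placed[v]) next
      dir <- rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      len <- if (is_h[u] || is_h[v]) 1.05 else 1.5
      coords[v, ] <- coords[u, ] + len * dir
      placed[v] <- TRUE
      queue <- c(queue, v)
    }
  }
  relax_coords(coords, b, target, is_h, n_iter)
}

# gradient steps on harmonic bonds plus soft nonbonded repulsion
relax_coords <- function(coords, bonds, target, is_h, n_iter = 200L,
                         step = 0.05) {
  n <- nrow(coords)
  if (n < 3L || nrow(bonds) == 0L) return(coords)
  a1 <- bonds$a1; a2 <- bonds$a2
  radius <- ifelse(is_h, 1.3, 1.9)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  bkey <- paste(pmin(a1, a2), pmax(a1, a2))
  pr <- pr[!(paste(pr[, 1L], pr[, 2L]) %in% bkey), , drop = FALSE]
  cut <- (radius[pr[, 1L]] + radius[pr[, 2L]]) / 2
  for (it in seq_len(n_iter)) {
    d <- coords[a1, , drop = FALSE] - coords[a2, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    len[len < 1e-9] <- 1e-9
    gb <- d * ((len - target) / len)
    rs <- rowsum(rbind(gb, -gb), c(a1, a2))
    grad <- matrix(0, n, 3L)
    grad[as.integer(rownames(rs)), ] <- rs
    if (nrow(pr) > 0L) {
      dv <- coords[pr[, 1L], , drop = FALSE] -
        coords[pr[, 2L], , drop = FALSE]
      dd <- sqrt(rowSums(dv^2))
      dd[dd < 1e-9] <- 1e-9
      pen <- dd < cut
      if (any(pen)) {
        push <- dv[pen, , drop = FALSE] * ((cut[pen] - dd[pen]) / dd[pen])
        rs2 <- rowsum(rbind(-push, push), c(pr[pen, 1L], pr[pen, 2L]))
        ridx <- as.integer(rownames(rs2))
        grad[ridx, ] <- grad[ridx, ] + rs2
      }
    }
    coords <- coords - step * grad
  }
  coords
}

# bridge bonds with both endpoints non-terminal: the rotatable torsion axes
rotatable_bonds <- function(graph) {
  b <- graph$bonds
  if (nrow(b) == 0L) return(integer())
  g <- as_igraph(graph)
  deg <- graph_degrees(graph)
  bridge_ids <- as.integer(igraph::bridges(g))
  which(seq_len(nrow(b)) %in% bridge_ids &
          deg[b$a1] >= 2L & deg[b$a2] >= 2L)
}

# rotors of a graph: for each rotatable bond (u, v), the atom set on the
# v side when the (bridge) bond is cut; precomputed once per graph because
# torsion kicks are applied per conformer
graph_rotors <- function(graph) {
  nb <- graph_neighbors(graph)
  lapply(rotatable_bonds(graph), function(k) {
    u <- graph$bonds$a1[k]; v <- graph$bonds$a2[k]
    side <- v
    queue <- v
    seen <- rep(FALSE, n_atoms(graph))
    seen[c(u, v)] <- TRUE
    while (length(queue) > 0L) {
      w <- queue[1L]; queue <- queue[-1L]
      for (x in nb[[w]]) {
        if (!seen[x]) {
          seen[x] <- TRUE
          side <- c(side, x)
          queue <- c(queue, x)
        }
      }
    }
    list(u = u, v = v, side = side)
  })
}

# rotate the subtree on the v-side of bridge bond (u, v) about the u->v axis
rotate_torsion <- function(coords, rotor, angle_deg) {
  u <- rotor$u; v <- rotor$v; side <- rotor$side
  axis <- coords[v, ] - coords[u, ]
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3L], axis[2L],
                axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shifted <- sweep(coords[side, , drop = FALSE], 2L, coords[u, ])
  coords[side, ] <- sweep(shifted %*% t(R), 2L, coords[u, ], "+")
  coords
}

# a fresh QM conformer: random torsions on the base geometry + a short relax
make_conformer_geometry <- function(mol) {
  graph <- mol$graph
  coords <- mol$coords
  for (rot in mol$rotors) {
    coords <- rotate_torsion(coords, rot, runif(1L, -180, 180))
  }
  is_h <- graph$atoms$element == "H"
  target <- ifelse(is_h[graph$bonds$a1] | is_h[graph$bonds$a2], 1.05, 1.5)
  relax_coords(coords, graph$bonds, target, is_h, n_iter = 25L)
}

#' Perturb a conformer with Cartesian noise and torsion kicks
#'
#' Emulates force-field re-minimization: each rotatable torsion receives a
#' Normal(0, `kick_sd`^2) degree kick, then every coordinate receives
#' Normal(0, `sigma`^2) Angstrom noise. With `sigma = 0` and
#' `kick_sd = 0` the conformer is returned unchanged.
#'
#' @param graph the `molecular_graph`.
#' @param conf a `conformer` or N x 3 coordinate matrix.
#' @param sigma Cartesian noise sd in Angstrom (>= 0).
#' @param kick_sd torsion kick sd in degrees (>= 0).
#' @param seed optional seed; when given, the perturbation is reproducible
#'   in isolation.
#' @return N x 3 coordinate matrix.
#' @export
perturb_conformer <- function(graph, conf, sigma, kick_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coords <- if (inherits(conf, "conformer")) conf$coords else as.matrix(conf)
  perturb_coords(graph, coords, sigma, kick_sd)
}

perturb_coords <- function(graph, coords, sigma, kick_sd, rotors = NULL) {
  stopifnot(sigma >= 0, kick_sd >= 0)
  if (kick_sd > 0) {
    if (is.null(rotors)) rotors <- graph_rotors(graph)
    for (rot in rotors) {
      coords <- rotate_torsion(coords, rot, rnorm(1L, 0, kick_sd))
    }
  }
  if (sigma > 0) {
    coords <- coords + matrix(rnorm(length(coords), 0, sigma),
                              nrow(coords), 3L)
  }
  coords
}

# keto -> enol flip at the molecule's planted site: H moves from C2 to O,
# C1=O becomes single, C1-C2 becomes double
tautomer_flip <- function(mol, conf_index) {
  graph <- mol$graph
  s <- mol$site
  b <- graph$bonds
  i_co <- which((b$a1 == s$c1 & b$a2 == s$o) |
                  (b$a1 == s$o & b$a2 == s$c1))
  i_cc <- which((b$a1 == s$c1 & b$a2 == s$c2) |
                  (b$a1 == s$c2 & b$a2 == s$c1))
  i_ch <- which((b$a1 == s$c2 & b$a2 == s$h) |
                  (b$a1 == s$h & b$a2 == s$c2))
  stopifnot(length(i_co) == 1L, length(i_cc) == 1L, length(i_ch) == 1L)
  b$order[i_co] <- "1"
  b$order[i_cc] <- "2"
  b$a1[i_ch] <- s$o
  b$a2[i_ch] <- s$h

  coords <- mol$qm_conformers[[conf_index]]$coords
  dir <- coords[s$h, ] - coords[s$o, ]
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-6) dir <- c(1, 0, 0) else dir <- dir / nrm
  coords[s$h, ] <- coords[s$o, ] + 0.97 * dir

  list(graph = molecular_graph(graph$atoms$element, b,
                               charges = graph$atoms$charge,
                               title = graph$title),
       coords = coords)
}

# hydrogen collapse: one H placed < 0.1 Angstrom from its parent atom, with
# an extreme force-field energy
apply_collapse <- function(record, ff_id) {
  graph <- record$graph
  h <- which(graph$atoms$element == "H")[1L]
  nb <- graph_neighbors(graph)
  parent <- nb[[h]][1L]
  cf <- record$ff_results[[ff_id]]
  dir <- cf$coords[h, ] - cf$coords[parent, ]
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-6) dir <- c(1, 0, 0) else dir <- dir / nrm
  cf$coords[h, ] <- cf$coords[parent, ] + 0.05 * dir
  cf$energy <- -1e6
  record$ff_results[[ff_id]] <- cf
  record
}
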