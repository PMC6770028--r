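# Synthetic aligned-ligand benchmark: pseudo-molecules from two chemotype
# families (benzamide-like and arylpiperazine-like) sharing a cationic
# nitrogen anchored at the receptor carboxylate, decorated with substituents
# whose presence drives activity through a planted sparse linear model on
# the CoMFA field columns.

#' Synthetic benchmark specification
#'
#' Defaults emulate the data regime of the modelled study: 176 compounds
#' from 2 chemotype families, pIC50 spanning 5 to above 9, Gaussian activity
#' noise of 0.3 pIC50 units, a small left-censored inactive tail fixed at
#' pIC50 = 5.0, and 5 planted latent structure-activity factors.
#'
#' @param n_compounds number of compounds.
#' @param n_latent number of planted signal sites (1..5); each site is an
#'   independent substituent position whose occupancy feeds activity through
#'   field columns around it.
#' @param noise_sd Gaussian noise on pIC50.
#' @param censor_fraction fraction of the lowest-activity tail recorded as
#'   censored inactives (pIC50 = 5.0 exactly).
#' @param jitter_sd per-atom coordinate jitter (Angstrom) emulating docking
#'   pose variation.
#' @param activity_span target pIC50 range of the noise-free signal.
#' @param multi_pose emit `n_poses` docking poses per compound, exactly one
#'   of which satisfies the salt-bridge criterion.
#' @param n_poses poses per compound in multi-pose mode.
#' @param seed RNG seed; generation is bit-reproducible given it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 176L, n_latent = 5L, noise_sd = 0.3,
                           censor_fraction = 0.05, jitter_sd = 0.15,
                           activity_span = c(5.1, 9.3),
                           multi_pose = FALSE, n_poses = 20L, seed = 42L) {
  stopifnot(n_compounds >= 10, n_latent >= 1, n_latent <= 5,
            noise_sd >= 0, censor_fraction >= 0, censor_fraction < 0.5)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_latent = as.integer(n_latent), noise_sd = noise_sd,
                 censor_fraction = censor_fraction, jitter_sd = jitter_sd,
                 activity_span = activity_span, multi_pose = multi_pose,
                 n_poses = as.integer(n_poses), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# The receptor-side carboxylate the synthetic poses are anchored to
# (a synthetic stand-in for the conserved TM3 aspartate).
#' @rdname synthetic_spec
#' @export
synthetic_anchor <- function() {
  anchor_site(c(3.0, -1.1, 0), c(3.0, 1.1, 0), "ASP114")
}

# Scaffold templates: atoms (element, x, y, z, formal_charge) and bonds.
# The protonatable nitrogen sits at the origin, ~3.2 A from both anchor
# oxygens, so alignment holds by construction.
scaffold_template <- function(family) {
  ring <- function(cx, cy, z, r = 1.39) {
    th <- seq(0, 300, by = 60) * pi / 180
    cbind(cx + r * cos(th), cy + r * sin(th), z)
  }
  if (family == "benzamide") {
    rg <- ring(-7.35, -0.15, 0.30)
    atoms <- data.frame(
      element = c("N", "H", "H", "C", "C", "N", "H", "C", "O",
                  rep("C", 6)),
      x = c(0, 0.50, 0.50, -1.45, -2.65, -3.90, -3.95, -5.05, -5.05, rg[, 1]),
      y = c(0, 0.80, -0.90, 0.25, -0.55, -0.05, 0.85, -0.75, -1.95, rg[, 2]),
      z = c(0, -0.60, -0.40, 0.30, -0.15, 0.25, 0.70, 0.05, -0.35, rg[, 3]),
      formal_charge = c(1L, rep(0L, 14)))
    bonds <- data.frame(
      i = c(1, 1, 1, 4, 5, 6, 6, 8, 8, 10, 11, 12, 13, 14, 15),
      j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 10),
      order = c(1, 1, 1, 1, 1, 1, 1, 2, 1, 4, 4, 4, 4, 4, 4))
  } else {  # arylpiperazine
    pz <- ring(-1.46, 0, 0, r = 1.46)
    ar <- ring(-5.77, 0, 0.15)
    atoms <- data.frame(
      element = c("N", "C", "C", "N", "C", "C", "H", rep("C", 6)),
      x = c(pz[1, 1], pz[2, 1], pz[3, 1], pz[4, 1], pz[5, 1], pz[6, 1],
            0.55, ar[, 1]),
      y = c(pz[1, 2], pz[2, 2], pz[3, 2], pz[4, 2], pz[5, 2], pz[6, 2],
            0, ar[, 2]),
      z = c(rep(0, 6), 1.0, ar[, 3]),
      formal_charge = c(1L, rep(0L, 12)))
    bonds <- data.frame(
      i = c(1, 2, 3, 4, 5, 6, 1, 4, 8, 9, 10, 11, 12, 13),
      j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13, 8),
      order = c(1, 1, 1, 1, 1, 1, 1, 1, 4, 4, 4, 4, 4, 4))
  }
  list(atoms = atoms, bonds = bonds)
}

# Substituent sites in the shared frame. The first five are signal sites
# (field type and sign of the planted effect); the sixth is a decoy.
substituent_sites <- function() {
  data.frame(
    site = paste0("S", 1:6),
    x = c(1.8, -7.3, -9.9, -2.6, -5.0, 0.6),
    y = c(0.9, 2.6, -0.2, -2.4, 2.0, -2.0),
    z = c(0.8, 0.4, 0.3, -0.4, -1.2, 1.4),
    field = c("steric", "steric", "steric", "electrostatic", "electrostatic",
              "steric"),
    sign = c(1, -1, 1, -1, 1, 0))
}

# Place one substituent at a site; returns atoms/bonds fragments. `attach`
# is the index of the nearest scaffold heavy atom.
substituent_atoms <- function(kind, site_pos, dir) {
  u <- dir / sqrt(sum(dir^2))
  switch(kind,
    none = NULL,
    methyl = list(atoms = data.frame(element = "C", x = site_pos[1],
                                     y = site_pos[2], z = site_pos[3],
                                     formal_charge = 0L),
                  internal_bonds = NULL),
    propyl = {
      p2 <- site_pos + 1.3 * u; p3 <- site_pos + 2.6 * u
      list(atoms = data.frame(element = c("C", "C", "C"),
                              x = c(site_pos[1], p2[1], p3[1]),
                              y = c(site_pos[2], p2[2], p3[2]),
                              z = c(site_pos[3], p2[3], p3[3]),
                              formal_charge = 0L),
           internal_bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1L))
    },
    chloro = list(atoms = data.frame(element = "Cl", x = site_pos[1],
                                     y = site_pos[2], z = site_pos[3],
                                     formal_charge = 0L),
                  internal_bonds = NULL),
    hydroxyl = {
      p2 <- site_pos + 0.96 * u
      list(atoms = data.frame(element = c("O", "H"),
                              x = c(site_pos[1], p2[1]),
                              y = c(site_pos[2], p2[2]),
                              z = c(site_pos[3], p2[3]),
                              formal_charge = 0L),
           internal_bonds = data.frame(i = 1, j = 2, order = 1L))
    },
    stopf("unknown substituent kind '%s'", kind))
}

substituent_kinds <- function() c("none", "methyl", "propyl", "chloro", "hydroxyl")
substituent_probs <- function() c(0.35, 0.20, 0.15, 0.15, 0.15)

# Build one decorated, jittered pseudo-molecule in the shared frame.
build_synthetic_pose <- function(compound_id, family, occupancy, jitter_sd) {
  tpl <- scaffold_template(family)
  atoms <- tpl$atoms
  bonds <- tpl$bonds
  sites <- substituent_sites()
  heavy <- which(atoms$element != "H")
  for (s in seq_len(nrow(sites))) {
    kind <- occupancy[s]
    if (kind == "none") next
    spos <- as.numeric(sites[s, c("x", "y", "z")])
    hxyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(hxyz, 2, spos)^2))
    attach <- heavy[which.min(d)]
    dir <- spos - as.numeric(atoms[attach, c("x", "y", "z")])
    frag <- substituent_atoms(kind, spos, dir)
    base <- nrow(atoms)
    atoms <- rbind(atoms, frag$atoms)
    bonds <- rbind(bonds,
                   data.frame(i = attach, j = base + 1L, order = 1L))
    if (!is.null(frag$internal_bonds)) {
      fb <- frag$internal_bonds
      bonds <- rbind(bonds, data.frame(i = base + fb$i, j = base + fb$j,
                                       order = fb$order))
    }
  }
  if (jitter_sd > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter_sd)
  }
  ligand_pose(compound_id, atoms, bonds, pose_index = 1L,
              frame_id = "synthetic-receptor")
}

#' Generate the synthetic aligned benchmark
#'
#' Builds `n_compounds` decorated pseudo-molecules (two families, common
#' cationic-nitrogen anchor), assigns PEOE charges, computes the CoMFA field
#' matrix, plants a sparse coefficient vector over field columns around the
#' first `n_latent` signal sites (each an independent substituent position,
#' so the activity signal has `n_latent` latent dimensions), and emits
#' activities `y = X b` affinely mapped onto the target pIC50 span plus
#' Gaussian noise, with the lowest tail left-censored at exactly 5.0.
#'
#' In multi-pose mode each compound additionally gets decoy poses displaced
#' from the anchor, so the salt-bridge alignment stage has real work to do.
#'
#' @param spec a [synthetic_spec].
#' @return list with `dataset` (an `aligned_dataset` of charged poses),
#'   `field_matrix` (the raw fields the activities were planted on),
#'   `truth` (planted coefficients, per-site regions, planted field
#'   contributions, the affine map and noise-free signal), and in multi-pose
#'   mode `all_poses` plus `true_pose_index`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sites <- substituent_sites()
  kinds <- substituent_kinds()
  with_seed(spec$seed, {
    n <- spec$n_compounds
    ids <- sprintf("CMP%03d", seq_len(n))
    fams <- sample(rep(c("benzamide", "arylpiperazine"), length.out = n))
    occ <- matrix(sample(kinds, n * nrow(sites), replace = TRUE,
                         prob = substituent_probs()),
                  n, nrow(sites))
    poses <- lapply(seq_len(n), function(i) {
      assign_charges(build_synthetic_pose(ids[i], fams[i], occ[i, ],
                                          spec$jitter_sd))
    })
    names(poses) <- ids
    anchor <- synthetic_anchor()
    grid <- build_grid(poses, spacing = 2.0, margin = 4.0)
    fm <- compute_field_matrix(poses, grid)
    # plant sparse coefficients around the signal sites
    meta <- fm$col_meta
    X <- fm$values
    b <- numeric(ncol(X))
    importance <- c(1.0, 0.9, 0.8, 0.7, 0.6)
    regions <- list()
    for (k in seq_len(spec$n_latent)) {
      spos <- as.numeric(sites[k, c("x", "y", "z")])
      d <- sqrt((meta$x - spos[1])^2 + (meta$y - spos[2])^2 +
                  (meta$z - spos[3])^2)
      cols <- which(meta$field == sites$field[k] & d <= 2.2)
      cols <- cols[apply(X[, cols, drop = FALSE], 2, stats::sd) > 1e-8]
      if (!length(cols)) {
        stopf("signal site %s has no varying field column: span unreachable",
              sites$site[k])
      }
      score <- rowSums(X[, cols, drop = FALSE])
      sdk <- stats::sd(score)
      if (sdk < 1e-8) {
        stopf("signal site %s carries no activity variance: span unreachable",
              sites$site[k])
      }
      wk <- importance[k] / sdk
      b[cols] <- b[cols] + sites$sign[k] * wk
      regions[[sites$site[k]]] <- cols
    }
    s_raw <- drop(X %*% b)
    if (diff(range(s_raw)) < 1e-8) stopf("planted signal is constant: span unreachable")
    # scale the signal to the target span, add noise in pIC50 units, then
    # re-map affinely so the span invariant holds by construction (the
    # planted model stays linear; coefficients and noise rescale with it)
    a1 <- diff(spec$activity_span) / diff(range(s_raw))
    y1 <- a1 * (s_raw - min(s_raw)) + spec$activity_span[1] +
      stats::rnorm(n, 0, spec$noise_sd)
    # anchor the map so the top ~3% of compounds (at least 2) sit above the
    # upper span bound, as in real series whose most potent members all
    # exceed pIC50 9
    k_top <- max(2L, ceiling(0.03 * n))
    y1_hi <- sort(y1, decreasing = TRUE)[k_top]
    a2 <- (spec$activity_span[2] - spec$activity_span[1]) /
      (y1_hi - min(y1))
    y <- a2 * (y1 - min(y1)) + spec$activity_span[1]
    b_true <- a1 * a2 * b
    intercept <- spec$activity_span[1] - a2 * min(y1) +
      a2 * (spec$activity_span[1] - a1 * min(s_raw))
    y0 <- drop(X %*% b_true) + intercept   # noise-free planted signal
    n_cens <- ceiling(spec$censor_fraction * n)
    censored <- rep(FALSE, n)
    if (n_cens > 0) censored[order(y)[seq_len(n_cens)]] <- TRUE
    censored <- censored | y < 5
    y[censored] <- 5.0
    if (max(y) < 9) {
      stopf("generated activities do not reach pIC50 9: span unreachable")
    }
    activities <- data.frame(compound_id = ids,
                             ic50_nM = ifelse(censored, ">100000",
                                              sprintf("%.6g", pic50_to_ic50(y))),
                             pic50 = y, censored = censored, family = fams)
    dataset <- structure(list(poses = poses, activities = activities,
                              anchor = anchor, max_dist = 4.0,
                              dropped = data.frame(compound_id = character(0),
                                                   reason = character(0))),
                         class = "aligned_dataset")
    planted_contrib <- vapply(c("steric", "electrostatic"), function(f) {
      j <- which(b_true != 0 & meta$field == f)
      sum(abs(b_true[j]) * fm$column_sd[j])
    }, numeric(1))
    planted_contrib <- 100 * planted_contrib / sum(planted_contrib)
    truth <- list(b = b_true, regions = regions,
                  n_latent = spec$n_latent,
                  planted_contributions = planted_contrib,
                  affine = c(scale = a1 * a2, intercept = intercept),
                  y_signal = y0, occupancy = occ, families = fams)
    out <- list(dataset = dataset, field_matrix = fm, truth = truth,
                spec = spec)
    if (spec$multi_pose) {
      mp <- make_decoy_poses(poses, anchor, spec$n_poses, dataset$max_dist)
      out$all_poses <- mp$all_poses
      out$true_pose_index <- mp$true_pose_index
    }
    out
  })
}

# Decoy docking poses: rigid translations away from the anchor, guaranteed
# to fail the salt-bridge cutoff; the true pose keeps its (random) index.
make_decoy_poses <- function(poses, anchor, n_poses, max_dist) {
  all_poses <- list()
  true_idx <- integer(length(poses))
  names(true_idx) <- names(poses)
  for (ci in seq_along(poses)) {
    p <- poses[[ci]]
    slot <- sample.int(n_poses, 1)
    true_idx[ci] <- slot
    for (k in seq_len(n_poses)) {
      if (k == slot) {
        q <- p
        q$pose_index <- k
      } else {
        repeat {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          shift <- u * stats::runif(1, 5, 10)
          q <- p
          q$pose_index <- k
          q$atoms$x <- p$atoms$x + shift[1]
          q$atoms$y <- p$atoms$y + shift[2]
          q$atoms$z <- p$atoms$z + shift[3]
          if (anchor_distance(q, anchor) > max_dist) break
        }
      }
      all_poses[[length(all_poses) + 1L]] <- q
    }
  }
  list(all_poses = all_poses, true_pose_index = true_idx)
}

#' Parameter-recovery report
#'
#' Compares a fitted CoMFA model against the generator's ground truth:
#' selected vs planted component count, sign agreement of the STDEV*COEFF
#' values with the planted coefficients over the retained planted columns,
#' and the error of the steric/electrostatic contribution split.
#'
#' @param model a `pls_model` fit on `prep$X`.
#' @param prep the `field_prep` used for fitting.
#' @param truth the `truth` component of [generate_dataset].
#' @param stats optional named list of additional statistics to carry along
#'   (e.g. q2, r2, external_r2).
#' @return list of recovery metrics.
#' @export
recovery_report <- function(model, prep, truth, stats = list()) {
  cf <- stdev_coeff_field(model, prep)
  v <- unlist(cf$values, use.names = FALSE)
  planted <- which(truth$b != 0)
  usable <- planted[prep$retained[planted] & v[planted] != 0]
  sign_agreement <- if (length(usable)) {
    mean(sign(v[usable]) == sign(truth$b[usable]))
  } else NA_real_
  contrib <- field_contributions(model, prep$X, prep$fields)
  contrib_err <- max(abs(contrib[names(truth$planted_contributions)] -
                           truth$planted_contributions))
  c(list(onc = model$n_components, n_latent = truth$n_latent,
         sign_agreement = sign_agreement,
         contributions = contrib,
         planted_contributions = truth$planted_contributions,
         contribution_error = contrib_err),
    stats)
}

#' Write the synthetic benchmark to disk
#'
#' Emits `poses.sdf` (charged poses; all docking poses in multi-pose mode),
#' `receptor_anchor.pdb` (a synthetic single-aspartate stand-in receptor),
#' `activities.csv` and `truth.json` into `dir`.
#'
#' @param gen result of [generate_dataset].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  poses <- gen$all_poses %||% unname(gen$dataset$poses)
  write_poses(poses, file.path(dir, "poses.sdf"))
  write_synthetic_receptor(file.path(dir, "receptor_anchor.pdb"))
  utils::write.csv(gen$dataset$activities, file.path(dir, "activities.csv"),
                   row.names = FALSE)
  tr <- gen$truth
  jsonlite::write_json(
    list(n_latent = tr$n_latent,
         planted_columns = which(tr$b != 0),
         planted_values = tr$b[tr$b != 0],
         planted_contributions = as.list(tr$planted_contributions),
         affine = as.list(tr$affine)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_synthetic_inputs
#' @param path output PDB path.
#' @export
write_synthetic_receptor <- function(path) {
  xyz <- rbind(N = c(5.8, -0.2, 1.5), CA = c(5.0, 0.3, 0.4),
               CB = c(4.2, -0.7, -0.4), CG = c(3.3, 0.0, -0.1),
               OD1 = c(3.0, -1.1, 0), OD2 = c(3.0, 1.1, 0))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", 6), resno = rep(114L, 6),
                   resid = rep("ASP", 6), eleno = 1:6,
                   elety = rownames(xyz), chain = rep("A", 6))
  invisible(path)
}
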