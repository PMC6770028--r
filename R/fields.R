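# CoMFA molecular interaction fields: Lennard-Jones (steric) and Coulomb
# (electrostatic, distance-dependent dielectric) energies of an sp3-carbon
# +1.0 e probe on a regular lattice enclosing the aligned dataset.

ELECTROSTATIC_CONSTANT <- 332.0636  # kcal * Angstrom / (mol * e^2)

.comfa_env <- new.env(parent = emptyenv())

# Tripos 5.2 vdW parameters, keyed by atom class (shipped in extdata).
tripos_vdw <- function() {
  if (is.null(.comfa_env$vdw)) {
    path <- system.file("extdata", "tripos_vdw.csv", package = "comfa")
    .comfa_env$vdw <- utils::read.csv(path, comment.char = "#")
  }
  .comfa_env$vdw
}

#' CoMFA probe specification
#'
#' The standard probe: an sp3 carbon with point charge +1.0 e and Tripos
#' Lennard-Jones parameters.
#'
#' @param charge probe point charge (e).
#' @param radius,epsilon probe Lennard-Jones parameters (Angstrom, kcal/mol).
#' @export
probe_spec <- function(charge = 1.0, radius = 1.70, epsilon = 0.107) {
  structure(list(atom_class = "sp3-C", charge = charge,
                 radius = radius, epsilon = epsilon), class = "probe_spec")
}

#' Build the field lattice
#'
#' Axis-aligned regular grid covering the union bounding box of all aligned
#' poses plus `margin`, with the extent snapped outward to whole grid steps.
#'
#' @param dataset an `aligned_dataset` or list of [ligand_pose].
#' @param spacing grid step in Angstrom.
#' @param margin enclosure margin in Angstrom.
#' @return A `grid_region` with `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(dataset, spacing = 2.0, margin = 4.0) {
  poses <- if (inherits(dataset, "aligned_dataset")) dataset$poses else dataset
  if (!length(poses)) stopf("cannot build a grid from an empty dataset")
  stopifnot(spacing > 0)
  xyz <- do.call(rbind, lapply(poses, atom_coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  structure(list(origin = unname(lo), spacing = spacing, dims = dims),
            class = "grid_region")
}

#' @export
print.grid_region <- function(x, ...) {
  cat(sprintf("<grid_region> %d x %d x %d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Lattice point coordinates
#'
#' Points are emitted with the z index varying fastest, then y, then x
#' (the OpenDX scan order used by [export_dx]).
#'
#' @param grid a `grid_region`.
#' @return numeric matrix, one row per lattice point.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k) grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1))
  g <- expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]])
  unname(as.matrix(g[, c("x", "y", "z")]))
}

atom_lj_params <- function(pose) {
  vdw <- tripos_vdw()
  hit <- match(pose$atoms$atom_class, vdw$atom_class)
  hit[is.na(hit)] <- match("other", vdw$atom_class)
  list(radius = vdw$radius[hit], epsilon = vdw$epsilon[hit])
}

# atoms x points distance matrix
dist_atoms_points <- function(pose, points) {
  xyz <- atom_coords(pose)
  dx <- outer(xyz[, 1], points[, 1], "-")
  dy <- outer(xyz[, 2], points[, 2], "-")
  dz <- outer(xyz[, 3], points[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Steric (Lennard-Jones) probe energy
#'
#' Tripos 6-12 potential summed over atoms,
#' `eps_ij * ((R_ij/r)^12 - 2 (R_ij/r)^6)` with `R_ij = R_atom + R_probe`
#' and `eps_ij = sqrt(eps_atom * eps_probe)`; the summed value is capped at
#' +30 kcal/mol (points coinciding with an atom return exactly the cap).
#'
#' @param pose a typed [ligand_pose].
#' @param points numeric matrix of probe positions (rows) or a length-3
#'   vector.
#' @param probe a [probe_spec].
#' @param cap upper energy cap in kcal/mol.
#' @return numeric vector of energies, one per point.
#' @export
steric_energy <- function(pose, points, probe = probe_spec(), cap = 30) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  lj <- atom_lj_params(pose)
  Rij <- lj$radius + probe$radius
  eij <- sqrt(lj$epsilon * probe$epsilon)
  r <- dist_atoms_points(pose, points)
  r[r < 1e-12] <- 1e-12
  s6 <- (Rij / r)^6        # recycles Rij down columns
  e <- colSums(eij * (s6^2 - 2 * s6))
  pmin(e, cap)
}

#' Electrostatic probe energy
#'
#' Coulomb interaction with a distance-dependent dielectric eps(r) = r:
#' `332.0636 * q_probe * sum_i q_i / r_i^2`, clamped to `[-cap, +cap]`.
#' Lattice points buried inside a molecule are handled at matrix assembly
#' (see [compute_field_matrix]).
#'
#' @inheritParams steric_energy
#' @return numeric vector of energies, one per point.
#' @export
electrostatic_energy <- function(pose, points, probe = probe_spec(), cap = 30) {
  if (anyNA(pose$atoms$charge)) {
    stopf("pose '%s' has no partial charges; run assign_charges() first",
          pose$compound_id)
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- dist_atoms_points(pose, points)
  r[r < 1e-12] <- 1e-12
  e <- ELECTROSTATIC_CONSTANT * probe$charge *
    colSums(pose$atoms$charge / r^2)
  pmax(pmin(e, cap), -cap)
}

# TRUE for lattice points lying inside the steric envelope (any atom within
# its own LJ radius).
inside_envelope <- function(pose, points) {
  lj <- atom_lj_params(pose)
  r <- dist_atoms_points(pose, points)
  colSums(r <= lj$radius) > 0
}

#' Compute the CoMFA field matrix
#'
#' Evaluates both fields at every lattice point for every compound. Columns
#' are ordered steric block first, then electrostatic block, each in lattice
#' scan order. Electrostatic values at points inside any molecule's steric
#' envelope are replaced by the column mean over the compounds for which the
#' point is outside (the Sybyl convention).
#'
#' @param dataset an `aligned_dataset` (or named list of charged poses).
#' @param grid a `grid_region` from [build_grid].
#' @param probe a [probe_spec].
#' @param steric_cap,electro_cap energy caps in kcal/mol.
#' @return A `field_matrix`: `values` (compounds x columns), `col_meta`,
#'   `column_sd`, `grid`, `probe`.
#' @export
compute_field_matrix <- function(dataset, grid, probe = probe_spec(),
                                 steric_cap = 30, electro_cap = 30) {
  poses <- if (inherits(dataset, "aligned_dataset")) dataset$poses else dataset
  if (!length(poses)) stopf("empty dataset")
  ids <- vapply(poses, function(p) p$compound_id, character(1))
  pts <- grid_points(grid)
  P <- nrow(pts)
  n <- length(poses)
  ster <- matrix(NA_real_, n, P)
  elec <- matrix(NA_real_, n, P)
  inside <- matrix(FALSE, n, P)
  for (i in seq_len(n)) {
    p <- poses[[i]]
    res <- tryCatch({
      list(s = steric_energy(p, pts, probe, steric_cap),
           e = electrostatic_energy(p, pts, probe, electro_cap),
           m = inside_envelope(p, pts))
    }, error = function(err) {
      stopf("field computation failed for compound '%s': %s",
            p$compound_id, conditionMessage(err))
    })
    ster[i, ] <- res$s
    elec[i, ] <- res$e
    inside[i, ] <- res$m
  }
  # Sybyl-style replacement of buried electrostatic values by column means
  for (j in which(colSums(inside) > 0)) {
    out <- !inside[, j]
    elec[inside[, j], j] <- if (any(out)) mean(elec[out, j]) else mean(elec[, j])
  }
  values <- cbind(ster, elec)
  rownames(values) <- ids
  col_meta <- data.frame(
    field = rep(c("steric", "electrostatic"), each = P),
    point = rep(seq_len(P), 2),
    x = rep(pts[, 1], 2), y = rep(pts[, 2], 2), z = rep(pts[, 3], 2))
  structure(list(values = values, col_meta = col_meta,
                 column_sd = apply(values, 2, stats::sd),
                 grid = grid, probe = probe),
            class = "field_matrix")
}

#' @export
print.field_matrix <- function(x, ...) {
  cat(sprintf("<field_matrix> %d compounds x %d columns (%d lattice points x 2 fields)\n",
              nrow(x$values), ncol(x$values), nrow(x$values) * 0 + ncol(x$values) / 2))
  invisible(x)
}

#' Row subset of a field matrix
#'
#' @param fm a `field_matrix`.
#' @param ids compound ids (rownames) or row indices to keep.
#' @return a `field_matrix` over the subset, with `column_sd` recomputed.
#' @export
subset_field_matrix <- function(fm, ids) {
  stopifnot(inherits(fm, "field_matrix"))
  v <- fm$values[ids, , drop = FALSE]
  out <- fm
  out$values <- v
  out$column_sd <- apply(v, 2, stats::sd)
  out
}

#' Column filtering and CoMFA standard scaling
#'
#' Drops columns whose standard deviation across compounds is below
#' `min_sigma` (the Sybyl minimum-sigma filter, default 2.0 kcal/mol), then
#' applies CoMFA-STD block scaling: each field block is scaled so that its
#' total column variance (after centering) is the same for both fields.
#' The returned preparation can be re-applied to new compounds (e.g. a test
#' set) with [apply_field_prep]; the filter is meant to be fit once on the
#' training set.
#'
#' @param fm a `field_matrix`, or plain matrix plus `fields`.
#' @param min_sigma minimum column standard deviation (kcal/mol).
#' @param scaling only `"CoMFA-STD"` is implemented.
#' @param fields optional character vector of per-column field labels when
#'   `fm` is a plain matrix.
#' @return A `field_prep`: `X` (filtered, block-scaled matrix), `retained`
#'   (logical over original columns), `block_scale`, `fields`, `col_meta`.
#' @export
filter_and_scale <- function(fm, min_sigma = 2.0, scaling = "CoMFA-STD",
                             fields = NULL) {
  scaling <- match.arg(scaling, "CoMFA-STD")
  if (inherits(fm, "field_matrix")) {
    X <- fm$values
    fields <- fm$col_meta$field
    col_meta <- fm$col_meta
  } else {
    X <- as.matrix(fm)
    if (is.null(fields)) fields <- rep("steric", ncol(X))
    col_meta <- NULL
  }
  sds <- apply(X, 2, stats::sd)
  retained <- sds >= min_sigma & is.finite(sds)
  if (!any(retained)) stopf("min_sigma %.2f drops every column", min_sigma)
  Xr <- X[, retained, drop = FALSE]
  fr <- fields[retained]
  block_scale <- vapply(unique(fr), function(f) {
    v <- sum(apply(Xr[, fr == f, drop = FALSE], 2, stats::var))
    if (v <= 0) 1 else 1 / sqrt(v)
  }, numeric(1))
  names(block_scale) <- unique(fr)
  Xs <- sweep(Xr, 2, block_scale[fr], "*")
  out <- structure(list(X = Xs, retained = retained, block_scale = block_scale,
                        fields = fr, min_sigma = min_sigma, col_meta = col_meta),
                   class = "field_prep")
  if (inherits(fm, "field_matrix")) attr(out, "grid") <- fm$grid
  out
}

#' @rdname filter_and_scale
#' @param prep a `field_prep` fitted on the training set.
#' @param newdata a `field_matrix` or matrix with the same original columns.
#' @export
apply_field_prep <- function(prep, newdata) {
  X <- if (inherits(newdata, "field_matrix")) newdata$values else as.matrix(newdata)
  if (ncol(X) != length(prep$retained)) {
    stopf("newdata has %d columns; preparation expects %d",
          ncol(X), length(prep$retained))
  }
  Xr <- X[, prep$retained, drop = FALSE]
  sweep(Xr, 2, prep$block_scale[prep$fields], "*")
}
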