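single_carbon <- function(at = c(0, 0, 0), id = "c1") {
  p <- ligand_pose(id, data.frame(element = "C", x = at[1], y = at[2], z = at[3]))
  p$atoms$charge <- 0
  p
}

test_that("the lattice encloses the dataset with margin, snapped outward", {
  g <- build_grid(list(single_carbon()), spacing = 2, margin = 4)
  expect_equal(g$origin, c(-4, -4, -4))
  expect_identical(g$dims, c(5L, 5L, 5L))
  g1 <- build_grid(list(single_carbon()), spacing = 1, margin = 4)
  expect_identical(g1$dims, c(9L, 9L, 9L))
  # every atom at least `margin` inside the box
  poses <- list(assign_charges(pose_ethylamine()), assign_charges(pose_methanol()))
  g2 <- build_grid(poses, spacing = 2, margin = 4)
  hi <- g2$origin + (g2$dims - 1) * g2$spacing
  for (p in poses) {
    xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
    expect_true(all(sweep(xyz, 2, g2$origin) >= 4 - 1e-9))
    expect_true(all(sweep(xyz, 2, hi) <= -4 + 1e-9))
  }
})

test_that("steric energy has the Tripos 6-12 form with a +30 cap", {
  p <- single_carbon()
  probe <- probe_spec()
  # far away: negligible
  expect_lt(abs(steric_energy(p, c(25, 0, 0), probe)), 1e-3)
  # on top of the atom: exactly the cap
  expect_equal(steric_energy(p, c(0, 0, 0), probe), 30)
  # at r = R_ij the potential equals the well depth -eps_ij
  rij <- 1.70 + probe$radius
  eij <- sqrt(0.107 * probe$epsilon)
  expect_equal(steric_energy(p, c(rij, 0, 0), probe), -eij, tolerance = 1e-12)
})

test_that("electrostatic energy uses 332.0636 with 1/r dielectric", {
  p <- single_carbon()
  p$atoms$charge <- 1
  e <- electrostatic_energy(p, c(10, 0, 0), probe_spec())
  expect_equal(e, 332.0636 / 100, tolerance = 1e-12)
  # zero charges give exactly zero
  p0 <- single_carbon()
  expect_identical(electrostatic_energy(p0, c(3, 1, 0)), 0)
  # mirror-symmetric +/- pair, probe on the symmetry plane
  pm <- ligand_pose("pair", data.frame(element = c("N", "O"),
                                       x = c(-2, 2), y = 0, z = 0))
  pm$atoms$charge <- c(0.4, -0.4)
  expect_lt(abs(electrostatic_energy(pm, c(0, 5, 1))), 1e-9)
  # uncharged pose is an error pointing at the charges stage
  expect_error(electrostatic_energy(pose_methanol(), c(0, 0, 5)),
               "assign_charges")
})

test_that("energies are additive over atom subsets before clamping", {
  p <- assign_charges(pose_ethylamine())
  idx1 <- 1:5; idx2 <- 6:10
  sub <- function(idx) {
    q <- ligand_pose("part", p$atoms[idx, c("element", "x", "y", "z")])
    q$atoms$charge <- p$atoms$charge[idx]
    q$atoms$atom_class <- p$atoms$atom_class[idx]
    q
  }
  pts <- rbind(c(6, 2, 1), c(-3, -4, 2), c(0, 8, 0))
  expect_equal(steric_energy(sub(idx1), pts, cap = Inf) +
                 steric_energy(sub(idx2), pts, cap = Inf),
               steric_energy(p, pts, cap = Inf), tolerance = 1e-12)
  expect_equal(electrostatic_energy(sub(idx1), pts, cap = Inf) +
                 electrostatic_energy(sub(idx2), pts, cap = Inf),
               electrostatic_energy(p, pts, cap = Inf), tolerance = 1e-12)
})

charged_poses <- function() {
  list(assign_charges(pose_methanol()),
       assign_charges(pose_ethylamine()),
       assign_charges(pose_piperazinium()),
       assign_charges(pose_benzene()),
       assign_charges(pose_pyridinium()))
}

test_that("the field matrix has compounds x 2P values matching point calls", {
  poses <- charged_poses()
  g <- build_grid(poses, spacing = 2, margin = 4)
  fm <- compute_field_matrix(poses, g)
  P <- prod(g$dims)
  expect_identical(dim(fm$values), as.integer(c(5, 2 * P)))
  expect_identical(fm$col_meta$field, rep(c("steric", "electrostatic"), each = P))
  # spot-check cells against direct single-point evaluation
  pts <- grid_points(g)
  set.seed(14)
  for (k in 1:10) {
    i <- sample(5, 1); j <- sample(P, 1)
    expect_equal(unname(fm$values[i, j]),
                 steric_energy(poses[[i]], pts[j, ], fm$probe),
                 tolerance = 1e-12)
  }
  # duplicated compound gives identical rows
  fm2 <- compute_field_matrix(c(poses, poses[1]), g)
  expect_equal(unname(fm2$values[6, ]), unname(fm2$values[1, ]))
})

test_that("buried electrostatic values are replaced by the outside mean", {
  big <- assign_charges(pose_piperazinium())
  small <- single_carbon(at = c(8, 8, 8), id = "far")
  g <- build_grid(list(big, small), spacing = 2, margin = 4)
  pts <- grid_points(g)
  fm <- compute_field_matrix(list(big, small), g)
  ins_big <- comfa:::inside_envelope(big, pts)
  ins_small <- comfa:::inside_envelope(small, pts)
  j <- which(ins_big & !ins_small)[1]
  expect_false(is.na(j))
  P <- prod(g$dims)
  # row 1 (buried) must carry row 2's (outside) value at that column
  expect_equal(unname(fm$values[1, P + j]), unname(fm$values[2, P + j]))
})

test_that("translating dataset and grid together leaves fields bit-identical", {
  poses <- charged_poses()
  g <- build_grid(poses, spacing = 2, margin = 4)
  fm <- compute_field_matrix(poses, g)
  shift <- c(11, -7, 3)
  poses2 <- lapply(poses, function(p) {
    p$atoms$x <- p$atoms$x + shift[1]
    p$atoms$y <- p$atoms$y + shift[2]
    p$atoms$z <- p$atoms$z + shift[3]
    p
  })
  g2 <- g
  g2$origin <- g$origin + shift
  fm2 <- compute_field_matrix(poses2, g2)
  expect_equal(fm$values, fm2$values, tolerance = 1e-10)
})

test_that("minimum-sigma filtering and CoMFA-STD scaling behave as specified", {
  set.seed(3)
  X <- cbind(matrix(rnorm(40, sd = 4), 10, 4), 7)  # last column constant
  fields <- c("steric", "steric", "electrostatic", "electrostatic", "electrostatic")
  prep <- filter_and_scale(X, min_sigma = 2, fields = fields)
  expect_false(prep$retained[5])                  # constant column dropped
  prep0 <- filter_and_scale(X, min_sigma = 0, fields = fields)
  expect_true(all(prep0$retained))
  # block variances equal after scaling
  bv <- tapply(apply(prep$X, 2, var), prep$fields, sum)
  expect_equal(unname(diff(range(bv))), 0, tolerance = 1e-9)
  # preparation re-applies identically to new rows
  Xs <- apply_field_prep(prep, X)
  expect_equal(unname(Xs), unname(prep$X))
})
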