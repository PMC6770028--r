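# Small molecules built in code for unit tests.

pose_methanol <- function() {
  ligand_pose("methanol", data.frame(
    element = c("C", "O", "H", "H", "H", "H"),
    x = c(0, 1.43, -0.5, -0.5, -0.5, 1.8),
    y = c(0, 0, 0.9, -0.9, 0, 0.8),
    z = c(0, 0, 0, 0, 1, 0.2)),
    data.frame(i = c(1, 1, 1, 1, 2), j = c(2, 3, 4, 5, 6), order = 1))
}

pose_ethylamine <- function() {
  ligand_pose("ethylamine", data.frame(
    element = c("C", "C", "N", "H", "H", "H", "H", "H", "H", "H"),
    x = c(0, 1.5, 2.2, -0.5, -0.5, -0.5, 1.9, 1.9, 3.2, 2.0),
    y = c(0, 0.5, -0.6, 0.9, -0.9, 0, 1.2, 1.2, -0.6, -1.5),
    z = c(0, 1.2, 1.9, 0.1, 0.2, -1, 1, 2, 2, 1.6)),
    data.frame(i = c(1, 2, 1, 1, 1, 2, 2, 3, 3),
               j = c(2, 3, 4, 5, 6, 7, 8, 9, 10), order = 1))
}

pose_ethane <- function() {
  ligand_pose("ethane", data.frame(
    element = c("C", "C", "H", "H", "H", "H", "H", "H"),
    x = c(0, 1.54, -0.5, -0.5, -0.5, 2.04, 2.04, 2.04),
    y = c(0, 0, 0.9, -0.9, 0, 0.9, -0.9, 0),
    z = c(0, 0, 0.3, 0.3, -1, 0.3, 0.3, 1)),
    data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
               j = c(2, 3, 4, 5, 6, 7, 8), order = 1))
}

ring_xyz <- function(r = 1.39, z = 0.1) {
  th <- seq(0, 300, 60) * pi / 180
  cbind(r * cos(th), r * sin(th), z)
}

pose_benzene <- function() {
  rg <- ring_xyz()
  ligand_pose("benzene", data.frame(
    element = rep("C", 6), x = rg[, 1], y = rg[, 2], z = rg[, 3]),
    data.frame(i = 1:6, j = c(2:6, 1), order = 4))
}

pose_pyridinium <- function() {
  rg <- ring_xyz()
  ligand_pose("pyridinium", data.frame(
    element = c("N", rep("C", 5), "H"),
    x = c(rg[, 1], 2.4), y = c(rg[, 2], 0), z = c(rg[, 3], 0.1),
    formal_charge = c(1L, rep(0L, 6))),
    data.frame(i = c(1:6, 1), j = c(2:6, 1, 7), order = c(rep(4, 6), 1)))
}

# Protonated piperazine fragment: one cationic and one neutral ring nitrogen.
pose_piperazinium <- function(shift = c(0, 0, 0)) {
  th <- seq(0, 300, 60) * pi / 180
  x <- -1.46 + 1.46 * cos(th)
  y <- 1.46 * sin(th)
  ligand_pose("piperazinium", data.frame(
    element = c("N", "C", "C", "N", "C", "C", "H"),
    x = c(x, 0.55) + shift[1], y = c(y, 0) + shift[2],
    z = c(rep(0, 6), 1) + shift[3],
    formal_charge = c(1L, rep(0L, 6))),
    data.frame(i = c(1:6, 1), j = c(2:6, 1, 7), order = 1))
}

# Neutral molecule with an amide nitrogen and one sp3 amine nitrogen.
pose_amide_amine <- function() {
  ligand_pose("amide_amine", data.frame(
    element = c("N", "C", "O", "C", "N", "H", "H"),
    x = c(0, 1.3, 1.4, 2.5, 3.8, -0.6, 4.2),
    y = c(0, 0.6, 1.8, -0.3, 0.3, -0.8, 1.1),
    z = c(0, 0, 0.2, -0.8, -0.5, 0.3, 0)),
    data.frame(i = c(1, 2, 2, 4, 1, 5),
               j = c(2, 3, 4, 5, 6, 7),
               order = c(1, 2, 1, 1, 1, 1)))
}

test_anchor <- function() anchor_site(c(3.0, -1.1, 0), c(3.0, 1.1, 0), "ASP114")

# Single cationic nitrogen at `npos`, with a carbon tail.
pose_with_n_at <- function(npos, compound_id = "probe", pose_index = 1L) {
  ligand_pose(compound_id, data.frame(
    element = c("N", "C", "H"),
    x = c(npos[1], npos[1] - 1.5, npos[1] + 0.4),
    y = c(npos[2], npos[2], npos[2] + 0.9),
    z = c(npos[3], npos[3], npos[3] - 0.3),
    formal_charge = c(1L, 0L, 0L)),
    data.frame(i = c(1, 1), j = c(2, 3), order = 1),
    pose_index = pose_index)
}
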