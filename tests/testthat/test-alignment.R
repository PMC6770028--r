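test_that("protonatable nitrogen detection follows the cation/amine rules", {
  # charged ring N of piperazinium is returned (not the neutral one)
  expect_identical(find_protonatable_nitrogens(pose_piperazinium()), 1L)
  # amide N excluded, sp3 amine accepted, in the same molecule
  expect_identical(find_protonatable_nitrogens(pose_amide_amine()), 5L)
  # two basic nitrogens: both returned in index order
  two_n <- ligand_pose("diamine", data.frame(
    element = c("N", "C", "C", "N"),
    x = c(0, 1.5, 3.0, 4.5), y = 0, z = c(0, 0.3, 0, 0.3)),
    data.frame(i = 1:3, j = 2:4, order = 1))
  expect_identical(find_protonatable_nitrogens(two_n), c(1L, 4L))
  # no candidate at all -> empty
  expect_length(find_protonatable_nitrogens(pose_benzene()), 0)
})

test_that("salt-bridge filter applies the distance cutoff to either oxygen", {
  anc <- test_anchor()
  near <- pose_with_n_at(c(0, 0, 0))            # ~3.2 A from both oxygens
  far <- pose_with_n_at(c(-4, 0, 0))            # ~7.1 A
  kept <- salt_bridge_filter(list(near, far), anc, max_dist = 4.0)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$compound_id, "probe")
  expect_length(salt_bridge_filter(list(), anc), 0)
})

test_that("filter pass count equals brute-force distance enumeration", {
  anc <- test_anchor()
  set.seed(21)
  poses <- lapply(1:20, function(k) {
    pose_with_n_at(runif(3, -6, 6), compound_id = "cpd", pose_index = k)
  })
  kept <- salt_bridge_filter(poses, anc, max_dist = 4.0)
  brute <- sum(vapply(poses, function(p) {
    npos <- as.numeric(p$atoms[1, c("x", "y", "z")])
    min(sqrt(sum((npos - anc$o1)^2)), sqrt(sum((npos - anc$o2)^2))) <= 4.0
  }, logical(1)))
  expect_length(kept, brute)
  expect_gt(brute, 0)
})

test_that("representative pose selection minimises the stated triple key", {
  anc <- test_anchor()
  p29 <- pose_with_n_at(c(0.3, -0.2, 0.1), pose_index = 1L)   # closer
  p35 <- pose_with_n_at(c(-0.5, 0.4, 0.3), pose_index = 2L)   # farther
  expect_identical(select_representative_pose(list(p35, p29), anc)$pose_index, 1L)
  expect_identical(select_representative_pose(list(p29), anc)$pose_index, 1L)
  expect_error(select_representative_pose(list(), anc), "no passing pose")
})

test_that("selection with a reference matches brute-force key minimisation", {
  anc <- test_anchor()
  ref <- pose_piperazinium()
  set.seed(8)
  poses <- lapply(1:6, function(k) {
    p <- pose_piperazinium(shift = runif(3, -0.8, 0.8))
    p$pose_index <- k
    p
  })
  sel <- select_representative_pose(poses, anc, reference = ref)
  keys <- do.call(rbind, lapply(poses, function(p) {
    data.frame(d = round(comfa:::anchor_distance(p, anc), 9),
               ov = -round(comfa:::overlap_score(p, ref), 9),
               idx = p$pose_index)
  }))
  best <- keys[order(keys$d, keys$ov, keys$idx), ][1, "idx"]
  expect_identical(sel$pose_index, as.integer(best))
  # permutation invariance of input order
  sel2 <- select_representative_pose(rev(poses), anc, reference = ref)
  expect_identical(sel2$pose_index, sel$pose_index)
})

test_that("aligned datasets keep one qualifying pose per compound", {
  anc <- test_anchor()
  set.seed(31)
  poses <- list()
  ids <- sprintf("CPD%02d", 1:8)
  for (cid in ids) {
    for (k in 1:5) {
      # compound CPD08 never gets a qualifying pose
      npos <- if (cid == "CPD08") runif(3, 5, 9) else
        if (k == 3) runif(3, -0.5, 0.5) else runif(3, 5, 9)
      poses[[length(poses) + 1L]] <- pose_with_n_at(npos, cid, k)
    }
  }
  act <- data.frame(compound_id = ids, pic50 = seq(9, 5.5, length.out = 8),
                    family = rep(c("a", "b"), 4))
  ds <- build_aligned_dataset(poses, act, anc, max_dist = 4.0)
  expect_length(ds$poses, 7)
  expect_identical(ds$dropped$compound_id, "CPD08")
  d <- vapply(ds$poses, comfa:::anchor_distance, numeric(1), anchor = anc)
  expect_true(all(d <= 4.0))
  # pose input order does not change the selection
  ds2 <- build_aligned_dataset(rev(poses), act, anc, max_dist = 4.0)
  expect_identical(
    vapply(ds$poses, function(p) p$pose_index, 1L),
    vapply(ds2$poses, function(p) p$pose_index, 1L))
})
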