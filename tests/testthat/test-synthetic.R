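test_that("default generation reproduces the study's data regime", {
  gen <- generate_dataset(synthetic_spec(seed = 42))
  act <- gen$dataset$activities
  expect_identical(nrow(act), 176L)
  expect_setequal(unique(act$family), c("benzamide", "arylpiperazine"))
  expect_lte(min(act$pic50), 5)
  expect_gte(max(act$pic50), 9)
  expect_true(all(act$pic50[act$censored] == 5.0))
  expect_gt(sum(act$censored), 0)
  # alignment holds by construction
  d <- vapply(gen$dataset$poses, comfa:::anchor_distance, numeric(1),
              anchor = gen$dataset$anchor)
  expect_true(all(d <= 4.0))
  # determinism
  gen2 <- generate_dataset(synthetic_spec(seed = 42))
  expect_identical(gen$dataset$activities, gen2$dataset$activities)
  expect_identical(gen$field_matrix$values, gen2$field_matrix$values)
})

test_that("a noise-free uncensored dataset is fit almost exactly", {
  gen <- generate_dataset(synthetic_spec(n_compounds = 50, noise_sd = 0,
                                         censor_fraction = 0, seed = 13))
  # keep every field column: the planted model is then exactly linear in X
  prep <- filter_and_scale(gen$field_matrix, min_sigma = 0)
  y <- gen$dataset$activities$pic50
  sel <- select_onc(prep$X, y, 15)
  m <- fit_pls(prep$X, y, sel$onc, fields = prep$fields)
  st <- regression_stats(m, prep$X, y)
  expect_gt(st$r2, 0.999)
})

test_that("multi-pose mode plants exactly one qualifying pose per compound", {
  gen <- generate_dataset(synthetic_spec(n_compounds = 12, multi_pose = TRUE,
                                         n_poses = 20, seed = 19))
  expect_length(gen$all_poses, 240)
  anc <- gen$dataset$anchor
  per_cpd <- split(gen$all_poses,
                   vapply(gen$all_poses, function(p) p$compound_id, ""))
  for (cid in names(per_cpd)) {
    pass <- salt_bridge_filter(per_cpd[[cid]], anc, 4.0)
    expect_length(pass, 1)
    expect_identical(pass[[1]]$pose_index,
                     unname(gen$true_pose_index[cid]))
  }
  # the alignment stage recovers every compound
  ds <- build_aligned_dataset(gen$all_poses, gen$dataset$activities, anc, 4.0)
  expect_length(ds$poses, 12)
  expect_identical(nrow(ds$dropped), 0L)
})

test_that("recovery report distinguishes a real fit from a broken one", {
  gen <- generate_dataset(synthetic_spec(n_compounds = 60, noise_sd = 0.1,
                                         censor_fraction = 0, seed = 23))
  prep <- filter_and_scale(gen$field_matrix)
  y <- gen$dataset$activities$pic50
  sel <- select_onc(prep$X, y, 8)
  m <- fit_pls(prep$X, y, sel$onc, fields = prep$fields)
  rec <- recovery_report(m, prep, gen$truth, stats = list(q2 = sel$q2))
  expect_gte(rec$sign_agreement, 0.8)
  expect_identical(rec$q2, sel$q2)
  # coefficient signs flipped: agreement collapses
  m_bad <- m
  m_bad$coefficients <- -m$coefficients
  rec_bad <- recovery_report(m_bad, prep, gen$truth)
  expect_equal(rec$sign_agreement + rec_bad$sign_agreement, 1)
  expect_lte(rec_bad$sign_agreement, 0.2)
})

test_that("synthetic inputs round-trip through the file formats", {
  gen <- generate_dataset(synthetic_spec(n_compounds = 16, seed = 29))
  dir <- withr::local_tempdir()
  write_synthetic_inputs(gen, dir)
  poses <- read_poses(file.path(dir, "poses.sdf"))
  expect_length(poses, 16)
  expect_false(anyNA(poses[[1]]$atoms$charge))
  act <- read_activities(file.path(dir, "activities.csv"))
  expect_identical(nrow(act), 16L)
  expect_equal(sort(act$compound_id),
               sort(vapply(poses, function(p) p$compound_id, "")))
  anc <- locate_anchor(file.path(dir, "receptor_anchor.pdb"),
                       chain = "A", resno = 114)
  expect_equal(anc$o1, gen$dataset$anchor$o1)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$n_latent, 5)
})
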