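# Synthetic cohort generator: ground truth structure, determinism,
# spectral containment, and recovery of the generative connectome.

test_that("cohort_spec validates its bounds and names the violation", {
  expect_error(cohort_spec(tr_seconds = -1), "tr_seconds",
               class = "fcrel_config_error")
  expect_error(cohort_spec(duration_seconds = 5), "duration_seconds",
               class = "fcrel_config_error")
  expect_error(cohort_spec(subject_sd = -0.1), "subject_sd",
               class = "fcrel_config_error")
  expect_error(cohort_spec(noise_band_hz = c(0.1, 0.9), tr_seconds = 1),
               "Nyquist", class = "fcrel_config_error")
  expect_error(cohort_spec(conditions = c("task", "rest")), "rest",
               class = "fcrel_config_error")
  expect_error(
    cohort_spec(task_modulation = list(task = task_modulation(1:80)),
                n_rois = 50),
    "engaged", class = "fcrel_config_error"
  )
})

test_that("ground truth has the contracted shape, symmetry and centering", {
  spec <- cohort_spec(n_subjects = 5, n_rois = 3, duration_seconds = 60)
  truth <- generate_ground_truth(spec)
  expect_equal(dim(truth$group_z), c(3, 3))
  expect_equal(truth$group_z, t(truth$group_z))
  expect_equal(diag(truth$group_z), rep(0, 3))
  # per-subject deviations centered across subjects to numerical zero
  expect_lt(max(abs(apply(truth$subject_dev, c(1, 2), mean))), 1e-12)
  for (s in 1:5) {
    expect_equal(truth$subject_dev[, , s], t(truth$subject_dev[, , s]))
  }
  # realized condition-level z maps into (-1, 1) under tanh
  z1 <- truth$group_z + truth$subject_dev[, , 1] + truth$task_delta$task
  expect_true(all(abs(tanh(z1[upper.tri(z1)])) < 1))
})

test_that("degenerate subject_sd gives exactly zero deviations", {
  spec <- cohort_spec(n_subjects = 4, n_rois = 6, subject_sd = 0,
                      duration_seconds = 60)
  truth <- generate_ground_truth(spec)
  expect_true(all(truth$subject_dev == 0))
})

test_that("same spec and seed reproduce the ground truth and runs exactly", {
  spec <- cohort_spec(n_subjects = 3, n_rois = 8, duration_seconds = 60,
                      seed = 42)
  t1 <- generate_ground_truth(spec)
  t2 <- generate_ground_truth(spec)
  expect_identical(t1, t2)
  r1 <- suppressWarnings(simulate_run(t1, spec, 2, "task", 1))
  r2 <- suppressWarnings(simulate_run(t2, spec, 2, "task", 1))
  expect_identical(r1, r2)
})

test_that("task_delta is confined to connections between engaged ROIs", {
  spec <- cohort_spec(
    n_subjects = 2, n_rois = 10, duration_seconds = 60,
    task_modulation = list(task = task_modulation(c(2, 5, 7),
                                                  delta_z = 0.4))
  )
  truth <- generate_ground_truth(spec)
  d <- truth$task_delta$task
  eng <- c(2, 5, 7)
  expect_true(all(d[eng, eng][upper.tri(diag(3))] == 0.4))
  d[eng, eng] <- 0
  expect_true(all(d == 0))
  expect_true(all(truth$task_delta$rest == 0))
})

test_that("a run honours the length contract and per-run seed derivation", {
  spec <- cohort_spec(n_subjects = 2, n_rois = 6, conditions = "rest",
                      duration_seconds = 60, tr_seconds = 1,
                      nuisance_coupling = 0, state_sd = 0)
  truth <- generate_ground_truth(spec)
  run1 <- simulate_run(truth, spec, 1, "rest", 1)
  expect_equal(nrow(run1$data), 60)
  expect_equal(nrow(run1$motion), 60)
  expect_equal(length(run1$wm), 60)
  expect_true(all(is.finite(run1$data)))
  # different run index: same truth component, different noise realisation
  run2 <- simulate_run(truth, spec, 1, "rest", 2)
  expect_false(isTRUE(all.equal(run1$data, run2$data)))
  # regenerating run 2 in isolation matches
  expect_identical(run2$data, simulate_run(truth, spec, 1, "rest", 2)$data)
})

test_that("simulated series keep >=95% of their power inside the band", {
  spec <- cohort_spec(n_subjects = 1, n_rois = 12, conditions = "rest",
                      duration_seconds = 300, nuisance_coupling = 0,
                      seed = 3)
  truth <- generate_ground_truth(spec)
  run <- suppressWarnings(simulate_run(truth, spec, 1, "rest", 1))
  n <- nrow(run$data)
  f <- (seq_len(n) - 1) / (n * spec$tr_seconds)
  f <- pmin(f, 1 / spec$tr_seconds - f)
  inband <- f >= spec$noise_band_hz[1] & f <= spec$noise_band_hz[2]
  for (j in c(1, 5, 12)) {
    p <- Mod(stats::fft(run$data[, j]))^2
    expect_gt(sum(p[inband]) / sum(p[-1]), 0.95)
  }
})

test_that("a long stationary run recovers its own generative connectome", {
  spec <- cohort_spec(n_subjects = 4, n_rois = 50, conditions = "rest",
                      runs_per_condition = 1, duration_seconds = 900,
                      state_sd = 0, nuisance_coupling = 0, seed = 7)
  truth <- generate_ground_truth(spec)
  run <- suppressWarnings(simulate_run(truth, spec, 1, "rest", 1))
  emp <- correlation_matrix(run)$z
  target <- truth$group_z + truth$subject_dev[, , 1]
  expect_gt(cor(emp, target[upper.tri(target)]), 0.9)
})

test_that("group-mean connectivity over 30 subjects recovers group_z", {
  co <- stationary_rest_runs()
  z <- dplyr::bind_rows(lapply(co$runs[seq(1, 60, by = 2)],
                               correlation_matrix))
  gm <- dplyr::summarise(z, z = mean(z), .by = c(roi_i, roi_j))
  gz <- co$truth$group_z
  expect_gt(cor(gm$z, gz[upper.tri(gz)]), 0.95)
})

test_that("toy volume produces disjoint tissue masks and labelled series", {
  toy <- make_toy_volume(c(10, 10, 10), seed = 1)
  expect_gt(sum(toy$gray$grid), 0)
  expect_gt(sum(toy$wm$grid), 0)
  expect_gt(sum(toy$csf$grid), 0)
  expect_equal(max(toy$gray$grid + toy$wm$grid + toy$csf$grid), 1)
  expect_identical(toy$data, make_toy_volume(c(10, 10, 10), seed = 1)$data)
  # zero voxel noise: all voxels of a region share one series
  toy0 <- make_toy_volume(c(10, 10, 10), seed = 2, voxel_noise_sd = 0)
  vox <- which(toy0$true_labels == 1, arr.ind = TRUE)
  s1 <- toy0$data[vox[1, 1], vox[1, 2], vox[1, 3], ]
  s2 <- toy0$data[vox[2, 1], vox[2, 2], vox[2, 3], ]
  expect_equal(s1, s2)
  expect_error(make_toy_volume(c(4, 10, 10)), class = "fcrel_config_error")
})
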