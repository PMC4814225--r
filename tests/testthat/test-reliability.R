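# ICC: mean-squares correctness against a direct-summation oracle,
# invariances, parameter recovery, reliability maps and the volume curve.

test_that("identical sessions give ICC = 1; missing rows are dropped", {
  m <- cbind(c(1, 2, 3, 5), c(1, 2, 3, 5))
  expect_equal(icc(m), 1)
  m_na <- rbind(m, c(NA, 7))
  expect_warning(v <- icc(m_na), class = "fcrel_dropped_rows")
  expect_equal(v, 1)
  expect_error(icc(matrix(3, 4, 2)), class = "fcrel_data_error")
  expect_error(icc(m[1, , drop = FALSE]), class = "fcrel_data_error")
})

test_that("ICC estimates are near zero without subject structure", {
  withr::with_seed(12, {
    m <- matrix(rnorm(200 * 4), 200, 4)
    expect_lt(abs(icc(m)), 0.1)
  })
})

test_that("mean squares match the direct-summation oracle on a 4x2 matrix", {
  m <- matrix(c(9.1, 7.8, 8.4, 10.2,
                9.5, 7.4, 8.9, 10.0), nrow = 4)
  for (form in c("icc21", "icc11", "icc31")) {
    o <- oracle_anova_ms(m)
    n <- nrow(m); k <- ncol(m)
    expected <- switch(form,
      icc21 = (o$msr - o$mse) /
        (o$msr + (k - 1) * o$mse + k * (o$msc - o$mse) / n),
      icc11 = (o$msr - o$msw) / (o$msr + (k - 1) * o$msw),
      icc31 = (o$msr - o$mse) / (o$msr + (k - 1) * o$mse)
    )
    expect_equal(icc(m, form), expected, tolerance = 1e-10)
  }
  expect_equal(icc(m), oracle_icc21(m), tolerance = 1e-10)
})

test_that("ICC is invariant to common shifts and positive scalings", {
  withr::with_seed(13, m <- matrix(rnorm(40), 10, 4) +
                     rnorm(10) %o% rep(1, 4))
  base <- icc(m)
  expect_equal(icc(m + 17), base, tolerance = 1e-10)
  expect_equal(icc(m * 3.5), base, tolerance = 1e-10)
})

test_that("consistency ICC(3,1) dominates agreement ICC(2,1) under a session effect", {
  withr::with_seed(15, {
    m <- matrix(rnorm(60), 15, 4) + rnorm(15) %o% rep(1, 4)
    m <- m + rep(1, 15) %o% c(0, 0.5, 1, 1.5)  # systematic session shifts
    expect_gt(icc(m, "icc31"), icc(m, "icc21"))
  })
})

test_that("ICC recovers the generative variance ratio", {
  withr::with_seed(16, {
    sigma_b <- 0.8
    sigma_e <- 0.6
    target <- sigma_b^2 / (sigma_b^2 + sigma_e^2)
    subj <- rnorm(200, 0, sigma_b)
    m <- subj %o% rep(1, 4) + matrix(rnorm(200 * 4, 0, sigma_e), 200, 4)
    expect_equal(icc(m), target, tolerance = 0.05)
  })
})

# build a rest tensor straight from a generative ratings model:
# z(connection, subject, run) = subject effect + noise
ratings_tensor <- function(n_subj, n_roi, n_run, sd_subject, sd_noise,
                           seed) {
  withr::with_seed(seed, {
    pairs <- expand.grid(roi_i = seq_len(n_roi), roi_j = seq_len(n_roi))
    pairs <- pairs[pairs$roi_i < pairs$roi_j, ]
    n_conn <- nrow(pairs)
    subj_eff <- matrix(rnorm(n_conn * n_subj, 0, sd_subject), n_conn)
    rows <- list()
    for (s in seq_len(n_subj)) {
      for (r in seq_len(n_run)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sprintf("S%03d", s), condition = "rest", run = r,
          roi_i = pairs$roi_i, roi_j = pairs$roi_j,
          z = subj_eff[, s] + rnorm(n_conn, 0, sd_noise)
        )
      }
    }
    fcrel:::as_fc_tensor(dplyr::bind_rows(rows))
  })
}

test_that("reliability maps are 1 for noiseless repeats and ~0 without subjects", {
  perfect <- ratings_tensor(8, 6, 3, sd_subject = 0.3, sd_noise = 0,
                            seed = 17)
  map <- icc_map(perfect)
  expect_true(all(abs(map$mean_icc - 1) < 1e-10))
  null <- ratings_tensor(40, 6, 3, sd_subject = 0, sd_noise = 0.3,
                         seed = 18)
  map0 <- icc_map(null)
  expect_lt(max(abs(map0$mean_icc)), 0.2)
  expect_lt(abs(mean(map0$mean_icc)), 0.1)
})

test_that("a cohort without subject differences has near-null reliability", {
  spec <- cohort_spec(n_subjects = 25, n_rois = 15, conditions = "rest",
                      runs_per_condition = 2, duration_seconds = 300,
                      subject_sd = 0, state_sd = 0, nuisance_coupling = 0,
                      seed = 19)
  tensor <- suppressWarnings(cohort_connectivity(spec))
  map <- icc_map(tensor)
  expect_lt(abs(mean(map$mean_icc)), 0.1)
})

test_that("doubling measurement noise lowers the median reliability", {
  lo <- icc_map(ratings_tensor(30, 8, 4, 0.3, 0.2, seed = 20))
  hi <- icc_map(ratings_tensor(30, 8, 4, 0.3, 0.4, seed = 20))
  expect_gt(stats::median(lo$mean_icc), stats::median(hi$mean_icc))
})


test_that("reliability rises with region volume", {
  voxels <- c(1, 4, 16, 64)
  tensor <- volume_tensor(voxels)
  volumes <- setNames(voxels * 0.008, seq_along(voxels))  # 2 mm voxels
  curve <- icc_volume_curve(tensor, volumes, targets = 5:14)
  expect_equal(nrow(curve), 4)
  expect_true(all(diff(curve$mean_icc) > 0))
  expect_equal(attr(curve, "rank_correlation"), 1)
})

test_that("equal volumes flag the rank correlation as degenerate", {
  tensor <- volume_tensor(c(4, 4, 4, 4))
  volumes <- setNames(rep(0.5, 4), 1:4)
  expect_warning(curve <- icc_volume_curve(tensor, volumes,
                                           targets = 5:14),
                 class = "fcrel_degenerate")
  expect_true(is.na(attr(curve, "rank_correlation")))
  expect_equal(nrow(curve), 4)
})

test_that("bilateral segmentation of 7 structures yields a 14-row table", {
  structures <- subcortical_structures()
  expect_equal(nrow(structures), 14)
  voxels <- rep(c(8, 27), 7)
  tensor <- volume_tensor(voxels, n_subj = 6, n_target = 5, n_time = 80,
                          seed = 25)
  volumes <- setNames(voxels * 0.008, seq_along(voxels))
  curve <- icc_volume_curve(tensor, volumes, targets = 15:19)
  expect_equal(nrow(curve), 14)
  expect_false(anyNA(curve$mean_icc))
})
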