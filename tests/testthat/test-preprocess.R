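# Preprocessing: volume discard, detrend, ideal bandpass, nuisance
# regression, and the fixed stage order.

make_run <- function(n_time = 1180, n_roi = 3, tr = 0.72, seed = 1) {
  withr::with_seed(seed, {
    toy_run(matrix(rnorm(n_time * n_roi), n_time, n_roi), tr = tr,
            motion = matrix(rnorm(n_time * 12), n_time, 12),
            wm = rnorm(n_time), csf = rnorm(n_time))
  })
}

test_that("initial-volume discard shortens every field jointly", {
  run <- make_run(1200)
  out <- discard_initial_volumes(run, 20)
  expect_equal(nrow(out$data), 1180)
  expect_equal(nrow(out$motion), 1180)
  expect_equal(length(out$wm), 1180)
  expect_equal(out$data[1, ], run$data[21, ])
  expect_identical(discard_initial_volumes(run, 0), run)
  short <- make_run(100)
  expect_error(discard_initial_volumes(short, 100),
               class = "fcrel_data_error")
})

test_that("linear detrend removes an exact line and matches least squares", {
  t0 <- 0:9
  expect_equal(linear_detrend(2 + 3 * t0), rep(0, 10))
  # quadratic: residual equals the normal-equations solution
  y <- t0^2
  X <- cbind(1, t0)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(linear_detrend(y), as.numeric(y - X %*% beta),
               tolerance = 1e-12)
  expect_equal(mean(linear_detrend(y)), 0, tolerance = 1e-12)
  expect_error(linear_detrend(c(1, 2)), class = "fcrel_data_error")
})

test_that("ideal bandpass passes in-band bins, kills DC and out-of-band", {
  n <- 1180; tr <- 0.72
  t_sec <- (seq_len(n) - 1) * tr
  f_in <- 42 / (n * tr)  # an exact DFT bin inside the band (~0.049 Hz)
  x <- sin(2 * pi * f_in * t_sec)
  expect_lt(max(abs(ideal_bandpass(x, tr) - x)), 1e-8)
  expect_equal(ideal_bandpass(rep(5, n), tr), rep(0, n), tolerance = 1e-12)
  x_hi <- sin(2 * pi * 0.3 * t_sec)
  out_hi <- ideal_bandpass(x_hi, tr)
  expect_lt(sum(out_hi^2) / sum(x_hi^2), 0.01)  # >= 20 dB rejection
  expect_error(ideal_bandpass(x, tr, band_hz = c(0.8, 0.9)),
               class = "fcrel_config_error")
})

test_that("ideal bandpass is idempotent", {
  withr::with_seed(2, x <- rnorm(500))
  once <- ideal_bandpass(x, 0.72)
  expect_lt(max(abs(ideal_bandpass(once, 0.72) - once)), 1e-10)
})

test_that("nuisance regression removes covariate signal exactly", {
  run <- make_run(600)
  # an ROI that IS the WM series leaves a zero residual
  run$data[, 1] <- run$wm
  out <- nuisance_regress(run, preproc_config(discard_volumes = 0))
  expect_lt(max(abs(out$data[, 1])), 1e-10)
})

test_that("regression residuals are orthogonal to the retained design", {
  run <- make_run(400)
  out <- nuisance_regress(run, preproc_config(discard_volumes = 0))
  cfg <- preproc_config(discard_volumes = 0)
  filt <- function(v) ideal_bandpass(linear_detrend(as.matrix(v)),
                                     run$tr_seconds, cfg$band_hz)
  X <- cbind(1, filt(run$wm), filt(run$csf), filt(run$motion))
  ip <- crossprod(X, out$data)
  norms <- outer(sqrt(colSums(X^2)), sqrt(colSums(out$data^2)))
  expect_lt(max(abs(ip) / pmax(norms, 1)), 1e-8)
})

test_that("regression recovers a planted motion dependency", {
  withr::with_seed(9, {
    n <- 1180
    run <- make_run(n)
    e <- rnorm(n)
    run$data[, 2] <- 0.7 * run$motion[, 1] + e
    cfg <- preproc_config(discard_volumes = 0)
    out <- nuisance_regress(run, cfg)
    e_filt <- ideal_bandpass(linear_detrend(e), run$tr_seconds, cfg$band_hz)
    # the model is linear, so the residual must equal the filtered error
    # minus its own projection on the design, to numerical precision
    X <- cbind(1,
               ideal_bandpass(linear_detrend(run$wm), run$tr_seconds),
               ideal_bandpass(linear_detrend(run$csf), run$tr_seconds),
               ideal_bandpass(linear_detrend(run$motion), run$tr_seconds))
    e_resid <- e_filt - X %*% qr.coef(qr(X), e_filt)
    expect_equal(out$data[, 2], as.numeric(e_resid), tolerance = 1e-8)
    expect_gt(cor(out$data[, 2], e_filt), 0.9)
  })
})

test_that("collinear design columns are dropped with a warning", {
  run <- make_run(300)
  run$csf <- run$wm  # perfectly collinear
  expect_warning(
    out <- nuisance_regress(run, preproc_config(discard_volumes = 0)),
    class = "fcrel_collinear_design"
  )
  expect_false("csf" %in% attr(out, "design"))
  expect_true(all(is.finite(out$data)))
})

test_that("the full pipeline applies discard, filter and regression in order", {
  run <- make_run(1200)
  out <- preprocess_run(run, preproc_config())
  expect_equal(nrow(out$data), 1180)
  # residual orthogonal to filtered wm on the discarded timebase
  kept <- run$wm[21:1200]
  w <- ideal_bandpass(linear_detrend(kept), run$tr_seconds)
  expect_lt(abs(sum(w * out$data[, 1])) /
              (sqrt(sum(w^2)) * sqrt(sum(out$data[, 1]^2))), 1e-8)
  # pre-cleaned stream: no regression, but filtering still applies
  clean <- preprocess_run(run, preproc_config(wm = FALSE, csf = FALSE,
                                              motion12 = FALSE))
  expect_equal(nrow(clean$data), 1180)
  expect_lt(abs(mean(clean$data[, 1])), 1e-10)
})
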