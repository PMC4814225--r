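# Nuisance preprocessing of ROI series: initial-volume discard, linear
# detrend, ideal Fourier bandpass, and WM/CSF/motion regression with
# identically filtered covariates.  The stage order is part of the
# contract: discard -> detrend -> bandpass -> regress.

#' Preprocessing configuration
#'
#' @param discard_volumes Number of initial volumes to drop (default 20,
#'   which turns a 1200-volume resting run into 1180 volumes).
#' @param band_hz Passband `(low, high)` in Hz of the ideal bandpass
#'   (default 0.001-0.1 Hz).
#' @param detrend Remove a least-squares linear trend first (default TRUE).
#' @param wm,csf,motion12 Which nuisance regressors to include.
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(discard_volumes = 20, band_hz = c(0.001, 0.1),
                           detrend = TRUE, wm = TRUE, csf = TRUE,
                           motion12 = TRUE) {
  stopifnot_scalar_number(discard_volumes, "discard_volumes")
  if (discard_volumes < 0 || discard_volumes != floor(discard_volumes)) {
    abort("`discard_volumes` must be a non-negative integer.",
          class = "fcrel_config_error")
  }
  if (!is.numeric(band_hz) || length(band_hz) != 2L ||
      !(band_hz[1] >= 0 && band_hz[1] < band_hz[2])) {
    abort("`band_hz` must be c(low, high) with 0 <= low < high.",
          class = "fcrel_config_error")
  }
  structure(
    list(discard_volumes = as.integer(discard_volumes),
         band_hz = as.double(band_hz), detrend = isTRUE(detrend),
         wm = isTRUE(wm), csf = isTRUE(csf), motion12 = isTRUE(motion12)),
    class = "preproc_config"
  )
}

#' Discard the initial volumes of a run
#'
#' Drops the first `n` time points jointly from the data matrix and every
#' recorded covariate (motion, WM, CSF) so the run stays aligned.
#'
#' @param run An `fc_run_series`.
#' @param n Number of initial volumes to drop (must leave at least one).
#' @return The shortened `fc_run_series`.
#' @export
discard_initial_volumes <- function(run, n) {
  stopifnot_scalar_number(n, "n")
  n <- as.integer(n)
  if (n < 0) {
    abort("`n` must be >= 0.", class = "fcrel_config_error")
  }
  if (n >= run_length(run)) {
    abort(sprintf("cannot discard %d of %d volumes.", n, run_length(run)),
          class = "fcrel_data_error")
  }
  if (n == 0L) {
    return(run)
  }
  keep <- (n + 1L):run_length(run)
  subset_run(run, keep)
}

# Keep the given time indices of every time-indexed field of a run.
subset_run <- function(run, keep) {
  run$data <- run$data[keep, , drop = FALSE]
  if (!is.null(run$motion)) run$motion <- run$motion[keep, , drop = FALSE]
  if (!is.null(run$wm)) run$wm <- run$wm[keep]
  if (!is.null(run$csf)) run$csf <- run$csf[keep]
  run
}

#' Remove a least-squares linear trend
#'
#' Fits `intercept + slope * t` (t = 0, 1, ...) to each column by ordinary
#' least squares and returns the residuals, which are exactly zero-mean.
#'
#' @param series Numeric vector or time x k matrix.
#' @return Detrended object of the same shape.
#' @export
linear_detrend <- function(series) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 3L) {
    abort("series must have at least 3 time points.",
          class = "fcrel_data_error")
  }
  t0 <- seq_len(n) - 1
  X <- cbind(1, t0)
  out <- x - X %*% qr.coef(qr(X), x)
  if (is.matrix(series)) out else drop(out)
}

#' Ideal (brick-wall) Fourier bandpass filter
#'
#' Computes the discrete Fourier transform, zeroes every coefficient whose
#' frequency magnitude falls outside `[low, high]` (the DC term is always
#' removed, and the band edges are kept), and returns the real part of the
#' inverse transform.  The filter is idempotent: applying it twice equals
#' applying it once.
#'
#' @param series Numeric vector or time x k matrix.
#' @param tr_seconds Sampling interval in seconds.
#' @param band_hz Passband `(low, high)` in Hz; the low edge must lie below
#'   the Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return Filtered object of the same shape.
#' @export
ideal_bandpass <- function(series, tr_seconds, band_hz = c(0.001, 0.1)) {
  x <- as.matrix(series)
  if (!all(is.finite(x))) {
    abort("series contains non-finite values.", class = "fcrel_data_error")
  }
  stopifnot_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  if (!is.numeric(band_hz) || length(band_hz) != 2L ||
      !(band_hz[1] >= 0 && band_hz[1] < band_hz[2])) {
    abort("`band_hz` must be c(low, high) with 0 <= low < high.",
          class = "fcrel_config_error")
  }
  nyquist <- 1 / (2 * tr_seconds)
  if (band_hz[1] > nyquist) {
    abort(sprintf("band lies entirely above the Nyquist frequency %.4f Hz.",
                  nyquist), class = "fcrel_config_error")
  }
  n <- nrow(x)
  keep <- band_bins(n, tr_seconds, band_hz)
  mask <- rep(0, n)
  mask[keep] <- 1
  out <- Re(stats::mvfft(stats::mvfft(x) * mask, inverse = TRUE)) / n
  dimnames(out) <- dimnames(x)
  if (is.matrix(series)) out else drop(out)
}

#' Regress nuisance covariates out of a run
#'
#' Implements the standard connectivity nuisance step: every ROI series and
#' every covariate (WM, CSF, 12 motion parameters) is first detrended and
#' bandpass filtered identically, then each ROI series is regressed by
#' ordinary least squares on an intercept plus the filtered covariates and
#' replaced by its residuals.  Collinear design columns are dropped with a
#' warning rather than failing silently.
#'
#' @param run An `fc_run_series` carrying the covariates it was acquired
#'   with.
#' @param config A [preproc_config()].
#' @return The run with residual data; attribute `"design"` records the
#'   retained design columns.
#' @export
nuisance_regress <- function(run, config = preproc_config()) {
  filt <- function(v) {
    v <- as.matrix(v)
    if (config$detrend) v <- linear_detrend(v)
    ideal_bandpass(v, run$tr_seconds, config$band_hz)
  }
  y <- filt(run$data)
  covs <- list()
  if (config$wm) {
    if (is.null(run$wm)) {
      abort("run has no WM series.", class = "fcrel_data_error")
    }
    covs$wm <- run$wm
  }
  if (config$csf) {
    if (is.null(run$csf)) {
      abort("run has no CSF series.", class = "fcrel_data_error")
    }
    covs$csf <- run$csf
  }
  if (config$motion12) {
    if (is.null(run$motion)) {
      abort("run has no motion parameters.", class = "fcrel_data_error")
    }
    m <- run$motion
    colnames(m) <- sprintf("motion%02d", seq_len(ncol(m)))
    covs$motion <- m
  }
  X <- cbind(intercept = rep(1, nrow(y)))
  for (nm in names(covs)) {
    v <- filt(covs[[nm]])
    if (is.null(colnames(v))) colnames(v) <- nm
    X <- cbind(X, v)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warn(sprintf("dropping %d collinear design column(s): %s",
                 length(dropped), paste(dropped, collapse = ", ")),
         class = "fcrel_collinear_design")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  run$data <- y - X %*% qr.coef(qrX, y)
  attr(run, "design") <- colnames(X)
  run
}

#' Run the full preprocessing pipeline on one acquisition
#'
#' Fixed stage order: discard initial volumes, then linear detrend, then
#' ideal bandpass, then (optionally) nuisance regression with identically
#' filtered covariates.  With all nuisance flags off (the pre-cleaned input
#' stream) the data are still discarded, detrended and filtered.
#'
#' @param run An `fc_run_series`.
#' @param config A [preproc_config()].
#' @return The preprocessed `fc_run_series`.
#' @export
preprocess_run <- function(run, config = preproc_config()) {
  run <- discard_initial_volumes(run, config$discard_volumes)
  if (config$wm || config$csf || config$motion12) {
    nuisance_regress(run, config)
  } else {
    y <- run$data
    if (config$detrend) y <- linear_detrend(y)
    run$data <- ideal_bandpass(y, run$tr_seconds, config$band_hz)
    run
  }
}
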