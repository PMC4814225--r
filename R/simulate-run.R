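# Simulation of a single BOLD acquisition from the cohort ground truth.

# Indices (1-based, in 1..n) of DFT bins whose frequency lies inside
# [low, high] Hz, mirrored for the negative frequencies; DC excluded.
band_bins <- function(n, tr, band) {
  freq <- (seq_len(n) - 1) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)  # fold to two-sided magnitude
  which(freq >= band[1] & freq <= band[2] & seq_len(n) != 1L)
}

# T x k matrix of independent unit-SD Gaussian noise restricted to the
# passband (ideal DFT brick-wall).
band_limited_noise <- function(n_time, k, tr, band) {
  keep <- band_bins(n_time, tr, band)
  if (length(keep) == 0L) {
    abort(sprintf(
      "noise band [%g, %g] Hz contains no resolvable frequency for %d samples at TR %g s.",
      band[1], band[2], n_time, tr
    ), class = "fcrel_config_error")
  }
  e <- matrix(rnorm(n_time * k), n_time, k)
  co <- stats::mvfft(e)
  mask <- rep(0, n_time)
  mask[keep] <- 1
  x <- Re(stats::mvfft(co * mask, inverse = TRUE)) / n_time
  sc <- apply(x, 2L, sd)
  sc[sc == 0] <- 1
  sweep(x, 2L, sc, "/")
}

# Stationary unit-variance Ornstein-Uhlenbeck process sampled every `tr`
# seconds with correlation time `timescale`.
ou_process <- function(n_time, tr, timescale) {
  a <- exp(-tr / timescale)
  x <- numeric(n_time)
  x[1] <- rnorm(1)
  innov <- rnorm(n_time - 1L, 0, sqrt(1 - a^2))
  for (t in seq_len(n_time - 1L)) x[t + 1L] <- a * x[t] + innov[t]
  x
}

# Canonical double-gamma haemodynamic response sampled at `tr`, peak
# normalised to 1.
canonical_hrf <- function(tr, length_seconds = 32) {
  t <- seq(0, length_seconds, by = tr)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

# Block-design regressor: boxcar with period `block_seconds` (half on)
# convolved with the canonical response, peak-normalised.
block_design_signal <- function(n_time, tr, block_seconds) {
  period <- max(2L, round(block_seconds / tr))
  box <- as.integer((seq_len(n_time) - 1L) %% period < period / 2)
  h <- canonical_hrf(tr)
  s <- stats::convolve(box, rev(h), type = "open")[seq_len(n_time)]
  if (max(abs(s)) > 0) s <- s / max(abs(s))
  s
}

# Repair a symmetric target matrix into a valid correlation matrix by
# flooring eigenvalues at `floor` and renormalising the diagonal.  Returns
# the matrix plus whether a repair was needed.
make_positive_definite <- function(C, floor = 1e-6) {
  ee <- eigen(C, symmetric = TRUE)
  if (ee$values[length(ee$values)] >= floor) {
    return(list(C = C, repaired = FALSE))
  }
  lam <- pmax(ee$values, floor)
  Cr <- ee$vectors %*% (lam * t(ee$vectors))
  list(C = cov2cor(Cr), repaired = TRUE)
}

#' Simulate one BOLD acquisition
#'
#' Realises a single run of band-limited, cross-sectionally correlated
#' ROI series for one subject and condition: (1) the target correlation
#' `C(t) = tanh(group_z + subject_dev + task_delta + state(t) * state_sd * W)`
#' fluctuates along the fixed direction `W` with a minutes-scale
#' Ornstein-Uhlenbeck state; (2) independent band-limited Gaussian noise is
#' coloured by the Cholesky factor of `C(t)`, held piecewise constant over
#' `spec$state_window_trs` TRs; (3) task conditions add a block-design
#' common signal to their engaged ROIs; (4) motion (smooth random walks),
#' white-matter and CSF series leak into every ROI with weight
#' `nuisance_coupling`.  Targets that are not positive definite are
#' repaired by eigenvalue flooring at 1e-6 (with a warning of class
#' `fcrel_pd_repair`).
#'
#' The run's random stream is derived from
#' `(spec$seed, subject, condition, run_index)`, so any run can be
#' regenerated in isolation.
#'
#' @param truth An [generate_ground_truth()] result.
#' @param spec The matching [cohort_spec()] (defaults to `truth$spec`).
#' @param subject Subject id (e.g. `"S001"`) or index.
#' @param condition Condition name.
#' @param run_index Run number within the condition (1-based).
#' @return An `fc_run_series`: list with `subject_id`, `condition`,
#'   `run_index`, `tr_seconds`, `data` (time x ROI matrix), `motion`
#'   (time x 12), `wm` and `csf` (time-length vectors).
#' @examples
#' spec <- cohort_spec(n_subjects = 2, n_rois = 8, duration_seconds = 60,
#'                     state_sd = 0, nuisance_coupling = 0)
#' truth <- generate_ground_truth(spec)
#' run <- simulate_run(truth, spec, "S001", "rest", 1)
#' dim(run$data)
#' @export
simulate_run <- function(truth, spec = truth$spec, subject, condition,
                         run_index = 1L) {
  if (!inherits(truth, "fc_ground_truth")) {
    abort("`truth` must come from generate_ground_truth().",
          class = "fcrel_config_error")
  }
  if (is.numeric(subject)) {
    subject_index <- as.integer(subject)
    if (subject_index < 1L || subject_index > spec$n_subjects) {
      abort("unknown subject index.", class = "fcrel_config_error")
    }
  } else {
    subject_index <- match(subject, spec$subject_ids)
    if (is.na(subject_index)) {
      abort(sprintf("unknown subject \"%s\".", subject),
            class = "fcrel_config_error")
    }
  }
  cond_index <- match(condition, spec$conditions)
  if (is.na(cond_index)) {
    abort(sprintf("unknown condition \"%s\".", condition),
          class = "fcrel_config_error")
  }
  n <- spec$n_rois
  tr <- spec$tr_seconds
  n_time <- round(spec$duration_seconds[[condition]] / tr)

  base_z <- truth$group_z +
    subject_dev_matrix(truth, subject_index, condition) +
    truth$task_delta[[condition]]

  run_seed <- derive_seed(spec$seed, subject_index, cond_index, run_index)
  with_seed(run_seed, {
    noise <- band_limited_noise(n_time, n, tr, spec$noise_band_hz)
    state <- if (spec$state_sd > 0) {
      ou_process(n_time, tr, spec$state_timescale_seconds)
    } else {
      numeric(n_time)
    }

    starts <- seq(1L, n_time, by = spec$state_window_trs)
    data <- matrix(0, n_time, n)
    n_repaired <- 0L
    for (s in starts) {
      idx <- s:min(s + spec$state_window_trs - 1L, n_time)
      z_w <- base_z + mean(state[idx]) * spec$state_sd * truth$state_direction
      C_w <- tanh(z_w)
      diag(C_w) <- 1
      pd <- make_positive_definite(C_w)
      n_repaired <- n_repaired + pd$repaired
      data[idx, ] <- noise[idx, , drop = FALSE] %*% chol(pd$C)
    }
    if (n_repaired > 0L) {
      warn(sprintf(
        "target correlation repaired by eigenvalue flooring in %d of %d state windows (%s/%s run %d).",
        n_repaired, length(starts), spec$subject_ids[subject_index],
        condition, run_index
      ), class = "fcrel_pd_repair")
    }

    mod <- spec$task_modulation[[condition]]
    if (!is.null(mod) && mod$amplitude > 0) {
      sig <- block_design_signal(n_time, tr, mod$block_seconds)
      data[, mod$engaged] <- data[, mod$engaged] + mod$amplitude * sig
    }

    # nuisance series exist (and are returned) even when their coupling into
    # the ROI data is zero, so regression designs stay well-defined
    motion <- sapply(seq_len(12L), function(i) {
      w <- cumsum(rnorm(n_time))
      w <- stats::filter(w, rep(1 / 5, 5), sides = 2L)
      w[is.na(w)] <- w[!is.na(w)][1L]
      as.numeric(scale(as.numeric(w)))
    })
    wm <- band_limited_noise(n_time, 1L, tr, spec$noise_band_hz)[, 1L]
    csf <- band_limited_noise(n_time, 1L, tr, spec$noise_band_hz)[, 1L]
    if (spec$nuisance_coupling > 0) {
      covs <- cbind(wm, csf, motion)
      loadings <- matrix(rnorm(ncol(covs) * n), ncol(covs), n)
      data <- data + spec$nuisance_coupling * (covs %*% loadings)
    }

    colnames(data) <- sprintf("ROI%04d", seq_len(n))
    run_series(
      subject_id = spec$subject_ids[subject_index],
      condition = condition,
      run_index = as.integer(run_index),
      tr_seconds = tr,
      data = data,
      motion = motion,
      wm = wm,
      csf = csf
    )
  })
}

#' Construct a run-series object
#'
#' Container for one acquisition: the ROI-by-time data matrix together with
#' the nuisance series recorded alongside it.  All time-indexed fields must
#' have the same length and be finite.
#'
#' @param subject_id,condition,run_index Run identifiers.
#' @param tr_seconds Sampling interval in seconds.
#' @param data Time x ROI numeric matrix (column names are ROI labels).
#' @param motion Time x 12 motion-parameter matrix (optional).
#' @param wm,csf White-matter / CSF mean series (optional).
#' @return An `fc_run_series` object.
#' @export
run_series <- function(subject_id, condition, run_index, tr_seconds, data,
                       motion = NULL, wm = NULL, csf = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) {
    abort("run data contains non-finite values.", class = "fcrel_data_error")
  }
  n_time <- nrow(data)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_time || !all(is.finite(motion))) {
      abort("motion must be a finite matrix with one row per time point.",
            class = "fcrel_data_error")
    }
  }
  for (nm in c("wm", "csf")) {
    v <- get(nm)
    if (!is.null(v) && (length(v) != n_time || !all(is.finite(v)))) {
      abort(sprintf("`%s` must be a finite series of length %d.", nm, n_time),
            class = "fcrel_data_error")
    }
  }
  stopifnot_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  structure(
    list(subject_id = subject_id, condition = condition,
         run_index = as.integer(run_index), tr_seconds = tr_seconds,
         data = data, motion = motion, wm = wm, csf = csf),
    class = "fc_run_series"
  )
}

#' @export
print.fc_run_series <- function(x, ...) {
  cat(sprintf("<fc_run_series> %s/%s run %d: %d time points x %d ROIs (TR %g s)\n",
              x$subject_id, x$condition, x$run_index, nrow(x$data),
              ncol(x$data), x$tr_seconds))
  invisible(x)
}

# Number of time points of a run.
run_length <- function(run) nrow(run$data)
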