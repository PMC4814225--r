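#' Describe a task condition's modulation of the BOLD signal
#'
#' A task condition does two things to the synthetic signal: it adds a
#' block-design common signal (a boxcar convolved with a canonical
#' double-gamma haemodynamic response) to the "engaged" regions, which
#' artificially synchronises them the way task timing synchronises real
#' task-engaged cortex; and it can shift the true Fisher-z connectivity of
#' every connection between engaged regions by a fixed amount
#' (`delta_z`), which is what task-contrast recovery experiments plant.
#'
#' @param engaged Integer indices of the engaged ROIs.
#' @param amplitude Common-signal amplitude in units of the noise SD
#'   (>= 0; 0 disables the evoked signal).
#' @param block_seconds Boxcar period in seconds (half on, half off).
#' @param delta_z Additive true Fisher-z modulation applied to every
#'   connection between two engaged ROIs.
#' @return A `task_modulation` list.
#' @export
task_modulation <- function(engaged, amplitude = 1, block_seconds = 30,
                            delta_z = 0) {
  engaged <- as.integer(engaged)
  if (length(engaged) < 1L || anyNA(engaged) || any(engaged < 1L)) {
    abort("`engaged` must be a non-empty set of positive ROI indices.",
          class = "fcrel_config_error")
  }
  stopifnot_scalar_number(amplitude, "amplitude")
  if (amplitude < 0) {
    abort("`amplitude` must be >= 0.", class = "fcrel_config_error")
  }
  stopifnot_scalar_number(block_seconds, "block_seconds", positive = TRUE)
  stopifnot_scalar_number(delta_z, "delta_z")
  structure(
    list(engaged = sort(unique(engaged)), amplitude = amplitude,
         block_seconds = block_seconds, delta_z = delta_z),
    class = "task_modulation"
  )
}

#' Specify a synthetic BOLD cohort
#'
#' The cohort generator emulates the statistical structure a
#' reliability/reproducibility analysis of functional connectivity relies
#' on: a shared group connectome, stable subject-specific connectivity
#' deviations, slow (minutes-scale) connectivity-state fluctuations,
#' task-locked common signal in engaged regions, and nuisance components
#' (white matter, CSF, 12 motion parameters) that leak into the ROI
#' series.  Defaults follow a multiband resting-state design: TR 0.72 s
#' and 15-minute runs.
#'
#' The inter-subject and intra-subject variance amplitudes of real
#' connectomes are not pinned down by the literature this emulates, so
#' `group_connectome_scale = 0.3`, `subject_sd = 0.1` and
#' `state_sd = 0.1` are calibration choices, documented in the methods
#' vignette.
#'
#' @param n_subjects,n_rois Cohort and parcellation size.
#' @param conditions Condition names; the first must be `"rest"`.
#' @param runs_per_condition Number of repeated runs per condition
#'   (scalar, or vector recycled along `conditions`).
#' @param tr_seconds Repetition time in seconds.
#' @param duration_seconds Run length in seconds (scalar, or vector
#'   recycled along `conditions`); must be at least `10 * tr_seconds`.
#' @param group_connectome_scale SD of the true group-mean Fisher-z
#'   off-diagonals.
#' @param subject_sd SD of the stable per-subject Fisher-z deviations.
#' @param subject_dev_by_condition If `TRUE`, subject deviations are drawn
#'   independently per condition (a null model in which individual
#'   differences do *not* persist across conditions); default `FALSE`
#'   shares one deviation matrix per subject across all conditions.
#' @param state_timescale_seconds Correlation time of the slow
#'   connectivity-state fluctuation (an Ornstein-Uhlenbeck process);
#'   minutes-scale by default.
#' @param state_sd Amplitude of the state fluctuation in Fisher-z units.
#' @param state_window_trs Window length (in TRs) over which the
#'   time-varying correlation target is held constant when colouring the
#'   noise; a fidelity/cost trade-off.
#' @param task_modulation Named list of [task_modulation()] objects for the
#'   non-rest conditions.  Conditions without an entry get a default
#'   modulation engaging the first fifth of the ROIs.
#' @param nuisance_coupling Scale of the leakage of motion/WM/CSF series
#'   into every ROI series (0 disables nuisance structure).
#' @param noise_band_hz Two-element `(low, high)` passband of the BOLD-like
#'   noise in Hz; `high` must not exceed Nyquist.
#' @param seed Integer master seed; every run derives its own stream from
#'   `(seed, subject, condition, run)` so runs are reproducible
#'   independently of generation order.
#' @return A validated `cohort_spec` list.
#' @seealso [generate_ground_truth()], [simulate_run()],
#'   [cohort_connectivity()]
#' @examples
#' spec <- cohort_spec(n_subjects = 4, n_rois = 10, duration_seconds = 60)
#' spec$subject_ids
#' @export
cohort_spec <- function(n_subjects = 30,
                        n_rois = 50,
                        conditions = c("rest", "task"),
                        runs_per_condition = 2,
                        tr_seconds = 0.72,
                        duration_seconds = 900,
                        group_connectome_scale = 0.3,
                        subject_sd = 0.1,
                        subject_dev_by_condition = FALSE,
                        state_timescale_seconds = 180,
                        state_sd = 0.1,
                        state_window_trs = 10,
                        task_modulation = NULL,
                        nuisance_coupling = 0.1,
                        noise_band_hz = c(0.001, 0.1),
                        seed = 1L) {
  stopifnot_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  stopifnot_scalar_number(n_rois, "n_rois", positive = TRUE)
  n_subjects <- as.integer(n_subjects)
  n_rois <- as.integer(n_rois)
  if (n_rois < 2L) {
    abort("`n_rois` must be >= 2 to define any connection.",
          class = "fcrel_config_error")
  }
  if (!is.character(conditions) || length(conditions) < 1L ||
      anyDuplicated(conditions)) {
    abort("`conditions` must be unique condition names.",
          class = "fcrel_config_error")
  }
  if (conditions[1L] != "rest") {
    abort("the first condition must be \"rest\".",
          class = "fcrel_config_error")
  }
  stopifnot_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  runs_per_condition <- as.integer(rep(runs_per_condition,
                                       length.out = length(conditions)))
  if (any(runs_per_condition < 1L)) {
    abort("`runs_per_condition` must be >= 1.", class = "fcrel_config_error")
  }
  duration_seconds <- rep(as.double(duration_seconds),
                          length.out = length(conditions))
  if (any(duration_seconds < 10 * tr_seconds)) {
    abort(sprintf(
      "`duration_seconds` must be >= 10 * tr_seconds = %g s.",
      10 * tr_seconds
    ), class = "fcrel_config_error")
  }
  for (nm in c("group_connectome_scale", "subject_sd", "state_sd",
               "nuisance_coupling")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v < 0) {
      abort(sprintf("`%s` must be >= 0.", nm), class = "fcrel_config_error")
    }
  }
  stopifnot_scalar_number(state_timescale_seconds, "state_timescale_seconds",
                          positive = TRUE)
  stopifnot_scalar_number(state_window_trs, "state_window_trs",
                          positive = TRUE)
  if (!is.numeric(noise_band_hz) || length(noise_band_hz) != 2L) {
    abort("`noise_band_hz` must be c(low, high).",
          class = "fcrel_config_error")
  }
  nyquist <- 1 / (2 * tr_seconds)
  if (!(noise_band_hz[1L] >= 0 && noise_band_hz[1L] < noise_band_hz[2L] &&
        noise_band_hz[2L] <= nyquist)) {
    abort(sprintf(
      "`noise_band_hz` must satisfy 0 <= low < high <= Nyquist = %.4f Hz.",
      nyquist
    ), class = "fcrel_config_error")
  }
  stopifnot_scalar_number(seed, "seed")

  tasks <- setdiff(conditions, "rest")
  mods <- task_modulation %||% list()
  if (!is.list(mods) || (length(mods) && is.null(names(mods)))) {
    abort("`task_modulation` must be a named list of task_modulation().",
          class = "fcrel_config_error")
  }
  unknown <- setdiff(names(mods), tasks)
  if (length(unknown)) {
    abort(sprintf("task_modulation given for unknown condition(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "fcrel_config_error")
  }
  default_engaged <- seq_len(max(2L, n_rois %/% 5L))
  for (tk in tasks) {
    if (is.null(mods[[tk]])) {
      mods[[tk]] <- task_modulation(default_engaged, amplitude = 1,
                                    block_seconds = 30, delta_z = 0.2)
    }
    if (any(mods[[tk]]$engaged > n_rois)) {
      abort(sprintf("engaged ROI index exceeds n_rois for condition \"%s\".",
                    tk), class = "fcrel_config_error")
    }
  }

  structure(
    list(
      n_subjects = n_subjects,
      n_rois = n_rois,
      conditions = conditions,
      runs_per_condition = setNames(runs_per_condition, conditions),
      tr_seconds = tr_seconds,
      duration_seconds = setNames(duration_seconds, conditions),
      group_connectome_scale = group_connectome_scale,
      subject_sd = subject_sd,
      subject_dev_by_condition = isTRUE(subject_dev_by_condition),
      state_timescale_seconds = state_timescale_seconds,
      state_sd = state_sd,
      state_window_trs = as.integer(state_window_trs),
      task_modulation = mods,
      nuisance_coupling = nuisance_coupling,
      noise_band_hz = as.double(noise_band_hz),
      seed = as.integer(seed),
      subject_ids = sprintf("S%03d", seq_len(n_subjects)),
      roi_labels = seq_len(n_rois)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_subjects, " subjects x ", x$n_rois, " ROIs\n",
      sep = "")
  cat("  conditions: ",
      paste(sprintf("%s (%d runs, %g s)", x$conditions,
                    x$runs_per_condition, x$duration_seconds),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  TR %g s, band %g-%g Hz, seed %d\n", x$tr_seconds,
              x$noise_band_hz[1], x$noise_band_hz[2], x$seed))
  invisible(x)
}
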