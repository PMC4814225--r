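# Shared simulated cohorts, built once per test session.  Problem sizes
# follow the experiments they feed (see the methods vignette): 15-minute
# runs at TR 0.72 s, 50-ROI parcellations for the duration/removal
# analyses, 30-ROI for the cross-subject and contrast analyses.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- builder()
  }
  .cohort_cache[[key]]
}

simulate_runs <- function(spec, truth, condition, runs) {
  out <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (r in runs) {
      out[[length(out) + 1L]] <-
        suppressWarnings(simulate_run(truth, spec, s, condition, r))
    }
  }
  out
}

# Stationary rest cohort (no slow state, no nuisance): two 15-min runs for
# 30 subjects x 50 ROIs.  Feeds the sqrt-time duration analysis.
stationary_rest_runs <- function() {
  cached("stationary_rest", function() {
    spec <- cohort_spec(n_subjects = 30, n_rois = 50, conditions = "rest",
                        runs_per_condition = 2, duration_seconds = 900,
                        state_sd = 0, nuisance_coupling = 0, seed = 5)
    truth <- generate_ground_truth(spec)
    list(spec = spec, truth = truth,
         runs = simulate_runs(spec, truth, "rest", 1:2))
  })
}

# Slow-state rest cohort (state timescale 180 s): four 15-min runs for
# 30 subjects x 50 ROIs.  Feeds the scrubbing-vs-truncation experiment.
slowstate_rest_runs <- function() {
  cached("slowstate_rest", function() {
    spec <- cohort_spec(n_subjects = 30, n_rois = 50, conditions = "rest",
                        runs_per_condition = 4, duration_seconds = 900,
                        state_sd = 0.1, state_timescale_seconds = 180,
                        nuisance_coupling = 0.1, seed = 9)
    truth <- generate_ground_truth(spec)
    list(spec = spec, truth = truth,
         runs = simulate_runs(spec, truth, "rest", 1:4))
  })
}

# Null cohort for the cross-subject correlation: subject deviations drawn
# independently per condition, 200 subjects, 5-min runs.
null_crosssubject_tensor <- function() {
  cached("null_crosssubject", function() {
    spec <- cohort_spec(
      n_subjects = 200, n_rois = 30, conditions = c("rest", "task"),
      runs_per_condition = 1, duration_seconds = 300,
      subject_dev_by_condition = TRUE, state_sd = 0, nuisance_coupling = 0,
      task_modulation = list(task = task_modulation(1:6, amplitude = 0,
                                                    delta_z = 0)),
      seed = 21
    )
    suppressWarnings(cohort_connectivity(spec))
  })
}

# Shared-deviation cohort: one 15-min rest and one 15-min task run for 40
# subjects; the task runs get truncated to probe duration dependence.
shared_dev_runs <- function() {
  cached("shared_dev", function() {
    spec <- cohort_spec(
      n_subjects = 40, n_rois = 30, conditions = c("rest", "task"),
      runs_per_condition = 1, duration_seconds = 900, state_sd = 0,
      nuisance_coupling = 0,
      task_modulation = list(task = task_modulation(1:6, amplitude = 0,
                                                    delta_z = 0)),
      seed = 22
    )
    truth <- generate_ground_truth(spec)
    list(
      spec = spec,
      rest = simulate_runs(spec, truth, "rest", 1L),
      task = simulate_runs(spec, truth, "task", 1L)
    )
  })
}

# Contrast-recovery cohort: delta z = +0.3 planted on the 10 connections
# among ROIs 1-5 of the task condition, 40 subjects.
contrast_tensor <- function() {
  cached("contrast", function() {
    spec <- cohort_spec(
      n_subjects = 40, n_rois = 30, conditions = c("rest", "task"),
      runs_per_condition = 1, duration_seconds = 900, state_sd = 0,
      nuisance_coupling = 0,
      task_modulation = list(task = task_modulation(1:5, amplitude = 0,
                                                    delta_z = 0.3)),
      seed = 23
    )
    truth <- generate_ground_truth(spec)
    list(spec = spec, truth = truth,
         tensor = suppressWarnings(cohort_connectivity(spec, truth)))
  })
}

# Scrub-vs-truncate experiment on the slow-state cohort (cached: it is
# reused by both the removal unit tests and the acceptance checks).
slowstate_removal_experiment <- function() {
  cached("removal_experiment", function() {
    co <- slowstate_rest_runs()
    removal_reliability_experiment(
      co$runs, fractions = c(0, 0.25, 0.5),
      preprocess = preproc_config(discard_volumes = 0), seed = 3
    )
  })
}
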