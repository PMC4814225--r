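# End-to-end pipeline over a synthetic cohort: simulate -> (optionally
# preprocess) -> connectivity -> reliability / reproducibility / removal
# summaries, with one JSON-able report.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages selected in `analyses` over one simulated cohort
#' and collects every summary number into a deterministic report list
#' (serialise it with `jsonlite::write_json`).  Rerunning with the same
#' configuration and seed reproduces the report bit for bit.
#'
#' @param spec A [cohort_spec()] (its `seed` drives all randomness).
#' @param preprocess `NULL` or a [preproc_config()] applied to every run.
#' @param analyses Character subset of `c("contrast", "similarity", "rms",
#'   "icc", "crosssubject")`.
#' @param q FDR level for the contrast stage.
#' @param icc_form ICC form for the reliability stage.
#' @return An `fc_report` list: `config` (echo of the spec), `pair_count`,
#'   per-stage summaries, and the PD-repair count.
#' @export
run_pipeline <- function(spec,
                         preprocess = NULL,
                         analyses = c("similarity", "rms", "icc"),
                         q = 0.05,
                         icc_form = "icc21") {
  analyses <- match.arg(analyses,
                        c("contrast", "similarity", "rms", "icc",
                          "crosssubject"),
                        several.ok = TRUE)
  truth <- generate_ground_truth(spec)
  tensor <- cohort_connectivity(spec, truth, preprocess = preprocess)
  report <- list(
    config = unclass(spec)[c("n_subjects", "n_rois", "conditions",
                             "runs_per_condition", "tr_seconds",
                             "duration_seconds", "group_connectome_scale",
                             "subject_sd", "state_timescale_seconds",
                             "state_sd", "nuisance_coupling",
                             "noise_band_hz", "seed")],
    pair_count = n_connections(spec$n_rois),
    n_pd_repairs = attr(tensor, "n_pd_repairs")
  )
  rest_runs <- spec$runs_per_condition[["rest"]]
  if ("similarity" %in% analyses) {
    sim <- condition_similarity(tensor)
    report$similarity <- list(
      slices = colnames(unclass(sim)),
      matrix = unclass(sim)
    )
  }
  if ("rms" %in% analyses && rest_runs >= 2L) {
    rms <- rms_difference(tensor, "rest", 1L, 2L)
    report$rms <- list(mean_rms = rms$mean_rms,
                       n_subjects = rms$n_subjects)
  }
  if ("icc" %in% analyses && rest_runs >= 2L) {
    map <- icc_map(tensor, condition = "rest", form = icc_form)
    report$icc <- list(form = icc_form,
                       mean_icc = mean(map$mean_icc, na.rm = TRUE),
                       median_icc = stats::median(map$mean_icc,
                                                  na.rm = TRUE))
  }
  if ("contrast" %in% analyses && length(spec$conditions) >= 2L) {
    ct <- paired_task_rest_difference(tensor, spec$conditions[2L], "rest",
                                      q = q)
    report$contrast <- list(
      conditions = attr(ct, "conditions"),
      n_significant = sum(ct$significant),
      n_family = attr(ct, "n_family"),
      boundary_dz = attr(ct, "boundary_dz")
    )
  }
  if ("crosssubject" %in% analyses && length(spec$conditions) >= 2L) {
    cs <- cross_subject_correlation(tensor, "rest", spec$conditions[2L])
    report$crosssubject <- list(mean_r = cs$mean_r, mean_z = cs$mean_z,
                                n_subjects = cs$n_subjects)
  }
  structure(report, class = "fc_report")
}

#' @export
print.fc_report <- function(x, ...) {
  cat("<fc_report>\n")
  cat(sprintf("  cohort: %d subjects x %d ROIs (%s)\n",
              x$config$n_subjects, x$config$n_rois,
              paste(x$config$conditions, collapse = ", ")))
  cat(sprintf("  pair count: %s\n", format(x$pair_count, big.mark = ",")))
  if (!is.null(x$rms)) {
    cat(sprintf("  rest rms(z) run1 vs run2: %.4f\n", x$rms$mean_rms))
  }
  if (!is.null(x$icc)) {
    cat(sprintf("  mean per-ROI ICC (%s): %.3f\n", x$icc$form,
                x$icc$mean_icc))
  }
  if (!is.null(x$contrast)) {
    cat(sprintf("  contrast %s - %s: %d significant of %d (boundary |dz| = %.3f)\n",
                x$contrast$conditions[1L], x$contrast$conditions[2L],
                x$contrast$n_significant, x$contrast$n_family,
                x$contrast$boundary_dz))
  }
  if (!is.null(x$crosssubject)) {
    cat(sprintf("  cross-subject mean r: %.3f\n", x$crosssubject$mean_r))
  }
  invisible(x)
}
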