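# broom-style tidiers for the fitted/result objects.

#' @exportS3Method generics::tidy
tidy.fc_contrast <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x)))
}

#' @exportS3Method generics::glance
glance.fc_contrast <- function(x, ...) {
  tibble(
    n_subjects = attr(x, "n_subjects"),
    n_family = attr(x, "n_family"),
    n_significant = sum(x$significant, na.rm = TRUE),
    q = attr(x, "q"),
    boundary_dz = attr(x, "boundary_dz")
  )
}

#' @exportS3Method generics::tidy
tidy.fc_rms <- function(x, ...) x$per_connection

#' @exportS3Method generics::glance
glance.fc_rms <- function(x, ...) {
  tibble(condition = x$condition, run_a = x$run_a, run_b = x$run_b,
         n_subjects = x$n_subjects, mean_rms = x$mean_rms)
}

#' @exportS3Method generics::tidy
tidy.fc_duration_curve <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x)))
}

#' @exportS3Method generics::glance
glance.fc_duration_curve <- function(x, ...) {
  tibble(loglog_slope = attr(x, "loglog_slope"),
         loglog_intercept = attr(x, "loglog_intercept"),
         n_durations = nrow(x))
}

#' @exportS3Method generics::tidy
tidy.fc_crosssubject <- function(x, ...) x$per_connection

#' @exportS3Method generics::glance
glance.fc_crosssubject <- function(x, ...) {
  tibble(condition_a = x$conditions[1L], condition_b = x$conditions[2L],
         n_subjects = x$n_subjects, n_skipped = x$n_skipped,
         mean_r = x$mean_r, mean_z = x$mean_z)
}

#' @exportS3Method generics::tidy
tidy.fc_icc_map <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x)[c("roi", "mean_icc", "n_targets")]))
}

#' @exportS3Method generics::glance
glance.fc_icc_map <- function(x, ...) {
  tibble(form = attr(x, "form"), condition = attr(x, "condition"),
         n_subjects = attr(x, "n_subjects"),
         n_sessions = attr(x, "n_sessions"),
         n_rois = nrow(x),
         mean_icc = mean(x$mean_icc, na.rm = TRUE),
         median_icc = stats::median(x$mean_icc, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
tidy.fc_similarity <- function(x, ...) {
  m <- unclass(x)
  attr(m, "slices") <- NULL
  as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE)) |>
    stats::setNames(c("slice_a", "slice_b", "similarity"))
}

#' @exportS3Method generics::tidy
tidy.fc_volume_curve <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x)[c("roi", "volume_cm3", "mean_icc")]))
}

#' @exportS3Method generics::glance
glance.fc_volume_curve <- function(x, ...) {
  tibble(n_rois = nrow(x), rank_correlation = attr(x, "rank_correlation"))
}

#' @exportS3Method generics::tidy
tidy.fc_removal <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x)))
}
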