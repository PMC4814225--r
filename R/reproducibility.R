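# Reproducibility: RMS difference between repeated acquisitions, its
# scaling with scan duration, similarity of group-mean connectomes across
# conditions, and the cross-subject correlation of individual differences.

#' Root-mean-square difference between two acquisitions
#'
#' For each connection, the RMS over subjects of the Fisher-z difference
#' between two runs of the same condition; averaged over connections this
#' is the expected uncertainty of a single-subject connectivity
#' measurement.
#'
#' @param tensor An `fc_tensor`.
#' @param condition Condition whose runs are compared.
#' @param run_a,run_b Run indices to compare.
#' @return An `fc_rms` list: `per_connection` tibble (`roi_i`, `roi_j`,
#'   `rms`), scalar `mean_rms`, and the comparison metadata.
#' @export
rms_difference <- function(tensor, condition = "rest", run_a = 1L,
                           run_b = 2L) {
  ta <- tensor_to_array(tensor, condition)
  ia <- match(run_a, ta$runs)
  ib <- match(run_b, ta$runs)
  if (is.na(ia) || is.na(ib)) {
    abort(sprintf("runs %s and %s not both present for \"%s\".",
                  format(run_a), format(run_b), condition),
          class = "fcrel_data_error")
  }
  d <- ta$z[, ia, , drop = TRUE] - ta$z[, ib, , drop = TRUE]
  d <- matrix(d, nrow = dim(ta$z)[1L])
  rms <- sqrt(colMeans(d^2))
  per_connection <- tibble(roi_i = ta$pairs$roi_i, roi_j = ta$pairs$roi_j,
                           rms = rms)
  structure(
    list(per_connection = per_connection,
         mean_rms = mean(rms, na.rm = TRUE),
         condition = condition, run_a = run_a, run_b = run_b,
         n_subjects = dim(ta$z)[1L]),
    class = "fc_rms"
  )
}

#' @export
print.fc_rms <- function(x, ...) {
  cat(sprintf("<fc_rms> %s run %s vs %s: mean RMS(z) = %.4f over %d connections, %d subjects\n",
              x$condition, format(x$run_a), format(x$run_b), x$mean_rms,
              nrow(x$per_connection), x$n_subjects))
  invisible(x)
}

#' Reproducibility as a function of scan duration
#'
#' Truncates each pair of repeated runs to a series of durations,
#' recomputes Fisher-z connectivity at every duration, measures the mean
#' RMS difference between the two acquisitions, and fits a least-squares
#' line to log(mean RMS) versus log(duration).  Sampling theory for
#' correlation estimates predicts a slope of -1/2: reproducibility improves
#' with the square root of imaging time.
#'
#' Truncation keeps time points from the start of the run (matching the
#' truncation semantics of the data-removal experiment).
#'
#' @param runs List of `fc_run_series`: at least two runs of the same
#'   condition per subject; the first two (by `run_index`) are compared.
#' @param durations_seconds Increasing vector (>= 3 values) of durations;
#'   durations shorter than 10 TRs are excluded with a warning.
#' @return An `fc_duration_curve`: tibble (`duration_seconds`, `mean_rms`)
#'   with attributes `loglog_slope` and `loglog_intercept`.
#' @export
duration_curve <- function(runs, durations_seconds) {
  if (length(durations_seconds) < 3L) {
    abort("need at least 3 durations.", class = "fcrel_config_error")
  }
  durations_seconds <- sort(as.double(durations_seconds))
  tr <- runs[[1L]]$tr_seconds
  ok <- durations_seconds >= 10 * tr
  if (!all(ok)) {
    warn(sprintf("%d duration(s) shorter than 10 TRs excluded.", sum(!ok)),
         class = "fcrel_short_duration")
    durations_seconds <- durations_seconds[ok]
  }
  max_t <- min(vapply(runs, run_length, 1L))
  if (any(round(durations_seconds / tr) > max_t)) {
    abort("a requested duration exceeds the available run length.",
          class = "fcrel_config_error")
  }
  rows <- purrr::map_dfr(durations_seconds, function(dur) {
    n_keep <- round(dur / tr)
    z <- dplyr::bind_rows(lapply(runs, function(r) {
      correlation_matrix(subset_run(r, seq_len(n_keep)))
    }))
    z <- as_fc_tensor(z)
    rms <- rms_difference(z, condition = z$condition[1L],
                          run_a = sort(unique(z$run))[1L],
                          run_b = sort(unique(z$run))[2L])
    tibble(duration_seconds = dur, mean_rms = rms$mean_rms)
  })
  if (any(rows$mean_rms <= 0)) {
    warn("degenerate (zero) RMS at some duration; log-log fit skipped.",
         class = "fcrel_degenerate")
    slope <- intercept <- NA_real_
  } else {
    fit <- lm(log(mean_rms) ~ log(duration_seconds), data = rows)
    slope <- unname(coef(fit)[2L])
    intercept <- unname(coef(fit)[1L])
  }
  attr(rows, "loglog_slope") <- slope
  attr(rows, "loglog_intercept") <- intercept
  class(rows) <- unique(c("fc_duration_curve", class(rows)))
  rows
}

#' Similarity of group-mean connectomes across conditions and runs
#'
#' Correlates, across connections, the group-mean Fisher-z vectors of every
#' pair of (condition, run) slices.  Repeat acquisitions of the same
#' condition should sit near the diagonal of this matrix; different tasks
#' should be less similar — the diagonal-dominance signature of
#' condition-specific but reproducible connectomes.
#'
#' @param tensor An `fc_tensor` with at least 2 (condition, run) slices.
#' @return An `fc_similarity` matrix (slices x slices, unit diagonal) with
#'   attribute `"slices"` describing each row.
#' @export
condition_similarity <- function(tensor) {
  slices <- tensor |>
    dplyr::summarise(z = mean(.data$z), .by = c("condition", "run",
                                                "roi_i", "roi_j"))
  wide <- tidyr::pivot_wider(slices,
                             names_from = c("condition", "run"),
                             values_from = "z", names_sep = ".")
  m <- as.matrix(wide[, -(1:2), drop = FALSE])
  if (nrow(m) < 2L) {
    abort("need at least 2 connections.", class = "fcrel_data_error")
  }
  if (ncol(m) < 2L) {
    abort("need at least 2 (condition, run) slices.",
          class = "fcrel_data_error")
  }
  sim <- cor(m, use = "pairwise.complete.obs")
  info <- do.call(rbind, strsplit(colnames(m), ".", fixed = TRUE))
  attr(sim, "slices") <- tibble(condition = info[, 1L],
                                run = as.integer(info[, 2L]))
  class(sim) <- c("fc_similarity", class(sim))
  sim
}

#' Cross-subject correlation of connectivity between two conditions
#'
#' For each connection, the Pearson correlation **across subjects** of
#' Fisher-z connectivity measured in condition `k1` against condition `k2`
#' (runs averaged within subject and condition first):
#' `r = 1/(m-1) * sum_m [(z_m,k1 - mean_k1)/S_k1] [(z_m,k2 - mean_k2)/S_k2]`
#' with sample standard deviations `S`.  A positive mean correlation says
#' the same subjects show relatively strong connectivity for the same
#' connections in both conditions — individual differences persist across
#' acquisition conditions.  The summary is the mean over connections of the
#' Fisher-transformed correlations.
#'
#' @param tensor An `fc_tensor`.
#' @param k1,k2 Condition names.
#' @param roi_subset Optional ROI labels restricting the connection set.
#' @return An `fc_crosssubject` list: `per_connection` tibble (`roi_i`,
#'   `roi_j`, `r`), `mean_z` (mean Fisher-z of r), `mean_r`
#'   (back-transformed), `n_subjects`, `n_skipped` (zero-variance
#'   connections, logged).
#' @export
cross_subject_correlation <- function(tensor, k1, k2, roi_subset = NULL) {
  z1 <- subject_condition_means(tensor, k1)
  z2 <- subject_condition_means(tensor, k2)
  common <- intersect(rownames(z1), rownames(z2))
  if (length(common) < 3L) {
    abort("need at least 3 subjects present in both conditions.",
          class = "fcrel_data_error")
  }
  cols <- intersect(colnames(z1), colnames(z2))
  if (!is.null(roi_subset)) {
    ij <- do.call(rbind, strsplit(cols, "-", fixed = TRUE))
    keep <- as.integer(ij[, 1L]) %in% roi_subset &
      as.integer(ij[, 2L]) %in% roi_subset
    cols <- cols[keep]
  }
  z1 <- z1[common, cols, drop = FALSE]
  z2 <- z2[common, cols, drop = FALSE]
  m <- length(common)
  s1 <- apply(z1, 2L, sd)
  s2 <- apply(z2, 2L, sd)
  ok <- is.finite(s1) & is.finite(s2) & s1 > 0 & s2 > 0
  if (any(!ok)) {
    inform(sprintf("%d connection(s) skipped (zero variance).", sum(!ok)))
  }
  r <- rep(NA_real_, length(cols))
  r[ok] <- colSums(scale(z1[, ok, drop = FALSE]) *
                     scale(z2[, ok, drop = FALSE])) / (m - 1)
  ij <- do.call(rbind, strsplit(cols, "-", fixed = TRUE))
  per_connection <- tibble(roi_i = as.integer(ij[, 1L]),
                           roi_j = as.integer(ij[, 2L]), r = r)
  mean_z <- mean(fisher_z(r[ok]))
  structure(
    list(per_connection = per_connection, mean_z = mean_z,
         mean_r = tanh(mean_z), n_subjects = m, n_skipped = sum(!ok),
         conditions = c(k1, k2)),
    class = "fc_crosssubject"
  )
}

#' @export
print.fc_crosssubject <- function(x, ...) {
  cat(sprintf("<fc_crosssubject> %s vs %s: mean r = %.3f (mean z = %.3f) over %d connections, %d subjects\n",
              x$conditions[1L], x$conditions[2L], x$mean_r, x$mean_z,
              sum(!is.na(x$per_connection$r)), x$n_subjects))
  invisible(x)
}
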