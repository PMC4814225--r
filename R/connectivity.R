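# Pairwise Fisher-z connectivity, the long-format connectivity tensor,
# seed maps, and paired task-vs-rest contrasts under FDR control.

#' Fisher z-transform of a correlation coefficient
#'
#' `atanh` with clipping at `1 - eps` so perfect correlations map to a
#' finite value; the inverse is [inv_fisher_z()].  Values outside `[-1, 1]`
#' by more than a rounding tolerance are an error.
#'
#' @param r Correlations in `[-1, 1]` (vectorised).
#' @param eps Clipping margin (default 1e-7).
#' @return Fisher-z values.
#' @examples
#' fisher_z(0.5)  # 0.5 * log(1.5 / 0.5)
#' @export
fisher_z <- function(r, eps = 1e-7) {
  bad <- is.finite(r) & abs(r) > 1 + 1e-8
  if (any(bad)) {
    abort(sprintf("correlation out of range: %g", r[which(bad)[1L]]),
          class = "fcrel_data_error")
  }
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' @rdname fisher_z
#' @param z Fisher-z values.
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Pairwise Fisher-z connectivity of one run
#'
#' Pearson correlation of every ROI pair of the run's data matrix,
#' Fisher-transformed, in long format (`roi_i < roi_j`).  ROIs with zero
#' variance produce `NA` connections with a warning; all-constant data is
#' an error.
#'
#' @param run An `fc_run_series`, or a plain time x ROI matrix.
#' @return Tibble with `subject_id`, `condition`, `run`, `roi_i`, `roi_j`,
#'   `z` (identifier columns are `NA` for a plain matrix).
#' @export
correlation_matrix <- function(run) {
  x <- if (inherits(run, "fc_run_series")) run$data else as.matrix(run)
  if (nrow(x) < 3L) {
    abort("need at least 3 time points to correlate.",
          class = "fcrel_data_error")
  }
  v <- apply(x, 2L, var)
  if (all(v == 0)) {
    abort("all ROI series are constant.", class = "fcrel_data_error")
  }
  if (any(v == 0)) {
    warn(sprintf("%d ROI series have zero variance; their connections are NA.",
                 sum(v == 0)), class = "fcrel_zero_variance")
  }
  ok <- v > 0
  r <- matrix(NA_real_, ncol(x), ncol(x))
  r[ok, ok] <- cor(x[, ok, drop = FALSE])
  out <- pair_index(ncol(x))
  out$z <- fisher_z(r[upper.tri(r)])
  if (inherits(run, "fc_run_series")) {
    tibble(subject_id = run$subject_id, condition = run$condition,
           run = run$run_index, out)
  } else {
    tibble(subject_id = NA_character_, condition = NA_character_,
           run = NA_integer_, out)
  }
}

#' Connectivity tensor of a whole synthetic cohort
#'
#' Simulates every (subject, condition, run) acquisition of the cohort,
#' optionally preprocesses each one, and stacks the Fisher-z connectivity
#' into one long tibble indexed by connection, subject, condition and run.
#' Positive-definiteness repair warnings from the simulator are collected
#' into the `n_pd_repairs` attribute instead of being raised one by one.
#'
#' @param spec A [cohort_spec()].
#' @param truth Optional pre-generated [generate_ground_truth()]; generated
#'   from `spec` when missing.
#' @param preprocess `NULL` to correlate the raw simulated series, or a
#'   [preproc_config()] applied to every run first.
#' @param conditions Conditions to include (default: all in the spec).
#' @return An `fc_tensor` tibble (`subject_id`, `condition`, `run`,
#'   `roi_i`, `roi_j`, `z`) with attributes `n_rois` and `n_pd_repairs`.
#' @export
cohort_connectivity <- function(spec, truth = NULL, preprocess = NULL,
                                conditions = spec$conditions) {
  truth <- truth %||% generate_ground_truth(spec)
  n_repairs <- 0L
  rows <- list()
  for (cond in conditions) {
    for (s in seq_len(spec$n_subjects)) {
      for (r in seq_len(spec$runs_per_condition[[cond]])) {
        run <- withCallingHandlers(
          simulate_run(truth, spec, s, cond, r),
          fcrel_pd_repair = function(w) {
            n_repairs <<- n_repairs + 1L
            invokeRestart("muffleWarning")
          }
        )
        if (!is.null(preprocess)) {
          run <- preprocess_run(run, preprocess)
        }
        rows[[length(rows) + 1L]] <- correlation_matrix(run)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  as_fc_tensor(out, n_rois = spec$n_rois, n_pd_repairs = n_repairs)
}

as_fc_tensor <- function(x, n_rois = max(x$roi_j), n_pd_repairs = NA_integer_) {
  attr(x, "n_rois") <- n_rois
  attr(x, "n_pd_repairs") <- n_pd_repairs
  class(x) <- unique(c("fc_tensor", class(x)))
  x
}

#' Seed-based connectivity map
#'
#' The slice of the tensor containing the seed region: every connection
#' between the seed and another ROI, with a `target` column, ordered by
#' target label within each (subject, condition, run).
#'
#' @param tensor An `fc_tensor` (or compatible long tibble).
#' @param seed_label Integer ROI label of the seed.
#' @return Tibble like `tensor` plus a `target` column.
#' @export
seed_map <- function(tensor, seed_label) {
  if (!seed_label %in% c(tensor$roi_i, tensor$roi_j)) {
    abort(sprintf("seed %s does not appear in the tensor.",
                  format(seed_label)), class = "fcrel_data_error")
  }
  tensor |>
    dplyr::filter(.data$roi_i == seed_label | .data$roi_j == seed_label) |>
    dplyr::mutate(target = ifelse(.data$roi_i == seed_label,
                                  .data$roi_j, .data$roi_i)) |>
    dplyr::arrange(.data$subject_id, .data$condition, .data$run,
                   .data$target)
}

# Average z over runs within subject x condition, returning a wide
# subjects x connections matrix per condition.
subject_condition_means <- function(tensor, condition) {
  df <- tensor |>
    dplyr::filter(.data$condition == !!condition) |>
    dplyr::summarise(z = mean(.data$z),
                     .by = c("subject_id", "roi_i", "roi_j"))
  wide <- tidyr::pivot_wider(df, names_from = c("roi_i", "roi_j"),
                             values_from = "z", names_sep = "-")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$subject_id
  m
}

#' Paired condition contrast with FDR control
#'
#' For every connection, runs are first averaged (in Fisher-z units) within
#' subject x condition, then a paired two-tailed t-test across subjects
#' tests whether `z[a] - z[b]` differs from zero, and Benjamini-Hochberg
#' step-up at rate `q` decides significance across the whole family of
#' tested connections.  Connections with missing values in any subject are
#' excluded from the family (the family size is recorded).
#'
#' The smallest significant mean difference — the data's own significance
#' boundary in Fisher-z units, the analogue of a printed "±0.12" style
#' threshold — is reported in `glance()`.
#'
#' @param tensor An `fc_tensor`.
#' @param condition_a,condition_b Condition names to contrast (`a - b`).
#' @param q FDR level (default 0.05).
#' @return An `fc_contrast` tibble: `roi_i`, `roi_j`, `mean_dz`,
#'   `statistic`, `p_value`, `q_value`, `significant`.
#' @export
paired_task_rest_difference <- function(tensor, condition_a, condition_b,
                                        q = 0.05) {
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% tensor$condition) {
      abort(sprintf("condition \"%s\" not in tensor.", cond),
            class = "fcrel_data_error")
    }
  }
  za <- subject_condition_means(tensor, condition_a)
  zb <- subject_condition_means(tensor, condition_b)
  common <- intersect(rownames(za), rownames(zb))
  if (length(common) < 3L) {
    abort("need at least 3 subjects with both conditions.",
          class = "fcrel_data_error")
  }
  zb <- zb[common, colnames(za), drop = FALSE]
  za <- za[common, , drop = FALSE]
  d <- za - zb
  n <- nrow(d)
  complete <- colSums(is.na(d)) == 0L
  mean_dz <- colMeans(d)
  sd_dz <- apply(d, 2L, sd)
  tstat <- ifelse(sd_dz > 0, mean_dz / (sd_dz / sqrt(n)),
                  ifelse(mean_dz == 0, 0, Inf * sign(mean_dz)))
  p <- 2 * pt(abs(tstat), df = n - 1L, lower.tail = FALSE)
  p[!complete] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[complete] <- p.adjust(p[complete], method = "BH")
  ij <- do.call(rbind, strsplit(colnames(d), "-", fixed = TRUE))
  out <- tibble(
    roi_i = as.integer(ij[, 1L]), roi_j = as.integer(ij[, 2L]),
    mean_dz = mean_dz, statistic = tstat, p_value = p, q_value = padj,
    significant = !is.na(padj) & padj <= q
  )
  out <- out[order(out$roi_j, out$roi_i), ]
  attr(out, "q") <- q
  attr(out, "n_subjects") <- n
  attr(out, "n_family") <- sum(complete)
  attr(out, "conditions") <- c(condition_a, condition_b)
  sig <- abs(out$mean_dz[out$significant])
  attr(out, "boundary_dz") <- if (length(sig)) min(sig) else NA_real_
  class(out) <- unique(c("fc_contrast", class(out)))
  out
}

#' Benjamini-Hochberg step-up rejection
#'
#' Which hypotheses the step-up rule rejects at rate `q`: the largest `i`
#' with sorted `p(i) <= i * q / m` and everything below it.  Thin,
#' explicit wrapper used by the contrast machinery.
#'
#' @param p P-values.
#' @param q FDR level.
#' @return Logical rejection vector aligned with `p`.
#' @export
bh_reject <- function(p, q = 0.05) {
  p.adjust(p, method = "BH") <= q
}
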