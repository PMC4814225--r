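# Intraclass-correlation reliability: per-connection ICC across repeated
# acquisitions, per-ROI reliability maps against a strategic target
# subset, and the ICC-versus-region-volume analysis.

icc_forms <- c("icc21", "icc11", "icc31")

# Two-way ANOVA mean squares for an n x k x M array of ratings
# (subjects x sessions x connections), fully vectorised over M.
icc_mean_squares <- function(zarr) {
  d <- dim(zarr)
  n <- d[1L]; k <- d[2L]; M <- d[3L]
  flat <- matrix(zarr, n * k, M)
  grand <- colMeans(flat)
  subj <- colMeans(aperm(zarr, c(2L, 1L, 3L)))      # n x M
  sess <- colMeans(zarr)                             # k x M
  dim(subj) <- c(n, M)
  dim(sess) <- c(k, M)
  sst <- colSums(sweep(flat, 2L, grand)^2)
  ssr <- k * colSums(sweep(subj, 2L, grand)^2)
  ssc <- n * colSums(sweep(sess, 2L, grand)^2)
  sse <- pmax(sst - ssr - ssc, 0)
  list(
    msr = ssr / (n - 1L),
    msc = ssc / (k - 1L),
    mse = sse / ((n - 1L) * (k - 1L)),
    msw = (sst - ssr) / (n * (k - 1L)),
    sst = sst, n = n, k = k
  )
}

icc_from_ms <- function(ms, form) {
  n <- ms$n; k <- ms$k
  out <- switch(form,
    icc21 = (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n),
    icc11 = (ms$msr - ms$msw) / (ms$msr + (k - 1) * ms$msw),
    icc31 = (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse),
    abort(sprintf("unknown ICC form \"%s\".", form),
          class = "fcrel_config_error")
  )
  out[ms$sst <= 0] <- NA_real_
  out
}

#' Intraclass correlation coefficient of a ratings matrix
#'
#' Single-measure ICC from the two-way ANOVA decomposition of a
#' subjects x sessions matrix.  The default form, ICC(2,1) (two-way random
#' effects, absolute agreement), is the conventional choice for test-retest
#' reliability of functional connectivity; one-way ICC(1,1) and consistency
#' ICC(3,1) are selectable.  Negative estimates are reported as computed so
#' null simulations centre on zero.
#'
#' @param ratings Numeric subjects x sessions matrix (>= 2 of each).  Rows
#'   containing missing cells are dropped with a warning.
#' @param form `"icc21"` (default), `"icc11"` or `"icc31"`.
#' @return The ICC estimate (scalar).
#' @examples
#' m <- cbind(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))
#' icc(m)
#' @export
icc <- function(ratings, form = c("icc21", "icc11", "icc31")) {
  form <- match.arg(form)
  m <- as.matrix(ratings)
  keep <- complete.cases(m)
  if (!all(keep)) {
    warn(sprintf("dropping %d row(s) with missing cells.", sum(!keep)),
         class = "fcrel_dropped_rows")
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("need at least 2 subjects and 2 sessions.",
          class = "fcrel_data_error")
  }
  ms <- icc_mean_squares(array(m, dim = c(nrow(m), ncol(m), 1L)))
  if (ms$sst <= 0) {
    abort("total variance is zero; ICC undefined.",
          class = "fcrel_data_error")
  }
  as.numeric(icc_from_ms(ms, form))
}

# Reshape a tensor slice (one condition) into a subjects x runs x
# connections array plus the connection key.
tensor_to_array <- function(tensor, condition) {
  df <- dplyr::filter(tensor, .data$condition == !!condition)
  if (nrow(df) == 0L) {
    abort(sprintf("no data for condition \"%s\".", condition),
          class = "fcrel_data_error")
  }
  subjects <- sort(unique(df$subject_id))
  runs <- sort(unique(df$run))
  pairs <- dplyr::distinct(df[, c("roi_i", "roi_j")]) |>
    dplyr::arrange(.data$roi_j, .data$roi_i)
  ci <- match(paste(df$roi_i, df$roi_j),
              paste(pairs$roi_i, pairs$roi_j))
  zarr <- array(NA_real_, dim = c(length(subjects), length(runs),
                                  nrow(pairs)))
  zarr[cbind(match(df$subject_id, subjects), match(df$run, runs), ci)] <- df$z
  list(z = zarr, subjects = subjects, runs = runs, pairs = pairs)
}

#' Per-connection ICC and per-ROI reliability map
#'
#' For every connection between a ROI and a target-subset ROI, computes the
#' ICC of Fisher-z connectivity across subjects (rows) and repeated runs
#' (sessions) of one condition, then summarises each ROI by the mean ICC
#' over its targets.  This is the 5-mm reliability-map construction: each
#' region's value says how well its connections to the strategic subset
#' distinguish individuals across repeated acquisitions.
#'
#' @param tensor An `fc_tensor`.
#' @param targets Integer labels of the target subset (default: every ROI).
#' @param condition Condition to evaluate (default `"rest"`).
#' @param form ICC form, see [icc()].
#' @return An `fc_icc_map`: tibble with `roi`, `mean_icc`, `n_targets`;
#'   attribute `"connections"` holds the per-connection ICC tibble.
#' @export
icc_map <- function(tensor, targets = NULL, condition = "rest",
                    form = c("icc21", "icc11", "icc31")) {
  form <- match.arg(form)
  ta <- tensor_to_array(tensor, condition)
  if (dim(ta$z)[2L] < 2L) {
    abort("need at least 2 runs per subject for ICC.",
          class = "fcrel_data_error")
  }
  targets <- targets %||% sort(unique(c(ta$pairs$roi_i, ta$pairs$roi_j)))
  on_target <- ta$pairs$roi_i %in% targets | ta$pairs$roi_j %in% targets
  zarr <- ta$z[, , on_target, drop = FALSE]
  pairs <- ta$pairs[on_target, ]
  incomplete <- apply(zarr, 3L, anyNA)
  if (any(incomplete)) {
    warn(sprintf("%d connection(s) with missing cells excluded.",
                 sum(incomplete)), class = "fcrel_dropped_rows")
    zarr <- zarr[, , !incomplete, drop = FALSE]
    pairs <- pairs[!incomplete, ]
  }
  ms <- icc_mean_squares(zarr)
  conn <- tibble(roi_i = pairs$roi_i, roi_j = pairs$roi_j,
                 icc = icc_from_ms(ms, form))
  per_roi <- dplyr::bind_rows(
    conn |> dplyr::filter(.data$roi_j %in% targets) |>
      dplyr::transmute(roi = .data$roi_i, icc = .data$icc),
    conn |> dplyr::filter(.data$roi_i %in% targets) |>
      dplyr::transmute(roi = .data$roi_j, icc = .data$icc)
  ) |>
    dplyr::summarise(mean_icc = mean(.data$icc, na.rm = TRUE),
                     n_targets = sum(!is.na(.data$icc)),
                     .by = "roi") |>
    dplyr::arrange(.data$roi)
  attr(per_roi, "connections") <- conn
  attr(per_roi, "form") <- form
  attr(per_roi, "condition") <- condition
  attr(per_roi, "n_subjects") <- dim(zarr)[1L]
  attr(per_roi, "n_sessions") <- dim(zarr)[2L]
  class(per_roi) <- unique(c("fc_icc_map", class(per_roi)))
  per_roi
}

#' Reliability as a function of region volume
#'
#' Pairs each evaluated region's mean ICC (to the target subset) with its
#' volume and reports the rank correlation between the two.  Larger regions
#' average away more voxel-level noise, so reliability should rise with
#' volume; this quantifies that.
#'
#' @param tensor An `fc_tensor` holding the evaluated regions (and the
#'   targets) as ROIs.
#' @param volumes Named numeric vector of region volumes in cm^3 (names are
#'   ROI labels), or a data frame with columns `roi` and `volume_cm3`.  A
#'   voxel-count vector from [roi_timeseries()] can be converted by
#'   multiplying with the voxel volume.
#' @param targets Target-subset labels (default: every ROI not in
#'   `volumes`).
#' @param condition,form Passed to [icc_map()].
#' @return An `fc_volume_curve` tibble (`roi`, `volume_cm3`, `mean_icc`)
#'   with attribute `rank_correlation` (Spearman; `NA` with a warning when
#'   fewer than 3 regions or a degenerate volume spread).
#' @export
icc_volume_curve <- function(tensor, volumes, targets = NULL,
                             condition = "rest",
                             form = c("icc21", "icc11", "icc31")) {
  form <- match.arg(form)
  vol <- if (is.data.frame(volumes)) {
    setNames(volumes$volume_cm3, volumes$roi)
  } else {
    volumes
  }
  rois <- as.integer(names(vol))
  if (anyNA(rois)) {
    abort("`volumes` must be named by integer ROI labels.",
          class = "fcrel_data_error")
  }
  all_rois <- sort(unique(c(tensor$roi_i, tensor$roi_j)))
  targets <- targets %||% setdiff(all_rois, rois)
  map <- icc_map(tensor, targets = targets, condition = condition,
                 form = form)
  out <- tibble(roi = rois, volume_cm3 = as.numeric(vol)) |>
    dplyr::left_join(map[, c("roi", "mean_icc")], by = "roi")
  rank_cor <- NA_real_
  if (nrow(out) < 3L) {
    warn("fewer than 3 regions; rank correlation not computed.",
         class = "fcrel_degenerate")
  } else if (length(unique(out$volume_cm3)) < 2L) {
    warn("all regions have the same volume; rank correlation undefined.",
         class = "fcrel_degenerate")
  } else {
    rank_cor <- cor(out$volume_cm3, out$mean_icc, method = "spearman",
                    use = "complete.obs")
  }
  attr(out, "rank_correlation") <- rank_cor
  attr(out, "form") <- form
  class(out) <- unique(c("fc_volume_curve", class(out)))
  out
}
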