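# Simulated scrubbing versus truncation: remove a fraction of time points
# by each strategy, re-run preprocessing -> connectivity -> ICC, and
# compare the reliability curves.

#' Randomly scrub time points from a run
#'
#' Deletes one uniformly-random subset of `round(fraction * T)` time
#' indices — the same subset from the data and from every covariate of the
#' run, so alignment is preserved — and concatenates the survivors in
#' order.  This emulates motion scrubbing without needing motion estimates:
#' the run keeps its full temporal extent (minus holes) but loses volumes.
#'
#' @param run An `fc_run_series`.
#' @param fraction Fraction of time points to remove, in `[0, 1)`.
#' @param seed Integer seed for the removed-index draw.
#' @return The scrubbed `fc_run_series`; attribute `"removed_indices"`
#'   records what was deleted.
#' @export
scrub_random <- function(run, fraction, seed = 1L) {
  check_fraction(fraction)
  n_time <- run_length(run)
  n_remove <- round(fraction * n_time)
  if (n_time - n_remove < 10L) {
    abort(sprintf("scrubbing %d of %d volumes leaves fewer than 10.",
                  n_remove, n_time), class = "fcrel_data_error")
  }
  if (n_remove == 0L) {
    attr(run, "removed_indices") <- integer(0)
    return(run)
  }
  removed <- with_seed(seed, sort(sample.int(n_time, n_remove)))
  out <- subset_run(run, setdiff(seq_len(n_time), removed))
  attr(out, "removed_indices") <- removed
  out
}

#' Truncate a run to its initial segment
#'
#' Keeps the first `round((1 - fraction) * T)` volumes.  Compared with
#' scrubbing the same fraction, truncation shortens the temporal window the
#' brain's slow state is sampled over, which is exactly what the
#' scrubbing-versus-truncation experiment probes.
#'
#' @param run An `fc_run_series`.
#' @param fraction Fraction of the run to drop from the end, in `[0, 1)`.
#' @return The truncated `fc_run_series`.
#' @export
truncate_run <- function(run, fraction) {
  check_fraction(fraction)
  n_keep <- round((1 - fraction) * run_length(run))
  if (n_keep < 10L) {
    abort(sprintf("truncation to %d volumes leaves fewer than 10.", n_keep),
          class = "fcrel_data_error")
  }
  subset_run(run, seq_len(n_keep))
}

check_fraction <- function(fraction) {
  stopifnot_scalar_number(fraction, "fraction")
  if (fraction < 0 || fraction >= 1) {
    abort("`fraction` must be in [0, 1).", class = "fcrel_config_error")
  }
  invisible(fraction)
}

#' Scrubbing-versus-truncation reliability experiment
#'
#' For every (strategy, fraction) cell: applies the removal to every run
#' (scrubbing draws a fresh removed-index set per run from `seed`),
#' recomputes Fisher-z connectivity, and measures the mean ICC across the
#' evaluated connections (subjects x repeated runs).  Preprocessing, when
#' requested, runs on the intact series *before* any removal — the order
#' used by volume-censoring practice, where filtering and nuisance
#' regression precede deletion of volumes.  Filtering a
#' scrubbed-then-concatenated series instead would misread the compressed
#' timebase (surviving points span the original duration but are indexed
#' contiguously), truncating the upper half of the signal band and
#' spuriously penalising scrubbing.
#'
#' If slow connectivity-state fluctuations drive within-subject
#' variability, scrubbing (which preserves the sampled temporal window)
#' should barely move the curve while truncation (which shrinks it) should
#' pull reliability down — the scan-duration-not-volume-count signature.
#'
#' @param runs List of `fc_run_series`: >= 2 runs of one condition per
#'   subject.
#' @param fractions Removal fractions (default 0 to 0.5 in steps of 0.05).
#' @param strategies Subset of `c("scrub_random", "truncate")`.
#' @param preprocess `NULL`, or a [preproc_config()] applied to each intact
#'   run before removal.
#' @param targets Optional ROI labels: restrict the ICC mean to connections
#'   incident to these seeds.
#' @param form ICC form, see [icc()].
#' @param seed Base seed for the scrub draws (one derived seed per run and
#'   fraction).
#' @return An `fc_removal` tibble: `strategy`, `fraction`, `mean_icc`,
#'   `n_connections`.
#' @export
removal_reliability_experiment <- function(runs,
                                           fractions = seq(0, 0.5, by = 0.05),
                                           strategies = c("scrub_random",
                                                          "truncate"),
                                           preprocess = NULL,
                                           targets = NULL,
                                           form = "icc21",
                                           seed = 1L) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (!is.null(preprocess)) {
    runs <- lapply(runs, preprocess_run, config = preprocess)
  }
  grid <- expand.grid(strategy = strategies, fraction = sort(fractions),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap_dfr(grid, function(strategy, fraction) {
    processed <- lapply(seq_along(runs), function(i) {
      r <- switch(strategy,
        scrub_random = scrub_random(
          runs[[i]], fraction,
          seed = derive_seed(seed, i, 1L, round(fraction * 100))
        ),
        truncate = truncate_run(runs[[i]], fraction)
      )
      correlation_matrix(r)
    })
    tensor <- as_fc_tensor(dplyr::bind_rows(processed))
    map <- icc_map(tensor, targets = NULL,
                   condition = tensor$condition[1L], form = form)
    conn <- attr(map, "connections")
    if (!is.null(targets)) {
      conn <- dplyr::filter(conn, .data$roi_i %in% targets |
                              .data$roi_j %in% targets)
    }
    tibble(strategy = strategy, fraction = fraction,
           mean_icc = mean(conn$icc, na.rm = TRUE),
           n_connections = sum(!is.na(conn$icc)))
  })
  attr(rows, "form") <- form
  attr(rows, "seed") <- seed
  class(rows) <- unique(c("fc_removal", class(rows)))
  rows
}
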