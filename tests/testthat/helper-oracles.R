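# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# Two-pass scalar Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Benjamini-Hochberg step-up by its definition: reject H_(1..i*) where i*
# is the largest i with p_(i) <= i * q / m.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ok)) reject[ord[seq_len(max(ok))]] <- TRUE
  reject
}

# Greedy sphere packing straight from the rule: scan points in order, keep
# a point iff it is >= spacing from everything kept so far.
oracle_greedy <- function(xyz, spacing) {
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    if (nrow(kept) == 0 ||
        all(sqrt(rowSums(sweep(kept, 2, p)^2)) >= spacing)) {
      kept <- rbind(kept, p)
    }
  }
  kept
}

# Two-way ANOVA mean squares by direct summation over cells.
oracle_anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), msw = (sst - ssr) / (n * (k - 1)))
}

oracle_icc21 <- function(m) {
  ms <- oracle_anova_ms(m)
  n <- nrow(m); k <- ncol(m)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
}

# Build an fc_run_series quickly from a plain data matrix.
toy_run <- function(data, subject = "S001", condition = "rest", run = 1L,
                    tr = 1, motion = NULL, wm = NULL, csf = NULL) {
  run_series(subject_id = subject, condition = condition, run_index = run,
             tr_seconds = tr, data = data, motion = motion, wm = wm,
             csf = csf)
}
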