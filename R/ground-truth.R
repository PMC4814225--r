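# True cohort parameters: group connectome, per-subject deviations, task
# modulations, and the direction of the slow state fluctuation.

# A symmetric matrix with zero diagonal whose upper triangle is drawn
# i.i.d. N(0, sd^2) and mirrored (so entries keep SD = sd).
sym_noise <- function(n, sd) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- rnorm(sum(ut), 0, sd)
  m + t(m)
}

# Group-mean Fisher-z connectome with a block/network factor structure.
# An unstructured i.i.d. z matrix of realistic amplitude is (almost surely)
# not a correlation matrix once n_rois is more than a handful, so the group
# connectome is built as cov2cor(L L' + s2 I) from network loadings L, with
# the idiosyncratic variance s2 calibrated so that the SD of the
# off-diagonal Fisher-z entries equals `scale`.  This keeps tanh(group_z)
# positive definite with a comfortable eigenvalue margin while matching the
# requested connectivity amplitude.
group_connectome_z <- function(n, scale, n_networks = NULL) {
  if (scale == 0) {
    return(matrix(0, n, n))
  }
  q <- n_networks %||% max(2L, min(6L, n %/% 8L))
  net <- rep(seq_len(q), length.out = n)
  L <- matrix(rnorm(n * q, 0, 0.15), n, q)
  L[cbind(seq_len(n), net)] <- runif(n, 0.4, 0.9)
  ut <- upper.tri(diag(n))
  zsd <- function(s2) {
    C0 <- cov2cor(tcrossprod(L) + diag(s2, n))
    sd(atanh(C0[ut]))
  }
  lo <- log(1e-4); hi <- log(1e4)
  if (zsd(exp(lo)) < scale) {
    # requested amplitude exceeds what the loading structure can deliver;
    # rescale in z space and let the simulator's PD repair absorb the rest
    warn(sprintf(
      "group_connectome_scale = %g exceeds the factor structure's range; z entries rescaled linearly.",
      scale
    ), class = "fcrel_generator_warning")
    C0 <- cov2cor(tcrossprod(L) + diag(exp(lo), n))
    z <- atanh(C0)
    diag(z) <- 0
    return(z * (scale / sd(z[ut])))
  }
  s2 <- exp(stats::uniroot(function(ls2) zsd(exp(ls2)) - scale,
                           c(lo, hi), tol = 1e-10)$root)
  C0 <- cov2cor(tcrossprod(L) + diag(s2, n))
  z <- atanh(C0)
  diag(z) <- 0
  z
}

# Center an n x n x m deviation array so the mean over subjects of every
# entry is exactly 0.
center_dev <- function(dev) {
  dev - array(rowMeans(dev, dims = 2L), dim = dim(dev))
}

#' Generate the ground truth of a synthetic cohort
#'
#' Draws the true group-mean Fisher-z connectome, the stable per-subject
#' deviation matrices (centered across subjects by construction), the
#' per-condition task modulations, and the fixed symmetric direction matrix
#' along which the slow connectivity state fluctuates.  Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An `fc_ground_truth` list with elements `group_z` (n x n
#'   symmetric, zero diagonal), `subject_dev` (n x n x n_subjects array, or
#'   a per-condition list of such arrays when
#'   `spec$subject_dev_by_condition`), `task_delta` (named list of n x n
#'   matrices), `state_direction` (n x n symmetric) and `spec`.
#' @examples
#' truth <- generate_ground_truth(cohort_spec(n_subjects = 3, n_rois = 10,
#'                                            duration_seconds = 60))
#' max(abs(apply(truth$subject_dev, c(1, 2), mean)))  # centered
#' @export
generate_ground_truth <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec().", class = "fcrel_config_error")
  }
  n <- spec$n_rois
  m <- spec$n_subjects
  with_seed(spec$seed, {
    group_z <- group_connectome_z(n, spec$group_connectome_scale)
    if (spec$subject_dev_by_condition) {
      subject_dev <- lapply(spec$conditions, function(cond) {
        dev <- array(0, dim = c(n, n, m))
        for (s in seq_len(m)) dev[, , s] <- sym_noise(n, spec$subject_sd)
        center_dev(dev)
      })
      names(subject_dev) <- spec$conditions
    } else {
      subject_dev <- array(0, dim = c(n, n, m))
      for (s in seq_len(m)) subject_dev[, , s] <- sym_noise(n, spec$subject_sd)
      subject_dev <- center_dev(subject_dev)
    }
    task_delta <- lapply(spec$conditions, function(cond) {
      delta <- matrix(0, n, n)
      mod <- spec$task_modulation[[cond]]
      if (!is.null(mod) && mod$delta_z != 0) {
        eng <- mod$engaged
        delta[eng, eng] <- mod$delta_z
        diag(delta) <- 0
      }
      delta
    })
    names(task_delta) <- spec$conditions
    state_direction <- sym_noise(n, 1)
    structure(
      list(group_z = group_z, subject_dev = subject_dev,
           task_delta = task_delta, state_direction = state_direction,
           spec = spec),
      class = "fc_ground_truth"
    )
  })
}

# Per-subject deviation matrix for a given condition.
subject_dev_matrix <- function(truth, subject_index, condition) {
  if (truth$spec$subject_dev_by_condition) {
    truth$subject_dev[[condition]][, , subject_index]
  } else {
    truth$subject_dev[, , subject_index]
  }
}

#' @export
print.fc_ground_truth <- function(x, ...) {
  cat("<fc_ground_truth> ", x$spec$n_rois, " ROIs, ", x$spec$n_subjects,
      " subjects\n", sep = "")
  cat(sprintf("  group z off-diagonal SD: %.3f\n",
              sd(x$group_z[upper.tri(x$group_z)])))
  invisible(x)
}
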