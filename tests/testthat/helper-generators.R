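# Small direct generators used by the reliability and acceptance suites.

# tensor emulating volume-dependent noise: evaluated regions' series carry
# voxel noise shrunk by sqrt(voxel count)
volume_tensor <- function(voxels, n_subj = 20, n_run = 2, n_target = 10,
                          n_time = 150, seed = 24) {
  withr::with_seed(seed, {
    n_eval <- length(voxels)
    rows <- list()
    for (s in seq_len(n_subj)) {
      base <- matrix(rnorm(n_time * n_target), n_time)
      mix <- matrix(rnorm(n_target * n_eval, 0, 0.4), n_target, n_eval)
      for (r in seq_len(n_run)) {
        targets <- base + matrix(rnorm(n_time * n_target, 0, 0.6), n_time)
        evals <- targets %*% mix +
          sapply(voxels, function(k) rnorm(n_time, 0, 3 / sqrt(k)))
        data <- cbind(evals, targets)
        run <- toy_run(data, subject = sprintf("S%03d", s), run = r)
        rows[[length(rows) + 1L]] <- correlation_matrix(run)
      }
    }
    fcrel:::as_fc_tensor(dplyr::bind_rows(rows))
  })
}
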