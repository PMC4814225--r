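#' Generate a toy voxel dataset for parcellation tests
#'
#' Builds a small synthetic head: a contiguous "gray matter" shell wrapped
#' around a white-matter core, with a CSF rim outside, plus a 4-D BOLD-like
#' dataset in which every gray voxel carries the band-limited series of its
#' (known) parent region broadcast to all member voxels with optional
#' voxel-level noise on top.  Used as a self-contained fixture for the
#' parcellation and ROI-extraction code paths.
#'
#' @param grid_shape Integer length-3 grid dimensions, each >= 8.
#' @param affine 4 x 4 voxel-to-world transform (default isotropic 2 mm,
#'   centered on the grid).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param n_time Number of time points of the 4-D data.
#' @param tr_seconds Sampling interval of the voxel series.
#' @param voxel_noise_sd SD of i.i.d. voxel-level noise added on top of the
#'   regional series (0 makes all voxels of a region identical).
#' @return A list with `gray`, `wm`, `csf` ([mask_volume()] objects),
#'   `data` (4-D array), `true_labels` (3-D integer array of the generating
#'   regions) and `tr_seconds`.
#' @examples
#' toy <- make_toy_volume(c(10, 10, 10), seed = 1)
#' sum(toy$gray$grid)
#' @export
make_toy_volume <- function(grid_shape, affine = NULL, seed = 1L,
                            n_time = 40L, tr_seconds = 1,
                            voxel_noise_sd = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    abort("`grid_shape` must have 3 dimensions, each >= 8.",
          class = "fcrel_config_error")
  }
  if (is.null(affine)) {
    affine <- diag(c(2, 2, 2, 1))
    affine[1:3, 4] <- -(grid_shape - 1) # center the grid near the origin
  }
  affine <- as.matrix(affine)
  if (abs(det(affine)) < .Machine$double.eps) {
    abort("`affine` must be invertible.", class = "fcrel_config_error")
  }

  with_seed(seed, {
    ctr <- (grid_shape - 1) / 2
    idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]) - 1L,
                                 j = seq_len(grid_shape[2]) - 1L,
                                 k = seq_len(grid_shape[3]) - 1L))
    # radial distance in voxel units, normalised by the grid radius
    r <- sqrt(((idx[, 1] - ctr[1]) / ctr[1])^2 +
              ((idx[, 2] - ctr[2]) / ctr[2])^2 +
              ((idx[, 3] - ctr[3]) / ctr[3])^2)
    wm_v <- r < 0.35
    gray_v <- r >= 0.35 & r < 0.75
    csf_v <- r >= 0.75 & r < 0.95

    shape3 <- function(v) array(as.numeric(v), dim = grid_shape)
    gray <- mask_volume(shape3(gray_v), affine, space = "toy")
    wm <- mask_volume(shape3(wm_v), affine, space = "toy")
    csf <- mask_volume(shape3(csf_v), affine, space = "toy")

    # carve the gray shell into octant regions around the center
    oct <- 1L +
      (idx[, 1] > ctr[1]) + 2L * (idx[, 2] > ctr[2]) + 4L * (idx[, 3] > ctr[3])
    labels <- integer(nrow(idx))
    labels[gray_v] <- oct[gray_v]
    true_labels <- array(labels, dim = grid_shape)

    roi_series <- band_limited_noise(n_time, 8L, tr_seconds, c(0.001, 0.1))
    data <- array(0, dim = c(grid_shape, n_time))
    flat <- matrix(0, nrow(idx), n_time)
    in_gray <- which(gray_v)
    flat[in_gray, ] <- t(roi_series)[labels[in_gray], , drop = FALSE]
    if (voxel_noise_sd > 0) {
      flat[in_gray, ] <- flat[in_gray, ] +
        matrix(rnorm(length(in_gray) * n_time, 0, voxel_noise_sd),
               length(in_gray), n_time)
    }
    data[] <- flat

    list(gray = gray, wm = wm, csf = csf, data = data,
         true_labels = true_labels, tr_seconds = tr_seconds)
  })
}
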