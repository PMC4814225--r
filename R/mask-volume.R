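#' Construct a mask volume
#'
#' A 3-D grid (binary or probability values) with a voxel-to-world affine.
#' Voxel indices are 0-based when mapped through the affine, so
#' `world = affine %*% c(i, j, k, 1)` for the voxel at `grid[i+1, j+1, k+1]`.
#' All geometric operations in the package work in world millimetres, which
#' keeps anisotropic voxels correct.
#'
#' @param grid 3-D numeric array with values in `[0, 1]`.
#' @param affine 4 x 4 invertible voxel-to-world (mm) transform.
#' @param space Free-text space tag (e.g. `"MNI152"`).
#' @return An `fc_mask` object.
#' @export
mask_volume <- function(grid, affine = diag(4), space = "") {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L) {
    abort("`grid` must be a 3-D array.", class = "fcrel_data_error")
  }
  if (any(grid < 0 | grid > 1, na.rm = TRUE)) {
    abort("mask values must lie in [0, 1].", class = "fcrel_data_error")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      !is.finite(d <- det(affine)) || abs(d) < .Machine$double.eps) {
    abort("`affine` must be an invertible 4 x 4 matrix.",
          class = "fcrel_data_error")
  }
  structure(list(grid = grid, affine = affine, space = space),
            class = "fc_mask")
}

#' @export
print.fc_mask <- function(x, ...) {
  cat(sprintf("<fc_mask> %s, %d in-mask voxels%s\n",
              paste(dim(x$grid), collapse = " x "),
              sum(x$grid > 0),
              if (nzchar(x$space)) paste0(" [", x$space, "]") else ""))
  invisible(x)
}

# World-mm coordinates (rows) of the given 0-based voxel index matrix.
voxel_to_world <- function(ijk0, affine) {
  xyz1 <- cbind(ijk0, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

# 0-based voxel indices of all voxels where grid > threshold, as a matrix.
mask_voxels <- function(mask, threshold = 0) {
  idx <- which(mask$grid > threshold, arr.ind = TRUE)
  idx - 1L
}

check_same_grid <- function(a, b, name) {
  if (!identical(dim(a$grid), dim(b$grid)) ||
      max(abs(a$affine - b$affine)) > 1e-6) {
    abort(sprintf("volume `%s` does not share the reference grid/affine.",
                  name), class = "fcrel_data_error")
  }
  invisible(TRUE)
}
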