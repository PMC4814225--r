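# Gray-matter parcellation: group mask compilation, greedy sphere-packing
# center selection, nearest-center voxel labelling, mask erosion,
# literature-coordinate mapping and ROI series extraction.

#' Compile a group gray-matter mask
#'
#' A voxel enters the group mask when the a-priori gray-matter probability
#' reaches `gray_threshold` and the voxel lies inside the brain mask of at
#' least `coverage` of the subjects (e.g. 95%).
#'
#' @param apriori_gray [mask_volume()] of gray-matter probabilities.
#' @param subject_brain_masks List of binary [mask_volume()]s on the same
#'   grid.
#' @param coverage Required fraction of subjects covering a voxel
#'   (`0 < coverage <= 1`).
#' @param gray_threshold A-priori gray probability cut-off (default 0.5).
#' @return Binary [mask_volume()].
#' @export
compile_group_mask <- function(apriori_gray, subject_brain_masks,
                               coverage = 0.95, gray_threshold = 0.5) {
  if (!inherits(apriori_gray, "fc_mask")) {
    abort("`apriori_gray` must be a mask_volume().",
          class = "fcrel_data_error")
  }
  if (!length(subject_brain_masks)) {
    abort("`subject_brain_masks` must be non-empty.",
          class = "fcrel_data_error")
  }
  if (!(coverage > 0 && coverage <= 1)) {
    abort("`coverage` must be in (0, 1].", class = "fcrel_config_error")
  }
  counts <- array(0, dim = dim(apriori_gray$grid))
  for (i in seq_along(subject_brain_masks)) {
    m <- subject_brain_masks[[i]]
    if (!inherits(m, "fc_mask")) {
      abort(sprintf("subject mask %d is not a mask_volume().", i),
            class = "fcrel_data_error")
    }
    check_same_grid(apriori_gray, m,
                    names(subject_brain_masks)[i] %||% paste0("subject_", i))
    counts <- counts + (m$grid > 0)
  }
  frac <- counts / length(subject_brain_masks)
  out <- (apriori_gray$grid >= gray_threshold) & (frac >= coverage)
  mask_volume(array(as.numeric(out), dim = dim(counts)),
              apriori_gray$affine, apriori_gray$space)
}

#' Greedy selection of ROI center coordinates
#'
#' Scans the in-mask voxels in a fixed order and keeps a voxel as a new
#' region center iff its world-space (mm) distance to every
#' already-selected center is at least `spacing_mm`.  With the default
#' inferior-to-superior scan this packs non-overlapping `spacing_mm`
#' diameter spheres starting from the most inferior voxels, the classical
#' recipe for a ~5-mm gray-matter parcellation.
#'
#' @param mask Binary [mask_volume()].
#' @param spacing_mm Minimum center-to-center distance in mm.
#' @param scan_order One of `"zyx"` (ascending world z, then y, then x;
#'   default) or `"index"` (array storage order).
#' @return Tibble with `label`, `x_mm`, `y_mm`, `z_mm` in selection order.
#' @examples
#' m <- mask_volume(array(1, c(11, 1, 1)), diag(4))
#' greedy_select_centers(m, spacing_mm = 5)  # centers at x = 0, 5, 10
#' @export
greedy_select_centers <- function(mask, spacing_mm, scan_order = "zyx") {
  if (!inherits(mask, "fc_mask")) {
    abort("`mask` must be a mask_volume().", class = "fcrel_data_error")
  }
  stopifnot_scalar_number(spacing_mm, "spacing_mm", positive = TRUE)
  vox <- mask_voxels(mask)
  if (nrow(vox) == 0L) {
    abort("mask is empty.", class = "fcrel_data_error")
  }
  xyz <- voxel_to_world(vox, mask$affine)
  ord <- switch(scan_order,
    zyx = order(xyz[, 3], xyz[, 2], xyz[, 1]),
    index = seq_len(nrow(xyz)),
    abort("`scan_order` must be \"zyx\" or \"index\".",
          class = "fcrel_config_error")
  )
  xyz <- xyz[ord, , drop = FALSE]

  sel <- matrix(NA_real_, nrow(xyz), 3L)
  k <- 0L
  sp2 <- spacing_mm^2
  for (v in seq_len(nrow(xyz))) {
    p <- xyz[v, ]
    if (k == 0L) {
      k <- 1L
      sel[1L, ] <- p
      next
    }
    d2 <- (sel[seq_len(k), 1L] - p[1L])^2 +
          (sel[seq_len(k), 2L] - p[2L])^2 +
          (sel[seq_len(k), 3L] - p[3L])^2
    if (all(d2 >= sp2)) {
      k <- k + 1L
      sel[k, ] <- p
    }
  }
  sel <- sel[seq_len(k), , drop = FALSE]
  tibble(label = seq_len(k), x_mm = sel[, 1L], y_mm = sel[, 2L],
         z_mm = sel[, 3L])
}

#' Assign every in-mask voxel to its nearest center
#'
#' Labels each in-mask voxel with the index of the nearest center in world
#' millimetres; distance ties are broken towards the lowest center index so
#' the labelling is deterministic.  Out-of-mask voxels get label 0.
#'
#' @param mask Binary [mask_volume()].
#' @param centers Tibble from [greedy_select_centers()] (columns `label`,
#'   `x_mm`, `y_mm`, `z_mm`), or a 3-column coordinate matrix.
#' @param spacing_mm Packing distance recorded on the result (metadata).
#' @return An `fc_roiset`: list with `centers` (tibble), `label_volume`
#'   (3-D integer array), `affine` and `spacing_mm`.
#' @export
assign_voxels <- function(mask, centers, spacing_mm = NA_real_) {
  cen <- as_center_matrix(centers)
  if (nrow(cen) == 0L) {
    abort("`centers` must be non-empty.", class = "fcrel_data_error")
  }
  vox <- mask_voxels(mask)
  if (nrow(vox) == 0L) {
    abort("mask is empty.", class = "fcrel_data_error")
  }
  xyz <- voxel_to_world(vox, mask$affine)
  lab <- nearest_center(xyz, cen)$label
  label_volume <- array(0L, dim = dim(mask$grid))
  label_volume[vox + 1L] <- lab
  structure(
    list(
      centers = tibble(label = seq_len(nrow(cen)), x_mm = cen[, 1L],
                       y_mm = cen[, 2L], z_mm = cen[, 3L]),
      label_volume = label_volume,
      affine = mask$affine,
      spacing_mm = spacing_mm
    ),
    class = "fc_roiset"
  )
}

as_center_matrix <- function(centers) {
  if (is.data.frame(centers)) {
    as.matrix(centers[, c("x_mm", "y_mm", "z_mm")])
  } else {
    m <- as.matrix(centers)
    if (ncol(m) != 3L) {
      abort("`centers` must have 3 coordinate columns.",
            class = "fcrel_data_error")
    }
    m
  }
}

# Nearest center (squared-distance argmin, ties to the lowest index) for a
# matrix of query points.  Chunked so the distance matrix stays small.
nearest_center <- function(xyz, cen, chunk = 20000L) {
  n <- nrow(xyz)
  lab <- integer(n)
  dist <- numeric(n)
  cen2 <- rowSums(cen^2)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    q <- xyz[idx, , drop = FALSE]
    # d2[v, c] = |q_v|^2 - 2 q_v . c + |c|^2
    d2 <- outer(rowSums(q^2), cen2, "+") - 2 * q %*% t(cen)
    w <- max.col(-d2, ties.method = "first")
    lab[idx] <- w
    dist[idx] <- sqrt(pmax(d2[cbind(seq_along(idx), w)], 0))
  }
  list(label = lab, distance = dist)
}

#' @export
print.fc_roiset <- function(x, ...) {
  cat(sprintf("<fc_roiset> %d centers, %d labelled voxels (spacing %s mm)\n",
              nrow(x$centers), sum(x$label_volume > 0),
              format(x$spacing_mm)))
  invisible(x)
}

#' Parcellate a mask into packed regions
#'
#' Convenience wrapper: greedy center selection followed by nearest-center
#' labelling.
#'
#' @inheritParams greedy_select_centers
#' @return An `fc_roiset`.
#' @export
parcellate_mask <- function(mask, spacing_mm = 5, scan_order = "zyx") {
  centers <- greedy_select_centers(mask, spacing_mm, scan_order)
  assign_voxels(mask, centers, spacing_mm = spacing_mm)
}

#' Erode a binary mask
#'
#' Keeps a voxel only when all of its face neighbours (6-connectivity by
#' default, 26 optionally) are inside the mask; voxels on the grid boundary
#' are always removed.  Used to restrict white-matter and CSF masks to
#' voxels surrounded on all sides by the same tissue before extracting
#' nuisance series.
#'
#' @param mask Binary [mask_volume()].
#' @param connectivity 6 (faces) or 26 (faces, edges and corners).
#' @return Eroded [mask_volume()].
#' @export
erode_mask <- function(mask, connectivity = 6) {
  if (!inherits(mask, "fc_mask")) {
    abort("`mask` must be a mask_volume().", class = "fcrel_data_error")
  }
  if (!connectivity %in% c(6, 26)) {
    abort("`connectivity` must be 6 or 26.", class = "fcrel_config_error")
  }
  g <- mask$grid > 0
  d <- dim(g)
  offsets <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off[rowSums(off == 0) != 3L, , drop = FALSE]
  }
  # pad with FALSE so boundary voxels see an out-of-mask neighbour
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- g
  keep <- g
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    keep <- keep & pad[2:(d[1] + 1L) + o[1],
                       2:(d[2] + 1L) + o[2],
                       2:(d[3] + 1L) + o[3]]
  }
  mask_volume(array(as.numeric(keep), dim = d), mask$affine, mask$space)
}

#' Map literature coordinates to parcellation labels
#'
#' Finds, for each coordinate, the nearest region center in world mm.
#' Coordinates farther than `max_distance_mm` from every center are
#' flagged as unmapped (`mapped = FALSE`, label `NA`) rather than silently
#' assigned, so strategic-subset definitions cannot pick up junk regions.
#'
#' @param roiset An `fc_roiset` (or anything with a `centers` tibble).
#' @param coords_mm Data frame or matrix of query coordinates (columns
#'   `x_mm`, `y_mm`, `z_mm` or three unnamed columns).
#' @param max_distance_mm Mapping tolerance (default 10 mm).
#' @return Tibble with the query coordinates, `label`, `distance_mm` and
#'   `mapped`.
#' @export
map_coordinates_to_rois <- function(roiset, coords_mm,
                                    max_distance_mm = 10) {
  cen <- as_center_matrix(roiset$centers)
  q <- if (is.data.frame(coords_mm)) {
    nm <- c("x_mm", "y_mm", "z_mm")
    if (all(nm %in% names(coords_mm))) {
      as.matrix(coords_mm[, nm])
    } else {
      as.matrix(coords_mm)
    }
  } else {
    as.matrix(coords_mm)
  }
  if (ncol(q) != 3L || !all(is.finite(q))) {
    abort("`coords_mm` must be finite coordinates with 3 columns.",
          class = "fcrel_data_error")
  }
  nc <- nearest_center(q, cen)
  mapped <- nc$distance <= max_distance_mm
  tibble(
    x_mm = q[, 1L], y_mm = q[, 2L], z_mm = q[, 3L],
    label = ifelse(mapped, roiset$centers$label[nc$label], NA_integer_),
    distance_mm = nc$distance,
    mapped = mapped
  )
}

#' Extract region-average time series from voxel data
#'
#' Unweighted mean over the member voxels of every label at each time
#' point.  Voxel counts (region volumes) are returned alongside because
#' region volume drives reliability: averaging more voxels suppresses
#' voxel-level noise.
#'
#' @param voxel_data 4-D array (x, y, z, time).
#' @param labels An `fc_roiset`, a labelled [mask_volume()], or a 3-D
#'   integer array of labels (0 = background).
#' @return List with `data` (time x label matrix, columns sorted by label),
#'   `voxel_counts` (named integer vector) and `labels` (the label ids).
#'   Labels present in the volume but without voxels yield `NA` series with
#'   a warning.
#' @export
roi_timeseries <- function(voxel_data, labels) {
  lab_arr <- if (inherits(labels, "fc_roiset")) {
    labels$label_volume
  } else if (inherits(labels, "fc_mask")) {
    array(as.integer(round(labels$grid)), dim = dim(labels$grid))
  } else {
    as.array(labels)
  }
  d <- dim(voxel_data)
  if (length(d) != 4L || !identical(d[1:3], dim(lab_arr))) {
    abort("`voxel_data` must be 4-D on the label grid.",
          class = "fcrel_data_error")
  }
  n_time <- d[4L]
  flat_lab <- as.integer(lab_arr)
  in_roi <- flat_lab > 0L
  ids <- if (inherits(labels, "fc_roiset")) {
    labels$centers$label
  } else {
    sort(unique(flat_lab[in_roi]))
  }
  counts <- tabulate(flat_lab[in_roi], nbins = max(ids))
  counts <- counts[ids]
  flat <- matrix(voxel_data, prod(d[1:3]), n_time)
  sums <- rowsum(flat[in_roi, , drop = FALSE], group = flat_lab[in_roi])
  present <- as.integer(rownames(sums))
  out <- matrix(NA_real_, n_time, length(ids))
  colnames(out) <- sprintf("ROI%04d", ids)
  keep <- match(present, ids)
  out[, keep] <- t(sums / counts[keep])
  if (any(counts == 0L)) {
    warn(sprintf("%d label(s) have no member voxels; series set to NA.",
                 sum(counts == 0L)), class = "fcrel_empty_roi")
  }
  list(data = out, voxel_counts = setNames(as.integer(counts), colnames(out)),
       labels = ids)
}

#' Canonical seed coordinates for five resting-state networks
#'
#' MNI coordinates (mm) conventionally used to probe the salience, default
#' mode, visual, sensorimotor and dorsal attention networks: right anterior
#' insula, left posterior cingulate, right occipital pole, right precentral
#' gyrus and left frontal eye field.
#'
#' @return Tibble with `seed`, `network`, `x_mm`, `y_mm`, `z_mm`.
#' @export
canonical_seeds <- function() {
  tibble(
    seed = 1:5,
    network = c("salience", "default mode", "visual", "sensorimotor",
                "dorsal attention"),
    region = c("right anterior insula", "left posterior cingulate",
               "right occipital pole", "right precentral gyrus",
               "left frontal eye field"),
    x_mm = c(42, -4, 14, 38, 25),
    y_mm = c(12, -50, -98, -22, -4),
    z_mm = c(10, 30, -10, 60, 50)
  )
}

#' Bilateral subcortical structures used for volume-dependent reliability
#'
#' The seven structures segmented per hemisphere (14 regions in total):
#' thalamus, caudate, putamen, amygdala, hippocampus, pallidum and nucleus
#' accumbens.
#'
#' @return Tibble with `structure` and `hemisphere` (14 rows).
#' @export
subcortical_structures <- function() {
  s <- c("thalamus", "caudate", "putamen", "amygdala", "hippocampus",
         "pallidum", "accumbens")
  tibble(
    structure = rep(s, each = 2L),
    hemisphere = rep(c("left", "right"), times = length(s))
  )
}
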