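# Parcellation: group-mask compilation, greedy packing, nearest-center
# labelling, erosion, coordinate mapping and series extraction.

strip_mask <- function(n = 11, pitch = 1) {
  af <- diag(c(pitch, 1, 1, 1))
  mask_volume(array(1, c(n, 1, 1)), af)
}

test_that("group mask combines gray prior with subject coverage", {
  grid <- array(1, c(4, 4, 4))
  gray <- mask_volume(grid * 0.9, diag(4))
  full <- mask_volume(grid, diag(4))
  # unanimous coverage reproduces the thresholded prior
  out <- compile_group_mask(gray, rep(list(full), 20), coverage = 0.95)
  expect_equal(out$grid, grid)
  # one voxel covered by 18/20 subjects fails a 95% requirement
  holey <- grid
  holey[2, 2, 2] <- 0
  masks <- c(rep(list(mask_volume(holey, diag(4))), 2),
             rep(list(full), 18))
  out2 <- compile_group_mask(gray, masks, coverage = 0.95)
  expect_equal(out2$grid[2, 2, 2], 0)
  expect_equal(sum(out2$grid), sum(grid) - 1)
  # coverage 1 with one empty subject mask empties the output
  empty <- mask_volume(array(0, dim(grid)), diag(4))
  out3 <- compile_group_mask(gray, c(list(empty), rep(list(full), 19)),
                             coverage = 1)
  expect_equal(sum(out3$grid), 0)
  # mismatched grid is reported with the offending volume
  bad <- mask_volume(array(1, c(3, 4, 4)), diag(4))
  expect_error(compile_group_mask(gray, list(full, bad)), "subject_2",
               class = "fcrel_data_error")
})

test_that("greedy packing on a 1-mm strip places centers every 5 mm", {
  centers <- greedy_select_centers(strip_mask(11), spacing_mm = 5)
  expect_equal(nrow(centers), 3)
  expect_equal(centers$x_mm, c(0, 5, 10))
  # spacing below the voxel pitch never binds
  all_c <- greedy_select_centers(strip_mask(11), spacing_mm = 0.5)
  expect_equal(nrow(all_c), 11)
  expect_error(greedy_select_centers(
    mask_volume(array(0, c(8, 8, 8)), diag(4)), 5
  ), class = "fcrel_data_error")
})

test_that("greedy packing matches the brute-force rule on random masks", {
  withr::with_seed(14, {
    for (trial in 1:4) {
      g <- array(as.numeric(runif(12^3) < 0.3), c(12, 12, 12))
      af <- diag(c(2, 2.5, 3, 1))  # anisotropic voxels
      m <- mask_volume(g, af)
      if (sum(g) == 0) next
      centers <- greedy_select_centers(m, spacing_mm = 6)
      cen <- as.matrix(centers[, c("x_mm", "y_mm", "z_mm")])
      # pairwise spacing invariant
      expect_gte(min(dist(cen)), 6)
      # equals the naive greedy scan in the same order
      vox <- which(g > 0, arr.ind = TRUE) - 1
      xyz <- cbind(vox, 1) %*% t(af)
      xyz <- xyz[order(xyz[, 3], xyz[, 2], xyz[, 1]), 1:3, drop = FALSE]
      expect_equal(unname(cen), unname(oracle_greedy(xyz, 6)))
      # maximality: no in-mask voxel is >= spacing from all centers
      d_min <- apply(xyz, 1, function(p) {
        min(sqrt(colSums((t(cen) - p)^2)))
      })
      expect_lt(max(d_min), 6)
    }
  })
})

test_that("voxel assignment is nearest-center with low-index tie breaking", {
  m <- strip_mask(11)
  centers <- greedy_select_centers(m, 5)
  rs <- assign_voxels(m, centers, spacing_mm = 5)
  labs <- rs$label_volume[, 1, 1]
  expect_equal(labs[3], 1)  # x = 2 mm closer to 0
  expect_equal(labs[4], 2)  # x = 3 mm closer to 5
  # labels partition the mask
  expect_equal(sum(rs$label_volume > 0), 11)
  expect_setequal(unique(labs), 1:3)
  # single center captures everything
  one <- assign_voxels(m, centers[1, ])
  expect_true(all(one$label_volume[, 1, 1] == 1))
  # equidistant voxel on a half-mm grid goes to the lower center index
  half <- strip_mask(11, pitch = 0.5)  # x = 0, 0.5, ..., 5
  rs2 <- assign_voxels(half, tibble::tibble(label = 1:2, x_mm = c(0, 5),
                                            y_mm = 0, z_mm = 0))
  expect_equal(rs2$label_volume[6, 1, 1], 1)  # x = 2.5 ties, lower wins
})

test_that("assignment partitions arbitrary masks", {
  withr::with_seed(8, {
    g <- array(as.numeric(runif(10^3) < 0.5), c(10, 10, 10))
    m <- mask_volume(g, diag(c(2, 2, 2, 1)))
    rs <- parcellate_mask(m, spacing_mm = 5)
    counts <- table(rs$label_volume[rs$label_volume > 0])
    expect_equal(sum(counts), sum(g))
    expect_equal(sort(as.integer(names(counts))), seq_len(nrow(rs$centers)))
  })
})

test_that("erosion keeps only voxels surrounded on all faces", {
  g <- array(0, c(5, 5, 5))
  g[2:4, 2:4, 2:4] <- 1  # solid 3x3x3 cube
  er <- erode_mask(mask_volume(g, diag(4)))
  expect_equal(sum(er$grid), 1)
  expect_equal(er$grid[3, 3, 3], 1)
  # two-voxel slab erodes away completely
  slab <- array(0, c(6, 6, 6))
  slab[2:5, 2:5, 3:4] <- 1
  expect_equal(sum(erode_mask(mask_volume(slab, diag(4)))$grid), 0)
  # full grid keeps its interior (boundary always removed)
  full <- erode_mask(mask_volume(array(1, c(6, 5, 4)), diag(4)))
  expect_equal(sum(full$grid), 4 * 3 * 2)
  # 26-connectivity is at least as strict
  er26 <- erode_mask(mask_volume(g, diag(4)), connectivity = 26)
  expect_equal(sum(er26$grid), 1)
})

test_that("coordinate mapping finds seeds and flags far coordinates", {
  seeds <- canonical_seeds()
  centers <- tibble::tibble(label = seq_len(nrow(seeds)),
                            x_mm = seeds$x_mm, y_mm = seeds$y_mm,
                            z_mm = seeds$z_mm)
  rs <- list(centers = centers)
  hit <- map_coordinates_to_rois(rs, seeds[, c("x_mm", "y_mm", "z_mm")])
  expect_equal(hit$label, 1:5)
  expect_equal(hit$distance_mm, rep(0, 5))
  expect_equal(dplyr::n_distinct(hit$label), 5)
  # a coordinate 50 mm out is flagged, not silently mapped
  far <- map_coordinates_to_rois(rs, data.frame(x_mm = 42 + 50, y_mm = 12,
                                                z_mm = 10))
  expect_false(far$mapped)
  expect_true(is.na(far$label))
  # nearby (within tolerance) coordinates map to the nearest center
  near <- map_coordinates_to_rois(rs, data.frame(x_mm = 40, y_mm = 12,
                                                 z_mm = 10))
  expect_equal(near$label, 1L)
  expect_equal(near$distance_mm, 2)
})

test_that("ROI series are unweighted voxel means with volume bookkeeping", {
  lab <- array(0L, c(4, 4, 1))
  lab[1:2, 1, 1] <- 1L
  lab[3:4, 1, 1] <- 2L
  dat <- array(0, c(4, 4, 1, 5))
  s <- sin(1:5)
  dat[1, 1, 1, ] <- s
  dat[2, 1, 1, ] <- s      # identical members: mean is the series itself
  dat[3, 1, 1, ] <- s
  dat[4, 1, 1, ] <- -s     # cancelling members: mean is zero
  ext <- roi_timeseries(dat, lab)
  expect_equal(unname(ext$data[, 1]), s)
  expect_equal(unname(ext$data[, 2]), rep(0, 5))
  expect_equal(unname(ext$voxel_counts), c(2L, 2L))
})

test_that("averaging k independent voxels shrinks variance like 1/k", {
  withr::with_seed(33, {
    n_time <- 4000
    for (k in c(1, 4, 16)) {
      lab <- array(0L, c(k, 1, 1))
      lab[] <- 1L
      dat <- array(rnorm(k * n_time), c(k, 1, 1, n_time))
      v <- var(roi_timeseries(dat, lab)$data[, 1])
      expect_equal(v, 1 / k, tolerance = 0.15)
    }
  })
})

test_that("an empty label yields an NA series and a warning", {
  lab <- array(0L, c(3, 3, 1))
  lab[1, 1, 1] <- 1L
  lab[2, 1, 1] <- 3L  # label 2 of an fc_roiset-style range is missing
  rs <- structure(list(
    centers = tibble::tibble(label = 1:3, x_mm = 0, y_mm = 0, z_mm = 0),
    label_volume = lab, affine = diag(4), spacing_mm = NA_real_
  ), class = "fc_roiset")
  dat <- array(rnorm(9 * 4), c(3, 3, 1, 4))
  expect_warning(ext <- roi_timeseries(dat, rs), class = "fcrel_empty_roi")
  expect_true(all(is.na(ext$data[, 2])))
  expect_false(anyNA(ext$data[, c(1, 3)]))
})
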