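# File formats: NIfTI-1 volumes for masks/label volumes, TSV + JSON
# sidecar for run series, TSV for coordinate and result tables.

#' Read and write mask/label volumes as NIfTI-1
#'
#' Thin wrappers over RNifti that carry the voxel-to-world affine in and
#' out.  Round-tripping preserves grid values exactly and the affine to
#' within 1e-6.  Both plain and gzipped files are accepted.
#'
#' @param mask A [mask_volume()] (or a 3-D/4-D array for `write_nifti`).
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_nifti` returns a [mask_volume()] for 3-D images and a
#'   plain array with attribute `"affine"` for 4-D images.
#' @export
write_nifti <- function(mask, path) {
  if (inherits(mask, "fc_mask")) {
    arr <- mask$grid
    af <- mask$affine
  } else {
    arr <- as.array(mask)
    af <- attr(mask, "affine")
  }
  img <- RNifti::asNifti(array(as.numeric(arr), dim = dim(arr)))
  if (!is.null(af)) {
    # the voxel scales must be on pixdim before the qform is attached,
    # otherwise the quaternion representation normalises them away
    scales <- sqrt(colSums(af[1:3, 1:3]^2))
    RNifti::pixdim(img) <- c(scales, rep(1, length(dim(arr)) - 3L))
    RNifti::qform(img) <- structure(af, code = 2L)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_nifti
#' @param space Space tag attached to the returned mask.
#' @export
read_nifti <- function(path, space = "") {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
                    abort(sprintf("not a readable NIfTI file: %s (%s)",
                                  path, conditionMessage(e)),
                          class = "fcrel_format_error")
                  })
  af <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L && all(arr >= 0) && all(arr <= 1)) {
    mask_volume(arr, af, space)
  } else {
    attr(arr, "affine") <- af
    arr
  }
}

#' Write a run series as TSV with a JSON sidecar
#'
#' The data matrix goes to `<path>` as tab-separated values (rows = time,
#' columns = ROI labels, full 17-significant-digit precision); subject,
#' condition, run and TR go to `<path ending .json>`; motion and WM/CSF
#' series go to sibling `*_motion.tsv` / `*_nuisance.tsv` files when
#' present.
#'
#' @param run An `fc_run_series`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(run, path) {
  write_tsv_matrix(run$data, path)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(subject_id = run$subject_id, condition = run$condition,
         run_index = run$run_index, tr_seconds = run$tr_seconds),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(run$motion)) {
    m <- run$motion
    colnames(m) <- sprintf("motion%02d", seq_len(ncol(m)))
    write_tsv_matrix(m, sub("\\.tsv$", "_motion.tsv", path))
  }
  if (!is.null(run$wm) || !is.null(run$csf)) {
    nn <- cbind(wm = run$wm, csf = run$csf)
    write_tsv_matrix(nn, sub("\\.tsv$", "_nuisance.tsv", path))
  }
  invisible(path)
}

write_tsv_matrix <- function(m, path) {
  df <- as.data.frame(m)
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)  # accept CRLF
  if (!length(lines)) {
    abort(sprintf("empty TSV: %s", path), class = "fcrel_format_error")
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    abort(sprintf("ragged row at line %d of %s.",
                  which(widths != length(header))[1L] + 1L, path),
          class = "fcrel_format_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(body)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1L] / length(header))
    abort(sprintf("non-numeric cell at line %d of %s.", bad_row + 1L, path),
          class = "fcrel_format_error")
  }
  m <- matrix(vals, ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  m
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  data <- read_tsv_matrix(path)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("missing sidecar JSON: %s", sidecar),
          class = "fcrel_format_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("subject_id", "condition", "run_index", "tr_seconds")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("sidecar %s lacks required field \"%s\".",
                    sidecar, field), class = "fcrel_format_error")
    }
  }
  motion_path <- sub("\\.tsv$", "_motion.tsv", path)
  nuis_path <- sub("\\.tsv$", "_nuisance.tsv", path)
  motion <- if (file.exists(motion_path)) read_tsv_matrix(motion_path)
  nuis <- if (file.exists(nuis_path)) read_tsv_matrix(nuis_path)
  run_series(
    subject_id = meta$subject_id, condition = meta$condition,
    run_index = meta$run_index, tr_seconds = meta$tr_seconds,
    data = data,
    motion = motion,
    wm = if (!is.null(nuis) && "wm" %in% colnames(nuis)) nuis[, "wm"],
    csf = if (!is.null(nuis) && "csf" %in% colnames(nuis)) nuis[, "csf"]
  )
}

#' Write/read ROI centers as a TSV coordinate table
#'
#' Columns `label`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param centers Tibble of centers (from [greedy_select_centers()]).
#' @param path TSV path.
#' @return The path (write) or the centers tibble (read).
#' @export
write_centers <- function(centers, path) {
  utils::write.table(
    format(as.data.frame(centers), digits = 17, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_centers
#' @export
read_centers <- function(path) {
  m <- read_tsv_matrix(path)
  tibble(label = as.integer(m[, "label"]), x_mm = m[, "x_mm"],
         y_mm = m[, "y_mm"], z_mm = m[, "z_mm"])
}
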