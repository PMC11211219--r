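#' Write / read a cine series as NIfTI
#'
#' Frames are stored as the 4th (time) dimension of a
#' `rows x cols x 1 x frames` volume; pixel spacing goes into `pixdim` (mm)
#' and the frame spacing into the temporal `pixdim` (ms).
#'
#' @param cine a [cine_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_cine_nifti` returns `path` invisibly; `read_cine_nifti`
#'   returns a [cine_series()].
#' @export
write_cine_nifti <- function(cine, path) {
  if (!inherits(cine, "cine_series")) stop("cine must be a cine_series")
  d <- dim(cine$intensities)
  arr <- array(cine$intensities, dim = c(d[1], d[2], 1L, d[3]))
  dt <- if (d[3] > 1) diff(cine$frame_times[1:2]) else 1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(cine$pixel_spacing[1], cine$pixel_spacing[2], 1, dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_cine_nifti
#' @export
read_cine_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L) {
    arr <- array(as.numeric(img), dim = d)[, , 1, , drop = FALSE]
    arr <- array(arr, dim = c(d[1], d[2], d[4]))
  } else if (length(d) == 3L) {
    arr <- array(as.numeric(img), dim = d)
  } else {
    stop("expected a 3-D or 4-D NIfTI volume")
  }
  pd <- RNifti::pixdim(img)
  dt <- if (length(pd) >= 4) pd[4] else 36.5
  cine_series(arr, pixel_spacing = pd[1:2],
              frame_times = (seq_len(dim(arr)[3]) - 1) * dt,
              metadata = list(source = path))
}

# per-frame row-wise run-length encoding of a logical mask (0-based on disk)
.rle_encode_mask <- function(mask) {
  runs <- list()
  for (i in seq_len(nrow(mask))) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      runs[[length(runs) + 1L]] <- c(i - 1L, starts[k] - 1L, ends[k] - 1L)
    }
  }
  runs
}

.rle_decode_mask <- function(runs, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (run in runs) {
    m[run[1] + 1L, (run[2] + 1L):(run[3] + 1L)] <- TRUE
  }
  m
}

#' Write / read landmarks as JSON
#'
#' Schema (documented, version 1): coordinates are (row, col) in mm with
#' the first pixel center at (0, 0); mask indices are 0-based (converted
#' to/from R's 1-based indexing at this boundary); per-frame LV cavity
#' masks are stored as row-wise runs `[row, col_start, col_end]`.
#'
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `write_landmarks_json` returns `path` invisibly;
#'   `read_landmarks_json` returns a [landmark_set()].
#' @export
write_landmarks_json <- function(landmarks, path) {
  if (!inherits(landmarks, "landmark_set")) {
    stop("landmarks must be a landmark_set")
  }
  d <- dim(landmarks$lv_masks)
  doc <- list(
    schema = "aolvratio-landmarks",
    version = 1L,
    units = "mm",
    axis_order = "row,col",
    index_base = 0L,
    image_shape = d[1:2],
    n_frames = d[3],
    valve_point = landmarks$valve_point,
    aorta_direction = landmarks$aorta_direction,
    lv_center = landmarks$lv_center,
    lv_mask_runs = lapply(seq_len(d[3]), function(t) {
      .rle_encode_mask(landmarks$lv_masks[, , t])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "aolvratio-landmarks")) {
    stop("not an aolvratio landmark file: ", path)
  }
  shape <- as.integer(doc$image_shape)
  nf <- as.integer(doc$n_frames)
  masks <- array(FALSE, dim = c(shape[1], shape[2], nf))
  for (t in seq_len(nf)) {
    runs <- doc$lv_mask_runs[[t]]
    if (is.matrix(runs)) runs <- lapply(seq_len(nrow(runs)), function(i) runs[i, ])
    masks[, , t] <- .rle_decode_mask(runs, shape)
  }
  landmark_set(doc$valve_point, doc$aorta_direction, doc$lv_center, masks)
}
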