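#' Circular region-of-interest specification
#'
#' A disc of nominal area 1 cm^2 (radius sqrt(100/pi) ~ 5.64 mm) in
#' physical (row, col) mm coordinates. A pixel belongs to the ROI iff its
#' center lies strictly inside the disc; the achieved pixel area therefore
#' depends on the grid and is recorded alongside the nominal area.
#'
#' @param center length-2 (row, col) mm coordinates of the disc center.
#' @param frame_index 1-based cine frame the ROI applies to.
#' @param area_cm2 nominal disc area, cm^2.
#' @return An object of class `roi_spec` with the derived `radius_mm`.
#' @export
roi_spec <- function(center, frame_index, area_cm2 = 1.0) {
  if (!(is.numeric(area_cm2) && area_cm2 > 0)) stop("area_cm2 must be > 0")
  structure(
    list(center = as.numeric(center),
         frame_index = as.integer(frame_index),
         area_cm2 = area_cm2,
         radius_mm = sqrt(area_cm2 * 100 / pi),
         achieved_area_cm2 = NA_real_),
    class = "roi_spec"
  )
}

# 1-based (row, col) pixel indices whose centers lie strictly inside the
# ROI disc. Only a bounding box of candidate pixels is scanned.
roi_pixel_indices <- function(roi, image_dim, spacing) {
  spacing <- rep_len(as.numeric(spacing), 2L)
  r0 <- roi$center[1]; c0 <- roi$center[2]; rad <- roi$radius_mm
  ilo <- max(1L, floor((r0 - rad) / spacing[1]) + 1L)
  ihi <- min(image_dim[1], ceiling((r0 + rad) / spacing[1]) + 1L)
  jlo <- max(1L, floor((c0 - rad) / spacing[2]) + 1L)
  jhi <- min(image_dim[2], ceiling((c0 + rad) / spacing[2]) + 1L)
  if (ilo > ihi || jlo > jhi) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  ii <- ilo:ihi; jj <- jlo:jhi
  rm <- (ii - 1) * spacing[1]
  cm <- (jj - 1) * spacing[2]
  D <- outer((rm - r0)^2, (cm - c0)^2, "+")
  inside <- which(D < rad^2, arr.ind = TRUE)
  cbind(row = ii[inside[, 1]], col = jj[inside[, 2]])
}

# the disc (continuous extent) must sit inside the image
.check_roi_inside <- function(roi, image_dim, spacing, what) {
  extent <- (image_dim[1:2] - 1L) * rep_len(as.numeric(spacing), 2L)
  lo <- roi$center - roi$radius_mm
  hi <- roi$center + roi$radius_mm
  if (any(lo < 0) || any(hi > extent)) {
    stop(sprintf("%s ROI (center %.1f, %.1f mm, radius %.1f mm) extends beyond the image",
                 what, roi$center[1], roi$center[2], roi$radius_mm),
         call. = FALSE)
  }
}

#' Select the end-systolic frame from LV cavity masks
#'
#' The measurement frame is the one with the smallest LV cavity, the
#' operational stand-in for visually identified end-systole. Cavity size is
#' mask pixel count times pixel area (mm^2); ties are broken by the
#' earliest frame.
#'
#' @param cine a [cine_series()].
#' @param landmarks a [landmark_set()] with per-frame LV masks.
#' @return 1-based index of the minimum-area frame.
#' @export
select_end_systolic_frame <- function(cine, landmarks) {
  if (!inherits(cine, "cine_series")) stop("cine must be a cine_series")
  if (!inherits(landmarks, "landmark_set")) {
    stop("landmarks must be a landmark_set")
  }
  masks <- landmarks$lv_masks
  if (!all(dim(masks) == dim(cine$intensities))) {
    stop("LV masks must match the cine dimensions")
  }
  counts <- apply(masks, 3, sum)
  if (any(counts == 0)) {
    stop("empty LV mask on frame(s) ",
         paste(which(counts == 0), collapse = ", "))
  }
  areas <- counts * prod(cine$pixel_spacing)
  which.min(areas)  # which.min takes the earliest of tied minima
}

#' Place the aortic and LV regions of interest
#'
#' The aortic ROI center is `valve_point + 10 mm * aorta_direction`
#' ("approximately 1 cm above the aortic valve leaflets", fixed at exactly
#' 10 mm); the LV ROI center is the annotated cavity center at the
#' mid-papillary level. Both are 1 cm^2 discs. Placement fails if a disc
#' extends beyond the image, or if any LV ROI pixel falls outside the LV
#' cavity mask of the measurement frame (guarding against myocardial or
#' papillary contamination).
#'
#' @param landmarks a [landmark_set()].
#' @param spacing pixel spacing, mm (row, col).
#' @param frame 1-based measurement frame index.
#' @param offset_mm distance from the valve to the aortic ROI center.
#' @param area_cm2 nominal ROI area.
#' @return list with `aorta` and `lv` [roi_spec()] objects (achieved pixel
#'   areas filled in).
#' @export
place_rois <- function(landmarks, spacing, frame, offset_mm = 10,
                       area_cm2 = 1.0) {
  if (!inherits(landmarks, "landmark_set")) {
    stop("landmarks must be a landmark_set")
  }
  spacing <- rep_len(as.numeric(spacing), 2L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  dims <- dim(landmarks$lv_masks)
  if (frame < 1L || frame > dims[3]) stop("frame out of range")

  ao_center <- landmarks$valve_point + offset_mm * landmarks$aorta_direction
  aorta <- roi_spec(ao_center, frame, area_cm2)
  lv <- roi_spec(landmarks$lv_center, frame, area_cm2)
  .check_roi_inside(aorta, dims, spacing, "aortic")
  .check_roi_inside(lv, dims, spacing, "LV")

  px_area_cm2 <- prod(spacing) / 100
  ao_px <- roi_pixel_indices(aorta, dims, spacing)
  lv_px <- roi_pixel_indices(lv, dims, spacing)
  if (nrow(ao_px) == 0 || nrow(lv_px) == 0) {
    stop("ROI selects no pixels at this spacing")
  }
  mask <- landmarks$lv_masks[, , frame]
  if (!all(mask[lv_px])) {
    stop("LV ROI extends outside the LV cavity mask on frame ", frame,
         call. = FALSE)
  }
  aorta$achieved_area_cm2 <- nrow(ao_px) * px_area_cm2
  lv$achieved_area_cm2 <- nrow(lv_px) * px_area_cm2
  list(aorta = aorta, lv = lv)
}

#' Mean signal inside an ROI
#'
#' Arithmetic mean of the intensities of pixels whose centers lie strictly
#' inside the ROI disc.
#'
#' @param frame_image 2-D intensity matrix.
#' @param roi a [roi_spec()].
#' @param spacing pixel spacing, mm.
#' @return mean intensity (scalar).
#' @export
mean_roi_signal <- function(frame_image, roi, spacing) {
  if (!is.matrix(frame_image)) stop("frame_image must be a matrix")
  if (!inherits(roi, "roi_spec")) stop("roi must be a roi_spec")
  px <- roi_pixel_indices(roi, dim(frame_image), spacing)
  if (nrow(px) == 0) stop("ROI selects no pixels")
  mean(frame_image[px])
}

#' Compute the Ao:LV ratio
#'
#' Divides the mean aortic blood signal by the mean LV blood signal. The
#' ratio is kept at full precision; `ratio_display` is the conventional
#' 2-decimal rendering (e.g. 67.5 / 186.2 -> "0.36").
#'
#' @param aorta_mean mean aortic ROI signal.
#' @param lv_mean mean LV ROI signal (> 0).
#' @param frame_index optional measurement frame recorded on the result.
#' @param aorta_roi,lv_roi optional [roi_spec()] provenance.
#' @return An object of class `ratio_measurement`.
#' @export
#' @examples
#' m <- compute_ratio(67.5, 186.2)
#' m$ratio_display
compute_ratio <- function(aorta_mean, lv_mean, frame_index = NA_integer_,
                          aorta_roi = NULL, lv_roi = NULL) {
  if (!is.finite(aorta_mean) || aorta_mean < 0) {
    stop("aorta_mean must be finite and >= 0")
  }
  if (!is.finite(lv_mean) || lv_mean <= 0) {
    stop("lv_mean must be > 0")
  }
  ratio <- aorta_mean / lv_mean
  structure(
    list(aorta_mean = aorta_mean, lv_mean = lv_mean, ratio = ratio,
         ratio_display = sprintf("%.2f", ratio),
         frame_index = frame_index, aorta_roi = aorta_roi, lv_roi = lv_roi),
    class = "ratio_measurement"
  )
}

#' @export
print.ratio_measurement <- function(x, ...) {
  cat(sprintf("Ao:LV ratio: %.1f / %.1f = %s (frame %s)\n",
              x$aorta_mean, x$lv_mean, x$ratio_display,
              ifelse(is.na(x$frame_index), "?", x$frame_index)))
  invisible(x)
}

#' Measure the Ao:LV ratio on a cine series
#'
#' Runs the full protocol: pick the end-systolic frame from the LV masks,
#' place the aortic and LV ROIs, average the blood signal in each, form
#' the ratio and classify it against the cut-off scheme.
#'
#' @param cine a [cine_series()].
#' @param landmarks a [landmark_set()].
#' @param scheme a [cutoff_scheme()].
#' @param offset_mm aortic ROI distance above the valve, mm.
#' @return A `ratio_measurement` with an additional `class` element
#'   (severity call, see [classify_severity()]).
#' @export
#' @examples
#' ph <- render_phantom(phantom_spec(true_ratio = 0.36))
#' m <- measure_cine(ph$cine, ph$landmarks)
#' c(m$ratio, as.character(m$class))
measure_cine <- function(cine, landmarks, scheme = cutoff_scheme(),
                         offset_mm = 10) {
  frame <- select_end_systolic_frame(cine, landmarks)
  rois <- place_rois(landmarks, cine$pixel_spacing, frame, offset_mm)
  img <- cine$intensities[, , frame]
  ao <- mean_roi_signal(img, rois$aorta, cine$pixel_spacing)
  lv <- mean_roi_signal(img, rois$lv, cine$pixel_spacing)
  m <- compute_ratio(ao, lv, frame, rois$aorta, rois$lv)
  m$class <- classify_severity(m$ratio, scheme)
  m
}
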