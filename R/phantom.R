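#' Multi-frame cine series container
#'
#' A single-slice cine: a `rows x cols x frames` non-negative intensity
#' array with pixel spacing in mm and frame times in ms. Physical
#' coordinates are (row, col) in mm with the first pixel center at (0, 0)
#' and mm = (index - 1) * spacing.
#'
#' @param intensities numeric array `rows x cols x frames`.
#' @param pixel_spacing length-2 numeric, mm per pixel (row, col).
#' @param frame_times numeric vector of frame times, ms.
#' @param metadata optional named list of source identifiers.
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(intensities, pixel_spacing, frame_times = NULL,
                        metadata = list()) {
  if (!(is.array(intensities) && length(dim(intensities)) == 3L)) {
    stop("intensities must be a rows x cols x frames array")
  }
  if (dim(intensities)[3] < 2L) stop("a cine needs at least 2 frames")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be > 0")
  nf <- dim(intensities)[3]
  if (is.null(frame_times)) frame_times <- (seq_len(nf) - 1) * 36.5
  if (length(frame_times) != nf) {
    stop("frame_times length must equal the number of frames")
  }
  structure(
    list(intensities = intensities, pixel_spacing = pixel_spacing,
         frame_times = as.numeric(frame_times), metadata = metadata),
    class = "cine_series"
  )
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("cine_series: %d x %d pixels, %d frames, spacing %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

#' Geometric landmarks for ROI placement
#'
#' The anchors the measurement protocol needs: the aortic valve point and
#' the unit direction of the ascending aorta (for the aortic ROI, placed
#' 1 cm above the leaflets), the LV cavity center at the mid-papillary
#' level (for the LV ROI), and per-frame binary LV cavity masks (for
#' end-systolic frame selection). Coordinates are (row, col) mm.
#'
#' @param valve_point length-2 mm coordinates of the aortic valve.
#' @param aorta_direction length-2 direction of the ascending aorta
#'   (normalised internally).
#' @param lv_center length-2 mm coordinates of the LV cavity center.
#' @param lv_masks logical array `rows x cols x frames` of LV cavity masks.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(valve_point, aorta_direction, lv_center, lv_masks) {
  if (!(is.array(lv_masks) && length(dim(lv_masks)) == 3L &&
        is.logical(lv_masks))) {
    stop("lv_masks must be a logical rows x cols x frames array")
  }
  nrm <- sqrt(sum(aorta_direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("aorta_direction must be non-zero")
  structure(
    list(valve_point = as.numeric(valve_point),
         aorta_direction = as.numeric(aorta_direction) / nrm,
         lv_center = as.numeric(lv_center),
         lv_masks = lv_masks),
    class = "landmark_set"
  )
}

#' Phantom specification
#'
#' Geometry and signal model of the synthetic 3-chamber cine: an elliptical
#' LV cavity that contracts sinusoidally (minimum area exactly at
#' `end_systolic_frame`) inside a myocardial ring, and an ascending-aorta
#' band starting at `valve_point` along `aorta_direction`. LV blood is
#' painted at `blood_signal` and the aortic lumen at
#' `blood_signal * true_ratio` -- a phenomenological flow void standing in
#' for intravoxel dephasing of the turbulent post-stenotic jet, not a
#' physics simulation. Optional Rician noise models the magnitude image.
#'
#' @param image_shape rows, cols in pixels.
#' @param pixel_spacing mm per pixel (row, col).
#' @param n_frames number of cine frames (>= 2).
#' @param end_systolic_frame 1-based frame index of minimum LV area.
#' @param lv_center LV cavity center, (row, col) mm.
#' @param lv_semi_axes_diastole diastolic cavity semi-axes, mm.
#' @param lv_contraction_fraction fractional semi-axis shortening at
#'   end-systole, in (0, 1).
#' @param myocardial_thickness ring thickness around the cavity, mm.
#' @param valve_point aortic valve location, (row, col) mm.
#' @param aorta_direction direction of the ascending aorta (normalised).
#' @param aorta_diameter lumen width, mm.
#' @param aorta_length length of the rendered aortic band, mm (>= 30 so the
#'   "1 cm above the leaflets" ROI always fits).
#' @param blood_signal LV blood intensity (arbitrary units).
#' @param myocardium_signal myocardial intensity.
#' @param background_signal air/soft-tissue background intensity.
#' @param true_ratio ground-truth Ao:LV ratio painted into the aorta (> 0).
#' @param noise_sigma Rician noise scale, intensity units (0 = noise-free).
#' @param frame_duration_ms temporal spacing of frames.
#' @param seed seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(true_ratio = 0.36)
#' ph <- render_phantom(spec)
#' ph$true_ratio
phantom_spec <- function(image_shape = c(128L, 128L),
                         pixel_spacing = c(1.46, 1.46),
                         n_frames = 25L,
                         end_systolic_frame = 9L,
                         lv_center = c(115, 95),
                         lv_semi_axes_diastole = c(33, 22),
                         lv_contraction_fraction = 0.35,
                         myocardial_thickness = 10,
                         valve_point = c(75, 95),
                         aorta_direction = c(-0.966, 0.259),
                         aorta_diameter = 28,
                         aorta_length = 40,
                         blood_signal = 186.2,
                         myocardium_signal = 80,
                         background_signal = 10,
                         true_ratio = 1.0,
                         noise_sigma = 0,
                         frame_duration_ms = 36.5,
                         seed = 1L) {
  spec <- list(image_shape = as.integer(rep_len(image_shape, 2L)),
               pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
               n_frames = as.integer(n_frames),
               end_systolic_frame = as.integer(end_systolic_frame),
               lv_center = as.numeric(lv_center),
               lv_semi_axes_diastole = as.numeric(lv_semi_axes_diastole),
               lv_contraction_fraction = lv_contraction_fraction,
               myocardial_thickness = myocardial_thickness,
               valve_point = as.numeric(valve_point),
               aorta_direction = as.numeric(aorta_direction),
               aorta_diameter = aorta_diameter,
               aorta_length = aorta_length,
               blood_signal = blood_signal,
               myocardium_signal = myocardium_signal,
               background_signal = background_signal,
               true_ratio = true_ratio,
               noise_sigma = noise_sigma,
               frame_duration_ms = frame_duration_ms,
               seed = as.integer(seed))
  if (any(spec$pixel_spacing <= 0)) stop("pixel_spacing must be > 0")
  if (spec$n_frames < 2L) stop("n_frames must be >= 2")
  if (spec$end_systolic_frame < 1L ||
      spec$end_systolic_frame > spec$n_frames) {
    stop("end_systolic_frame must lie in 1..n_frames")
  }
  if (!(spec$true_ratio > 0)) stop("true_ratio must be > 0")
  if (!(spec$lv_contraction_fraction > 0 &&
        spec$lv_contraction_fraction < 1)) {
    stop("lv_contraction_fraction must lie in (0, 1)")
  }
  if (spec$aorta_length < 30) {
    stop("aorta_length must be >= 30 mm so the aortic ROI fits")
  }
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  nrm <- sqrt(sum(spec$aorta_direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("aorta_direction must be non-zero")
  spec$aorta_direction <- spec$aorta_direction / nrm
  structure(spec, class = "phantom_spec")
}

# image extent in mm (coordinates of the last pixel center)
.extent_mm <- function(shape, spacing) (shape - 1L) * spacing

.check_point_inside <- function(p, extent, what) {
  if (any(p < 0) || any(p > extent)) {
    stop(sprintf("phantom geometry places %s outside the image (point %.1f, %.1f mm; extent %.1f x %.1f mm)",
                 what, p[1], p[2], extent[1], extent[2]), call. = FALSE)
  }
}

#' Render a synthetic 3-chamber cine phantom
#'
#' Paints each frame on the pixel grid: background, myocardial ring, LV
#' cavity blood, then the aortic band (painted last so the outflow tract is
#' lumen-valued). The cavity semi-axes scale by
#' `1 - f * (1 + cos(2 pi (t - ES) / n)) / 2`, so the area minimum falls
#' exactly on the end-systolic frame. When `noise_sigma > 0`, Rician noise
#' `sqrt((I + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)` is applied,
#' matching the magnitude-image noise model; at high SNR it coincides with
#' Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `cine` ([cine_series()]), `landmarks`
#'   ([landmark_set()] with per-frame cavity masks) and `true_ratio`.
#' @export
render_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  shape <- spec$image_shape
  sp <- spec$pixel_spacing
  extent <- .extent_mm(shape, sp)

  d <- spec$aorta_direction
  dperp <- c(-d[2], d[1])
  half <- spec$aorta_diameter / 2
  corners <- rbind(
    spec$valve_point + half * dperp,
    spec$valve_point - half * dperp,
    spec$valve_point + spec$aorta_length * d + half * dperp,
    spec$valve_point + spec$aorta_length * d - half * dperp
  )
  for (k in seq_len(nrow(corners))) {
    .check_point_inside(corners[k, ], extent,
                        "the aorta (valve_point/aorta_direction)")
  }
  .check_point_inside(spec$lv_center, extent, "lv_center")
  .check_point_inside(spec$lv_center + spec$lv_semi_axes_diastole +
                        spec$myocardial_thickness, extent, "the LV (lv_center)")
  .check_point_inside(spec$lv_center - spec$lv_semi_axes_diastole -
                        spec$myocardial_thickness, extent, "the LV (lv_center)")

  rmm <- (seq_len(shape[1]) - 1) * sp[1]
  cmm <- (seq_len(shape[2]) - 1) * sp[2]
  R <- matrix(rmm, shape[1], shape[2])
  C <- matrix(cmm, shape[1], shape[2], byrow = TRUE)

  U <- (R - spec$valve_point[1]) * d[1] + (C - spec$valve_point[2]) * d[2]
  W <- (R - spec$valve_point[1]) * dperp[1] +
       (C - spec$valve_point[2]) * dperp[2]
  aorta <- U >= 0 & U <= spec$aorta_length & abs(W) <= half

  nf <- spec$n_frames
  es <- spec$end_systolic_frame
  img <- array(spec$background_signal, dim = c(shape[1], shape[2], nf))
  masks <- array(FALSE, dim = c(shape[1], shape[2], nf))
  th <- spec$myocardial_thickness
  for (t in seq_len(nf)) {
    w <- (1 + cos(2 * pi * (t - es) / nf)) / 2
    s <- 1 - spec$lv_contraction_fraction * w
    a <- spec$lv_semi_axes_diastole[1] * s
    b <- spec$lv_semi_axes_diastole[2] * s
    E <- ((R - spec$lv_center[1]) / a)^2 + ((C - spec$lv_center[2]) / b)^2
    Eo <- ((R - spec$lv_center[1]) / (a + th))^2 +
          ((C - spec$lv_center[2]) / (b + th))^2
    cavity <- E <= 1
    frame <- matrix(spec$background_signal, shape[1], shape[2])
    frame[Eo <= 1] <- spec$myocardium_signal
    frame[cavity] <- spec$blood_signal
    frame[aorta] <- spec$blood_signal * spec$true_ratio
    img[, , t] <- frame
    masks[, , t] <- cavity
  }

  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed, {
      n1 <- array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
      n2 <- array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
      sqrt((img + n1)^2 + n2^2)
    })
  }

  cine <- cine_series(img, sp,
                      frame_times = (seq_len(nf) - 1) * spec$frame_duration_ms,
                      metadata = list(source = "aolvratio phantom",
                                      true_ratio = spec$true_ratio))
  lm <- landmark_set(spec$valve_point, d, spec$lv_center, masks)
  list(cine = cine, landmarks = lm, true_ratio = spec$true_ratio)
}
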