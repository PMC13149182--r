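# QCT-style vBMD measurement: an elliptical trabecular ROI of 90-110 mm^2 on
# the mid-vertebral slice, a linear HU -> mg/cm^3 calibration, and the
# standard 80/120 mg/cm^3 three-class grouping. The default identity
# calibration makes phantom HU numerically equal to vBMD, so grouping logic
# can be exercised without a vendor calibration.

#' Linear HU to vBMD calibration
#'
#' @param slope (mg/cm^3) per HU, must be positive. Default 1.
#' @param intercept mg/cm^3. Default 0.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(slope = 1, intercept = 0) {
  stopifnot(is.finite(slope), slope > 0, is.finite(intercept))
  structure(list(slope = slope, intercept = intercept),
            class = "calibration_model")
}

#' Trabecular HU for a target vBMD under a calibration (inverse map)
#'
#' Convenience for building phantoms whose trabecular core measures a chosen
#' vBMD: `hu = (vbmd - intercept) / slope`.
#'
#' @param vbmd target volumetric BMD, mg/cm^3.
#' @param cal a [calibration_model()].
#' @return HU value.
#' @export
hu_for_vbmd <- function(vbmd, cal = calibration_model()) {
  (vbmd - cal$intercept) / cal$slope
}

#' Elliptical ROI specification
#'
#' @param center mm pair, in-plane center.
#' @param semi_axes mm pair; the ROI area `pi * a * b` must lie in
#'   `[90, 110]` mm^2 (the protocol's window).
#' @param slice_index axial slice carrying the ROI.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, semi_axes, slice_index) {
  area <- pi * semi_axes[1] * semi_axes[2]
  stopifnot(length(center) == 2L, length(semi_axes) == 2L,
            all(semi_axes > 0), area >= 90, area <= 110,
            slice_index >= 1L)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 slice_index = as.integer(slice_index),
                 area = area),
            class = "roi_spec")
}

#' Logical in-plane mask of an ROI on a given grid
#'
#' @param roi a [roi_spec()].
#' @param dim2 in-plane grid dimensions (rows, columns).
#' @param spacing in-plane mm pair.
#' @return logical matrix.
#' @export
roi_mask <- function(roi, dim2, spacing) {
  xc <- (seq_len(dim2[1]) - 0.5) * spacing[1] - roi$center[1]
  yc <- (seq_len(dim2[2]) - 0.5) * spacing[2] - roi$center[2]
  X <- matrix(xc, dim2[1], dim2[2])
  Y <- matrix(yc, dim2[1], dim2[2], byrow = TRUE)
  (X / roi$semi_axes[1])^2 + (Y / roi$semi_axes[2])^2 <= 1
}

#' Place the trabecular vBMD ROI
#'
#' Centers an ellipse at the trabecular centroid of the mid-vertebral slice,
#' with aspect ratio matched to the trabecular cross-section, scaled to
#' `target_area` and shrunk (3% steps) until it lies entirely inside the
#' trabecular mask — maximally including trabecular bone while avoiding
#' cortex. Fails with a flag when no ellipse of at least 90 mm^2 fits.
#'
#' @param seg a [segmentation_result()].
#' @param target_area mm^2, default 100 (midpoint of the 90-110 window).
#' @return A [roi_spec()], or a list `list(ok = FALSE, flag = ...)` when
#'   placement is infeasible.
#' @export
place_roi <- function(seg, target_area = 100) {
  stopifnot(inherits(seg, "segmentation_result"),
            target_area >= 90, target_area <= 110)
  trab_slices <- which(apply(seg$trabecular_mask, 3, any))
  if (!length(trab_slices))
    return(list(ok = FALSE, flag = "no_trabecular_core"))
  k <- trab_slices[ceiling(length(trab_slices) / 2)]
  m <- seg$trabecular_mask[, , k]
  sp <- seg$spacing[1:2]
  idx <- which(m, arr.ind = TRUE)
  ctr <- c(mean(idx[, 1]) - 0.5, mean(idx[, 2]) - 0.5) * sp
  # aspect from the second moments of the trabecular cross-section
  sx <- stats::sd((idx[, 1] - 0.5) * sp[1])
  sy <- stats::sd((idx[, 2] - 0.5) * sp[2])
  aspect <- if (is.finite(sx / sy) && sy > 0) sx / sy else 1
  b0 <- sqrt(target_area / (pi * aspect))
  a0 <- aspect * b0
  scale <- 1
  repeat {
    a <- a0 * scale; b <- b0 * scale
    if (pi * a * b < 90) return(list(ok = FALSE, flag = "trabecular_region_too_small"))
    roi_try <- list(center = ctr, semi_axes = c(a, b), slice_index = k)
    class(roi_try) <- "roi_spec"
    inside <- roi_mask(roi_try, dim(m), sp)
    if (!any(inside & !m)) break
    scale <- scale * 0.97
  }
  roi_spec(ctr, c(a, b), k)
}

#' Measure vBMD in an ROI
#'
#' `vbmd = slope * mean(HU in ROI) + intercept`.
#'
#' @param volume a [voxel_volume()].
#' @param roi a [roi_spec()].
#' @param cal a [calibration_model()].
#' @return vBMD in mg/cm^3.
#' @export
measure_vbmd <- function(volume, roi, cal = calibration_model()) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(roi, "roi_spec"),
            roi$slice_index <= dim(volume$hu)[3])
  m <- roi_mask(roi, dim(volume$hu)[1:2], volume$spacing[1:2])
  if (!any(m)) stop("empty ROI")
  cal$slope * mean(volume$hu[, , roi$slice_index][m]) + cal$intercept
}

#' Classify vBMD into the three-group scheme
#'
#' Boundary semantics exactly as specified: normal is vBMD > 120 mg/cm^3,
#' osteopenia is 80 <= vBMD <= 120 (both endpoints included), osteoporosis
#' is vBMD < 80. Non-osteoporosis = normal or osteopenia.
#'
#' @param vbmd numeric vector of vBMD values, mg/cm^3, finite.
#' @return factor with levels `normal`, `osteopenia`, `osteoporosis`.
#' @examples
#' classify_bmd(c(121, 120, 80, 79.9))
#' @export
classify_bmd <- function(vbmd) {
  if (any(!is.finite(vbmd))) stop("vbmd must be finite")
  factor(ifelse(vbmd > 120, "normal",
         ifelse(vbmd >= 80, "osteopenia", "osteoporosis")),
         levels = c("normal", "osteopenia", "osteoporosis"))
}

#' Final vBMD from one or two vertebral measurements
#'
#' The reference protocol averages L1 and L2; single-vertebra runs use L1
#' alone. This helper averages whatever it is given.
#'
#' @param ... one or two numeric vBMD values.
#' @return their mean.
#' @export
final_vbmd <- function(...) {
  v <- c(...)
  stopifnot(length(v) >= 1L, length(v) <= 2L, all(is.finite(v)))
  mean(v)
}
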