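# Cortical/trabecular segmentation surrogate: threshold + per-slice
# morphological closing + 2D hole filling + largest-3D-component selection.
# Stands in for the proprietary AI system whose algorithm is not publicly
# reproducible; the downstream morphometry definitions are agnostic to how
# the mask was produced.

#' Segmentation configuration
#'
#' @param bone_threshold HU threshold separating bone from soft tissue
#'   (default 250: above soft tissue and typical osteoporotic trabecular
#'   attenuation, below cortical bone).
#' @param closing_radius disk radius in voxels for per-slice morphological
#'   closing of the bone mask (default 1; 0 disables).
#' @param min_component_voxels components smaller than this are treated as
#'   speckle, not as competing bodies (default 50).
#' @param slice_range optional integer pair restricting segmentation to a
#'   slice interval (default NULL = all slices).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(bone_threshold = 250,
                                closing_radius = 1L,
                                min_component_voxels = 50L,
                                slice_range = NULL) {
  stopifnot(is.finite(bone_threshold), closing_radius >= 0,
            min_component_voxels >= 1,
            is.null(slice_range) ||
              (length(slice_range) == 2L && slice_range[1] <= slice_range[2]))
  structure(list(bone_threshold = bone_threshold,
                 closing_radius = as.integer(closing_radius),
                 min_component_voxels = as.integer(min_component_voxels),
                 slice_range = slice_range),
            class = "segmentation_config")
}

#' Segmentation result constructor (validates mask invariants)
#'
#' Cortical and trabecular masks must be disjoint and both contained in the
#' body mask; the per-slice centroid is defined wherever the body mask is
#' non-empty.
#'
#' @param cortical_mask,trabecular_mask,body_mask logical 3D arrays of equal
#'   dimension.
#' @param per_slice_centroid numeric matrix (n_slices x 2) of body-mask area
#'   centroids in physical mm, NA rows for empty slices.
#' @param qc_flags character vector of diagnostic codes.
#' @param spacing mm triple of the segmented volume.
#' @return An object of class `segmentation_result`.
#' @export
segmentation_result <- function(cortical_mask, trabecular_mask, body_mask,
                                per_slice_centroid, qc_flags = character(0),
                                spacing) {
  stopifnot(identical(dim(cortical_mask), dim(trabecular_mask)),
            identical(dim(cortical_mask), dim(body_mask)))
  if (any(cortical_mask & trabecular_mask))
    stop("cortical and trabecular masks overlap")
  if (any(cortical_mask & !body_mask) || any(trabecular_mask & !body_mask))
    stop("masks not contained in body mask")
  structure(list(cortical_mask = cortical_mask,
                 trabecular_mask = trabecular_mask,
                 body_mask = body_mask,
                 per_slice_centroid = per_slice_centroid,
                 qc_flags = qc_flags,
                 spacing = spacing),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> cortical %d vox, trabecular %d vox, flags: %s\n",
              sum(x$cortical_mask), sum(x$trabecular_mask),
              if (length(x$qc_flags)) paste(x$qc_flags, collapse = ", ") else "none"))
  invisible(x)
}

#' Segment the vertebral body of a CT volume
#'
#' Per slice: bone mask = HU >= threshold followed by morphological closing;
#' body mask = hole-filled bone mask; cortical = bone voxels; trabecular =
#' body minus cortical. Across slices the largest 6-connected bone component
#' is retained. A second component at or above `min_component_voxels` is
#' rejected (at most one vertebral body is expected upstream). An empty bone
#' mask yields an empty result with a `no_bone` flag rather than an error.
#'
#' @param volume a [voxel_volume()].
#' @param config a [segmentation_config()].
#' @return A [segmentation_result()].
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 3))
#' seg <- segment_vertebra(ph$volume, segmentation_config())
#' sum(seg$cortical_mask & ph$truth$cortical_mask) / sum(seg$cortical_mask)
#' @export
segment_vertebra <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(config, "segmentation_config"))
  hu <- volume$hu
  d <- dim(hu)
  slices <- seq_len(d[3])
  if (!is.null(config$slice_range))
    slices <- slices[slices >= config$slice_range[1] &
                     slices <= config$slice_range[2]]

  bone <- array(FALSE, d)
  for (k in slices) {
    m <- hu[, , k] >= config$bone_threshold
    if (config$closing_radius > 0 && any(m))
      m <- binary_close2d(m, config$closing_radius)
    bone[, , k] <- m
  }

  empty_result <- function(flags) {
    segmentation_result(array(FALSE, d), array(FALSE, d), array(FALSE, d),
                        matrix(NA_real_, d[3], 2), flags, volume$spacing)
  }
  if (!any(bone)) return(empty_result("no_bone"))

  cc <- label_components3d(bone)
  big <- which(cc$sizes >= config$min_component_voxels)
  if (length(big) > 1L)
    stop(sprintf(
      "more than one vertebral body candidate above threshold (component sizes: %s)",
      paste(sort(cc$sizes[big], decreasing = TRUE), collapse = ", ")))
  keep <- if (length(big) == 1L) big else which.max(cc$sizes)
  bone <- cc$labels == keep

  body <- array(FALSE, d)
  centroid <- matrix(NA_real_, d[3], 2)
  sp <- volume$spacing
  for (k in slices) {
    if (!any(bone[, , k])) next
    body[, , k] <- fill_holes2d(bone[, , k])
    idx <- which(body[, , k], arr.ind = TRUE)
    centroid[k, ] <- c(mean(idx[, 1]) - 0.5, mean(idx[, 2]) - 0.5) * sp[1:2]
  }
  trabecular <- body & !bone

  flags <- character(0)
  if (!any(trabecular)) flags <- c(flags, "no_trabecular_core")
  segmentation_result(bone, trabecular, body, centroid, flags, sp)
}
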