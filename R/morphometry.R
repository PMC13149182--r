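# The four L1 cortical-bone quantitative parameters. Thickness follows the
# 12-point protocol: per slice, rays are cast outward from the body centroid
# at uniform angles; each ray's thickness is the physical length of the
# outermost contiguous cortical run it crosses, with sub-voxel boundary
# interpolation; the slice value is the mean over rays, and the vertebra
# value the unweighted mean over measurable slices. Area, volume and density
# are voxel-count based.

#' Morphometry configuration
#'
#' @param n_rays number of thickness rays per slice, uniformly spaced over
#'   360 degrees (default 12, the measurement protocol's point count).
#' @param ray_start_angle first ray direction in degrees (default 0 =
#'   anterior, the first in-plane axis).
#' @param min_hits_per_slice slices where fewer rays hit cortex are flagged
#'   unmeasurable and excluded from vertebra averages (default 6).
#' @param slice_trim number of slices dropped at each cranio-caudal end
#'   before averaging, e.g. to exclude endplates (default 0 = include all).
#' @param density_denominator `"cortical"` (default) divides summed cortical
#'   HU by cortical volume; `"body"` divides by whole vertebral-body volume.
#'   The protocol's wording admits either reading; the choice only rescales
#'   average_density.
#' @param step_frac ray sampling step as a fraction of the smaller in-plane
#'   spacing (default 0.1).
#' @return An object of class `morphometry_config`.
#' @export
morphometry_config <- function(n_rays = 12L,
                               ray_start_angle = 0,
                               min_hits_per_slice = 6L,
                               slice_trim = 0L,
                               density_denominator = c("cortical", "body"),
                               step_frac = 0.1) {
  stopifnot(n_rays >= 3L, is.finite(ray_start_angle),
            min_hits_per_slice >= 1L, slice_trim >= 0L,
            step_frac > 0, step_frac <= 0.5)
  structure(list(n_rays = as.integer(n_rays),
                 ray_start_angle = as.numeric(ray_start_angle),
                 min_hits_per_slice = as.integer(min_hits_per_slice),
                 slice_trim = as.integer(slice_trim),
                 density_denominator = match.arg(density_denominator),
                 step_frac = step_frac),
            class = "morphometry_config")
}

#' Ray-cast cortical thickness of one slice
#'
#' Casts `n_rays` rays outward from the centroid at uniform angles. Along
#' each ray the cortical mask is sampled bilinearly at a fine step; the
#' thickness is the length of the outermost contiguous run of mask values
#' >= 0.5, with the run's entry and exit positions refined by linear
#' interpolation of the 0.5 crossing. Rays that meet no cortex are missing.
#'
#' @param cortical_slice logical (or 0/1) matrix, one axial slice of the
#'   cortical mask.
#' @param centroid_mm length-2 physical coordinates of the ray origin, mm.
#' @param spacing in-plane mm pair (row, column).
#' @param config a [morphometry_config()].
#' @return list with `ray_thicknesses` (mm, NA where missing),
#'   `mean_thickness` (mean over non-missing rays; NA if none),
#'   `n_hits`, and `measurable` (n_hits >= min_hits_per_slice).
#' @export
measure_slice_thickness <- function(cortical_slice, centroid_mm, spacing,
                                    config = morphometry_config()) {
  stopifnot(length(centroid_mm) == 2L, all(is.finite(centroid_mm)),
            length(spacing) == 2L, all(spacing > 0))
  m <- cortical_slice * 1.0
  step <- config$step_frac * min(spacing)
  # longest ray needed: grid diagonal
  t_max <- sqrt((nrow(m) * spacing[1])^2 + (ncol(m) * spacing[2])^2)
  tt <- seq(0, t_max, by = step)
  angles <- (config$ray_start_angle * pi / 180) +
    2 * pi * (seq_len(config$n_rays) - 1L) / config$n_rays

  thick <- rep(NA_real_, config$n_rays)
  for (r in seq_len(config$n_rays)) {
    xs <- centroid_mm[1] + tt * cos(angles[r])
    ys <- centroid_mm[2] + tt * sin(angles[r])
    v <- bilinear_sample(m, xs, ys, spacing[1], spacing[2])
    inside <- v >= 0.5
    if (!any(inside)) next
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    last_true <- max(which(runs$values))
    i0 <- starts[last_true]; i1 <- ends[last_true]
    # refine entry crossing between samples i0-1 and i0
    entry <- tt[i0]
    if (i0 > 1L) {
      f <- (0.5 - v[i0 - 1L]) / (v[i0] - v[i0 - 1L])
      entry <- tt[i0 - 1L] + f * step
    }
    exit <- tt[i1]
    if (i1 < length(tt)) {
      f <- (v[i1] - 0.5) / (v[i1] - v[i1 + 1L])
      exit <- tt[i1] + f * step
    }
    thick[r] <- exit - entry
  }
  n_hits <- sum(!is.na(thick))
  list(ray_thicknesses = thick,
       mean_thickness = if (n_hits > 0L) mean(thick, na.rm = TRUE) else NA_real_,
       n_hits = n_hits,
       measurable = n_hits >= config$min_hits_per_slice)
}

#' Measure the four cortical parameters of one vertebra
#'
#' Average thickness is the unweighted mean over measurable (and untrimmed)
#' slices of the per-slice 12-ray mean; average area the unweighted mean of
#' per-slice cortical areas (voxel count x in-plane pixel area); total
#' volume the cortical voxel count x voxel volume; average density the sum
#' of HU over cortical voxels divided by the denominator volume (cortical by
#' default, see [morphometry_config()]).
#'
#' @param seg a [segmentation_result()].
#' @param volume the [voxel_volume()] the segmentation came from.
#' @param config a [morphometry_config()].
#' @return An object of class `vertebra_morphometry`: `average_density`
#'   (HU/mm^3), `average_thickness` (mm), `average_area` (mm^2),
#'   `total_volume` (mm^3), per-slice detail in `$slices`, and `qc_flags`.
#'   With zero cortical voxels all parameters are NA and the flag
#'   `no_cortex` is set.
#' @export
measure_vertebra <- function(seg, volume, config = morphometry_config()) {
  stopifnot(inherits(seg, "segmentation_result"),
            inherits(volume, "voxel_volume"),
            identical(dim(seg$cortical_mask), dim(volume$hu)))
  sp <- volume$spacing
  pix_area <- sp[1] * sp[2]
  vox_vol <- prod(sp)
  d <- dim(volume$hu)

  n_cort <- sum(seg$cortical_mask)
  if (n_cort == 0L) {
    return(structure(list(average_density = NA_real_,
                          average_thickness = NA_real_,
                          average_area = NA_real_, total_volume = NA_real_,
                          slices = NULL, qc_flags = c(seg$qc_flags, "no_cortex")),
                     class = "vertebra_morphometry"))
  }

  body_slices <- which(apply(seg$body_mask, 3, any))
  if (config$slice_trim > 0L && length(body_slices) > 2L * config$slice_trim) {
    body_slices <- body_slices[(config$slice_trim + 1L):
                               (length(body_slices) - config$slice_trim)]
  }

  slices <- lapply(body_slices, function(k) {
    st <- measure_slice_thickness(seg$cortical_mask[, , k],
                                  seg$per_slice_centroid[k, ], sp[1:2], config)
    data.frame(slice_index = k,
               mean_thickness = st$mean_thickness,
               n_hits = st$n_hits,
               measurable = st$measurable,
               cortical_area = sum(seg$cortical_mask[, , k]) * pix_area)
  })
  slices <- do.call(rbind, slices)

  qc <- seg$qc_flags
  meas <- slices[slices$measurable, ]
  if (nrow(meas) < nrow(slices)) qc <- c(qc, "unmeasurable_slices_excluded")

  total_volume <- n_cort * vox_vol
  denom <- switch(config$density_denominator,
                  cortical = total_volume,
                  body = sum(seg$body_mask) * vox_vol)
  structure(list(
    average_density = sum(volume$hu[seg$cortical_mask]) / denom,
    average_thickness = if (nrow(meas)) mean(meas$mean_thickness) else NA_real_,
    average_area = if (nrow(meas)) mean(meas$cortical_area) else NA_real_,
    total_volume = total_volume,
    slices = slices,
    qc_flags = qc
  ), class = "vertebra_morphometry")
}

#' @export
print.vertebra_morphometry <- function(x, ...) {
  cat(sprintf(paste0("<vertebra_morphometry> density %.1f HU/mm^3, ",
                     "thickness %.2f mm, area %.1f mm^2, volume %.2f x10^3 mm^3\n"),
              x$average_density, x$average_thickness, x$average_area,
              x$total_volume / 1e3))
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Batch morphometry over a list of volumes
#'
#' Segments and measures each volume independently; per-subject failures are
#' recorded and do not abort the batch. Order-preserving.
#'
#' @param volumes list of [voxel_volume()] objects.
#' @param seg_config a [segmentation_config()].
#' @param morph_config a [morphometry_config()].
#' @param ids optional subject identifiers (default `V1`, `V2`, ...).
#' @return data frame with one row per volume: `subject_id`, the four
#'   parameters (volume in mm^3), `ok` and `qc_flags` (collapsed, `;`).
#' @export
cohort_measure <- function(volumes, seg_config = segmentation_config(),
                           morph_config = morphometry_config(),
                           ids = NULL) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  ids <- ids %||% sprintf("V%d", seq_along(volumes))
  rows <- lapply(seq_along(volumes), function(i) {
    res <- tryCatch({
      seg <- segment_vertebra(volumes[[i]], seg_config)
      mm <- measure_vertebra(seg, volumes[[i]], morph_config)
      data.frame(subject_id = ids[i],
                 average_density = mm$average_density,
                 average_thickness = mm$average_thickness,
                 average_area = mm$average_area,
                 total_volume = mm$total_volume,
                 ok = !("no_cortex" %in% mm$qc_flags),
                 qc_flags = paste(mm$qc_flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(subject_id = ids[i], average_density = NA_real_,
                 average_thickness = NA_real_, average_area = NA_real_,
                 total_volume = NA_real_, ok = FALSE,
                 qc_flags = paste0("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-subject morphometry to CSV (and JSON)
#'
#' Column layout: subject_id, average_density, average_thickness_mm,
#' average_area_mm2, total_volume_mm3, qc_flags. Volumes are written raw in
#' mm^3; reports render them in the 10^3 mm^3 display convention.
#'
#' @param df output of [cohort_measure()].
#' @param path CSV path; a JSON twin is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(df, path) {
  out <- data.frame(subject_id = df$subject_id,
                    average_density = df$average_density,
                    average_thickness_mm = df$average_thickness,
                    average_area_mm2 = df$average_area,
                    total_volume_mm3 = df$total_volume,
                    qc_flags = df$qc_flags)
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(out, paste0(path, ".json"), digits = NA, na = "null")
  invisible(path)
}
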