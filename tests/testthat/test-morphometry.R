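test_that("circular annulus: every ray measures the shell thickness", {
  # circular cross-section, outer r = 20 mm, shell 2 mm
  ph <- generate_phantom(phantom_spec(outer_semi_axes = c(20, 20),
                                      cortical_thickness = 2, seed = 1))
  seg <- segment_vertebra(ph$volume)
  k <- ph$truth$body_slices[10]
  st <- measure_slice_thickness(seg$cortical_mask[, , k],
                                seg$per_slice_centroid[k, ],
                                ph$volume$spacing[1:2])
  expect_equal(st$n_hits, 12)
  # per-ray: boundary quantization is half a voxel at each of the two
  # interfaces, so the guarantee is one in-plane spacing per ray ...
  expect_true(all(abs(st$ray_thicknesses - 2) <= 0.7 + 1e-9))
  # ... and half a spacing for the slice mean (errors cancel across rays)
  expect_lt(abs(st$mean_thickness - 2), 0.35)
})

test_that("elliptical shell ray values match the continuous-geometry oracle", {
  ph <- default_phantom()   # 18 x 14 mm, 2 mm shell
  seg <- default_segmentation()
  k <- ph$truth$body_slices[10]
  cfg <- morphometry_config()
  st <- measure_slice_thickness(seg$cortical_mask[, , k],
                                seg$per_slice_centroid[k, ],
                                ph$volume$spacing[1:2], cfg)
  angles <- 2 * pi * (0:11) / 12
  oracle <- vapply(angles, function(a) oracle_ray_thickness(18, 14, 2, a), 0)
  expect_true(all(abs(st$ray_thicknesses - oracle) <= 0.7 + 1e-9))
  expect_lt(abs(st$mean_thickness - mean(oracle)), 0.35)
})

test_that("empty cortical slice: all rays missing, slice unmeasurable", {
  st <- measure_slice_thickness(matrix(FALSE, 20, 20), c(7, 7), c(0.7, 0.7))
  expect_true(all(is.na(st$ray_thicknesses)))
  expect_equal(st$n_hits, 0)
  expect_false(st$measurable)
})

test_that("noiseless default phantom: parameters recover ground truth", {
  ph <- default_phantom()
  seg <- default_segmentation()
  mm <- measure_vertebra(seg, ph$volume)
  expect_lt(abs(mm$average_thickness - 2), 0.35)
  expect_lt(abs(mm$total_volume - ph$truth$true_volume) / ph$truth$true_volume,
            0.05)
  expect_lt(abs(mm$average_area - mean(ph$truth$true_area_by_slice)) /
              mean(ph$truth$true_area_by_slice), 0.05)
})

test_that("density definition algebra on a uniform shell", {
  ph <- default_phantom()
  seg <- default_segmentation()
  mm <- measure_vertebra(seg, ph$volume)
  v <- prod(ph$volume$spacing)
  # uniform 1200 HU shell: sum(HU)/volume = 1200 / voxel volume
  expect_equal(mm$average_density, 1200 / v, tolerance = 1e-10)

  # doubling HU doubles density, leaves mask-derived parameters unchanged
  vol2 <- voxel_volume(ph$volume$hu * 2, ph$volume$spacing)
  mm2 <- measure_vertebra(seg, vol2)
  expect_equal(mm2$average_density, 2 * mm$average_density, tolerance = 1e-10)
  expect_identical(mm2$average_thickness, mm$average_thickness)
  expect_identical(mm2$average_area, mm$average_area)
  expect_identical(mm2$total_volume, mm$total_volume)

  # adding a constant shifts density by c / voxel volume exactly
  vol3 <- voxel_volume(ph$volume$hu + 100, ph$volume$spacing)
  mm3 <- measure_vertebra(seg, vol3)
  expect_equal(mm3$average_density - mm$average_density, 100 / v,
               tolerance = 1e-10)
  expect_identical(mm3$total_volume, mm$total_volume)

  # body-denominator option only rescales density
  mmb <- measure_vertebra(seg, ph$volume,
                          morphometry_config(density_denominator = "body"))
  expect_equal(mmb$average_density,
               mm$average_density * sum(seg$cortical_mask) / sum(seg$body_mask),
               tolerance = 1e-10)
  expect_identical(mmb$total_volume, mm$total_volume)
})

test_that("in-plane translation changes parameters by at most a quantization step", {
  base <- generate_phantom(phantom_spec(seed = 1))
  shifted <- generate_phantom(phantom_spec(margin_mm = 7.4, seed = 1))  # ~2 voxel shift
  mb <- measure_vertebra(segment_vertebra(base$volume), base$volume)
  ms <- measure_vertebra(segment_vertebra(shifted$volume), shifted$volume)
  expect_lt(abs(mb$average_thickness - ms$average_thickness), 0.35)
  expect_lt(abs(mb$average_area - ms$average_area) / mb$average_area, 0.05)
  expect_lt(abs(mb$total_volume - ms$total_volume) / mb$total_volume, 0.05)
})

test_that("zero cortical voxels give an NA result with a qc flag", {
  vol <- voxel_volume(array(40, c(10, 10, 3)), c(0.7, 0.7, 1.25))
  seg <- segment_vertebra(vol)
  mm <- measure_vertebra(seg, vol)
  expect_true(all(is.na(c(mm$average_density, mm$average_thickness,
                          mm$average_area, mm$total_volume))))
  expect_true("no_cortex" %in% mm$qc_flags)
})

test_that("cohort_measure isolates failures and preserves order", {
  ok_spec <- phantom_spec(outer_semi_axes = c(12, 10), body_height = 10,
                          margin_mm = 3, seed = 4)
  vol <- generate_phantom(ok_spec)$volume
  empty <- voxel_volume(array(40, c(10, 10, 3)), c(0.7, 0.7, 1.25))
  out <- cohort_measure(list(vol, empty, vol))
  expect_equal(nrow(out), 3)
  expect_equal(out$ok, c(TRUE, FALSE, TRUE))
  expect_equal(out$average_thickness[1], out$average_thickness[3])
  expect_equal(out$subject_id, c("V1", "V2", "V3"))
})

test_that("measured thickness is strictly monotone in true thickness", {
  th <- c(1, 2, 3)
  vols <- lapply(th, function(t)
    generate_phantom(phantom_spec(cortical_thickness = t, seed = 30))$volume)
  out <- cohort_measure(vols)
  expect_true(all(diff(out$average_thickness) > 0))
})

test_that("slice trimming drops endplate slices from the averages", {
  ph <- generate_phantom(phantom_spec(taper = 0.5, seed = 2))
  seg <- segment_vertebra(ph$volume)
  full <- measure_vertebra(seg, ph$volume)
  trimmed <- measure_vertebra(seg, ph$volume, morphometry_config(slice_trim = 4))
  # tapered shell is thinnest at the endplates, so trimming raises the mean
  expect_gt(trimmed$average_thickness, full$average_thickness)
  expect_identical(trimmed$total_volume, full$total_volume)
})
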