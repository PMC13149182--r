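test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(cortical_thickness = 0))
  expect_error(phantom_spec(cortical_thickness = 15, outer_semi_axes = c(18, 14)))
  expect_error(phantom_spec(cortical_hu = 100, trabecular_hu = 150))
  expect_error(phantom_spec(voxel_spacing = c(0.7, -0.7, 1.25)))
})

test_that("noiseless phantom geometry matches analytic truth", {
  ph <- default_phantom()   # thickness 2 mm, semi-axes 18 x 14
  expect_true(all(ph$truth$true_thickness_by_slice == 2))
  # analytic annulus area per slice
  expect_equal(ph$truth$true_area_by_slice,
               rep(pi * (18 * 14 - 16 * 12), 20), tolerance = 1e-12)
  # voxelized shell volume within 5% of analytic at default spacing
  vox_vol <- sum(ph$truth$cortical_mask) * prod(ph$volume$spacing)
  expect_lt(abs(vox_vol - ph$truth$true_volume) / ph$truth$true_volume, 0.05)
  # masks disjoint
  expect_false(any(ph$truth$cortical_mask & ph$truth$trabecular_mask))
  # HU values as stated in the scene
  expect_equal(sort(unique(as.vector(ph$volume$hu))), c(40, 150, 1200))
})

test_that("example geometry: semi-axes (20, 15), thickness 2 gives pi*66 area", {
  ph <- generate_phantom(phantom_spec(outer_semi_axes = c(20, 15),
                                      cortical_thickness = 2, seed = 1))
  expect_equal(ph$truth$true_area_by_slice[1], pi * (20 * 15 - 18 * 13),
               tolerance = 1e-12)
  # voxel-counting verification of the analytic value
  pix_area <- prod(ph$volume$spacing[1:2])
  counted <- sum(ph$truth$cortical_mask[, , ph$truth$body_slices[1]]) * pix_area
  expect_lt(abs(counted - pi * 66) / (pi * 66), 0.05)
})

test_that("voxelized volume converges to analytic as spacing shrinks", {
  err <- sapply(c(0.7, 0.35), function(h) {
    ph <- generate_phantom(phantom_spec(voxel_spacing = c(h, h, 1.25), seed = 1))
    vox <- sum(ph$truth$cortical_mask) * prod(ph$volume$spacing)
    abs(vox - ph$truth$true_volume) / ph$truth$true_volume
  })
  expect_lt(err[2], err[1])
})

test_that("phantom generation is deterministic and noise/blur behave", {
  s <- phantom_spec(noise_sd = 10, psf_fwhm = 1, seed = 99)
  a <- generate_phantom(s); b <- generate_phantom(s)
  expect_identical(a$volume$hu, b$volume$hu)
  # noise changes voxels but not ground truth
  clean <- generate_phantom(phantom_spec(seed = 99))
  expect_false(identical(a$volume$hu, clean$volume$hu))
  expect_identical(a$truth$cortical_mask, clean$truth$cortical_mask)
  # different seed, different noise
  c2 <- generate_phantom(phantom_spec(noise_sd = 10, psf_fwhm = 1, seed = 100))
  expect_false(identical(a$volume$hu, c2$volume$hu))
})

test_that("sub-resolution shell raises a metadata warning", {
  ph <- generate_phantom(phantom_spec(cortical_thickness = 0.5, seed = 1))
  expect_true("shell_below_inplane_resolution" %in% ph$meta$warnings)
  expect_length(default_phantom()$meta$warnings, 0)
})

test_that("tapered thickness profile thins toward the endplates", {
  ph <- generate_phantom(phantom_spec(taper = 0.4, seed = 1))
  tt <- ph$truth$true_thickness_by_slice
  mid <- ceiling(length(tt) / 2)
  expect_lt(tt[1], tt[mid])
  expect_lt(tt[length(tt)], tt[mid])
  expect_equal(max(tt), 2, tolerance = 0.05)
})

test_that("cohort generator reproduces the stated group structure", {
  coh <- generate_cohort(cohort_spec(seed = 42))
  expect_equal(nrow(coh), 169)
  expect_equal(as.vector(table(coh$bmd_group)[c("normal", "osteopenia",
                                                "osteoporosis")]),
               c(59, 58, 52))
  # vBMD consistent with group label under the boundary semantics
  expect_true(all(classify_bmd(coh$vbmd) == coh$bmd_group))
  # determinism
  expect_identical(coh, generate_cohort(cohort_spec(seed = 42)))
  expect_false(identical(coh, generate_cohort(cohort_spec(seed = 43))))
})

test_that("degenerate draw: SD zero returns the group means exactly", {
  g <- data.frame(parameter = rep(c("average_thickness", "average_area"), each = 1),
                  group = "only", n = 1, mean = c(1.5, 300), sd = 0)
  # n = 1 allowed for generation (variance-based tests later require n >= 2)
  coh <- generate_cohort(cohort_spec(groups = g, seed = 1))
  expect_equal(coh$average_thickness, 1.5)
  expect_equal(coh$average_area, 300)
})

test_that("large draws recover the stated mean (Monte Carlo oracle)", {
  g <- data.frame(parameter = "average_thickness", group = "osteoporosis",
                  n = 10000, mean = 1.19, sd = 0.63)
  coh <- generate_cohort(cohort_spec(groups = g, seed = 7))
  se <- 0.63 / sqrt(10000)
  # truncation at the positive floor biases upward by ~0.008; stays inside 3 SE
  expect_lt(abs(mean(coh$average_thickness) - 1.19), 3 * se + 0.01)
  expect_true(any(coh$truncated))   # negative mass exists at this mean/SD
})

test_that("screening registry carries the stated exclusion structure", {
  reg <- generate_screening_registry(seed = 3)
  expect_equal(nrow(reg), 326)
  expect_equal(sum(reg$excluded), 157)
  # flags mutually exclusive by construction: one category column, and
  # excluded <-> category present
  expect_identical(reg$excluded, !is.na(reg$exclusion_category))
  cats <- table(reg$exclusion_category)
  ref <- reference_tables()$screening
  expect_equal(as.vector(cats[ref$category]), ref$n_excluded)
  expect_identical(reg, generate_screening_registry(seed = 3))
})
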