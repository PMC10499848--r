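test_that("phantom truth is self-consistent and the mask is one component", {
  ph <- phantom_fine()
  # measurements recomputed from the truth landmarks equal the stored set
  re <- measure_landmarks(ph$truth$landmarks)
  expect_identical(unclass(re), unclass(ph$truth$measurements))
  lab <- scapseg:::cpp_label_components(ph$mask$data == 1, dim(ph$mask$data), 6L)
  expect_equal(max(lab), 1)
  # targeted angles are realized by construction
  expect_equal(ph$truth$measurements$critical_shoulder_angle, 32,
               tolerance = 1e-9)
  expect_equal(ph$truth$measurements$retroversion, 2, tolerance = 0.1)
  expect_equal(ph$truth$measurements$inclination_angle, 5, tolerance = 1e-9)
})

test_that("zero version and inclination give a face perpendicular to the blade axis", {
  ph <- generate_phantom(phantom_spec(version = 0, inclination = 0,
                                      shape = c(120, 120, 120),
                                      spacing = c(1, 1, 1)))
  tr <- ph$truth
  expect_equal(tr$measurements$retroversion, 0, tolerance = 1e-9)
  expect_equal(tr$measurements$inclination_angle, 0, tolerance = 1e-9)
  ap <- tr$landmarks$glenoid_posterior - tr$landmarks$glenoid_anterior
  md <- tr$landmarks$medial_scapula_edge - tr$landmarks$glenoid_center
  expect_equal(sum(ap * md), 0, tolerance = 1e-9)
})

test_that("left-sided phantoms mirror the right with identical truth magnitudes", {
  r <- generate_phantom(phantom_spec(shape = c(120, 120, 120),
                                     spacing = c(1, 1, 1)))
  l <- generate_phantom(phantom_spec(shape = c(120, 120, 120),
                                     spacing = c(1, 1, 1), side = "left"))
  for (nm in names(r$truth$measurements))
    expect_equal(l$truth$measurements[[nm]], r$truth$measurements[[nm]],
                 tolerance = 1e-9)
  # the voxelized masks are mirror images along the slice axis
  expect_equal(sum(l$mask$data), sum(r$mask$data), tolerance = 0.02)
})

test_that("intensity rendering is seeded, plausible and invertible when clean", {
  ph <- fixture("phantom_1mm", function() {
    generate_phantom(phantom_spec(shape = c(120, 120, 120),
                                  spacing = c(1, 1, 1)))
  })
  v1 <- render_intensity(ph$mask, noise_sd = 0.02, bias_amplitude = 0.2,
                         seed = 9)
  v2 <- render_intensity(ph$mask, noise_sd = 0.02, bias_amplitude = 0.2,
                         seed = 9)
  expect_identical(v1$data, v2$data)
  expect_true(all(v1$data >= 0))

  clean <- render_intensity(ph$mask, noise_sd = 0, bias_amplitude = 0)
  rec <- (clean$data > 100 & clean$data < 600) * 1
  expect_identical(rec, ph$mask$data)

  # bias inflates the maximum; validation normalization still bounds it
  biased <- render_intensity(ph$mask, noise_sd = 0, bias_amplitude = 0.5,
                             seed = 4)
  expect_gt(max(biased$data), max(clean$data) * 1.03)
  vn <- normalize_volume(biased, normalization_spec("validation"))
  expect_lt(max(vn$data), 2)

  # rendering + validation normalization + band threshold recovers the bone
  noisy <- render_intensity(ph$mask, noise_sd = 0.02, bias_amplitude = 0,
                            seed = 5)
  nn <- normalize_volume(noisy, normalization_spec("validation"))
  mx <- max(nn$data)
  rec2 <- as_mask((nn$data > 0.15 * mx & nn$data < 0.55 * mx) * 1)
  expect_gte(dice_coefficient(rec2, as_mask(ph$mask$data)), 0.95)
})

test_that("cohorts are reproducible, distinct, and written to disk on request", {
  tmp <- withr::local_tempdir()
  co <- generate_cohort(3, shape = c(96, 96, 96), spacing = c(1.25, 1.25, 1.25),
                        seed = 21, dir = tmp)
  co2 <- generate_cohort(3, shape = c(96, 96, 96),
                         spacing = c(1.25, 1.25, 1.25), seed = 21)
  for (i in 1:3) {
    expect_identical(co[[i]]$mask$data, co2[[i]]$mask$data)
    expect_identical(co[[i]]$volume$data, co2[[i]]$volume$data)
  }
  hs <- vapply(co, function(s) s$truth$measurements$glenoid_height, numeric(1))
  expect_gt(length(unique(hs)), 1)
  expect_true(file.exists(file.path(tmp, "phantom_002_mask.nii.gz")))
  truth <- jsonlite::read_json(file.path(tmp, "truth.json"),
                               simplifyVector = TRUE)
  expect_length(truth, 3)
  expect_error(generate_cohort(0), "n must be")
})

test_that("phantoms that cannot fit the grid are rejected before rasterizing", {
  expect_error(generate_phantom(phantom_spec(shape = c(48, 48, 48),
                                             spacing = c(0.5, 0.5, 0.5))),
               "does not fit")
})
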