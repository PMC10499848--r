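test_that("zero probability and degenerate transforms leave pairs unchanged", {
  ph <- phantom_coarse()
  v <- render_intensity(ph$mask, noise_sd = 0, bias_amplitude = 0, seed = 1)
  out <- augment_pair(v, ph$mask, augment_spec(per_transform_prob = 0, seed = 1))
  expect_identical(out$volume$data, v$data)
  expect_identical(out$mask$data, ph$mask$data)

  degen <- augment_spec(per_transform_prob = 1, rotation_range = 0,
                        scale_range = c(1, 1), translation_range = 0,
                        elastic_amplitude = 0, blur_sigma_range = c(1e-6, 1e-6),
                        noise_sd_range = c(0, 0), seed = 2)
  out2 <- augment_pair(v, ph$mask, degen)
  expect_identical(out2$mask$data, ph$mask$data)
  expect_equal(out2$volume$data, v$data, tolerance = 1e-6)
})

test_that("masks stay strictly binary under augmentation", {
  ph <- phantom_coarse()
  v <- render_intensity(ph$mask, noise_sd = 0.02, seed = 3)
  for (seed in 1:4) {
    out <- augment_pair(v, ph$mask,
                        augment_spec(per_transform_prob = 1, seed = seed))
    expect_true(all(out$mask$data %in% c(0, 1)))
  }
})

test_that("right-angle rotation conserves foreground voxel count exactly", {
  d <- c(32, 32, 32)
  box <- array(0, d)
  box[9:20, 12:25, 7:19] <- 1
  src <- scapseg:::.affine_coords(d, rotation = c(0, 0, 90), scale = 1,
                                  translation = c(0, 0, 0))
  rot <- array(scapseg:::cpp_resample(box, d, src, TRUE, 0), d)
  expect_identical(sum(rot), sum(box))
})

test_that("general affine keeps foreground volume within 5% of the scaled volume", {
  d <- c(64, 64, 64)
  box <- array(0, d)
  box[21:44, 19:42, 23:46] <- 1
  m <- as_mask(box)
  v <- as_volume(box * 100)
  spec <- augment_spec(per_transform_prob = 1, elastic_amplitude = 0,
                       blur_sigma_range = c(0, 0), noise_sd_range = c(0, 0),
                       translation_range = 3, seed = 9)
  out <- augment_pair(v, m, spec)
  scale_used <- withr::with_seed(9, {
    runif(4); runif(3); runif(1, 0.9, 1.1)
  })
  expected <- sum(box) * scale_used^3
  expect_lt(abs(sum(out$mask$data) - expected) / expected, 0.05)
})

test_that("dataset augmentation has the right size, order and reproducibility", {
  ph <- phantom_coarse()
  v <- render_intensity(ph$mask, noise_sd = 0, seed = 1)
  pairs <- replicate(3, list(volume = v, mask = ph$mask), simplify = FALSE)
  spec <- augment_spec(copies_per_original = 2, seed = 5)
  out <- augment_dataset(pairs, spec)
  expect_length(out, 3 * (1 + 2))
  expect_identical(out[[1]]$volume$data, v$data)  # originals retained first
  out2 <- augment_dataset(pairs, spec)
  for (i in seq_along(out))
    expect_identical(out[[i]]$volume$data, out2[[i]]$volume$data)
  expect_length(augment_dataset(pairs, augment_spec(copies_per_original = 0,
                                                    seed = 1)), 3)
  expect_error(augment_dataset(list(), spec), "non-empty")
})
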