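test_that("crop removes leading rows/columns and nothing else", {
  v <- as_volume(array(seq_len(300 * 300 * 10), c(300, 300, 10)))
  cv <- crop_volume(v, crop_spec(112, 112))
  expect_equal(dim(cv$data), c(188, 188, 10))
  expect_equal(cv$data[1, 1, 1], v$data[113, 113, 1])
  expect_identical(crop_volume(v, crop_spec(0, 0))$data, v$data)
  expect_error(crop_volume(as_volume(array(0, c(50, 50, 2))),
                           crop_spec(112, 112)), "smaller")
})

test_that("interleaved split/merge invert each other and track spacing", {
  withr::with_seed(1, {
    v <- as_volume(array(rnorm(6 * 5 * 5), c(6, 5, 5)), c(1, 1, 0.5))
    hs <- interleave_split(v)
    expect_equal(dim(hs$even$data)[3], 3)
    expect_equal(dim(hs$odd$data)[3], 2)
    expect_equal(hs$even$spacing[3], 1)
    merged <- interleave_merge(hs$even, hs$odd)
    expect_identical(merged$data, v$data)
    expect_equal(merged$spacing, v$spacing)
  })
  d2 <- as_volume(array(0, c(4, 4, 2)))
  expect_equal(dim(interleave_split(d2)$even$data)[3], 1)
  expect_error(interleave_split(as_volume(array(0, c(4, 4, 1)))),
               "at least 2 slices")
  a <- as_probmap(array(0, c(4, 4, 4)))
  b <- as_probmap(array(0, c(4, 4, 2)))
  expect_error(interleave_merge(a, b), "cannot be interleaved")
})

test_that("validation normalization divides by max then 85th percentile", {
  withr::with_seed(2, {
    a <- array(runif(8^3, 0, 2000), c(8, 8, 8))
    v <- as_volume(a)
    out <- normalize_volume(v, normalization_spec("validation"))
    p85 <- quantile(a / max(a), 0.85, names = FALSE)
    expect_equal(max(out$data), 1 / p85, tolerance = 1e-12)
    # scale invariance: normalize(c * v) == normalize(v)
    out2 <- normalize_volume(as_volume(3.7 * a),
                             normalization_spec("validation"))
    expect_equal(out2$data, out$data, tolerance = 1e-12)
  })
})

test_that("training normalization draws one uniform divisor in the band", {
  a <- array(runif(6^3, 0, 1500), c(6, 6, 6))
  a[1] <- 2000  # pin the maximum
  v <- as_volume(a)
  for (mode in c("train3d", "train2d")) {
    half <- if (mode == "train3d") 1000 else 500
    out <- normalize_volume(v, normalization_spec(mode, seed = 11))
    div <- 2000 / max(out$data)
    expect_gte(div, 2000 - half)
    expect_lte(div, 2000 + half)
    out2 <- normalize_volume(v, normalization_spec(mode, seed = 11))
    expect_identical(out$data, out2$data)  # seeded reproducibility
  }
  expect_error(normalize_volume(as_volume(array(-1, c(2, 2, 2))),
                                normalization_spec("train3d")),
               "strictly positive")
})
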