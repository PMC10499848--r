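r2d <- 180 / pi

test_that("measurement formulas are exact on hand-built landmark sets", {
  # glenoid face in the y (superior) / x (anterior) plane, lateral = +z
  lm <- make_landmarks(
    sup = c(0, 19, 0), inf = c(0, -19, 0),
    ant = c(14, 0, 0), post = c(-14, 0, 0),
    center = c(0, 0, 0), medial = c(0, 0, -60),
    flat = c(0.5, 15, -10), f0 = c(0.5, 15, -25),
    fdir = c(0, 0, 1), acromion = c(0, 11, 21))
  expect_equal(glenoid_height(lm), 38)
  expect_equal(glenoid_width(lm), 28)
  expect_equal(retroversion(lm), 0)     # face plane contains the medial line
  expect_equal(inclination_angle(lm), 0)
  expect_equal(critical_shoulder_angle(lm),
               atan2(21, 30) * r2d, tolerance = 1e-10)
  expect_equal(rsa_angle(lm), asin(10 / sqrt(10^2 + 34^2 + 0.25)) * r2d,
               tolerance = 1e-10)

  # posterior rim pulled medially by 5 degrees: retroversion +5
  a5 <- 5 / r2d
  lm2 <- lm
  lm2$glenoid_anterior <- c(14 * cos(a5), 0, 14 * sin(a5))
  lm2$glenoid_posterior <- -lm2$glenoid_anterior
  expect_equal(retroversion(lm2), 5, tolerance = 1e-10)

  # superior rim tilted 10 degrees toward lateral: inclination +10
  a10 <- 10 / r2d
  lm3 <- lm
  lm3$glenoid_superior <- c(0, 19 * cos(a10), 19 * sin(a10))
  lm3$glenoid_inferior <- -lm3$glenoid_superior
  expect_equal(inclination_angle(lm3), 10, tolerance = 1e-10)

  # acromion on the glenoid line: CSA 0
  lm4 <- lm
  lm4$lateral_acromion <- c(0, 10, 0)
  expect_equal(critical_shoulder_angle(lm4), 0)
  # fossa endpoint straight above the inferior rim: RSA 0
  lm5 <- lm
  lm5$lateral_supraspinatus_fossa <- c(0, 15, 0)
  expect_equal(rsa_angle(lm5), 0)
})

test_that("landmarks and measurements are recovered on the default phantom", {
  ph <- phantom_fine()
  lm <- extract_landmarks(ph$mask)
  tr <- ph$truth
  for (nm in setdiff(names(tr$landmarks), "fossa_floor_direction")) {
    expect_lt(sqrt(sum((lm[[nm]] - tr$landmarks[[nm]])^2)), 4,
              label = sprintf("landmark %s distance", nm))
  }
  mm <- measure_landmarks(lm)
  expect_lt(abs(mm$glenoid_height - tr$measurements$glenoid_height), 2)
  expect_lt(abs(mm$glenoid_width - tr$measurements$glenoid_width), 2)
  expect_lt(abs(mm$retroversion - tr$measurements$retroversion), 2)
  expect_lt(abs(mm$inclination_angle - tr$measurements$inclination_angle), 2)
  expect_lt(abs(mm$critical_shoulder_angle -
                  tr$measurements$critical_shoulder_angle), 2)
  expect_lt(abs(mm$rsa_angle - tr$measurements$rsa_angle), 2.5)
})

test_that("measurements are equivariant under mirroring (left shoulders)", {
  right <- phantom_fine()
  left <- generate_phantom(phantom_spec(side = "left"))
  mr <- measure_mask(right$mask)
  ml <- measure_mask(left$mask)
  for (nm in names(mr)) expect_equal(ml[[nm]], mr[[nm]], tolerance = 1e-6)
})

test_that("degenerate masks fail with a landmark-extraction error", {
  d <- c(48, 48, 48)
  sph <- array(0, d)
  ii <- arrayInd(seq_len(prod(d)), d) - 24
  sph[rowSums(ii^2) < 15^2] <- 1
  expect_error(extract_landmarks(as_mask(sph)), "landmark extraction failed")
  expect_error(extract_landmarks(as_mask(array(0, c(8, 8, 8)))),
               "landmark extraction failed")
})

test_that("surface distances match a brute-force oracle and scale with spacing", {
  a <- random_mask(c(9, 9, 9), 0.25, seed = 2)
  b <- random_mask(c(9, 9, 9), 0.25, seed = 3)
  sdm <- surface_distance_map(a, b)
  # brute force: nearest surface voxel of b for each surface voxel of a
  d <- dim(a$data)
  sa <- array(scapseg:::cpp_surface_voxels(a$data == 1, d), d)
  sb <- array(scapseg:::cpp_surface_voxels(b$data == 1, d), d)
  pa <- arrayInd(which(sa), d)
  pb <- arrayInd(which(sb), d)
  brute <- apply(pa, 1, function(p) {
    sqrt(min(colSums((t(pb) - p)^2)))
  })
  expect_equal(sort(sdm$distances), sort(brute), tolerance = 1e-10)

  # identical masks: all zero
  expect_equal(surface_distance_map(a, a)$max, 0)

  # two spheres offset by 3 voxels at 1 mm isotropic spacing
  d2 <- c(24, 24, 24)
  mk_sphere <- function(c0) {
    arr <- array(0, d2)
    ii <- arrayInd(seq_len(prod(d2)), d2)
    arr[rowSums(sweep(ii, 2, c0)^2) < 6^2] <- 1
    as_mask(arr)
  }
  s1 <- mk_sphere(c(10, 12, 12))
  s2 <- mk_sphere(c(13, 12, 12))
  sd12 <- surface_distance_map(s1, s2)
  expect_lte(sd12$mean, 3)
  expect_equal(sd12$max, 3, tolerance = 0.35)

  # distances scale linearly with spacing
  s1w <- as_mask(s1$data, c(2, 2, 2))
  s2w <- as_mask(s2$data, c(2, 2, 2))
  expect_equal(surface_distance_map(s1w, s2w)$mean, 2 * sd12$mean,
               tolerance = 1e-10)
})

test_that("trial-mean comparison reproduces the published example table", {
  tab <- glenoid_trials_example()
  expected <- list(
    "056" = c(glenoid_width = 1.29, glenoid_height = 3.46,
              inclination_angle = 1.77, retroversion = 3.27,
              critical_shoulder_angle = 2.72),
    "057" = c(glenoid_width = 1.83, glenoid_height = 1.44,
              inclination_angle = 3.31, retroversion = 3.38,
              critical_shoulder_angle = 0.05, rsa_angle = 1.90))
  for (pat in names(expected)) {
    sub <- tab[tab$patient == pat, ]
    tr_a <- split(sub$value[sub$modality == "mri"],
                  sub$measurement[sub$modality == "mri"])
    tr_b <- split(sub$value[sub$modality == "ct"],
                  sub$measurement[sub$modality == "ct"])
    cmp <- compare_measurements(tr_a, tr_b)
    for (ms in names(expected[[pat]])) {
      got <- cmp$mean_difference_2dp[cmp$measurement == ms]
      expect_equal(got, unname(expected[[pat]][ms]), tolerance = 1e-9,
                   label = sprintf("%s %s", pat, ms))
    }
  }
  ident <- compare_measurements(list(a = c(1, 2)), list(a = c(2, 1)))
  expect_equal(ident$mean_difference, 0)
  expect_error(compare_measurements(list(), list()), "non-empty")
})

test_that("report rounding goes half away from zero", {
  expect_equal(round_half_away(1.285, 2), 1.29)
  expect_equal(round_half_away(3.455, 2), 3.46)
  expect_equal(round_half_away(-1.285, 2), -1.29)
  expect_equal(round_half_away(2.4449, 2), 2.44)
})
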