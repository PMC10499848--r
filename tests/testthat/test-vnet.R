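test_that("analytic gradients match finite differences", {
  for (dims in c(2, 3)) {
    cfg <- vnet_config(dims = dims, n_channels = 2, n_levels = 1,
                       convs_per_level = 1, bottom_convs = 1, kernel_size = 3,
                       dropout_keep_prob = 1, learning_rate = 1e-3)
    m <- build_model(cfg, seed = 42)
    dd <- if (dims == 3) c(4, 4, 4, 1) else c(4, 4, 1, 1)
    withr::with_seed(1, {
      x <- array(rnorm(prod(dd)), dd)
      y <- array(rbinom(prod(dd), 1, 0.4), dd)
    })
    lossfn <- function(model) {
      fw <- scapseg:::.vn_forward(model, x)
      neg_log_dice_loss(fw$p, y, smooth = 1e-3)
    }
    fw <- scapseg:::.vn_forward(m, x)
    g0 <- array(scapseg:::.dice_loss_grad(fw$p, y, 1e-3), dim(fw$p))
    gr <- scapseg:::.vn_backward(m, fw, g0)
    eps <- 1e-6
    withr::with_seed(2, {
      for (nm in names(gr)) {
        for (j in sample(length(m$params[[nm]]),
                         min(2, length(m$params[[nm]])))) {
          m2 <- m; m2$params[[nm]][j] <- m$params[[nm]][j] + eps
          m3 <- m; m3$params[[nm]][j] <- m$params[[nm]][j] - eps
          fd <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
          expect_equal(gr[[nm]][j], fd, tolerance = 1e-4)
        }
      }
    })
  }
})

test_that("forward passes produce same-shape probability maps", {
  cfg3 <- tiny3d_config()
  m3 <- build_model(cfg3, seed = 1)
  x <- array(rnorm(16^3), c(16, 16, 16, 1))
  fw <- scapseg:::.vn_forward(m3, x)
  expect_equal(dim(fw$p), c(16, 16, 16, 1))
  expect_true(all(fw$p >= 0 & fw$p <= 1))

  cfg2 <- vnet_config(dims = 2, n_channels = 2, n_levels = 2,
                      convs_per_level = c(1, 1), bottom_convs = 1,
                      kernel_size = 3, dropout_keep_prob = 1)
  m2 <- build_model(cfg2, seed = 1)
  x2 <- array(rnorm(24 * 24), c(24, 24, 1, 1))
  fw2 <- scapseg:::.vn_forward(m2, x2)
  expect_equal(dim(fw2$p), c(24, 24, 1, 1))
  # all-zero input still yields a valid probability field
  fz <- scapseg:::.vn_forward(m3, array(0, c(16, 16, 16, 1)))
  expect_true(all(is.finite(fz$p)) && all(fz$p >= 0 & fz$p <= 1))
})

test_that("inference is deterministic; training-mode dropout is not", {
  cfg <- tiny3d_config()
  cfg$dropout_keep_prob <- 0.7
  m <- build_model(cfg, seed = 3)
  v <- as_volume(array(rnorm(16^3), c(16, 16, 16)))
  p1 <- predict(m, v)
  p2 <- predict(m, v)
  expect_identical(p1$data, p2$data)
  withr::with_seed(5, {
    t1 <- scapseg:::.vn_forward(m, array(v$data, c(16, 16, 16, 1)),
                                training = TRUE)$p
    t2 <- scapseg:::.vn_forward(m, array(v$data, c(16, 16, 16, 1)),
                                training = TRUE)$p
    expect_false(identical(t1, t2))
  })
})

test_that("inputs not divisible by the downsampling factor are padded back", {
  m <- build_model(tiny3d_config(), seed = 1)
  v <- as_volume(array(rnorm(10 * 12 * 9), c(10, 12, 9)))
  p <- predict(m, v)
  expect_equal(dim(p$data), c(10, 12, 9))
})

test_that("2D networks run slice-wise along each view axis", {
  cfg2 <- vnet_config(dims = 2, n_channels = 2, n_levels = 1,
                      convs_per_level = 1, bottom_convs = 1, kernel_size = 3,
                      dropout_keep_prob = 1)
  m2 <- build_model(cfg2, seed = 2)
  v <- as_volume(array(rnorm(8 * 10 * 6), c(8, 10, 6)))
  for (view in c("axial", "sagittal", "coronal")) {
    p <- predict(m2, v, view = view)
    expect_equal(dim(p$data), c(8, 10, 6))
    expect_true(all(p$data >= 0 & p$data <= 1))
  }
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- vnet_config(dims = 2, n_channels = 2, n_levels = 1,
                     convs_per_level = 1, bottom_convs = 1, kernel_size = 3)
  expect_identical(n_parameters(build_model(cfg, seed = 1)), 333L)
  expect_identical(n_parameters(build_model(cfg, seed = 99)), 333L)
  # full-size published configurations build and count deterministically
  expect_identical(n_parameters(build_model(vnet_config(dims = 2), seed = 1)),
                   n_parameters(build_model(vnet_config(dims = 2), seed = 2)))
})

test_that("configuration invariants are enforced", {
  expect_error(vnet_config(dims = 3, n_levels = 2, convs_per_level = c(1, 2, 3)),
               "one entry per level")
  expect_error(vnet_config(kernel_size = 4), "odd")
  expect_error(vnet_config(dropout_keep_prob = 0), "0, 1")
  expect_error(vnet_config(learning_rate = 0), "learning_rate")
})

test_that("checkpoints round-trip parameters and configuration", {
  m <- build_model(tiny3d_config(), seed = 11)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  x <- as_volume(array(rnorm(8^3), c(8, 8, 8)))
  expect_identical(predict(m, x)$data, predict(m2, x)$data)
})
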