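test_that("dice coefficient matches its definition", {
  a <- array(c(1, 1, 1, 1, 0, 0), c(6, 1, 1))
  b <- array(c(0, 0, 1, 1, 1, 1), c(6, 1, 1))
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, 1 - a), 0)
  expect_equal(dice_coefficient(a, b), 0.5)  # 4-voxel masks sharing 2
  expect_equal(dice_coefficient(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)
  expect_error(dice_coefficient(array(0, c(2, 2, 2)), array(0, c(3, 2, 2))),
               "differ")
})

test_that("negative log dice loss has its closed-form values", {
  a <- array(c(1, 1, 1, 1, 0, 0), c(6, 1, 1))
  b <- array(c(0, 0, 1, 1, 1, 1), c(6, 1, 1))
  expect_equal(neg_log_dice_loss(a, a), 0)
  expect_equal(neg_log_dice_loss(a, b), log10(2))
  expect_error(neg_log_dice_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 2)),
                                 smooth = 0), "empty")
  # disjoint masks with small smoothing: large but finite
  f <- neg_log_dice_loss(a, 1 - a, smooth = 1e-5)
  expect_true(is.finite(f) && f > 4)
})

test_that("loss equals -log10(dice) across random probability/mask pairs", {
  withr::with_seed(10, {
    for (i in 1:100) {
      p <- array(runif(4^3), c(4, 4, 4))
      y <- array(rbinom(4^3, 1, 0.4), c(4, 4, 4))
      expect_equal(neg_log_dice_loss(p, y),
                   -log10(dice_coefficient(p, y)), tolerance = 1e-12)
    }
  })
})

test_that("consecutive k-fold split partitions subjects with sizes n/k (+1)", {
  s <- kfold_split(1:55, 5)
  sizes <- vapply(s$folds, function(f) length(f$val_ids), integer(1))
  expect_equal(sizes, rep(11L, 5))
  expect_equal(s$folds[[1]]$val_ids, 1:11)  # consecutive, unshuffled

  s2 <- kfold_split(1:7, 3)
  expect_equal(vapply(s2$folds, function(f) length(f$val_ids), integer(1)),
               c(3L, 2L, 2L))
  s3 <- kfold_split(letters[1:4], 2)
  expect_equal(s3$folds[[1]]$val_ids, c("a", "b"))
  expect_error(kfold_split(1:3, 5), "cannot exceed")

  withr::with_seed(3, {
    for (i in 1:10) {
      n <- sample(10:60, 1)
      k <- sample(2:8, 1)
      sp <- kfold_split(seq_len(n), k)
      val_all <- sort(unlist(lapply(sp$folds, `[[`, "val_ids")))
      expect_identical(val_all, seq_len(n))   # each subject validates once
      for (f in sp$folds)
        expect_identical(sort(c(f$val_ids, f$train_ids)), seq_len(n))
      expect_lte(diff(range(table(sp$assignments))), 1)
    }
  })
})

test_that("early stopping triggers after patience+1 stagnant validation epochs", {
  ph <- phantom_coarse()
  # learning rate ~0 keeps the validation DSC rigged constant
  cfg <- tiny3d_config()
  m <- build_model(cfg, seed = 1)
  pair <- list(volume = as_volume(ph$mask$data * 0.5, ph$mask$spacing),
               mask = ph$mask)
  rec <- train_model(m, list(pair), list(pair),
                     train_config(max_iterations = 1000, validate_every = 5,
                                  patience = 1, learning_rate = 1e-300,
                                  seed = 1))
  expect_equal(rec$iterations_run, 10L)  # initial epoch + 1 without improvement
  expect_equal(nrow(rec$history), 2L)
})

test_that("exactly one validation epoch occurs when budgets coincide", {
  ph <- phantom_coarse()
  m <- build_model(tiny3d_config(), seed = 2)
  pair <- list(volume = as_volume(ph$mask$data * 0.5, ph$mask$spacing),
               mask = ph$mask)
  rec <- train_model(m, list(pair), list(pair),
                     train_config(max_iterations = 6, validate_every = 6,
                                  learning_rate = 1e-4, seed = 1))
  expect_equal(nrow(rec$history), 1L)
  expect_equal(rec$iterations_run, 6L)
})

test_that("the DSC gate keeps strictly-above-threshold members only", {
  mk <- function(id, dsc) structure(list(model_id = id, val_dsc = dsc),
                                    class = "scap_trained_record")
  recs <- list(mk("a", 0.86), mk("b", 0.65), mk("c", 0.72))
  e <- build_ensemble(recs, 0.70)
  expect_length(e$members, 2)
  expect_identical(attr(e, "excluded"), "b")

  # 40 models of which exactly 4 fall at or below the gate
  withr::with_seed(8, {
    dscs <- c(runif(36, 0.701, 0.95), c(0.70, 0.60, 0.55, 0.30))
    recs40 <- lapply(seq_along(dscs), function(i) mk(paste0("m", i), dscs[i]))
    expect_length(build_ensemble(recs40, 0.70)$members, 36)
  })
  expect_error(build_ensemble(list(mk("x", 0.5), mk("y", 0.5)), 0.70),
               "empty ensemble")
})

test_that("ensemble averaging is symmetric and bounded by member extremes", {
  v <- as_volume(array(rnorm(8^3), c(8, 8, 8)))
  mk_rec <- function(seed) {
    m <- build_model(tiny3d_config(), seed = seed)
    structure(list(model_id = paste0("m", seed), model = m, val_dsc = 0.9,
                   view = "axial", interleaved = FALSE),
              class = "scap_trained_record")
  }
  recs <- lapply(1:3, mk_rec)
  e1 <- build_ensemble(recs, 0.5)
  e2 <- build_ensemble(recs[c(3, 1, 2)], 0.5)
  p1 <- ensemble_predict(e1, v)
  p2 <- ensemble_predict(e2, v)
  expect_equal(p1$data, p2$data, tolerance = 1e-12)  # permutation invariance

  singles <- lapply(recs, function(r) ensemble_predict(build_ensemble(list(r), 0.5), v)$data)
  lo <- pmin(singles[[1]], pmin(singles[[2]], singles[[3]]))
  hi <- pmax(singles[[1]], pmax(singles[[2]], singles[[3]]))
  expect_true(all(p1$data >= lo - 1e-12 & p1$data <= hi + 1e-12))
  expect_equal(singles[[1]],
               ensemble_predict(build_ensemble(recs[1], 0.5), v)$data)
})

test_that("interleaved 3D members are reconstructed on the full grid", {
  m <- build_model(tiny3d_config(), seed = 4)
  rec <- structure(list(model_id = "i", model = m, val_dsc = 0.9,
                        view = "axial", interleaved = TRUE),
                   class = "scap_trained_record")
  v <- as_volume(array(rnorm(8 * 8 * 12), c(8, 8, 12)))
  p <- ensemble_predict(build_ensemble(list(rec), 0.5), v)
  expect_equal(dim(p$data), c(8, 8, 12))
})
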