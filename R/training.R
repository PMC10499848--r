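# Loss and metric definitions, consecutive K-fold splitting, the training
# loop with early stopping, and DSC-gated ensembling.

#' Dice similarity coefficient
#'
#' `2 * sum(p * y) / (sum(p) + sum(y))` between a prediction (binary mask or
#' soft probability map) and a reference binary mask. Both-empty inputs
#' return 1 by convention.
#'
#' @param p prediction: `scap_mask`, `scap_probmap` or array.
#' @param y reference `scap_mask` or array.
#' @return scalar in \[0, 1\].
#' @export
dice_coefficient <- function(p, y) {
  pa <- .grid_data(p); ya <- .grid_data(y)
  .assert(all(dim(pa) == dim(ya)), "shapes differ: %s vs %s",
          paste(dim(pa), collapse = "x"), paste(dim(ya), collapse = "x"))
  den <- sum(pa) + sum(ya)
  if (den == 0) return(1)
  2 * sum(pa * ya) / den
}

#' Negative logarithmic Dice loss
#'
#' `F = -log10( (2 * sum(p*y) + smooth) / (sum(p) + sum(y) + smooth) )`.
#' Zero exactly at a perfect prediction; log10(2) at Dice 0.5. The additive
#' `smooth` keeps the logarithm finite when prediction and reference do not
#' overlap.
#'
#' @param p predicted probability map (`scap_probmap` or array).
#' @param y reference `scap_mask` or array, same shape.
#' @param smooth non-negative smoothing constant.
#' @return scalar loss, >= 0.
#' @export
neg_log_dice_loss <- function(p, y, smooth = 0) {
  pa <- .grid_data(p); ya <- .grid_data(y)
  .assert(all(dim(pa) == dim(ya)), "shapes differ: %s vs %s",
          paste(dim(pa), collapse = "x"), paste(dim(ya), collapse = "x"))
  .assert(smooth >= 0, "smooth must be >= 0")
  num <- 2 * sum(pa * ya) + smooth
  den <- sum(pa) + sum(ya) + smooth
  .assert(den > 0, "both inputs empty with smooth = 0: dice undefined")
  -log10(num / den) + 0  # avoid returning negative zero at dice = 1
}

# Gradient of neg_log_dice_loss with respect to p.
.dice_loss_grad <- function(pa, ya, smooth) {
  num <- 2 * sum(pa * ya) + smooth
  den <- sum(pa) + sum(ya) + smooth
  -(1 / log(10)) * (2 * ya / num - 1 / den)
}

#' Consecutive K-fold split
#'
#' Splits subjects, in their given order and without shuffling, into k
#' consecutive contiguous folds whose sizes differ by at most one (larger
#' folds first). Each fold serves once as the validation set while the
#' remaining k-1 folds form the training set.
#'
#' @param subject_ids ordered vector of subject identifiers.
#' @param k number of folds (>= 2, <= number of subjects).
#' @return a `scap_fold_split` with `assignments` (0-based fold index per
#'   subject) and per-fold `train_ids` / `val_ids`.
#' @export
kfold_split <- function(subject_ids, k = 5) {
  n <- length(subject_ids)
  .assert(k >= 2 && k == round(k), "k must be an integer >= 2")
  .assert(k <= n, "k (%d) cannot exceed the number of subjects (%d)", k, n)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  assignments <- rep(seq_len(k) - 1L, times = sizes)
  folds <- lapply(seq_len(k) - 1L, function(f) {
    list(val_ids = subject_ids[assignments == f],
         train_ids = subject_ids[assignments != f])
  })
  structure(list(k = as.integer(k), assignments = assignments, folds = folds),
            class = "scap_fold_split")
}

#' Training configuration
#'
#' @param max_iterations maximum optimizer steps (default 100000).
#' @param validate_every training steps between validation epochs (90).
#' @param patience validation epochs without improvement before early
#'   stopping (30). An improvement is an increase of the best mean
#'   validation DSC by more than 1e-4.
#' @param learning_rate optional override of the model config's rate.
#' @param smooth Dice-loss smoothing constant.
#' @param seed optional integer seed (dropout, data order reproducibility).
#' @param stop_dsc optional validation DSC at which training stops early as
#'   converged.
#' @return a `scap_train_config`.
#' @export
train_config <- function(max_iterations = 100000, validate_every = 90,
                         patience = 30, learning_rate = NULL, smooth = 1e-5,
                         seed = NULL, stop_dsc = NULL) {
  .assert(max_iterations >= 1 && validate_every >= 1 && patience >= 1,
          "all counts must be positive")
  structure(list(max_iterations = as.integer(max_iterations),
                 validate_every = as.integer(validate_every),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, smooth = smooth,
                 seed = seed, stop_dsc = stop_dsc),
            class = "scap_train_config")
}

# Adam with the standard internal parameters (beta1 0.9, beta2 0.999,
# eps 1e-8), state kept per parameter.
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.pair_arrays <- function(pair) {
  list(v = .grid_data(pair$volume), m = .grid_data(pair$mask))
}

# Mean validation DSC of binarized predictions at threshold 0.5.
.validation_dsc <- function(model, val_pairs) {
  mean(vapply(val_pairs, function(p) {
    pa <- .pair_arrays(p)
    pm <- .predict3d_or_2d(model, pa$v)
    dice_coefficient((pm >= 0.5) * 1, pa$m)
  }, numeric(1)))
}

.predict3d_or_2d <- function(model, arr) {
  if (model$config$dims == 3) .predict3d(model, arr)
  else .predict2d(model, arr, "axial")
}

#' Train a segmentation model
#'
#' Runs Adam on the negative log-Dice loss, one volume (or slice stack
#' element) per iteration, cycling through the training pairs in order.
#' Every `validate_every` steps a validation epoch computes the mean
#' validation DSC (predictions binarized at 0.5); the best-scoring
#' parameters are checkpointed. Training stops at `max_iterations`, after
#' `patience` validation epochs without improvement, or once `stop_dsc` is
#' reached.
#'
#' @param model a `scap_vnet` from [build_model()].
#' @param train_pairs,val_pairs non-empty lists of `list(volume=, mask=)`,
#'   preprocessed/normalized as required by the model.
#' @param cfg a [train_config()].
#' @param model_id label for the returned record.
#' @param verbose print a line per validation epoch.
#' @return a `scap_trained_record`: `model` (best checkpoint), `val_dsc`
#'   (best mean validation DSC), `history` (data.frame of iteration, loss,
#'   val_dsc), `iterations_run`.
#' @export
train_model <- function(model, train_pairs, val_pairs, cfg = train_config(),
                        model_id = "model", verbose = FALSE) {
  .assert(length(train_pairs) > 0 && length(val_pairs) > 0,
          "training and validation sets must be non-empty")
  lr <- cfg$learning_rate %||% model$config$learning_rate
  .with_seed(cfg$seed, {
    st <- .adam_init(model$params)
    best <- -Inf
    best_params <- model$params
    stale <- 0L
    hist_it <- integer(0); hist_loss <- numeric(0); hist_dsc <- numeric(0)
    it <- 0L
    done <- FALSE
    arrs <- lapply(train_pairs, .pair_arrays)
    while (!done && it < cfg$max_iterations) {
      it <- it + 1L
      pa <- arrs[[(it - 1L) %% length(arrs) + 1L]]
      x <- .as_input4d(pa$v)
      fw <- .vn_forward(model, x, training = TRUE)
      p <- fw$p
      y <- .as_input4d(pa$m)
      loss <- neg_log_dice_loss(p, y, cfg$smooth)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at iteration %d", it),
             call. = FALSE)
      gout <- array(.dice_loss_grad(p, y, cfg$smooth), dim(p))
      grads <- .vn_backward(model, fw, gout)
      upd <- .adam_step(model$params, grads, st, lr)
      model$params <- upd$params
      st <- upd$state
      if (it %% cfg$validate_every == 0L) {
        vd <- .validation_dsc(model, val_pairs)
        hist_it <- c(hist_it, it)
        hist_loss <- c(hist_loss, loss)
        hist_dsc <- c(hist_dsc, vd)
        if (verbose)
          message(sprintf("[%s] iter %d loss %.4f val DSC %.4f", model_id, it,
                          loss, vd))
        if (vd > best + 1e-4) {
          best <- vd
          best_params <- model$params
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= cfg$patience) done <- TRUE
        }
        if (!is.null(cfg$stop_dsc) && best >= cfg$stop_dsc) done <- TRUE
      }
    }
    model$params <- best_params
    structure(list(model_id = model_id, model = model, val_dsc = best,
                   history = data.frame(iteration = hist_it, loss = hist_loss,
                                        val_dsc = hist_dsc),
                   iterations_run = it, view = "axial", interleaved = FALSE),
              class = "scap_trained_record")
  })
}

#' Assemble a DSC table from trained model records
#'
#' @param records list of `scap_trained_record` (or lists with `model_id`
#'   and `val_dsc`).
#' @param ... additional grouping columns recycled across records (e.g.
#'   `dims`, `view`, `variant`, `fold`).
#' @return data.frame with columns model_id, dsc and any groupings.
#' @export
dsc_table <- function(records, ...) {
  df <- data.frame(model_id = vapply(records, function(r) r$model_id, ""),
                   dsc = vapply(records, function(r) r$val_dsc, 0),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep(extra[[nm]], length.out = nrow(df))
  df
}

#' Build a DSC-gated ensemble
#'
#' Keeps every trained record whose best validation DSC is strictly above
#' the threshold (default 0.70); the excluded model ids are attached as the
#' `excluded` attribute.
#'
#' @param records non-empty list of `scap_trained_record`.
#' @param threshold gate on validation DSC.
#' @return a `scap_ensemble` with the retained members.
#' @export
build_ensemble <- function(records, threshold = 0.70) {
  .assert(length(records) > 0, "no records supplied")
  keep <- vapply(records, function(r) r$val_dsc > threshold, logical(1))
  if (!any(keep))
    stop(sprintf("empty ensemble: no model has validation DSC above %.2f",
                 threshold), call. = FALSE)
  structure(list(members = records[keep], dsc_threshold = threshold),
            class = "scap_ensemble",
            excluded = vapply(records[!keep], function(r) r$model_id, ""))
}

# Full-resolution probability map from one ensemble member: 2D members run
# slice-wise along their own view axis; interleaved 3D members predict both
# interleaved slice stacks and the maps are re-interleaved.
.member_predict <- function(record, v) {
  model <- record$model
  arr <- .grid_data(v)
  sp <- .grid_spacing(v)
  if (model$config$dims == 2) {
    return(.predict2d(model, arr, record$view %||% "axial"))
  }
  if (isTRUE(record$interleaved)) {
    halves <- interleave_split(as_volume(arr, sp))
    pe <- .predict3d(model, .grid_data(halves$even))
    po <- .predict3d(model, .grid_data(halves$odd))
    return(.grid_data(interleave_merge(as_probmap(pe, c(sp[1:2], sp[3] * 2)),
                                       as_probmap(po, c(sp[1:2], sp[3] * 2)))))
  }
  .predict3d(model, arr)
}

#' Ensemble prediction by probability averaging
#'
#' Runs every member on the volume, reconstructs all predictions on the
#' full-resolution grid and returns their unweighted voxel-wise mean. The
#' result is permutation-invariant in the members and bounded voxel-wise by
#' the member minimum and maximum.
#'
#' @param ensemble a `scap_ensemble`.
#' @param v input `scap_volume` (validation-normalized).
#' @return a `scap_probmap`.
#' @export
ensemble_predict <- function(ensemble, v) {
  .assert(inherits(ensemble, "scap_ensemble"), "not a scap_ensemble")
  maps <- lapply(ensemble$members, .member_predict, v = v)
  d <- dim(maps[[1]])
  for (m in maps) .assert(all(dim(m) == d),
                          "member prediction shapes differ after reconstruction")
  acc <- Reduce(`+`, maps) / length(maps)
  as_probmap(array(acc, d), .grid_spacing(v))
}
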