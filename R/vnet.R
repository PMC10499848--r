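# Configurable 2D/3D V-Net encoder-decoder segmentation networks.
#
# Topology: an input convolution lifts the single-channel image to
# `n_channels`; each encoder level applies `convs_per_level[i]` convolution
# blocks (kernel `kernel_size`, PReLU activations) with a residual add,
# then downsamples by a strided 2x block convolution that doubles the
# channel count. `bottom_convs` blocks sit at the bottleneck. The decoder
# mirrors the encoder with transposed block convolutions and additive skip
# connections from the matching encoder level. A 1-voxel convolution and a
# sigmoid produce the per-voxel foreground probability (background is the
# complement, so the two class probabilities sum to one). Dropout (inverted,
# with the configured keep probability) is applied after each residual
# block during training only.
#
# 2D networks are the same machinery with a singleton slice axis: kernels
# (k, k, 1) and downsampling blocks (2, 2, 1), run on one slice at a time.
# Forward and backward passes are hand-written against compiled
# convolution kernels; there is no external deep-learning runtime
# underneath.

#' V-Net architecture configuration
#'
#' Defaults follow the satisfactory 2D / 3D configurations: 16 channels,
#' 2 levels, `[4, 4]` convolutions and 2 bottom convolutions with learning
#' rate 5e-4 for 2D; 12 channels, 4 levels, `[1, 3, 4, 3]` convolutions and
#' 4 bottom convolutions with learning rate 1e-5 for 3D. Kernel size 5 is
#' the conventional V-Net choice; small test networks typically use 3.
#'
#' @param dims 2 or 3.
#' @param n_channels base channel count of the first level.
#' @param n_levels encoder depth.
#' @param convs_per_level integer vector, one block count per level.
#' @param bottom_convs number of convolution blocks at the bottleneck.
#' @param kernel_size odd spatial kernel extent of the convolution blocks.
#' @param dropout_keep_prob keep probability in (0, 1]; default 0.95.
#' @param learning_rate Adam step size.
#' @return a `scap_vnet_config`.
#' @export
vnet_config <- function(dims = 3,
                        n_channels = if (dims == 2) 16 else 12,
                        n_levels = if (dims == 2) 2 else 4,
                        convs_per_level = if (dims == 2) c(4, 4) else c(1, 3, 4, 3),
                        bottom_convs = if (dims == 2) 2 else 4,
                        kernel_size = 5,
                        dropout_keep_prob = 0.95,
                        learning_rate = if (dims == 2) 5e-4 else 1e-5) {
  .assert(dims %in% c(2, 3), "dims must be 2 or 3")
  .assert(length(convs_per_level) == n_levels,
          "convs_per_level must have one entry per level (%d)", n_levels)
  .assert(all(convs_per_level >= 1) && bottom_convs >= 1,
          "all convolution counts must be >= 1")
  .assert(kernel_size %% 2 == 1 && kernel_size >= 1,
          "kernel_size must be odd and >= 1")
  .assert(dropout_keep_prob > 0 && dropout_keep_prob <= 1,
          "dropout_keep_prob must lie in (0, 1]")
  .assert(learning_rate > 0, "learning_rate must be > 0")
  structure(list(dims = dims, n_channels = as.integer(n_channels),
                 n_levels = as.integer(n_levels),
                 convs_per_level = as.integer(convs_per_level),
                 bottom_convs = as.integer(bottom_convs),
                 kernel_size = as.integer(kernel_size),
                 dropout_keep_prob = dropout_keep_prob,
                 learning_rate = learning_rate,
                 kernel = if (dims == 2) c(kernel_size, kernel_size, 1L)
                          else rep(kernel_size, 3L),
                 block = if (dims == 2) c(2L, 2L, 1L) else c(2L, 2L, 2L)),
            class = "scap_vnet_config")
}

.conv_param <- function(kdim, cin, cout) {
  fan_in <- prod(kdim) * cin
  array(stats::rnorm(prod(kdim) * cin * cout, 0, sqrt(2 / fan_in)),
        c(kdim, cin, cout))
}

#' Build a V-Net segmentation model
#'
#' Initializes all trainable parameters (He-style normal initialization,
#' PReLU slopes at 0.1, zero biases) for the given configuration.
#'
#' @param config a [vnet_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return a `scap_vnet` model object.
#' @export
build_model <- function(config = vnet_config(), seed = NULL) {
  .with_seed(seed, {
    P <- list()
    C <- config$n_channels
    L <- config$n_levels
    k <- config$kernel
    blk <- config$block
    B <- prod(blk)
    addc <- function(name, cin, cout, kdim = k) {
      P[[paste0(name, "_w")]] <<- .conv_param(kdim, cin, cout)
      P[[paste0(name, "_b")]] <<- numeric(cout)
      P[[paste0(name, "_a")]] <<- rep(0.1, cout)
    }
    addc("in", 1L, C)
    for (i in seq_len(L)) {
      ci <- C * 2^(i - 1)
      for (j in seq_len(config$convs_per_level[i]))
        addc(sprintf("enc%d_c%d", i, j), ci, ci)
      P[[sprintf("down%d_w", i)]] <- array(
        stats::rnorm(B * ci * 2 * ci, 0, sqrt(2 / (B * ci))),
        c(blk, ci, 2L * ci))
      P[[sprintf("down%d_b", i)]] <- numeric(2 * ci)
      P[[sprintf("down%d_a", i)]] <- rep(0.1, 2 * ci)
    }
    cb <- C * 2^L
    for (j in seq_len(config$bottom_convs)) addc(sprintf("bot_c%d", j), cb, cb)
    for (i in rev(seq_len(L))) {
      ci <- C * 2^(i - 1)
      P[[sprintf("up%d_w", i)]] <- matrix(
        stats::rnorm(2 * ci * B * ci, 0, sqrt(2 / (2 * ci))), 2 * ci, B * ci)
      P[[sprintf("up%d_b", i)]] <- numeric(ci)
      P[[sprintf("up%d_a", i)]] <- rep(0.1, ci)
      for (j in seq_len(config$convs_per_level[i]))
        addc(sprintf("dec%d_c%d", i, j), ci, ci)
    }
    P[["out_w"]] <- .conv_param(c(1L, 1L, 1L), C, 1L)
    P[["out_b"]] <- 0
    structure(list(config = config, params = P), class = "scap_vnet")
  })
}

#' Number of trainable parameters
#' @param model a `scap_vnet`.
#' @return integer parameter count (a pure function of the configuration).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.scap_vnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<scap_vnet> %dD, %d channels, %d levels, convs [%s], %s parameters\n",
              cfg$dims, cfg$n_channels, cfg$n_levels,
              paste(cfg$convs_per_level, collapse = ", "),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# Forward pass over a (X, Y, Z, 1) input array. Returns the probability
# array plus the op tape needed for backpropagation.
.vn_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  P <- model$params
  blk <- cfg$block
  d <- dim(x)
  .assert(length(d) == 4 && d[4] == 1, "input must be (X, Y, Z, 1)")
  div <- c(blk[1]^cfg$n_levels, blk[2]^cfg$n_levels, blk[3]^cfg$n_levels)
  .assert(all(d[1:3] %% div == 0),
          "spatial size %s must be divisible by %s for %d levels",
          paste(d[1:3], collapse = "x"), paste(div, collapse = "x"),
          cfg$n_levels)

  vals <- vector("list", 512)
  ops <- vector("list", 512)
  nval <- 0L; nop <- 0L
  newval <- function(v) { nval <<- nval + 1L; vals[[nval]] <<- v; nval }
  emit <- function(kind, v, ins, pname = NULL, extra = NULL) {
    id <- newval(v)
    nop <<- nop + 1L
    ops[[nop]] <<- list(kind = kind, ins = ins, out = id, pname = pname,
                        extra = extra)
    id
  }
  conv <- function(id, pname) {
    force(id)
    xv <- vals[[id]]
    w <- P[[paste0(pname, "_w")]]
    emit("conv", cpp_conv_fwd(xv, dim(xv), w, dim(w), P[[paste0(pname, "_b")]]),
         id, pname)
  }
  prelu <- function(id, pname) {
    force(id)
    xv <- vals[[id]]
    emit("prelu", cpp_prelu_fwd(xv, dim(xv), P[[paste0(pname, "_a")]]),
         id, pname)
  }
  down <- function(id, pname, cout) {
    force(id)
    xv <- vals[[id]]
    emit("down", cpp_down_fwd(xv, dim(xv), P[[paste0(pname, "_w")]],
                              P[[paste0(pname, "_b")]], blk, cout),
         id, pname, extra = list(cout = cout))
  }
  up <- function(id, pname, cout) {
    force(id)
    xv <- vals[[id]]
    emit("up", cpp_up_fwd(xv, dim(xv), P[[paste0(pname, "_w")]],
                          P[[paste0(pname, "_b")]], blk, cout),
         id, pname, extra = list(cout = cout))
  }
  addn <- function(a, b) {
    force(a); force(b)
    emit("add", vals[[a]] + vals[[b]], c(a, b))
  }
  dropout <- function(id) {
    force(id)
    keep <- cfg$dropout_keep_prob
    if (!training || keep >= 1) return(id)
    mk <- (stats::runif(length(vals[[id]])) < keep) / keep
    emit("dropout", array(vals[[id]] * mk, dim(vals[[id]])), id,
         extra = list(mask = mk))
  }

  id <- newval(x)
  id <- prelu(conv(id, "in"), "in")
  L <- cfg$n_levels
  skips <- integer(L)
  for (i in seq_len(L)) {
    rin <- id
    for (j in seq_len(cfg$convs_per_level[i])) {
      nm <- sprintf("enc%d_c%d", i, j)
      id <- prelu(conv(id, nm), nm)
    }
    id <- dropout(addn(id, rin))
    skips[i] <- id
    nm <- sprintf("down%d", i)
    id <- prelu(down(id, nm, cfg$n_channels * 2^i), nm)
  }
  rin <- id
  for (j in seq_len(cfg$bottom_convs)) {
    nm <- sprintf("bot_c%d", j)
    id <- prelu(conv(id, nm), nm)
  }
  id <- dropout(addn(id, rin))
  for (i in rev(seq_len(L))) {
    nm <- sprintf("up%d", i)
    id <- prelu(up(id, nm, cfg$n_channels * 2^(i - 1)), nm)
    id <- addn(id, skips[i])
    rin <- id
    for (j in seq_len(cfg$convs_per_level[i])) {
      nm <- sprintf("dec%d_c%d", i, j)
      id <- prelu(conv(id, nm), nm)
    }
    id <- dropout(addn(id, rin))
  }
  id <- conv(id, "out")
  z <- vals[[id]]
  out <- emit("sigmoid", 1 / (1 + exp(-z)), id)
  list(p = vals[[out]], vals = vals, ops = ops, nval = nval, nop = nop,
       out = out)
}

# Backpropagate d(loss)/d(p) through the tape; returns named gradient list
# aligned with model$params.
.vn_backward <- function(model, fw, gout) {
  P <- model$params
  vals <- fw$vals
  blk <- model$config$block
  g <- vector("list", fw$nval)
  grads <- list()
  acc <- function(id, gv) {
    g[[id]] <<- if (is.null(g[[id]])) gv else g[[id]] + gv
  }
  gacc <- function(pn, gv) {
    grads[[pn]] <<- if (is.null(grads[[pn]])) gv else grads[[pn]] + gv
  }
  acc(fw$out, gout)
  for (oi in rev(seq_len(fw$nop))) {
    op <- fw$ops[[oi]]
    gy <- g[[op$out]]
    if (is.null(gy)) next
    switch(op$kind,
      conv = {
        xv <- vals[[op$ins]]
        w <- P[[paste0(op$pname, "_w")]]
        r <- cpp_conv_bwd(xv, dim(xv), w, dim(w), gy)
        acc(op$ins, r$gx)
        gacc(paste0(op$pname, "_w"), r$gw)
        gacc(paste0(op$pname, "_b"), r$gb)
      },
      down = {
        xv <- vals[[op$ins]]
        r <- cpp_down_bwd(xv, dim(xv), P[[paste0(op$pname, "_w")]], blk,
                          op$extra$cout, gy)
        acc(op$ins, r$gx)
        gacc(paste0(op$pname, "_w"), r$gw)
        gacc(paste0(op$pname, "_b"), r$gb)
      },
      up = {
        xv <- vals[[op$ins]]
        r <- cpp_up_bwd(xv, dim(xv), P[[paste0(op$pname, "_w")]], blk,
                        op$extra$cout, gy)
        acc(op$ins, r$gx)
        gacc(paste0(op$pname, "_w"), r$gw)
        gacc(paste0(op$pname, "_b"), r$gb)
      },
      prelu = {
        xv <- vals[[op$ins]]
        r <- cpp_prelu_bwd(xv, dim(xv), P[[paste0(op$pname, "_a")]], gy)
        acc(op$ins, r$gx)
        gacc(paste0(op$pname, "_a"), r$ga)
      },
      add = {
        acc(op$ins[1], gy)
        acc(op$ins[2], gy)
      },
      dropout = {
        acc(op$ins, array(gy * op$extra$mask, dim(gy)))
      },
      sigmoid = {
        y <- vals[[op$out]]
        acc(op$ins, gy * y * (1 - y))
      },
      stop("unknown op kind: ", op$kind))
  }
  grads
}

.as_input4d <- function(a) {
  d <- dim(a)
  if (length(d) == 2) d <- c(d, 1L)
  array(a, c(d, 1L))
}

# Inference on a 3D array with a 3D network, mirror-padding the grid to a
# multiple of the downsampling factor.
.predict3d <- function(model, arr) {
  L <- model$config$n_levels
  pad <- .pad_to_multiple(arr, 2^L)
  fw <- .vn_forward(model, .as_input4d(pad$data), training = FALSE)
  .unpad(array(fw$p, dim(pad$data)), pad$orig)
}

.view_axis <- function(view) {
  switch(view, axial = 3L, sagittal = 1L, coronal = 2L,
         stop("view must be axial, sagittal or coronal"))
}

# Slice-wise inference of a 2D network over a volume along a view axis.
.predict2d <- function(model, arr, view = "axial") {
  ax <- .view_axis(view)
  L <- model$config$n_levels
  d <- dim(arr)
  out <- array(0, d)
  for (s in seq_len(d[ax])) {
    sl <- switch(ax, arr[s, , ], arr[, s, ], arr[, , s])
    pad <- .pad_to_multiple(array(sl, c(dim(sl), 1L)), c(2^L, 2^L, 1L))
    fw <- .vn_forward(model, .as_input4d(pad$data), training = FALSE)
    res <- .unpad(array(fw$p, dim(pad$data)), pad$orig)[, , 1]
    switch(ax, out[s, , ] <- res, out[, s, ] <- res, out[, , s] <- res)
  }
  out
}

#' Predict a segmentation probability map
#'
#' Runs the network in inference mode (dropout disabled, deterministic).
#' 3D networks consume the whole volume; 2D networks are applied slice by
#' slice along the chosen view axis and the per-slice maps are stacked back
#' into a volume. Inputs whose spatial size is not divisible by the
#' network's downsampling factor are mirror-padded and the padding is
#' removed from the output.
#'
#' @param object a `scap_vnet`.
#' @param volume a `scap_volume` (or 3D array), already normalized with the
#'   validation scheme.
#' @param view slicing axis for 2D networks: "axial", "sagittal", "coronal".
#' @param ... unused.
#' @return a `scap_probmap` of the same shape as the input.
#' @export
predict.scap_vnet <- function(object, volume, view = "axial", ...) {
  arr <- .grid_data(volume)
  .assert(length(dim(arr)) == 3, "volume must be three-dimensional")
  p <- if (object$config$dims == 3) .predict3d(object, arr)
       else .predict2d(object, arr, view)
  as_probmap(p, .grid_spacing(volume))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the trainable parameters with
#' the architecture configuration embedded, so a loaded model is usable
#' as-is for inference or further training.
#'
#' @param model a `scap_vnet`.
#' @param path checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `scap_vnet`.
#' @export
save_model <- function(model, path) {
  .assert(inherits(model, "scap_vnet"), "not a scap_vnet model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  .assert(inherits(m, "scap_vnet"), "file %s does not hold a scap_vnet", path)
  m
}
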