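# Deterministic preprocessing: in-plane cropping, interleaved slice
# splitting/recombination and the three intensity-normalization schemes.
#
# The canonical high-resolution acquisition is 512 x 512 x 248 voxels at
# 0.375 x 0.375 mm in-plane with 0.5 mm slice spacing; cropping the first
# 112 rows and columns and splitting into the two interleaved slice stacks
# yields two 400 x 400 x 124 volumes, which keeps full resolution while
# halving the memory footprint of a 3D training example.

#' Crop specification
#'
#' Number of leading rows/columns removed from the in-plane axes. The
#' default (112, 112) removes the empty margin of a 512x512 shoulder
#' acquisition without touching the scapula.
#'
#' @param n_rows,n_cols non-negative integer counts of leading rows/columns
#'   to drop.
#' @return a `scap_crop_spec`.
#' @export
crop_spec <- function(n_rows = 112, n_cols = 112) {
  .assert(n_rows >= 0 && n_cols >= 0 && n_rows == round(n_rows) &&
            n_cols == round(n_cols), "crop counts must be non-negative integers")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "scap_crop_spec")
}

#' Crop leading rows and columns from a volume or mask
#'
#' Removes the first `n_rows` rows and `n_cols` columns (indices from 0);
#' slices and spacing are untouched.
#'
#' @param v a `scap_volume` or `scap_mask`.
#' @param spec a [crop_spec()].
#' @return same container type with shape (rows - n_rows, cols - n_cols,
#'   slices).
#' @export
crop_volume <- function(v, spec = crop_spec()) {
  a <- .grid_data(v)
  d <- dim(a)
  .assert(spec$n_rows < d[1] && spec$n_cols < d[2],
          "crop (%d, %d) must be smaller than the in-plane extent (%d, %d)",
          spec$n_rows, spec$n_cols, d[1], d[2])
  out <- a[(spec$n_rows + 1L):d[1], (spec$n_cols + 1L):d[2], , drop = FALSE]
  .rewrap(v, out, .grid_spacing(v))
}

.rewrap <- function(template, data, spacing) {
  if (inherits(template, "scap_mask")) as_mask(data, spacing)
  else if (inherits(template, "scap_probmap")) as_probmap(data, spacing)
  else as_volume(data, spacing)
}

#' Split a volume into its two interleaved slice stacks
#'
#' The first output keeps slices 0, 2, 4, ... and the second slices
#' 1, 3, 5, ... (0-based); the slice-axis spacing doubles in both. Odd slice
#' counts are allowed, in which case the first stack is one slice longer.
#'
#' @param v a `scap_volume`, `scap_mask` or `scap_probmap` with >= 2 slices.
#' @return list of two same-type objects, `even` (slices 0,2,...) and
#'   `odd` (slices 1,3,...).
#' @export
interleave_split <- function(v) {
  a <- .grid_data(v)
  d <- dim(a)
  .assert(d[3] >= 2, "interleave_split needs at least 2 slices (got %d)", d[3])
  sp <- .grid_spacing(v)
  sp2 <- c(sp[1:2], sp[3] * 2)
  even <- a[, , seq(1, d[3], by = 2), drop = FALSE]
  odd <- a[, , seq(2, d[3], by = 2), drop = FALSE]
  list(even = .rewrap(v, even, sp2), odd = .rewrap(v, odd, sp2))
}

#' Re-interleave two half-resolution slice stacks
#'
#' Inverse of [interleave_split()]: output slice 2i comes from `a`, slice
#' 2i+1 from `b`; slice spacing is halved. `a` may have one more slice than
#' `b` (odd original depth).
#'
#' @param a,b same-type grids differing only in slice count, with
#'   `count(a)` in `{count(b), count(b) + 1}`.
#' @return the merged full-depth object.
#' @export
interleave_merge <- function(a, b) {
  da <- dim(.grid_data(a)); db <- dim(.grid_data(b))
  .assert(all(da[1:2] == db[1:2]),
          "in-plane shapes differ: %s vs %s",
          paste(da[1:2], collapse = "x"), paste(db[1:2], collapse = "x"))
  .assert(da[3] == db[3] || da[3] == db[3] + 1,
          "slice counts %d and %d cannot be interleaved", da[3], db[3])
  nz <- da[3] + db[3]
  out <- array(0, c(da[1:2], nz))
  out[, , seq(1, nz, by = 2)] <- .grid_data(a)
  out[, , seq(2, nz, by = 2)] <- .grid_data(b)
  sp <- .grid_spacing(a)
  .rewrap(a, out, c(sp[1:2], sp[3] / 2))
}

#' Intensity normalization specification
#'
#' Three schemes are supported. Training volumes are divided by a random
#' divisor drawn uniformly from `[max - jitter, max + jitter]` -- jitter 1000
#' for 3D training, 500 for 2D training -- which makes training robust to
#' coil-gain intensity inflation and acts as implicit augmentation.
#' Validation volumes are divided by the exact maximum and then by the 85th
#' percentile of the rescaled intensities (linear-interpolation percentile
#' over all voxels), which tames outlier-dominated scaling.
#'
#' @param mode "train3d", "train2d" or "validation".
#' @param jitter half-width of the uniform divisor range (intensity units);
#'   defaults to 1000 / 500 / 0 by mode.
#' @param percentile_divide whether the 85th-percentile second division is
#'   applied (validation mode only).
#' @param seed optional integer seed making the divisor draw reproducible.
#' @return a `scap_norm_spec`.
#' @export
normalization_spec <- function(mode = c("validation", "train3d", "train2d"),
                               jitter = NULL, percentile_divide = NULL,
                               seed = NULL) {
  mode <- match.arg(mode)
  jitter <- jitter %||% switch(mode, train3d = 1000, train2d = 500,
                               validation = 0)
  percentile_divide <- percentile_divide %||% (mode == "validation")
  .assert(jitter >= 0, "jitter must be >= 0")
  .assert(!percentile_divide || mode == "validation",
          "percentile_divide is only available in validation mode")
  structure(list(mode = mode, jitter = jitter,
                 percentile_divide = percentile_divide, seed = seed),
            class = "scap_norm_spec")
}

#' Normalize a volume's intensities
#'
#' Applies the scheme described in [normalization_spec()]. In the training
#' modes exactly one uniform value is consumed from the random stream per
#' call (redrawn, up to 10 times, only in the degenerate case of a
#' non-positive divisor).
#'
#' @param v a `scap_volume` with at least one strictly positive intensity.
#' @param spec a [normalization_spec()].
#' @return normalized `scap_volume`.
#' @export
normalize_volume <- function(v, spec = normalization_spec()) {
  a <- .grid_data(v)
  mx <- max(a)
  .assert(mx > 0, "volume must contain a strictly positive intensity")
  out <- if (spec$mode == "validation") {
    b <- a / mx
    if (spec$percentile_divide) {
      p85 <- stats::quantile(b, 0.85, names = FALSE, type = 7)
      .assert(p85 > 0, "85th percentile is non-positive; cannot normalize")
      b <- b / p85
    }
    b
  } else {
    draw <- function() stats::runif(1, mx - spec$jitter, mx + spec$jitter)
    div <- .with_seed(spec$seed, {
      d <- draw()
      tries <- 1L
      while (d <= 0 && tries < 10L) {
        d <- draw()
        tries <- tries + 1L
      }
      d
    })
    .assert(div > 0, "could not draw a strictly positive divisor (max=%g, jitter=%g)",
            mx, spec$jitter)
    a / div
  }
  as_volume(out, .grid_spacing(v))
}
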