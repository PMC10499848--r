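# Stochastic dataset expansion: random affine, elastic deformation,
# Gaussian blur and additive noise, applied jointly to an image and its
# mask. Spatial transforms share parameters between image and mask; the
# mask is resampled with nearest-neighbour so labels stay strictly binary;
# intensity transforms touch the image only.

#' Augmentation specification
#'
#' Each of the four transform families (affine, elastic, blur, noise) is
#' applied independently with probability `per_transform_prob` per generated
#' copy; `copies_per_original` augmented copies are produced per original
#' (defaults: 30% chance, 8 copies). Ranges are chosen to deform plausibly
#' without destroying the thin scapular blade; all are overridable.
#'
#' @param per_transform_prob probability in \[0,1\] that each listed
#'   transform family is applied.
#' @param copies_per_original number of augmented copies per original.
#' @param rotation_range max rotation magnitude per axis (degrees).
#' @param scale_range length-2 multiplicative scale range.
#' @param translation_range max translation per axis (voxels).
#' @param elastic_amplitude max random displacement (voxels).
#' @param elastic_smoothness control-point spacing of the displacement
#'   field (voxels); larger = smoother.
#' @param blur_sigma_range length-2 Gaussian blur sigma range (voxels).
#' @param noise_sd_range length-2 additive noise SD range, as a fraction of
#'   the image maximum.
#' @param seed optional integer seed.
#' @return a `scap_augment_spec`.
#' @export
augment_spec <- function(per_transform_prob = 0.30, copies_per_original = 8,
                         rotation_range = 15, scale_range = c(0.9, 1.1),
                         translation_range = 10, elastic_amplitude = 4,
                         elastic_smoothness = 8,
                         blur_sigma_range = c(0.5, 1.5),
                         noise_sd_range = c(0.01, 0.05), seed = NULL) {
  .assert(per_transform_prob >= 0 && per_transform_prob <= 1,
          "per_transform_prob must lie in [0, 1]")
  .assert(copies_per_original >= 0 && copies_per_original == round(copies_per_original),
          "copies_per_original must be a non-negative integer")
  .assert(rotation_range >= 0 && translation_range >= 0 &&
            elastic_amplitude >= 0 && elastic_smoothness > 0 &&
            all(blur_sigma_range >= 0) && all(noise_sd_range >= 0),
          "all augmentation ranges must be non-negative")
  structure(list(per_transform_prob = per_transform_prob,
                 copies_per_original = as.integer(copies_per_original),
                 rotation_range = rotation_range, scale_range = scale_range,
                 translation_range = translation_range,
                 elastic_amplitude = elastic_amplitude,
                 elastic_smoothness = elastic_smoothness,
                 blur_sigma_range = blur_sigma_range,
                 noise_sd_range = noise_sd_range, seed = seed),
            class = "scap_augment_spec")
}

# Grid of destination voxel coordinates (0-based), as an n x 3 matrix.
.coord_grid <- function(d) {
  cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

# Source coordinates for an affine output->input map about the grid centre.
.affine_coords <- function(d, rotation, scale, translation) {
  R <- .rot_euler(rotation)
  ctr <- (d - 1) / 2
  dst <- .coord_grid(d)
  rel <- sweep(dst, 2, ctr + translation)
  src <- rel %*% t(solve(R * scale))  # inverse map: R^-1 / scale
  sweep(src, 2, ctr, FUN = "+")
}

# Smooth random displacement field: coarse N(0, amplitude) control grid
# upsampled trilinearly to the full resolution. Returns an n x 3 matrix of
# per-voxel displacements (voxels).
.elastic_field <- function(d, amplitude, smoothness) {
  cd <- pmax(2L, as.integer(ceiling(d / smoothness)) + 1L)
  dst <- .coord_grid(d)
  scalef <- (cd - 1) / pmax(d - 1, 1)
  cc <- sweep(dst, 2, scalef, FUN = "*")
  disp <- matrix(0, nrow(dst), 3)
  for (ax in 1:3) {
    coarse <- array(stats::rnorm(prod(cd), 0, amplitude), cd)
    disp[, ax] <- cpp_resample(coarse, cd, cc, FALSE, 0)
  }
  disp
}

.resample_pair <- function(varr, marr, src, d) {
  v2 <- array(cpp_resample(varr, d, src, FALSE, 0), d)
  m2 <- array(cpp_resample(marr, d, src, TRUE, 0), d)
  list(v = v2, m = m2)
}

#' Augment one image/mask pair
#'
#' Draws four application flags (affine, elastic, blur, noise), then the
#' parameters of each applied transform, from the current RNG stream (or
#' `spec$seed` if set). Spatial transforms use identical parameters for
#' image and mask; output shape equals input shape.
#'
#' @param v a `scap_volume` (or 3D array).
#' @param m the paired `scap_mask`, same shape and spacing.
#' @param spec an [augment_spec()].
#' @return list with elements `volume` and `mask`.
#' @export
augment_pair <- function(v, m, spec = augment_spec()) {
  varr <- .grid_data(v); marr <- .grid_data(m)
  .assert(all(dim(varr) == dim(marr)),
          "image and mask shapes differ: %s vs %s",
          paste(dim(varr), collapse = "x"), paste(dim(marr), collapse = "x"))
  sp <- .grid_spacing(v)
  .with_seed(spec$seed, {
    d <- dim(varr)
    apply_tf <- stats::runif(4) < spec$per_transform_prob
    if (apply_tf[1]) {  # affine
      rot <- stats::runif(3, -spec$rotation_range, spec$rotation_range)
      scl <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
      trl <- stats::runif(3, -spec$translation_range, spec$translation_range)
      src <- .affine_coords(d, rot, scl, trl)
      rp <- .resample_pair(varr, marr, src, d)
      varr <- rp$v; marr <- rp$m
    }
    if (apply_tf[2]) {  # elastic
      disp <- .elastic_field(d, spec$elastic_amplitude, spec$elastic_smoothness)
      src <- .coord_grid(d) + disp
      rp <- .resample_pair(varr, marr, src, d)
      varr <- rp$v; marr <- rp$m
    }
    if (apply_tf[3]) {  # Gaussian blur (image only)
      sg <- stats::runif(1, spec$blur_sigma_range[1], spec$blur_sigma_range[2])
      varr <- array(cpp_gauss_blur(varr, dim(varr), rep(sg, 3)), d)
    }
    if (apply_tf[4]) {  # additive noise (image only)
      sd <- stats::runif(1, spec$noise_sd_range[1], spec$noise_sd_range[2])
      varr <- varr + stats::rnorm(length(varr), 0, sd * max(abs(varr)))
    }
    list(volume = as_volume(varr, sp), mask = as_mask(marr, sp))
  })
}

#' Augment a dataset of image/mask pairs
#'
#' Returns the originals followed by `copies_per_original` augmented copies
#' of each, in deterministic order (all copies of pair 1, then pair 2, ...).
#' With a fixed `spec$seed` the result is bit-reproducible.
#'
#' @param pairs non-empty list of `list(volume =, mask =)` pairs.
#' @param spec an [augment_spec()].
#' @return list of pairs of length `n * (1 + copies_per_original)`.
#' @export
augment_dataset <- function(pairs, spec = augment_spec()) {
  .assert(length(pairs) > 0, "augment_dataset needs a non-empty pair list")
  per_pair_spec <- spec
  per_pair_spec$seed <- NULL  # one stream for the whole dataset
  .with_seed(spec$seed, {
    out <- pairs
    for (p in pairs) {
      for (i in seq_len(spec$copies_per_original)) {
        out[[length(out) + 1L]] <- augment_pair(p$volume, p$mask, per_pair_spec)
      }
    }
    out
  })
}
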