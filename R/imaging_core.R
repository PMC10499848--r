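# Domain types for volumetric images and masks, plus NIfTI I/O.
#
# All grids follow a fixed axis convention (row, column, slice) with the
# slice axis being the acquisition (axial) axis. Voxel indices are 0-based
# in physical math: physical coordinate = index * spacing (mm).

.new_grid <- function(data, spacing, class) {
  .assert(is.array(data) && length(dim(data)) == 3,
          "data must be a 3D array (got %s dims)", length(dim(data)))
  .assert(all(dim(data) >= 1), "all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  .assert(length(spacing) == 3 && all(is.finite(spacing)) && all(spacing > 0),
          "spacing must be three positive finite values (mm/voxel)")
  .assert(all(is.finite(data)), "intensities must be finite (no NaN/Inf)")
  structure(list(data = data, spacing = spacing),
            class = c(class, "scap_grid"))
}

#' Volumetric image containers
#'
#' `as_volume()`, `as_mask()` and `as_probmap()` wrap a 3D array together
#' with its per-axis physical voxel spacing (mm). A mask holds strictly
#' binary values (the segmentation ground truth), a probability map holds
#' values in \[0, 1\] (a model's predicted foreground probability per voxel),
#' and a volume holds arbitrary finite intensities.
#'
#' @param data 3D numeric array, axes ordered (row, column, slice).
#' @param spacing length-3 positive numeric, mm per voxel along each axis.
#' @return an object of class `scap_volume`, `scap_mask` or `scap_probmap`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1)) {
  .new_grid(data, spacing, "scap_volume")
}

#' @rdname as_volume
#' @export
as_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- data * 1  # logical -> numeric
  obj <- .new_grid(data, spacing, "scap_mask")
  .assert(all(data %in% c(0, 1)), "mask values must be exactly 0 or 1")
  obj
}

#' @rdname as_volume
#' @export
as_probmap <- function(data, spacing = c(1, 1, 1)) {
  obj <- .new_grid(data, spacing, "scap_probmap")
  .assert(all(data >= 0 & data <= 1), "probabilities must lie in [0, 1]")
  obj
}

#' @export
print.scap_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

.grid_data <- function(x) if (inherits(x, "scap_grid")) x$data else x
.grid_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "scap_grid")) x$spacing else default
}

#' Read a volumetric NIfTI image
#'
#' Loads a `.nii`/`.nii.gz` file into a [as_volume()] container, taking the
#' voxel spacing from the header and squeezing singleton trailing dimensions.
#'
#' @param path path to a readable NIfTI file.
#' @param as one of "volume", "mask", "probmap": container to return.
#' @return a `scap_volume` (or mask / probability map).
#' @export
read_volume <- function(path, as = c("volume", "mask", "probmap")) {
  as <- match.arg(as)
  .assert(file.exists(path), "cannot read NIfTI file: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "failed to read NIfTI file %s: %s", path,
                    conditionMessage(e)), call. = FALSE))
  a <- as.array(img)
  a <- array(as.numeric(a), dim(a))  # plain array, no header attributes
  d <- dim(a)
  if (length(d) > 3) {
    .assert(all(d[-(1:3)] == 1),
            "image in %s has more than three non-singleton dimensions", path)
    dim(a) <- d[1:3]
    d <- dim(a)
  }
  .assert(length(d) == 3,
          "image in %s is not three-dimensional (dims: %s)",
          path, paste(d, collapse = "x"))
  sp <- RNifti::pixdim(img)[1:3]
  .assert(all(is.finite(a)), "image %s contains NaN/Inf voxels", path)
  switch(as,
         volume  = as_volume(a, sp),
         mask    = as_mask(a, sp),
         probmap = as_probmap(a, sp))
}

#' Write a volumetric image as NIfTI
#'
#' Masks are stored as unsigned 8-bit integers, volumes and probability maps
#' as 32-bit floats; spacing is preserved in the header.
#'
#' @param v a `scap_volume`, `scap_mask` or `scap_probmap`.
#' @param path output path (`.nii` or `.nii.gz`); parent dir must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  .assert(inherits(v, "scap_grid"), "v must be a volume, mask or probmap")
  .assert(dir.exists(dirname(path)),
          "parent directory does not exist: %s", dirname(path))
  dt <- if (inherits(v, "scap_mask")) "uint8" else "float"
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, file = path, datatype = dt)
  invisible(path)
}

#' Threshold a probability map into a binary mask
#'
#' A voxel becomes foreground iff its probability is greater than or equal
#' to the threshold.
#'
#' @param p a `scap_probmap` (or plain array in \[0,1\]).
#' @param threshold scalar strictly inside (0, 1); default 0.5.
#' @return a `scap_mask` on the same grid.
#' @export
binarize <- function(p, threshold = 0.5) {
  .assert(is.numeric(threshold) && length(threshold) == 1 &&
            threshold > 0 && threshold < 1,
          "threshold must lie strictly inside (0, 1)")
  as_mask((.grid_data(p) >= threshold) * 1, .grid_spacing(p))
}
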