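# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Round half away from zero
#'
#' Decimal rounding with ties moved away from zero (so 1.285 -> 1.29 at two
#' decimals), the convention used when reporting measurement tables. Base
#' `round()` rounds ties to even, which changes several two-decimal cells.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Temporarily seed the RNG, restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  .assert(n > 1e-12, "degenerate zero-length vector")
  v / n
}

.clamp1 <- function(x) pmin(1, pmax(-1, x))

# Unsigned angle between two 3D vectors, in degrees.
.angle_deg <- function(u, v) {
  acos(.clamp1(sum(.unit(u) * .unit(v)))) * 180 / pi
}

# Rotation matrices (degrees) about the grid axes.
.rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
.rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
.rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
.rot_euler <- function(angles) {
  .rot_z(angles[3]) %*% .rot_y(angles[2]) %*% .rot_x(angles[1])
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Pad a 3D array at the trailing end of each axis with mirrored values so each
# spatial extent becomes a multiple of `mult` (per-axis vector allowed).
.pad_to_multiple <- function(a, mult) {
  d <- dim(a)
  mult <- rep(mult, length.out = 3)
  target <- ceiling(d / mult) * mult
  if (all(target == d)) return(list(data = a, orig = d))
  out <- array(0, target)
  idx <- lapply(1:3, function(i) {
    need <- target[i] - d[i]
    .assert(need < d[i], "axis %d too short (%d) to mirror-pad to %d",
            i, d[i], target[i])
    c(seq_len(d[i]), rev(seq_len(d[i]))[seq_len(need)])
  })
  out[] <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  list(data = out, orig = d)
}

.unpad <- function(a, orig) {
  a[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), drop = FALSE]
}
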