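# Automatic landmark extraction from a 3D scapula mask and the six
# clinical glenoid measurements (height, width, retroversion, inclination,
# critical shoulder angle, RSA angle), plus surface-distance maps and
# trial-mean comparisons between modalities.
#
# The landmark detector is fully deterministic and intrinsic (derived from
# the shape itself, so it is invariant under rigid motion and mirroring):
#   1. keep the largest connected component;
#   2. the medial-lateral axis is the leading principal axis of the voxel
#      cloud, oriented toward the heavier (glenoid + acromion) end;
#   3. the glenoid face is found as the largest connected cluster of
#      lateral-facing surface voxels and validated as near-planar;
#   4. rim points are the extremal patch points along the in-plane
#      principal axes; the superior direction is fixed by the acromion-side
#      mass lateral of the face, the anterior direction by the posterior
#      protrusion of the scapular spine (sign of the third moment along the
#      thinnest whole-bone axis);
#   5. the medial border is the foreground point farthest from the glenoid
#      centre on the medial side;
#   6. the supraspinatus fossa floor is the long, anterior-most cluster of
#      superior-facing surface voxels medial of the glenoid, fitted with a
#      3D line;
#   7. the lateral acromion is the most lateral point of the bone above the
#      superior glenoid rim.
# All coordinates are physical (mm): voxel index times spacing, 0-based.

.pick_extreme <- function(pts, proj, maximize = TRUE, tol = 0.5) {
  lim <- if (maximize) max(proj) else min(proj)
  sel <- if (maximize) proj >= lim - tol else proj <= lim + tol
  colMeans(pts[sel, , drop = FALSE])
}

#' Extract glenoid and scapular landmarks from a bone mask
#'
#' Deterministic geometric landmark detection; see the package vignette for
#' the full procedure and its assumptions (a single connected scapula-like
#' shape with a near-planar lateral articular surface, an acromion above
#' the superior glenoid rim and a posteriorly protruding spine).
#'
#' @param m a `scap_mask` (or binary 3D array; mm spacing then assumed 1).
#' @return a `scap_landmarks` list of named physical points (mm):
#'   `glenoid_superior`, `glenoid_inferior`, `glenoid_anterior`,
#'   `glenoid_posterior`, `glenoid_center`, `medial_scapula_edge`,
#'   `lateral_supraspinatus_fossa`, `fossa_floor_point`,
#'   `fossa_floor_direction` (unit vector), `lateral_acromion`.
#' @export
extract_landmarks <- function(m) {
  arr <- .grid_data(m)
  sp <- .grid_spacing(m)
  d <- dim(arr)
  fg <- arr == 1
  .assert(any(fg), "landmark extraction failed: empty mask")

  lab <- cpp_label_components(fg, d, 6L)
  counts <- tabulate(lab[lab > 0])
  mask <- array(lab == which.max(counts), d)

  vox <- arrayInd(which(mask), d) - 1L
  phys <- sweep(vox, 2, sp, `*`)
  pr <- stats::prcomp(phys, center = TRUE, scale. = FALSE)
  e1 <- pr$rotation[, 1]
  proj1 <- drop(phys %*% e1)
  span <- diff(range(proj1))
  .assert(span > 10 * max(sp),
          "landmark extraction failed: component too small")
  # orient e1 toward the glenoid/acromion end: that end is much thicker
  # along the bone's thinnest axis than the tapering blade tip
  proj3 <- drop(phys %*% pr$rotation[, 3])
  hi_sel <- proj1 > max(proj1) - 0.25 * span
  lo_sel <- proj1 < min(proj1) + 0.25 * span
  if (stats::sd(proj3[hi_sel]) < stats::sd(proj3[lo_sel])) {
    e1 <- -e1
    proj1 <- -proj1
  }

  # surface voxels with outward normals from the smoothed indicator
  surf <- array(cpp_surface_voxels(mask, d), d)
  sm <- array(cpp_gauss_blur(mask * 1, d, 1.5 / sp), d)
  sidx <- which(surf)
  sv <- arrayInd(sidx, d)
  sphys <- sweep(sv - 1L, 2, sp, `*`)
  nrm <- matrix(0, length(sidx), 3)
  for (ax in 1:3) {
    up <- sv; up[, ax] <- pmin(up[, ax] + 1L, d[ax])
    dn <- sv; dn[, ax] <- pmax(dn[, ax] - 1L, 1L)
    nrm[, ax] <- -(sm[up] - sm[dn]) / (2 * sp[ax])
  }
  nl <- sqrt(rowSums(nrm^2))
  nl[nl < 1e-12] <- 1
  nrm <- nrm / nl

  # glenoid face: largest connected near-planar lateral-facing patch
  # (the leading principal axis only approximates the medial-lateral
  # direction, so the acceptance cone is generous; the cluster-size
  # criterion and the planarity check isolate the articular face)
  csel <- drop(nrm %*% e1) > cos(60 * pi / 180)
  .assert(any(csel), "landmark extraction failed: no lateral articular patch")
  cand <- array(FALSE, d)
  cand[sidx[csel]] <- TRUE
  clab <- cpp_label_components(cand, d, 26L)
  ccount <- tabulate(clab[clab > 0])
  .assert(max(ccount) >= 30,
          "landmark extraction failed: lateral articular patch too small")
  patch <- which(clab == which.max(ccount))
  pphys <- sweep(arrayInd(patch, d) - 1L, 2, sp, `*`)
  prp <- stats::prcomp(pphys, center = TRUE, scale. = FALSE)
  .assert(prp$sdev[3] < 2.0,
          "landmark extraction failed: lateral patch is not planar (rms %.2f mm)",
          prp$sdev[3])
  nrm_g <- prp$rotation[, 3]
  if (sum(nrm_g * e1) < 0) nrm_g <- -nrm_g
  Gc <- colMeans(pphys)
  u <- prp$rotation[, 1]
  v <- prp$rotation[, 2]

  # refine: the cluster's edge voxels have blended normals and spill over
  # the rim, so re-select the articular face as the surface voxels inside a
  # thin slab around the fitted plane that are 26-connected to the initial
  # patch (other structures crossing the plane far from the face stay
  # disconnected within the slab), then refit plane and axes
  sd0 <- sweep(sphys, 2, Gc)
  fsel0 <- abs(drop(sd0 %*% nrm_g)) <= 1.25 * max(sp) + 0.5
  if (sum(fsel0) >= 30) {
    slab <- array(FALSE, d)
    slab[sidx[fsel0]] <- TRUE
    slab_lab <- cpp_label_components(slab, d, 26L)
    seed_labs <- slab_lab[patch]
    seed_labs <- seed_labs[seed_labs > 0]
    if (length(seed_labs) > 0) {
      face_lab <- as.integer(names(which.max(table(seed_labs))))
      face_idx <- which(slab_lab == face_lab)
      if (length(face_idx) >= 30) {
        pphys <- sweep(arrayInd(face_idx, d) - 1L, 2, sp, `*`)
        prp <- stats::prcomp(pphys, center = TRUE, scale. = FALSE)
        nrm_g2 <- prp$rotation[, 3]
        if (sum(nrm_g2 * nrm_g) < 0) nrm_g2 <- -nrm_g2
        nrm_g <- nrm_g2
        Gc <- colMeans(pphys)
        u <- prp$rotation[, 1]
        v <- prp$rotation[, 2]
      }
    }
  }

  dall <- sweep(phys, 2, Gc)
  dn_all <- drop(dall %*% nrm_g)
  du_all <- drop(dall %*% u)
  dv_all <- drop(dall %*% v)
  dup <- drop(sweep(pphys, 2, Gc) %*% u)
  dvp <- drop(sweep(pphys, 2, Gc) %*% v)
  half_extent <- max(diff(range(dup)), diff(range(dvp))) / 2

  # superior: side of the in-plane major axis holding the acromion-side
  # mass (lateral of the face but outside the articular disc)
  off <- dn_all > -2 & sqrt(du_all^2 + dv_all^2) > half_extent + 2
  .assert(any(off),
          "landmark extraction failed: cannot determine the superior direction")
  if (mean(du_all[off]) < 0) {
    u <- -u
    du_all <- -du_all
    dup <- -dup
  }

  tol <- 0.75 * max(sp)
  sup <- .pick_extreme(pphys, dup, TRUE, tol)
  inf <- .pick_extreme(pphys, dup, FALSE, tol)

  # medial border: farthest foreground point on the medial side
  dist2 <- rowSums(dall^2)
  dist2[dn_all >= 0] <- -Inf
  .assert(any(is.finite(dist2)) && max(dist2) > 0,
          "landmark extraction failed: no medial border found")
  M <- phys[which.max(dist2), ]

  # supraspinatus fossa floor: among long superior-facing clusters medial
  # of the articular surface, the inferior-most one (the floor lies below
  # the spine crest)
  sdn <- drop(sweep(sphys, 2, Gc) %*% nrm_g)
  fsel <- drop(nrm %*% u) > cos(35 * pi / 180) & sdn < -7
  .assert(any(fsel),
          "landmark extraction failed: no supraspinatus fossa floor candidates")
  cand2 <- array(FALSE, d)
  cand2[sidx[fsel]] <- TRUE
  flab <- cpp_label_components(cand2, d, 26L)
  fcount <- tabulate(flab[flab > 0])
  best <- NULL
  best_du <- Inf
  for (li in which(fcount >= 20)) {
    cphys <- sweep(arrayInd(which(flab == li), d) - 1L, 2, sp, `*`)
    cp <- stats::prcomp(cphys, center = TRUE, scale. = FALSE)
    extent <- diff(range(cphys %*% cp$rotation[, 1]))
    if (extent < 15) next
    cdu <- sum((colMeans(cphys) - Gc) * u)
    if (cdu < best_du) {
      best_du <- cdu
      best <- list(phys = cphys, dir = cp$rotation[, 1])
    }
  }
  .assert(!is.null(best),
          "landmark extraction failed: no extended supraspinatus fossa floor")
  f_dir <- best$dir
  if (sum(f_dir * e1) < 0) f_dir <- -f_dir
  F0 <- colMeans(best$phys)
  # complete the strip's lateral tip: voxels right at the end have blended
  # normals and miss the orientation cone, so take all surface voxels in a
  # 2 mm tube around the fitted line, reaching at most 2.5 mm beyond the
  # detected cluster
  cl_prj <- drop(sweep(best$phys, 2, F0) %*% f_dir)
  pl <- sweep(sphys, 2, F0)
  prj_all <- drop(pl %*% f_dir)
  perp2 <- rowSums(pl^2) - prj_all^2
  band <- perp2 <= 4 & prj_all <= max(cl_prj) + 2.5 & prj_all >= min(cl_prj)
  F_lat <- .pick_extreme(sphys[band, , drop = FALSE], prj_all[band], TRUE, tol)

  # anterior: the spine ridge rises just above the fossa floor strip and is
  # offset posteriorly from it
  ap <- .unit(.cross3(u, f_dir))
  rel_u <- drop(sweep(phys, 2, F0) %*% u)
  rel_f <- drop(sweep(phys, 2, F0) %*% f_dir)
  f_half <- diff(range(drop(best$phys %*% f_dir))) / 2
  ridge_sel <- rel_u > 1 & rel_u < 8 & abs(rel_f) < f_half
  .assert(any(ridge_sel),
          "landmark extraction failed: no spine ridge above the fossa floor")
  ridge_ap <- mean(drop(sweep(phys[ridge_sel, , drop = FALSE], 2, F0) %*% ap))
  strip_ap <- mean(drop(sweep(best$phys, 2, F0) %*% ap))
  .assert(abs(strip_ap - ridge_ap) > 0.5,
          "landmark extraction failed: cannot determine the anterior direction")
  anterior <- sign(strip_ap - ridge_ap) * ap
  if (sum(v * anterior) < 0) {
    v <- -v
    dv_all <- -dv_all
    dvp <- -dvp
  }
  ant <- .pick_extreme(pphys, dvp, TRUE, tol)
  post <- .pick_extreme(pphys, dvp, FALSE, tol)

  # lateral acromion: most lateral point above the superior glenoid rim
  lat_dir <- .unit(nrm_g - sum(nrm_g * u) * u)
  acr <- du_all > max(dup) + 3
  .assert(any(acr),
          "landmark extraction failed: no acromion above the superior glenoid rim")
  aphys <- phys[acr, , drop = FALSE]
  A <- .pick_extreme(aphys, drop(sweep(aphys, 2, Gc) %*% lat_dir), TRUE, tol)

  structure(list(glenoid_superior = sup, glenoid_inferior = inf,
                 glenoid_anterior = ant, glenoid_posterior = post,
                 glenoid_center = Gc, medial_scapula_edge = M,
                 lateral_supraspinatus_fossa = F_lat,
                 fossa_floor_point = F0, fossa_floor_direction = f_dir,
                 lateral_acromion = A),
            class = "scap_landmarks",
            frame = list(lateral = as.numeric(nrm_g), superior = as.numeric(u),
                         anterior = as.numeric(v)))
}

#' @export
print.scap_landmarks <- function(x, ...) {
  cat("<scap_landmarks>\n")
  for (nm in names(x))
    cat(sprintf("  %-28s %s\n", nm,
                paste(sprintf("%7.2f", x[[nm]]), collapse = " ")))
  invisible(x)
}

.lm_check <- function(l) .assert(inherits(l, "scap_landmarks"),
                                 "expected a scap_landmarks object")

#' Glenoid size and orientation measurements
#'
#' All measurements are computed from a [extract_landmarks()] result in
#' physical coordinates (mm / degrees):
#' \describe{
#'   \item{glenoid_height}{distance from the superior to the inferior rim
#'     point.}
#'   \item{glenoid_width}{distance from the anterior to the posterior rim
#'     point.}
#'   \item{retroversion}{signed angle between the anterior-posterior
#'     glenoid line and the line from the glenoid centre to the medial
#'     scapular border, referenced to perpendicular (a face perpendicular
#'     to the scapular axis reads 0); positive when the face tilts
#'     posteriorly.}
#'   \item{inclination_angle}{signed angle between the inferior-superior
#'     glenoid line and the supraspinatus fossa floor line, referenced to
#'     perpendicular; positive for superior inclination.}
#'   \item{critical_shoulder_angle}{angle at the inferior glenoid between
#'     the glenoid line and the line to the lateral acromion.}
#'   \item{rsa_angle}{angle between the line from the inferior glenoid to
#'     the lateral supraspinatus fossa and the perpendicular erected on the
#'     fossa floor line; positive for a medial tilt.}
#' }
#'
#' @param l a `scap_landmarks`.
#' @return scalar measurement (mm or degrees).
#' @export
glenoid_height <- function(l) {
  .lm_check(l)
  h <- sqrt(sum((l$glenoid_superior - l$glenoid_inferior)^2))
  .assert(h > 1e-6, "degenerate geometry: coincident superior/inferior rim")
  h
}

#' @rdname glenoid_height
#' @export
glenoid_width <- function(l) {
  .lm_check(l)
  w <- sqrt(sum((l$glenoid_anterior - l$glenoid_posterior)^2))
  .assert(w > 1e-6, "degenerate geometry: coincident anterior/posterior rim")
  w
}

#' @rdname glenoid_height
#' @export
retroversion <- function(l) {
  .lm_check(l)
  ap <- .unit(l$glenoid_posterior - l$glenoid_anterior)
  md <- .unit(l$medial_scapula_edge - l$glenoid_center)
  asin(.clamp1(sum(ap * md))) * 180 / pi
}

#' @rdname glenoid_height
#' @export
inclination_angle <- function(l) {
  .lm_check(l)
  si <- .unit(l$glenoid_superior - l$glenoid_inferior)
  asin(.clamp1(sum(si * .unit(l$fossa_floor_direction)))) * 180 / pi
}

#' @rdname glenoid_height
#' @export
critical_shoulder_angle <- function(l) {
  .lm_check(l)
  a <- l$lateral_acromion - l$glenoid_inferior
  .assert(sqrt(sum(a^2)) > 1e-6,
          "degenerate geometry: acromion coincides with the inferior glenoid")
  .angle_deg(l$glenoid_superior - l$glenoid_inferior, a)
}

#' @rdname glenoid_height
#' @export
rsa_angle <- function(l) {
  .lm_check(l)
  fl <- .unit(l$lateral_supraspinatus_fossa - l$glenoid_inferior)
  asin(.clamp1(-sum(fl * .unit(l$fossa_floor_direction)))) * 180 / pi
}

#' Compute all six glenoid measurements
#'
#' @param l a `scap_landmarks`, or use [measure_mask()] to go straight from
#'   a binary mask.
#' @return a `scap_measurements` named list: glenoid_height, glenoid_width
#'   (mm), retroversion, inclination_angle, critical_shoulder_angle,
#'   rsa_angle (degrees).
#' @export
measure_landmarks <- function(l) {
  structure(list(glenoid_height = glenoid_height(l),
                 glenoid_width = glenoid_width(l),
                 retroversion = retroversion(l),
                 inclination_angle = inclination_angle(l),
                 critical_shoulder_angle = critical_shoulder_angle(l),
                 rsa_angle = rsa_angle(l)),
            class = "scap_measurements")
}

#' @rdname measure_landmarks
#' @param m a `scap_mask`.
#' @export
measure_mask <- function(m) measure_landmarks(extract_landmarks(m))

#' @export
print.scap_measurements <- function(x, ...) {
  cat("<scap_measurements>\n")
  units <- c(glenoid_height = "mm", glenoid_width = "mm", retroversion = "deg",
             inclination_angle = "deg", critical_shoulder_angle = "deg",
             rsa_angle = "deg")
  for (nm in names(x))
    cat(sprintf("  %-24s %8.2f %s\n", nm, x[[nm]], units[[nm]]))
  invisible(x)
}

#' Directed surface-distance map between two masks
#'
#' For every surface voxel of `a`, the Euclidean distance (mm, exact
#' distance transform with anisotropic spacing) to the nearest surface
#' voxel of `b`. Directed: call with arguments swapped for the reverse map.
#'
#' @param a,b `scap_mask` objects on the same grid.
#' @return a `scap_surface_distances` list with `distances` (mm, one per
#'   surface voxel of `a`), `mean`, `max`.
#' @export
surface_distance_map <- function(a, b) {
  aa <- .grid_data(a); ba <- .grid_data(b)
  .assert(all(dim(aa) == dim(ba)), "masks must share one grid")
  sp <- .grid_spacing(a)
  .assert(any(aa == 1) && any(ba == 1), "surface distances need non-empty masks")
  d <- dim(aa)
  sa <- array(cpp_surface_voxels(aa == 1, d), d)
  sb <- array(cpp_surface_voxels(ba == 1, d), d)
  edt <- array(cpp_edt(sb, d, sp), d)
  dist <- edt[sa]
  structure(list(distances = dist, mean = mean(dist), max = max(dist)),
            class = "scap_surface_distances")
}

#' @export
print.scap_surface_distances <- function(x, ...) {
  cat(sprintf("<scap_surface_distances> n=%d mean=%.3f mm max=%.3f mm\n",
              length(x$distances), x$mean, x$max))
  invisible(x)
}

#' Compare per-measurement trial means between two modalities
#'
#' For each measurement, the absolute difference of the per-modality trial
#' means, with a report column rounded half away from zero to two decimals
#' (the convention used in published measurement tables).
#'
#' @param trials_a,trials_b named lists of numeric trial vectors (same
#'   names, at least one trial each).
#' @return data.frame with columns measurement, mean_a, mean_b,
#'   mean_difference, mean_difference_2dp.
#' @export
compare_measurements <- function(trials_a, trials_b) {
  .assert(length(trials_a) > 0 && setequal(names(trials_a), names(trials_b)),
          "trial lists must share the same non-empty measurement names")
  nm <- names(trials_a)
  rows <- lapply(nm, function(k) {
    a <- trials_a[[k]]; b <- trials_b[[k]]
    .assert(length(a) >= 1 && length(b) >= 1,
            "measurement %s needs at least one trial per modality", k)
    md <- abs(mean(a) - mean(b))
    data.frame(measurement = k, mean_a = mean(a), mean_b = mean(b),
               mean_difference = md,
               mean_difference_2dp = round_half_away(md, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Example paired MRI/CT glenoid measurement trials
#'
#' Two glenoid measurement sessions (trials) per modality for two subjects
#' with matching MRI-derived and CT-derived bone models, as used to
#' demonstrate [compare_measurements()].
#'
#' @return data.frame with columns patient, measurement, modality, trial,
#'   value (mm for height/width, degrees for the angles).
#' @export
glenoid_trials_example <- function() {
  vals <- list(
    "056" = list(
      glenoid_width           = list(mri = c(27.52, 26.88), ct = c(28.37, 28.60)),
      glenoid_height          = list(mri = c(43.05, 40.94), ct = c(39.12, 37.96)),
      inclination_angle       = list(mri = c(97.48, 99.32), ct = c(95.73, 97.53)),
      retroversion            = list(mri = c(0.74, -0.50),  ct = c(4.69, 2.08)),
      critical_shoulder_angle = list(mri = c(30.45, 31.63), ct = c(27.43, 29.21)),
      rsa_angle               = list(mri = c(7.87, 11.30),  ct = c(10.74, 12.93))),
    "057" = list(
      glenoid_width           = list(mri = c(31.15, 31.23), ct = c(33.06, 32.97)),
      glenoid_height          = list(mri = c(48.89, 46.47), ct = c(46.70, 45.78)),
      inclination_angle       = list(mri = c(69.89, 69.25), ct = c(66.03, 66.49)),
      retroversion            = list(mri = c(32.10, 35.50), ct = c(29.39, 31.45)),
      critical_shoulder_angle = list(mri = c(27.11, 26.65), ct = c(27.20, 26.66)),
      rsa_angle               = list(mri = c(14.18, 15.65), ct = c(16.33, 17.30))))
  rows <- list()
  for (pat in names(vals))
    for (ms in names(vals[[pat]]))
      for (mod in names(vals[[pat]][[ms]])) {
        v <- vals[[pat]][[ms]][[mod]]
        rows[[length(rows) + 1]] <- data.frame(
          patient = pat, measurement = ms, modality = mod,
          trial = seq_along(v), value = v, stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}
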