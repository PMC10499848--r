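# Synthetic scapula phantoms: a geometric union of primitives -- an
# elliptical glenoid disc (rotated by version about the superior-inferior
# axis and by inclination about the anterior-posterior axis), a thin
# tapering blade extending medially, a superior spine ridge offset
# posteriorly (leaving an exposed supraspinatus-fossa floor strip on the
# blade's top edge), a connector and a spherical lateral acromion placed in
# closed form to hit a requested critical shoulder angle. Landmarks are
# known in continuous coordinates before voxelization, so the implied
# measurement set is analytic and every downstream module can be tested
# without patient data.
#
# Local anatomical frame (right side): x = anterior, y = superior,
# z = lateral. A left-sided phantom mirrors the lateral axis. The whole
# bone can be rigidly rotated (Euler angles) and translated inside the
# grid; all truth landmarks are transformed identically.

#' Phantom specification
#'
#' All physical sizes in mm, angles in degrees. `version` is positive for
#' anteversion (so a retroverted glenoid has negative version and a
#' positive [retroversion()] readout); `inclination` is positive superior.
#' `csa` is met exactly by construction; `rsa` is met unless the implied
#' fossa endpoint would collide with the articular disc, in which case the
#' endpoint is clamped medially and the realized (stored) RSA angle grows.
#'
#' @param glenoid_height,glenoid_width glenoid ellipse diameters (mm);
#'   height must exceed width by at least 2 mm (anatomical, and required
#'   for unambiguous axis identification).
#' @param version,inclination glenoid face orientation (degrees, each in
#'   (-45, 45)).
#' @param glenoid_thickness articular disc thickness (mm, in \[3, 6\]).
#' @param blade_length medial extent of the blade from the glenoid face
#'   centre (mm).
#' @param blade_thickness blade plate thickness (mm).
#' @param csa,rsa target critical shoulder angle and RSA angle (degrees).
#' @param side "right" or "left".
#' @param shape grid extent in voxels (length 3).
#' @param spacing voxel spacing (mm, length 3).
#' @param orientation rigid rotation of the whole bone (Euler angles,
#'   degrees, about the grid axes).
#' @param center physical position (mm) of the bone's bounding-box centre;
#'   default grid centre.
#' @return a `scap_phantom_spec`.
#' @export
phantom_spec <- function(glenoid_height = 38, glenoid_width = 28,
                         version = -2, inclination = 5,
                         glenoid_thickness = 6, blade_length = 55,
                         blade_thickness = 4, csa = 32, rsa = 12,
                         side = c("right", "left"),
                         shape = c(192, 192, 192),
                         spacing = c(0.5, 0.5, 0.5),
                         orientation = c(0, 0, 0), center = NULL) {
  side <- match.arg(side)
  .assert(glenoid_height > 0 && glenoid_width > 0 &&
            glenoid_height >= glenoid_width + 2,
          "glenoid height must exceed width by at least 2 mm")
  .assert(abs(version) < 45 && abs(inclination) < 45,
          "version and inclination must lie in (-45, 45) degrees")
  .assert(glenoid_thickness >= 3 && glenoid_thickness <= 6,
          "glenoid_thickness must lie in [3, 6] mm")
  .assert(blade_length > glenoid_width, "blade_length too short")
  .assert(blade_thickness >= 2 && blade_thickness <= 8,
          "blade_thickness must lie in [2, 8] mm")
  .assert(csa > 10 && csa < 60, "csa target must lie in (10, 60) degrees")
  .assert(rsa > 0 && rsa < 40, "rsa target must lie in (0, 40) degrees")
  .assert(all(shape >= 8) && all(spacing > 0), "invalid grid")
  structure(list(glenoid_height = glenoid_height,
                 glenoid_width = glenoid_width, version = version,
                 inclination = inclination,
                 glenoid_thickness = glenoid_thickness,
                 blade_length = blade_length,
                 blade_thickness = blade_thickness, csa = csa, rsa = rsa,
                 side = side, shape = as.integer(shape),
                 spacing = as.numeric(spacing),
                 orientation = as.numeric(orientation), center = center),
            class = "scap_phantom_spec")
}

# Continuous local-frame geometry shared by the rasterizer and the truth
# landmarks.
.phantom_geometry <- function(spec) {
  h <- spec$glenoid_height; w <- spec$glenoid_width
  t <- spec$glenoid_thickness; tb <- spec$blade_thickness
  d2r <- pi / 180
  Rgl <- .rot_x(spec$inclination) %*% .rot_y(spec$version)
  u <- drop(Rgl %*% c(0, 1, 0))   # in-face superior axis
  v <- drop(Rgl %*% c(1, 0, 0))   # in-face anterior axis
  nrm <- drop(Rgl %*% c(0, 0, 1)) # face normal (lateral)

  sup <- (h / 2) * u; inf <- -(h / 2) * u
  ant <- (w / 2) * v; post <- -(w / 2) * v

  y_top <- h / 2 - 4
  y_bot <- -h / 2 - 5
  z_M <- -spec$blade_length
  z_edge <- -(t + 5)  # blade's lateral border, clear of the face plane

  # supraspinatus fossa floor strip endpoint, solved for the RSA target and
  # clamped clear of the articular face plane (the clamp matters at strong
  # inferior inclination; the realized RSA angle then exceeds the target)
  x_F <- 0.5
  a_span <- sqrt((y_top - inf[2])^2 + (x_F - inf[1])^2)
  zF <- min(inf[3] - a_span * tan(spec$rsa * d2r),
            (-(t + 3) - y_top * nrm[2] - x_F * nrm[1]) / nrm[3])

  # acromion placed in closed form for the CSA target: along the CSA
  # direction from the inferior rim until it sits 12 mm above the superior
  # rim as seen along the glenoid axis
  g_lat <- .unit(c(0, 0, 1) - sum(c(0, 0, 1) * u) * u)
  dirA <- cos(spec$csa * d2r) * u + sin(spec$csa * d2r) * g_lat
  LA <- (h + 12) / cos(spec$csa * d2r)
  A <- inf + LA * dirA
  r_acr <- 6
  S <- A - r_acr * c(0, 0, 1)

  poly <- rbind(c(y_top, zF),            # lateral top (fossa end)
                c(y_top, z_M + 8),       # medial top
                c(0, z_M),               # medial border tip
                c(y_bot, z_edge),        # inferior lateral
                c(y_top - 10, z_edge))   # lateral, below the notch
  # junction overlaps scale with voxel size so thin unions stay
  # 6-connected on coarse, arbitrarily rotated grids; at 0.5 mm they reduce
  # to the nominal 1-2 mm contacts
  msp <- max(spec$spacing)
  # central tab attaching the blade to the back of the articular disc
  tab <- list(x = c(-tb / 2, tb / 2), y = c(-8, 8),
              z = c(z_edge - max(2, 2 * msp), -t + max(1, 2 * msp)))
  ridge <- list(x = c(-tb / 2 - 3, -tb / 2 + max(1, 2 * msp)),
                y = c(y_top - max(0, 2 * msp - 1), y_top + 5),
                z = c(z_M + 8, zF))
  conn_a <- c(-tb / 2 - 1, y_top + 4, zF - 2)
  conn_w <- c(-8, max(A[2], sup[2] + 10), zF - 2)

  list(u = u, v = v, n = nrm, sup = sup, inf = inf, ant = ant, post = post,
       y_top = y_top, y_bot = y_bot, z_M = z_M, z_edge = z_edge, zF = zF,
       x_F = x_F, A = A, S = S, r_acr = r_acr, poly = poly, tab = tab,
       ridge = ridge, conn_a = conn_a, conn_w = conn_w, conn_r = 2,
       h = h, w = w, t = t, tb = tb)
}

# Convex polygon membership in the (y, z) plane; vertices ordered.
.in_poly <- function(y, z, poly) {
  k <- nrow(poly)
  inside <- rep(TRUE, length(y))
  ref <- colMeans(poly)
  for (i in seq_len(k)) {
    p <- poly[i, ]; q <- poly[if (i == k) 1 else i + 1, ]
    cr <- (y - p[1]) * (q[2] - p[2]) - (z - p[2]) * (q[1] - p[1])
    crr <- (ref[1] - p[1]) * (q[2] - p[2]) - (ref[2] - p[2]) * (q[1] - p[1])
    inside <- inside & (cr * sign(crr) >= -1e-9)
  }
  inside
}

.seg_dist <- function(p, a, b) {
  ab <- b - a
  tt <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
           (p[, 3] - a[3]) * ab[3]) / sum(ab^2)
  tt <- pmin(1, pmax(0, tt))
  dx <- p[, 1] - (a[1] + tt * ab[1])
  dy <- p[, 2] - (a[2] + tt * ab[2])
  dz <- p[, 3] - (a[3] + tt * ab[3])
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Generate a scapula phantom mask with analytic ground truth
#'
#' Voxelizes the phantom onto the requested grid and returns the binary
#' mask together with the continuous truth: landmark coordinates (mm,
#' world frame) and the measurement set implied by them (computed with the
#' same [measure_landmarks()] formulas used on extracted landmarks, so the
#' truth is self-consistent by construction).
#'
#' @param spec a [phantom_spec()].
#' @return list with `mask` (`scap_mask`) and `truth` (list of `landmarks`,
#'   `measurements`, `spec`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  g <- .phantom_geometry(spec)
  d <- spec$shape
  sp <- spec$spacing
  Dm <- diag(c(1, 1, if (spec$side == "left") -1 else 1))
  Rg <- .rot_euler(spec$orientation)
  Mrot <- Rg %*% Dm
  Minv <- Dm %*% t(Rg)  # (Rg Dm)^-1; Dm is its own inverse

  # bounding corners of all primitives (local frame)
  rad_disc <- max(g$h, g$w) / 2 + g$t
  corners <- rbind(
    as.matrix(expand.grid(c(-rad_disc, rad_disc), c(-rad_disc, rad_disc),
                          c(-rad_disc, rad_disc))),
    cbind(g$tb / 2 * c(-1, 1, -1, 1),
          rep(range(g$poly[, 1]), 2)[c(1, 1, 2, 2)],
          rep(range(g$poly[, 2]), each = 2)[c(1, 2, 1, 2)]),
    as.matrix(expand.grid(g$ridge$x, g$ridge$y, g$ridge$z)),
    matrix(rep(g$conn_a, each = 2) + c(-4, 4), 2),
    matrix(rep(g$conn_w, each = 2) + c(-4, 4), 2),
    matrix(rep(g$S, each = 2) + c(-7, 7), 2))
  wc <- t(Mrot %*% t(corners))
  ext <- (d - 1) * sp
  ctr <- spec$center %||% (ext / 2)
  C0 <- ctr - (apply(wc, 2, max) + apply(wc, 2, min)) / 2
  wmin <- apply(wc, 2, min) + C0
  wmax <- apply(wc, 2, max) + C0
  .assert(all(wmin >= -1e-6) && all(wmax <= ext + 1e-6),
          "phantom does not fit the grid (needs %s mm, grid %s mm)",
          paste(sprintf("%.0f", wmax - wmin), collapse = "x"),
          paste(sprintf("%.0f", ext), collapse = "x"))

  arr <- array(0, d)
  rasterize <- function(corners_local, member) {
    wcl <- sweep(t(Mrot %*% t(corners_local)), 2, C0, `+`)
    lo <- pmax(floor(apply(wcl, 2, min) / sp), 0)
    hi <- pmin(ceiling(apply(wcl, 2, max) / sp), d - 1)
    if (any(hi < lo)) return(invisible())
    ii <- lapply(1:3, function(ax) seq(lo[ax], hi[ax]))
    idx <- as.matrix(expand.grid(ii[[1]], ii[[2]], ii[[3]]))
    phys <- sweep(idx, 2, sp, `*`)
    local <- t(Minv %*% (t(phys) - C0))
    sel <- member(local)
    if (any(sel)) {
      lin <- 1 + idx[sel, 1] + d[1] * (idx[sel, 2] + d[2] * idx[sel, 3])
      arr[lin] <<- 1
    }
    invisible()
  }

  # articular disc
  rasterize(corners[1:8, , drop = FALSE], function(q) {
    qn <- q %*% g$n; qu <- q %*% g$u; qv <- q %*% g$v
    qn >= -g$t & qn <= 0 & (qu / (g$h / 2))^2 + (qv / (g$w / 2))^2 <= 1
  })
  # blade (thickness tapers toward the medial tip; floor keeps the thin
  # plate voxelizable on coarse grids)
  min_half <- 0.75 * max(sp)
  conn_r_eff <- max(g$conn_r, 1.6 * max(sp))
  bl_c <- as.matrix(expand.grid(g$tb / 2 * c(-1, 1), range(g$poly[, 1]),
                                range(g$poly[, 2])))
  rasterize(bl_c, function(q) {
    ht <- pmax(g$tb / 2 * pmin(1, pmax(0.15, (q[, 3] - g$z_M) / 15)),
               min_half)
    abs(q[, 1]) <= ht & .in_poly(q[, 2], q[, 3], g$poly)
  })
  # attachment tab (disc back face to blade border)
  rasterize(as.matrix(expand.grid(g$tab$x, g$tab$y, g$tab$z)), function(q) {
    q[, 1] >= g$tab$x[1] & q[, 1] <= g$tab$x[2] &
      q[, 2] >= g$tab$y[1] & q[, 2] <= g$tab$y[2] &
      q[, 3] >= g$tab$z[1] & q[, 3] <= g$tab$z[2]
  })
  # spine ridge
  rasterize(as.matrix(expand.grid(g$ridge$x, g$ridge$y, g$ridge$z)),
            function(q) {
    q[, 1] >= g$ridge$x[1] & q[, 1] <= g$ridge$x[2] &
      q[, 2] >= g$ridge$y[1] & q[, 2] <= g$ridge$y[2] &
      q[, 3] >= g$ridge$z[1] & q[, 3] <= g$ridge$z[2]
  })
  # connector capsules and acromion sphere
  cap_c <- rbind(matrix(rep(g$conn_a, each = 2) + c(-4, 4), 2),
                 matrix(rep(g$conn_w, each = 2) + c(-4, 4), 2))
  rasterize(as.matrix(expand.grid(range(cap_c[, 1]), range(cap_c[, 2]),
                                  range(cap_c[, 3]))),
            function(q) .seg_dist(q, g$conn_a, g$conn_w) <= conn_r_eff)
  cap_c2 <- rbind(matrix(rep(g$conn_w, each = 2) + c(-4, 4), 2),
                  matrix(rep(g$S, each = 2) + c(-4, 4), 2))
  rasterize(as.matrix(expand.grid(range(cap_c2[, 1]), range(cap_c2[, 2]),
                                  range(cap_c2[, 3]))),
            function(q) .seg_dist(q, g$conn_w, g$S) <= conn_r_eff)
  rasterize(matrix(rep(g$S, each = 2) + c(-7, 7), 2), function(q) {
    sqrt((q[, 1] - g$S[1])^2 + (q[, 2] - g$S[2])^2 + (q[, 3] - g$S[3])^2) <=
      g$r_acr
  })

  lab <- cpp_label_components(arr == 1, d, 6L)
  ncomp <- max(lab)
  if (ncomp != 1) {
    # sharp polygon corners can voxelize to isolated voxels; the continuous
    # union is connected, so such fragments are cleanup, not disconnection
    counts <- tabulate(lab[lab > 0], ncomp)
    major <- which.max(counts)
    stray <- setdiff(seq_len(ncomp), major)
    .assert(all(counts[stray] <= 8),
            "phantom generation failed: %d disconnected components (sizes %s)",
            ncomp, paste(sort(counts, decreasing = TRUE), collapse = "/"))
    arr[lab > 0 & lab != major] <- 0
  }

  to_world <- function(p) drop(Mrot %*% p) + C0
  lms <- structure(list(
    glenoid_superior = to_world(g$sup),
    glenoid_inferior = to_world(g$inf),
    glenoid_anterior = to_world(g$ant),
    glenoid_posterior = to_world(g$post),
    glenoid_center = to_world(c(0, 0, 0)),
    medial_scapula_edge = to_world(c(0, 0, g$z_M)),
    lateral_supraspinatus_fossa = to_world(c(g$x_F, g$y_top, g$zF)),
    fossa_floor_point = to_world(c(g$x_F, g$y_top, (g$z_M + 8 + g$zF) / 2)),
    fossa_floor_direction = drop(Mrot %*% c(0, 0, 1)),
    lateral_acromion = to_world(g$A)),
    class = "scap_landmarks",
    frame = list(lateral = drop(Mrot %*% c(0, 0, 1)),
                 superior = drop(Mrot %*% g$u),
                 anterior = drop(Mrot %*% g$v)))

  list(mask = as_mask(arr, sp),
       truth = list(landmarks = lms, measurements = measure_landmarks(lms),
                    spec = spec))
}

#' Render an MRI-like intensity volume from a phantom mask
#'
#' Emulates desk-scale fat-saturated T2-like contrast: dark background,
#' bright soft-tissue shell around the bone, low-intensity bone; a smooth
#' multiplicative bias field emulates coil-gain artifacts and additive
#' Gaussian noise is applied last (intensities clamped at zero).
#'
#' @param m a `scap_mask`.
#' @param noise_sd additive noise SD, as a fraction of the volume maximum.
#' @param bias_amplitude peak relative amplitude of the bias field.
#' @param seed optional integer seed.
#' @return a `scap_volume`.
#' @export
render_intensity <- function(m, noise_sd = 0.02, bias_amplitude = 0.2,
                             seed = NULL) {
  arr <- .grid_data(m)
  sp <- .grid_spacing(m)
  d <- dim(arr)
  .with_seed(seed, {
    sm <- array(cpp_gauss_blur(arr, d, 2 / sp), d)
    shell <- sm > 0.04 & arr == 0
    # soft-tissue body: an ellipsoid filling most of the field of view plus
    # the peri-osseous shell, so the bright-voxel fraction resembles a real
    # shoulder acquisition (the 85th-percentile normalization step assumes
    # a substantial tissue fraction)
    ctr <- (d - 1) / 2
    semi <- 0.45 * (d - 1)
    body <- array(FALSE, d)
    bx <- ((seq_len(d[1]) - 1 - ctr[1]) / semi[1])^2
    by <- ((seq_len(d[2]) - 1 - ctr[2]) / semi[2])^2
    bz <- ((seq_len(d[3]) - 1 - ctr[3]) / semi[3])^2
    body[] <- outer(outer(bx, by, `+`), bz, `+`) <= 1
    tissue <- (body | sm > 0.01) & arr == 0 & !shell
    v <- 300 * arr + 1000 * shell + 700 * tissue
    if (bias_amplitude > 0) {
      cd <- pmax(2L, as.integer(ceiling(d / 16)) + 1L)
      coarse <- array(stats::rnorm(prod(cd)), cd)
      coarse <- array(cpp_gauss_blur(coarse, cd, c(2, 2, 2)), cd)
      cc <- sweep(.coord_grid(d), 2, (cd - 1) / pmax(d - 1, 1), `*`)
      field <- cpp_resample(coarse, cd, cc, FALSE, 0)
      field <- field / max(abs(field))
      v <- v * (1 + bias_amplitude * array(field, d))
    }
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd * max(v))
    as_volume(pmax(v, 0), sp)
  })
}

#' Default cohort sampling ranges
#' @return named list of c(min, max) ranges for the phantom parameters.
#' @export
cohort_ranges <- function() {
  list(glenoid_height = c(30, 50), glenoid_width = c(22, 34),
       version = c(-15, 5), inclination = c(-15, 15),
       csa = c(25, 38), rsa = c(8, 18), orientation = c(-10, 10))
}

#' Generate a cohort of synthetic scapula phantoms
#'
#' Draws phantom parameters uniformly from the given ranges (glenoid
#' height is kept at least 2 mm above width), voxelizes each phantom and
#' renders its intensity volume. Reproducible under `seed`.
#'
#' @param n number of phantoms.
#' @param ranges parameter ranges as in [cohort_ranges()].
#' @param shape,spacing cohort grid (default 160^3 at 0.75 mm isotropic).
#' @param noise_sd,bias_amplitude rendering parameters.
#' @param seed optional integer seed.
#' @param dir optional directory: writes `phantom_###_{image,mask}.nii.gz`
#'   plus `truth.json`.
#' @return list of per-subject lists `(volume, mask, truth)`.
#' @export
generate_cohort <- function(n, ranges = cohort_ranges(),
                            shape = c(160, 160, 160),
                            spacing = c(0.75, 0.75, 0.75),
                            noise_sd = 0.02, bias_amplitude = 0.2,
                            seed = NULL, dir = NULL) {
  .assert(n >= 1, "n must be >= 1")
  .assert(all(vapply(ranges, function(r) length(r) == 2 && r[2] >= r[1],
                     logical(1))), "invalid ranges")
  .with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      draw <- function(nm) stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
      w <- draw("glenoid_width")
      h <- max(draw("glenoid_height"), w + 2.5)
      spc <- phantom_spec(
        glenoid_height = h, glenoid_width = w, version = draw("version"),
        inclination = draw("inclination"), csa = draw("csa"),
        rsa = draw("rsa"), shape = shape, spacing = spacing,
        orientation = stats::runif(3, ranges$orientation[1],
                                   ranges$orientation[2]))
      ph <- generate_phantom(spc)
      vol <- render_intensity(ph$mask, noise_sd, bias_amplitude)
      out[[i]] <- list(volume = vol, mask = ph$mask, truth = ph$truth)
    }
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      truths <- list()
      for (i in seq_len(n)) {
        id <- sprintf("phantom_%03d", i)
        write_volume(out[[i]]$volume, file.path(dir, paste0(id, "_image.nii.gz")))
        write_volume(out[[i]]$mask, file.path(dir, paste0(id, "_mask.nii.gz")))
        tr <- out[[i]]$truth
        truths[[id]] <- list(
          landmarks = lapply(unclass(tr$landmarks), as.numeric),
          measurements = unclass(tr$measurements))
      }
      jsonlite::write_json(truths, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out
  })
}
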