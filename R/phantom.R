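#' Specify a synthetic colonic crypt
#'
#' A crypt is modelled as a tube descending from the mucosal surface
#' (`z = 0`) into the tissue. Its centerline is a helix of radius
#' `helix_radius` completing `helix_turns` full revolutions over `depth`,
#' superimposed on an axis tilted by `axis_tilt` degrees toward
#' `tilt_azimuth`. Positive `helix_turns` is counterclockwise when viewed
#' from the mucosal surface looking into the tissue (increasing
#' `atan2(y, x)` with depth); negative is clockwise.
#'
#' @param crypt_id Integer identifier.
#' @param base_x,base_y Surface anchor of the crypt axis (um).
#' @param depth Extent below the surface (um), > 0.
#' @param tube_radius Outer tube radius (um); a length-2 vector gives a
#'   linearly varying radius from surface to bottom.
#' @param helix_radius Radial offset of the centerline from the axis (um).
#' @param helix_turns Signed number of full revolutions over `depth`.
#' @param axis_tilt Polar tilt of the crypt axis (degrees, |tilt| < 30).
#' @param tilt_azimuth Direction of the tilt in the xy-plane (degrees).
#' @param phase Starting azimuth of the helix (degrees).
#' @param goblet_density Goblet mucus blobs per 100 um of centerline.
#' @param lumen_fraction Lumen radius / tube radius, in `[0, 1)`.
#' @return One-row tibble; rows from several calls can be `dplyr::bind_rows()`ed
#'   into a specimen's crypt table.
#' @export
crypt_spec <- function(crypt_id, base_x, base_y, depth = 250,
                       tube_radius = 35, helix_radius = 0, helix_turns = 0,
                       axis_tilt = 0, tilt_azimuth = 0, phase = 0,
                       goblet_density = 4, lumen_fraction = 0.55) {
  vals <- c(base_x, base_y, depth, tube_radius, helix_radius, helix_turns,
            axis_tilt, tilt_azimuth, phase, goblet_density, lumen_fraction)
  if (any(!is.finite(vals))) stop("non-finite crypt parameter", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (any(tube_radius <= 0)) stop("tube_radius must be > 0", call. = FALSE)
  if (lumen_fraction < 0 || lumen_fraction >= 1) {
    stop("lumen_fraction must be in [0, 1)", call. = FALSE)
  }
  if (abs(axis_tilt) >= 30) stop("|axis_tilt| must be < 30 degrees", call. = FALSE)
  tibble::tibble(
    crypt_id = as.integer(crypt_id), base_x = base_x, base_y = base_y,
    depth = depth,
    tube_radius_top = tube_radius[1],
    tube_radius_bottom = tube_radius[length(tube_radius)],
    helix_radius = helix_radius, helix_turns = helix_turns,
    axis_tilt = axis_tilt, tilt_azimuth = tilt_azimuth, phase = phase,
    goblet_density = goblet_density, lumen_fraction = lumen_fraction
  )
}

#' Specify per-crypt inflammation
#'
#' @param crypt_id Crypt the pattern applies to.
#' @param pattern `"none"`, `"cryptitis"` (individual neutrophils in the
#'   lumen, biased to the crypt bottom) or `"abscess"` (a contiguous
#'   neutrophil mass filling the lower lumen, with a breach in the crypt
#'   wall emulating disrupted epithelium).
#' @param neutrophil_count Number of individual neutrophils to place.
#' @param neutrophil_radius Cell radius in um (default 5, i.e. 10 um diameter).
#' @param placement_bias Fraction of cells placed in the bottom third of the
#'   crypt (the remainder are uniform over the upper two thirds).
#' @param abscess_fill Fraction of the crypt depth occupied by the abscess
#'   plug (abscess pattern only).
#' @return One-row tibble.
#' @export
inflammation_spec <- function(crypt_id, pattern = c("none", "cryptitis", "abscess"),
                              neutrophil_count = 0, neutrophil_radius = 5,
                              placement_bias = 1 / 3, abscess_fill = 0.3) {
  pattern <- match.arg(pattern)
  if (neutrophil_count < 0) stop("neutrophil_count must be >= 0", call. = FALSE)
  if (neutrophil_radius <= 0) stop("neutrophil_radius must be > 0", call. = FALSE)
  tibble::tibble(
    crypt_id = as.integer(crypt_id), pattern = pattern,
    neutrophil_count = as.integer(neutrophil_count),
    neutrophil_radius = neutrophil_radius,
    placement_bias = placement_bias, abscess_fill = abscess_fill
  )
}

#' Imaging noise model for phantom rendering
#'
#' Additive Gaussian read noise plus multiplicative exponential intensity
#' decay with depth, the simplest model that stresses slice-wise
#' thresholding the way cleared-tissue imaging attenuation does.
#'
#' @param sigma SD of additive Gaussian noise (intensity units; signal is
#'   rendered on a 0-1 scale).
#' @param attenuation_rate Decay rate per um of depth; intensity at depth z
#'   is multiplied by `exp(-attenuation_rate * z)`.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma = 0, attenuation_rate = 0) {
  stopifnot(sigma >= 0, attenuation_rate >= 0)
  structure(list(sigma = sigma, attenuation_rate = attenuation_rate),
            class = "noise_model")
}

# centerline position at physical depths z (vectorised)
centerline_xy <- function(spec, z) {
  tilt <- spec$axis_tilt * pi / 180
  az <- spec$tilt_azimuth * pi / 180
  theta <- spec$phase * pi / 180 + 2 * pi * spec$helix_turns * z / spec$depth
  list(
    x = spec$base_x + z * tan(tilt) * cos(az) + spec$helix_radius * cos(theta),
    y = spec$base_y + z * tan(tilt) * sin(az) + spec$helix_radius * sin(theta)
  )
}

tube_radius_at <- function(spec, z) {
  spec$tube_radius_top +
    (spec$tube_radius_bottom - spec$tube_radius_top) * z / spec$depth
}

#' Analytic crypt centerline
#'
#' Samples the exact (noise-free) centerline of a [crypt_spec()] at a fixed
#' z step from the surface to the crypt bottom.
#'
#' @param spec One-row crypt spec tibble.
#' @param step z spacing in um (0 < step <= depth).
#' @return Tibble with columns `z_um`, `x_um`, `y_um`, ordered by depth.
#' @export
generate_centerline <- function(spec, step = 50) {
  spec <- as.list(spec[1, ])
  if (!is.finite(step) || step <= 0 || step > spec$depth) {
    stop("step must satisfy 0 < step <= depth", call. = FALSE)
  }
  z <- seq(0, spec$depth, by = step)
  p <- centerline_xy(spec, z)
  tibble::tibble(z_um = z, x_um = p$x, y_um = p$y)
}

# exact covariance of the filled tube: covariance of the centerline path
# (z uniform over the clipped depth) plus the in-plane disk second moment
# r(z)^2/4; cross-sections in z-planes are disks, so this is exact up to
# the dense-z quadrature.
analytic_crypt_moments <- function(spec, max_depth = 250, dz = 0.5) {
  d <- min(spec$depth, max_depth)
  z <- seq(0, d, by = dz)
  p <- centerline_xy(spec, z)
  r2 <- tube_radius_at(spec, z)^2
  pts <- cbind(p$x, p$y, z)
  C <- stats::cov(pts) * (length(z) - 1) / length(z)  # population covariance
  C[1, 1] <- C[1, 1] + mean(r2) / 4
  C[2, 2] <- C[2, 2] + mean(r2) / 4
  C
}

# analytic truth values for one crypt spec
analytic_truth <- function(spec, max_depth = 250, centerline_step = 50,
                           twist_threshold = 90,
                           ellipticity_fun = ellipticity_prolate) {
  cl <- generate_centerline(spec, step = centerline_step)
  spec <- as.list(spec[1, ])
  d <- min(spec$depth, max_depth)
  zfine <- seq(0, d, by = 0.5)
  vol <- pi * mean(tube_radius_at(spec, zfine)^2) * d
  ax <- sort(sqrt(5 * pmax(eigen(analytic_crypt_moments(spec, max_depth),
                                 symmetric = TRUE)$values, 0)))
  cl <- cl[cl$z_um <= d + 1e-9, ]
  tort <- tortuosity(cl)
  twist <- 360 * spec$helix_turns * (max(cl$z_um) / spec$depth)
  if (spec$helix_radius == 0) twist <- 0
  tibble::tibble(
    crypt_id = spec$crypt_id,
    volume_um3 = vol,
    semi_a = ax[1], semi_b = ax[2], semi_c = ax[3],
    ellipticity_prolate = ellipticity_fun(ax[1], ax[2], ax[3]),
    tortuosity = tort,
    net_twist_deg = twist,
    chirality = classify_chirality(twist, twist_threshold),
    depth_used = d
  )
}

#' Paint a solid sphere into a voxel volume
#'
#' Utility for building fixtures and for neutrophil/goblet rendering: sets
#' all voxels whose centres lie within `radius_um` of `center_um` to
#' `intensity` (maximum with the existing value).
#'
#' @param arr Numeric 3D array (modified copy returned).
#' @param voxel_size `(x, y, z)` spacing in um.
#' @param center_um Physical centre `(x, y, z)` in um.
#' @param radius_um Sphere radius in um.
#' @param intensity Value to paint.
#' @return The modified array.
#' @export
paint_sphere <- function(arr, voxel_size, center_um, radius_um, intensity = 1) {
  paint_ellipsoid(arr, voxel_size, center_um, rep(radius_um, 3), intensity)
}

#' Paint a solid axis-aligned ellipsoid into a voxel volume
#'
#' @inheritParams paint_sphere
#' @param semi_axes_um Semi-axes `(x, y, z)` in um.
#' @export
paint_ellipsoid <- function(arr, voxel_size, center_um, semi_axes_um,
                            intensity = 1) {
  d <- dim(arr)
  a <- semi_axes_um
  lo <- pmax(1L, floor((center_um - a) / voxel_size + 0.5))
  hi <- pmin(d, ceiling((center_um + a) / voxel_size + 0.5))
  if (any(lo > hi)) return(arr)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  cx <- ((xs - 0.5) * voxel_size[1] - center_um[1]) / a[1]
  cy <- ((ys - 0.5) * voxel_size[2] - center_um[2]) / a[2]
  cz <- ((zs - 0.5) * voxel_size[3] - center_um[3]) / a[3]
  dist2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  sub <- arr[xs, ys, zs, drop = FALSE]
  sel <- dist2 <= 1
  sub[sel] <- pmax(sub[sel], intensity)
  arr[xs, ys, zs] <- sub
  arr
}

#' Rasterize a specimen phantom
#'
#' Renders crypt specs into a PAFhy-like intensity channel: a bright
#' basement-membrane shell at the outer tube boundary, a dimmer wall,
#' goblet-cell mucus blobs inside the wall, and neutrophils per the
#' inflammation table (bright spheres; the abscess pattern fills the lower
#' lumen contiguously and breaches the wall). An optional nuclear
#' counterstain channel carries random speckle. Additive Gaussian noise and
#' exponential depth attenuation are applied per `noise`.
#'
#' Rendering intensities (0-1 scale): membrane 0.9, wall 0.35, goblet 0.7,
#' neutrophil 0.95, background 0.02.
#'
#' @param specs Tibble of [crypt_spec()] rows.
#' @param inflammation Optional tibble of [inflammation_spec()] rows.
#' @param shape Grid size `(nx, ny, nz)` in voxels.
#' @param voxel_size `(x, y, z)` spacing in um (default 2 um isotropic).
#' @param noise A [noise_model()].
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @param group_label Specimen group (`"UC"`, `"CD"`, `"non-IBD"`).
#' @param specimen_id Identifier recorded in the truth table.
#' @param membrane_thickness Basement-membrane shell thickness in um.
#' @param include_nuclear Render the nuclear speckle channel.
#' @param overlap_tolerance Allowed fractional overlap of neighbouring tube
#'   radii before generation fails (ground truth would become ambiguous).
#' @param max_depth Depth normalization used for the analytic truth table (um).
#' @return A `specimen_phantom`: list with `volumes` (named [voxel_volume()]s),
#'   `voxel_size`, `crypt_specs`, `inflammation`, `truth` (analytic per-crypt
#'   morphometry), `group_label`, `specimen_id`, `seed`.
#' @export
rasterize_specimen <- function(specs, inflammation = NULL,
                               shape = c(192, 192, 128), voxel_size = 2,
                               noise = noise_model(), seed = 1,
                               group_label = "non-IBD", specimen_id = "S1",
                               membrane_thickness = 4,
                               include_nuclear = FALSE,
                               overlap_tolerance = 0.05,
                               max_depth = 250) {
  voxel_size <- if (length(voxel_size) == 1) rep(voxel_size, 3) else voxel_size
  stopifnot(all(voxel_size > 0), nrow(specs) >= 1)
  d <- as.integer(shape)
  ext <- d * voxel_size

  # fit + overlap checks on a coarse z grid
  zchk <- seq(0, max(specs$depth), by = 10)
  for (i in seq_len(nrow(specs))) {
    si <- as.list(specs[i, ])
    zi <- zchk[zchk <= si$depth]
    p <- centerline_xy(si, zi)
    r <- tube_radius_at(si, zi)
    if (any(p$x - r < 0) || any(p$x + r > ext[1]) ||
        any(p$y - r < 0) || any(p$y + r > ext[2]) || si$depth > ext[3]) {
      stop("crypt ", si$crypt_id, " does not fit inside the grid", call. = FALSE)
    }
    if (i > 1) for (j in seq_len(i - 1)) {
      sj <- as.list(specs[j, ])
      zj <- zchk[zchk <= min(si$depth, sj$depth)]
      pi_ <- centerline_xy(si, zj); pj <- centerline_xy(sj, zj)
      gap <- sqrt((pi_$x - pj$x)^2 + (pi_$y - pj$y)^2)
      lim <- (tube_radius_at(si, zj) + tube_radius_at(sj, zj)) * (1 - overlap_tolerance)
      if (any(gap < lim)) {
        stop("crypts ", si$crypt_id, " and ", sj$crypt_id,
             " overlap beyond tolerance", call. = FALSE)
      }
    }
  }

  set.seed(seed)
  bg <- 0.02
  pafhy <- array(bg, d)
  wall_mask <- array(FALSE, d)   # basement membrane + wall voxels
  lumen_mask <- array(FALSE, d)

  xs_um <- (seq_len(d[1]) - 0.5) * voxel_size[1]
  ys_um <- (seq_len(d[2]) - 0.5) * voxel_size[2]

  inflammation <- inflammation %||%
    dplyr::bind_rows(lapply(specs$crypt_id, inflammation_spec, pattern = "none"))

  # the rendered shell must stay contiguous at coarse voxel pitches
  membrane_thickness <- max(membrane_thickness, 1.5 * max(voxel_size))

  for (i in seq_len(nrow(specs))) {
    si <- as.list(specs[i, ])
    infl <- inflammation[inflammation$crypt_id == si$crypt_id, ]
    breach_z <- if (nrow(infl) && infl$pattern[1] == "abscess") {
      si$depth * (1 - infl$abscess_fill[1] / 2)  # breach mid-plug
    } else NA_real_
    for (k in seq_len(d[3])) {
      z <- (k - 0.5) * voxel_size[3]
      if (z > si$depth) next
      ctr <- centerline_xy(si, z)
      r_out <- tube_radius_at(si, z)
      r_lum <- r_out * si$lumen_fraction
      xr <- which(abs(xs_um - ctr$x) <= r_out + voxel_size[1])
      yr <- which(abs(ys_um - ctr$y) <= r_out + voxel_size[2])
      if (!length(xr) || !length(yr)) next
      dist <- sqrt(outer((xs_um[xr] - ctr$x)^2, (ys_um[yr] - ctr$y)^2, `+`))
      sl <- pafhy[xr, yr, k, drop = FALSE]; dim(sl) <- dim(dist)
      wm <- wall_mask[xr, yr, k, drop = FALSE]; dim(wm) <- dim(dist)
      lm <- lumen_mask[xr, yr, k, drop = FALSE]; dim(lm) <- dim(dist)
      memb <- dist <= r_out & dist >= r_out - membrane_thickness
      wall <- dist < r_out - membrane_thickness & dist >= r_lum
      lum <- dist < r_lum
      if (!is.na(breach_z) && abs(z - breach_z) <= 6) {
        # disrupted epithelium: open an angular window in the wall
        ang <- atan2(outer(rep(1, length(xr)), ys_um[yr] - ctr$y),
                     outer(xs_um[xr] - ctr$x, rep(1, length(yr))))
        open <- abs(wrap_angle(ang * 180 / pi)) < 25
        memb[open] <- FALSE
        wall[open] <- FALSE
      }
      sl[wall] <- pmax(sl[wall], 0.12)
      sl[memb] <- pmax(sl[memb], 0.9)
      wm[memb | wall] <- TRUE
      lm[lum] <- TRUE
      pafhy[xr, yr, k] <- sl
      wall_mask[xr, yr, k] <- wm
      lumen_mask[xr, yr, k] <- lm
    }

    # goblet mucus: elongated ellipsoidal blobs inside the wall shell,
    # larger than the neutrophil size gate so cell detection ignores them
    n_gob <- round(si$goblet_density * si$depth / 100)
    if (n_gob > 0) {
      gz <- stats::runif(n_gob, 20, si$depth - 20)
      gaz <- stats::runif(n_gob, 0, 2 * pi)
      for (g in seq_len(n_gob)) {
        ctr <- centerline_xy(si, gz[g])
        r_out <- tube_radius_at(si, gz[g])
        r_mid <- r_out * (si$lumen_fraction + 1) / 2
        gr <- min(5, max((r_out * (1 - si$lumen_fraction)) / 2 - 1, 2))
        pafhy <- paint_ellipsoid(
          pafhy, voxel_size,
          c(ctr$x + r_mid * cos(gaz[g]), ctr$y + r_mid * sin(gaz[g]), gz[g]),
          c(gr, gr, 16), 0.7
        )
      }
    }

    # neutrophils
    if (nrow(infl) && infl$pattern[1] != "none") {
      nr <- infl$neutrophil_radius[1]
      if (infl$pattern[1] == "abscess") {
        # contiguous plug filling the lower lumen
        z0 <- si$depth * (1 - infl$abscess_fill[1])
        for (k in seq_len(d[3])) {
          z <- (k - 0.5) * voxel_size[3]
          if (z < z0 || z > si$depth) next
          ctr <- centerline_xy(si, z)
          r_lum <- tube_radius_at(si, z) * si$lumen_fraction
          xr <- which(abs(xs_um - ctr$x) <= r_lum + voxel_size[1])
          yr <- which(abs(ys_um - ctr$y) <= r_lum + voxel_size[2])
          if (!length(xr) || !length(yr)) next
          dist <- sqrt(outer((xs_um[xr] - ctr$x)^2, (ys_um[yr] - ctr$y)^2, `+`))
          sl <- pafhy[xr, yr, k, drop = FALSE]; dim(sl) <- dim(dist)
          sl[dist < r_lum] <- pmax(sl[dist < r_lum], 0.95)
          pafhy[xr, yr, k] <- sl
        }
      }
      nc <- infl$neutrophil_count[1]
      if (nc > 0) {
        bias <- infl$placement_bias[1]
        in_bottom <- stats::runif(nc) < bias
        placed <- matrix(numeric(0), 0, 3)
        min_gap <- 2 * nr + 2 * max(voxel_size)  # keep cells 26-disconnected
        for (q in seq_len(nc)) {
          for (try in 1:60) {
            zq <- if (in_bottom[q]) {
              stats::runif(1, 2 / 3 * si$depth + nr, si$depth - nr)
            } else {
              stats::runif(1, nr + 2, 2 / 3 * si$depth)
            }
            ctr <- centerline_xy(si, zq)
            r_lum <- tube_radius_at(si, zq) * si$lumen_fraction
            rad <- stats::runif(1, 0, max(r_lum - nr - 2, 0))
            az <- stats::runif(1, 0, 2 * pi)
            pos <- c(ctr$x + rad * cos(az), ctr$y + rad * sin(az), zq)
            clear <- !nrow(placed) ||
              min(sqrt(rowSums(sweep(placed, 2, pos)^2))) >= min_gap
            if (infl$pattern[1] == "abscess" && zq > si$depth * (1 - infl$abscess_fill[1]) - nr) {
              clear <- FALSE  # keep individual cells out of the plug
            }
            if (clear || try == 60) {
              placed <- rbind(placed, pos)
              pafhy <- paint_sphere(pafhy, voxel_size, pos, nr, 0.95)
              break
            }
          }
        }
      }
    }
  }

  # noise model: depth attenuation then additive Gaussian
  if (noise$attenuation_rate > 0) {
    att <- exp(-noise$attenuation_rate * (seq_len(d[3]) - 0.5) * voxel_size[3])
    pafhy <- sweep(pafhy, 3, att, `*`)
  }
  if (noise$sigma > 0) {
    pafhy <- pafhy + stats::rnorm(length(pafhy), 0, noise$sigma)
  }
  pafhy <- pmax(pafhy, 0)

  volumes <- list(PAFhy = voxel_volume(pafhy, voxel_size, "PAFhy"))
  if (include_nuclear) {
    nuc <- array(stats::runif(prod(d), 0, 0.05), d)
    n_nuc <- round(prod(ext[1:2]) / 400)
    for (q in seq_len(n_nuc)) {
      nuc <- paint_sphere(nuc, voxel_size,
                          stats::runif(3, 0, ext), stats::runif(1, 2, 4), 0.6)
    }
    volumes$nuclear <- voxel_volume(nuc, voxel_size, "nuclear")
  }

  truth <- dplyr::bind_rows(lapply(seq_len(nrow(specs)), function(i) {
    analytic_truth(specs[i, ], max_depth = max_depth)
  }))
  truth <- dplyr::mutate(truth,
    specimen_id = specimen_id, group = group_label, .before = 1
  )

  structure(
    list(
      volumes = volumes, voxel_size = voxel_size,
      crypt_specs = specs, inflammation = inflammation,
      truth = truth, lumen_mask = lumen_mask, wall_mask = wall_mask,
      group_label = group_label, specimen_id = specimen_id, seed = seed
    ),
    class = "specimen_phantom"
  )
}

#' @export
print.specimen_phantom <- function(x, ...) {
  cat(sprintf("<specimen_phantom '%s'> group %s, %d crypt(s), seed %d\n",
              x$specimen_id, x$group_label, nrow(x$crypt_specs), x$seed))
  print(x$volumes$PAFhy)
  invisible(x)
}

#' Mirror a specimen phantom in x
#'
#' Reflects all channels (and masks) along the x axis. Reflection inverts
#' handedness: every crypt's ground-truth twist changes sign, which the
#' chirality estimator must reproduce exactly.
#'
#' @param phantom A `specimen_phantom`.
#' @return The reflected phantom (truth table twist/chirality updated).
#' @export
reflect_x <- function(phantom) {
  stopifnot(inherits(phantom, "specimen_phantom"))
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  for (ch in names(phantom$volumes)) {
    phantom$volumes[[ch]]$intensities <- flip(phantom$volumes[[ch]]$intensities)
  }
  phantom$lumen_mask <- flip(phantom$lumen_mask)
  phantom$wall_mask <- flip(phantom$wall_mask)
  phantom$truth$net_twist_deg <- -phantom$truth$net_twist_deg
  phantom$truth$chirality <- unname(
    c(CCW = "CW", CW = "CCW", none = "none")[phantom$truth$chirality]
  )
  phantom$crypt_specs$helix_turns <- -phantom$crypt_specs$helix_turns
  phantom
}
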