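#' Filled crypt body voxels
#'
#' Linear indices of the filled crypt: basement-membrane wall union
#' enclosed lumen. Morphometry treats crypts as filled bodies.
#'
#' @param label_map A `crypt_label_map`.
#' @param crypt_id Crypt label.
#' @return Integer vector of linear indices into the label arrays.
#' @export
crypt_voxels <- function(label_map, crypt_id) {
  which(label_map$labels == crypt_id | label_map$lumen_labels == crypt_id)
}

#' Prolate ellipticity from ellipsoid semi-axes
#'
#' Shape descriptor of the moment-equivalent ellipsoid with semi-axes
#' `a <= b <= c`: `e_p = (c - b) / (c - a)`, which is 1 for an ideal prolate
#' body (`a = b < c`, a cigar such as a straight crypt) and falls toward 0
#' for oblate or spherical bodies (dilated, distorted crypts). A sphere
#' (`a = b = c`) is defined to have `e_p = 0`.
#'
#' The formula is pluggable throughout the package (every caller accepts an
#' `ellipticity_fun`), so an alternative moment-based definition can be
#' substituted without touching the morphometry pipeline.
#'
#' @param a,b,c Semi-axes in um, `0 < a <= b <= c`.
#' @return Dimensionless value in `[0, 1]`.
#' @export
#' @examples
#' ellipticity_prolate(1, 2, 3) # 0.5
ellipticity_prolate <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("semi-axes must be positive", call. = FALSE)
  if (a > b + 1e-9 || b > c + 1e-9) stop("require a <= b <= c", call. = FALSE)
  ifelse(c - a < 1e-12 * c, 0, (c - b) / (c - a))
}

#' Voxel-set volume
#'
#' Volume of a filled crypt body (wall plus lumen) as voxel count times the
#' physical voxel volume.
#'
#' @param voxels Matrix of voxel indices (n x 3) or a logical 3D array.
#' @param voxel_size `(x, y, z)` spacing in um.
#' @return Volume in um^3.
#' @export
compute_volume <- function(voxels, voxel_size) {
  n <- if (is.array(voxels) && length(dim(voxels)) == 3) sum(voxels != 0) else nrow(voxels)
  if (is.null(n) || n == 0) stop("empty voxel set", call. = FALSE)
  n * prod(voxel_size)
}

#' Moment-ellipsoid semi-axes of a voxel set
#'
#' Eigen-decomposition of the second central moment of the filled voxel
#' set; each semi-axis is `sqrt(5 * lambda_i)`, the moment relation for a
#' uniform solid ellipsoid (crypts are analyzed as filled bodies).
#'
#' @inheritParams compute_volume
#' @return Semi-axes `(a, b, c)` in um, sorted ascending.
#' @export
fit_ellipsoid <- function(voxels, voxel_size) {
  if (is.array(voxels) && length(dim(voxels)) == 3) {
    voxels <- arrayInd(which(voxels != 0), dim(voxels))
  }
  if (nrow(voxels) < 4) stop("need >= 4 voxels to fit an ellipsoid", call. = FALSE)
  pts <- sweep(voxels - 0.5, 2, voxel_size, `*`)
  C <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  ev <- eigen(C, symmetric = TRUE)$values
  if (min(ev) < 1e-9 * max(ev)) {
    stop("degenerate (coplanar) voxel set", call. = FALSE)
  }
  sort(sqrt(5 * ev))
}

#' Clip a crypt to a maximum depth below the mucosal surface
#'
#' Retains voxels no deeper than `max_depth` um from the detected mucosal
#' surface (the shallowest z at which the crypt has any labeled voxel),
#' normalizing morphometry across specimens of different thickness.
#'
#' @param label_map A `crypt_label_map` (see [link_sections()]).
#' @param crypt_id Label to clip.
#' @param max_depth Depth limit in um (default 250).
#' @return Integer matrix (n x 3) of retained voxel indices.
#' @export
clip_to_depth <- function(label_map, crypt_id, max_depth = 250) {
  stopifnot(max_depth > 0)
  idx <- crypt_voxels(label_map, crypt_id)
  if (!length(idx)) stop("empty crypt: ", crypt_id, call. = FALSE)
  co <- arrayInd(idx, dim(label_map$labels))
  vz <- label_map$voxel_size[3]
  z_um <- (co[, 3] - 0.5) * vz
  z0 <- min(z_um)
  keep <- z_um - z0 <= max_depth
  if (!any(keep)) stop("crypt entirely below max_depth", call. = FALSE)
  co[keep, , drop = FALSE]
}

#' Extract a crypt centerline by slice-wise centroids
#'
#' One point per sampled optical slice (default every 50 um): the area
#' centroid of the filled crypt cross-section at that depth. For a crypt
#' spanning the full 250 um normalization depth this yields the six points
#' conventionally labeled a-f. A sampled slice with an empty cross-section
#' inside the span is interpolated from its neighbours.
#'
#' @param voxels Voxel index matrix (n x 3), e.g. from [clip_to_depth()].
#' @param voxel_size `(x, y, z)` spacing in um.
#' @param spacing Slice spacing in um (default 50).
#' @return Tibble `(z_um, x_um, y_um)` ordered by increasing depth.
#' @export
extract_centerline <- function(voxels, voxel_size, spacing = 50) {
  stopifnot(spacing > 0)
  pts <- sweep(voxels - 0.5, 2, voxel_size, `*`)
  z0 <- min(pts[, 3]); z1 <- max(pts[, 3])
  # one point per `spacing` of depth; the deepest point sits on the bottom
  # slice even when the voxel span falls just short of a full multiple
  n_int <- floor((z1 - z0 + spacing / 2) / spacing)
  if (n_int < 1) stop("crypt spans fewer than 2 sampled slices", call. = FALSE)
  targets <- pmin(z0 + spacing * (0:n_int), z1)
  half <- voxel_size[3] / 2
  cl <- lapply(targets, function(zt) {
    sel <- abs(pts[, 3] - zt) <= half + 1e-9
    if (!any(sel)) return(c(NA_real_, NA_real_))
    c(mean(pts[sel, 1]), mean(pts[sel, 2]))
  })
  cl <- do.call(rbind, cl)
  miss <- is.na(cl[, 1])
  if (all(miss)) stop("all sampled slices empty", call. = FALSE)
  if (any(miss)) {
    for (j in 1:2) {
      cl[, j] <- stats::approx(targets[!miss], cl[!miss, j], xout = targets,
                               rule = 2)$y
    }
  }
  tibble::tibble(z_um = targets - z0, x_um = cl[, 1], y_um = cl[, 2])
}

#' Centerline tortuosity
#'
#' Ratio of the summed consecutive point-to-point distances to the straight
#' end-to-end distance: for the canonical six 50-um points a-f,
#' `(D_ab + D_bc + D_cd + D_de + D_ef) / D_af`. Equals 1 exactly for a
#' straight crypt and grows with distortion; generalizes to any number of
#' points (>= 2) for crypts shallower than the full normalization depth.
#'
#' @param cl Centerline tibble with `x_um`, `y_um`, `z_um` (or an n x 3
#'   matrix of coordinates).
#' @return Tortuosity `T >= 1` (dimensionless).
#' @export
tortuosity <- function(cl) {
  pts <- if (is.data.frame(cl)) cbind(cl$x_um, cl$y_um, cl$z_um) else as.matrix(cl)
  n <- nrow(pts)
  if (n < 2) stop("need >= 2 centerline points", call. = FALSE)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  chord <- sqrt(sum((pts[n, ] - pts[1, ])^2))
  if (chord < 1e-9 * max(sum(seg), 1)) {
    stop("coincident first/last centerline points: tortuosity undefined", call. = FALSE)
  }
  sum(seg) / chord
}

#' Per-crypt morphometry table
#'
#' Runs the full morphometric battery over every labeled crypt: depth
#' clipping (250 um normalization), filled volume, moment-ellipsoid
#' semi-axes, prolate ellipticity, 50-um centerline, tortuosity, net twist
#' and chirality class.
#'
#' @param label_map A `crypt_label_map` from [link_sections()].
#' @param max_depth Depth normalization in um (default 250).
#' @param centerline_spacing Centerline slice spacing in um (default 50).
#' @param twist_threshold Degrees of net twist required to call a chirality
#'   (default 90).
#' @param ellipticity_fun Pluggable ellipticity definition
#'   (default [ellipticity_prolate()]).
#' @param specimen_id,group Metadata columns added to the output.
#' @return Tibble with one row per crypt: `crypt_id`, `volume_um3`,
#'   `semi_a`/`semi_b`/`semi_c` (um), `ellipticity_prolate`, `tortuosity`,
#'   `net_twist_deg`, `chirality`, `depth_used`, surface anchor
#'   `surface_x_um`/`surface_y_um`, and a `centerline` list-column.
#' @export
measure_crypts <- function(label_map, max_depth = 250, centerline_spacing = 50,
                           twist_threshold = 90,
                           ellipticity_fun = ellipticity_prolate,
                           specimen_id = NA_character_, group = NA_character_) {
  ids <- sort(setdiff(unique(as.integer(label_map$labels)), 0L))
  vx <- label_map$voxel_size
  rows <- lapply(ids, function(k) {
    vox <- clip_to_depth(label_map, k, max_depth)
    vol <- compute_volume(vox, vx)
    ax <- tryCatch(fit_ellipsoid(vox, vx), error = function(e) rep(NA_real_, 3))
    cl <- extract_centerline(vox, vx, centerline_spacing)
    tw <- net_twist(cl)
    tibble::tibble(
      specimen_id = specimen_id, group = group, crypt_id = k,
      volume_um3 = vol,
      semi_a = ax[1], semi_b = ax[2], semi_c = ax[3],
      ellipticity_prolate = if (anyNA(ax)) NA_real_ else ellipticity_fun(ax[1], ax[2], ax[3]),
      tortuosity = tortuosity(cl),
      net_twist_deg = tw,
      chirality = classify_chirality(tw, twist_threshold),
      depth_used = max(cl$z_um),
      surface_x_um = cl$x_um[1], surface_y_um = cl$y_um[1],
      centerline = list(cl)
    )
  })
  dplyr::bind_rows(rows)
}
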