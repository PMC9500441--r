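#' Extract crypt cross-sections slice by slice
#'
#' Determines crypt areas from the PAFhy-positive basement membrane on
#' sampled optical slices: each sampled z-plane is thresholded (Otsu per
#' slice by default, or a fixed intensity for reproducibility runs), holes
#' are filled so the ring-like membrane becomes a filled disk, 2D
#' 8-connected components are extracted, and components are kept when
#' their filled area and circularity fall inside the configured gates.
#'
#' @param vol A [voxel_volume()] (PAFhy channel).
#' @param slice_interval Sampling interval in um (13 and 66 are the two
#'   conventional settings; any positive value works).
#' @param threshold_policy `"otsu-per-slice"` or `"fixed"`.
#' @param fixed_threshold Intensity used when `threshold_policy = "fixed"`.
#' @param area_range_um2 Keep sections with filled area inside this window.
#' @param min_circularity Keep sections with `4*pi*A/P^2` at least this
#'   (1 = perfect circle).
#' @return A `crypt_sections` tibble: one row per kept section with
#'   `z_index`, `z_um`, `section_id`, centroid `x_um`/`y_um`, `area_um2`,
#'   equivalent radius `r_eq_um`, and a `pixels` list-column of in-slice
#'   linear indices. Grid shape, spacing, sampled planes and per-plane
#'   thresholds are carried in attributes.
#' @export
extract_crypt_sections <- function(vol, slice_interval = 13,
                                   threshold_policy = c("otsu-per-slice", "fixed"),
                                   fixed_threshold = NULL,
                                   area_range_um2 = c(300, 6e4),
                                   min_circularity = 0.3) {
  stopifnot(inherits(vol, "voxel_volume"))
  threshold_policy <- match.arg(threshold_policy)
  d <- dim(vol$intensities)
  vx <- vol$voxel_size
  depth_um <- d[3] * vx[3]
  if (slice_interval <= 0 || slice_interval > depth_um) {
    stop("slice_interval must be in (0, volume depth]", call. = FALSE)
  }
  if (length(vol$intensities) == 0) stop("empty volume", call. = FALSE)
  step <- max(1L, as.integer(round(slice_interval / vx[3])))
  zs <- seq(1L, d[3], by = step)
  px_area <- vx[1] * vx[2]

  rows <- list()
  thresholds <- stats::setNames(numeric(length(zs)), zs)
  for (si in seq_along(zs)) {
    z <- zs[si]
    img <- vol$intensities[, , z]
    rng <- range(img)
    thr <- if (threshold_policy == "fixed") {
      if (is.null(fixed_threshold)) stop("fixed_threshold required", call. = FALSE)
      fixed_threshold
    } else if (rng[2] - rng[1] < 1e-9) {
      rng[2] + 1  # flat slice: nothing above threshold
    } else {
      EBImage::otsu(EBImage::Image(img), range = rng)
    }
    thresholds[si] <- thr
    bw <- img > thr
    if (!any(bw)) next
    # close 1-voxel gaps so a thin membrane ring encloses its hole
    bwc <- EBImage::closing(EBImage::Image(bw * 1), matrix(1, 3, 3))
    lab0 <- EBImage::bwlabel(bwc)
    filled <- EBImage::fillHull(lab0)
    lab <- EBImage::bwlabel(filled > 0)
    shp <- EBImage::computeFeatures.shape(lab)
    if (is.null(shp)) next
    labm <- as.integer(round(as.numeric(EBImage::imageData(lab))))
    for (k in seq_len(nrow(shp))) {
      area <- shp[k, "s.area"] * px_area
      perim <- shp[k, "s.perimeter"]
      circ <- if (perim > 0) 4 * pi * shp[k, "s.area"] / perim^2 else 1
      if (area < area_range_um2[1] || area > area_range_um2[2]) next
      if (circ < min_circularity) next
      pix <- which(labm == k)
      ix <- ((pix - 1L) %% d[1]) + 1L
      iy <- ((pix - 1L) %/% d[1]) + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        z_index = z, z_um = (z - 0.5) * vx[3], section_id = k,
        x_um = mean((ix - 0.5) * vx[1]), y_um = mean((iy - 0.5) * vx[2]),
        area_um2 = area, r_eq_um = sqrt(area / pi),
        pixels = list(pix)
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    z_index = integer(), z_um = numeric(), section_id = integer(),
    x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
    r_eq_um = numeric(), pixels = list()
  )
  structure(out,
    class = c("crypt_sections", class(out)),
    dim3 = d, voxel_size = vx, z_planes = zs,
    slice_interval = slice_interval, thresholds = thresholds
  )
}

# translate an in-slice pixel set by integer offsets, dropping pixels that
# leave the grid
shift_pixels <- function(pix, dxy, d) {
  ix <- ((pix - 1L) %% d[1]) + 1L + dxy[1]
  iy <- ((pix - 1L) %/% d[1]) + 1L + dxy[2]
  ok <- ix >= 1L & ix <= d[1] & iy >= 1L & iy <= d[2]
  (iy[ok] - 1L) * d[1] + ix[ok]
}

#' Link slice sections into a 3D crypt label map
#'
#' Greedy chain linking between consecutive sampled slices: candidate
#' pairs are gated by centroid displacement (at most
#' `max(2 x median section radius, 30 um)`), and matched in order of
#' decreasing pixel overlap (ties and zero-overlap candidates fall back to
#' nearest centroid), so two chains whose sections touch in one slice keep
#' their own continuity. Chains covering at least `min_span_frac` of the
#' sampled slices become crypts; voxels between sampled slices are
#' assigned by translating the nearer section to the interpolated
#' centroid, and each chain is extended beyond its terminal sampled slices
#' while the underlying intensity supports it (so 13-um and 66-um interval
#' maps of the same clean specimen agree). Within each filled section,
#' above-threshold components touching the section boundary form the
#' basement-membrane wall (`labels`); the enclosed remainder is the lumen
#' (`lumen_labels`); the two are disjoint and the filled crypt body is
#' their union ([crypt_voxels()]).
#'
#' @param sections A `crypt_sections` object from [extract_crypt_sections()].
#' @param vol The [voxel_volume()] the sections came from.
#' @param min_span_frac Minimum fraction of sampled slices a chain must
#'   cover (default 0.6; excludes goblet-blob artifacts).
#' @param min_gate_um Lower bound of the centroid displacement gate (um).
#' @return A `crypt_label_map`: list with integer arrays `labels` and
#'   `lumen_labels` (0 = background), `voxel_size`, `slice_interval` and
#'   the per-plane `thresholds`.
#' @export
link_sections <- function(sections, vol, min_span_frac = 0.6, min_gate_um = 30) {
  d <- attr(sections, "dim3")
  vx <- attr(sections, "voxel_size")
  zs <- attr(sections, "z_planes")
  thresholds <- attr(sections, "thresholds")
  empty_map <- function() structure(
    list(labels = array(0L, d), lumen_labels = array(0L, d),
         voxel_size = vx, slice_interval = attr(sections, "slice_interval"),
         thresholds = thresholds),
    class = "crypt_label_map"
  )
  if (!nrow(sections)) return(empty_map())

  gate <- max(2 * stats::median(sections$r_eq_um), min_gate_um)

  chains <- list()  # each: list(rows = list of section row indices, last = row idx)
  for (si in seq_along(zs)) {
    z <- zs[si]
    cur <- which(sections$z_index == z)
    if (!length(cur)) next
    # a chain may skip up to two sampled slices (e.g. when the touching
    # sections of two crypts merge into a single component for a slice or
    # two); min_span_frac still rejects fragmentary chains
    active <- which(vapply(chains, function(ch) {
      si - ch$last_si >= 1L && si - ch$last_si <= 3L
    }, logical(1)))
    if (length(active) && length(cur)) {
      cand <- expand.grid(ci = active, ri = cur)
      cand$dist <- sqrt(
        (sections$x_um[cand$ri] -
           vapply(chains[cand$ci], function(ch) sections$x_um[ch$last], 0))^2 +
        (sections$y_um[cand$ri] -
           vapply(chains[cand$ci], function(ch) sections$y_um[ch$last], 0))^2
      )
      cand <- cand[cand$dist <= gate, , drop = FALSE]
      if (nrow(cand)) {
        cand$overlap <- mapply(function(ci, ri) {
          length(intersect(sections$pixels[[chains[[ci]]$last]],
                           sections$pixels[[ri]]))
        }, cand$ci, cand$ri)
        cand <- cand[order(-cand$overlap, cand$dist), , drop = FALSE]
        used_c <- integer(); used_r <- integer()
        for (q in seq_len(nrow(cand))) {
          ci <- cand$ci[q]; ri <- cand$ri[q]
          if (ci %in% used_c || ri %in% used_r) next
          chains[[ci]]$rows <- c(chains[[ci]]$rows, ri)
          chains[[ci]]$last <- ri
          chains[[ci]]$last_si <- si
          used_c <- c(used_c, ci); used_r <- c(used_r, ri)
        }
        cur <- setdiff(cur, used_r)
      }
    }
    for (ri in cur) {
      chains[[length(chains) + 1L]] <- list(rows = list(ri), last = ri, last_si = si)
    }
  }

  spans <- vapply(chains, function(ch) length(ch$rows), integer(1))
  keep <- which(spans >= max(2L, ceiling(min_span_frac * length(zs))))
  map <- empty_map()
  if (!length(keep)) return(map)

  labels <- map$labels
  lumen <- map$lumen_labels
  thr_of_plane <- function(z) thresholds[which.min(abs(zs - z))]

  shift2 <- function(M, dx, dy) {
    out <- matrix(FALSE, nrow(M), ncol(M))
    xs <- seq_len(nrow(M)) - dx; ys <- seq_len(ncol(M)) - dy
    okx <- xs >= 1 & xs <= nrow(M); oky <- ys >= 1 & ys <= ncol(M)
    out[okx, oky] <- M[xs[okx], ys[oky]]
    out
  }

  # wall = bright (above-threshold) in-section components touching the
  # section boundary, i.e. the basement-membrane ring; the rest of the
  # filled section is enclosed lumen (labels and lumen_labels disjoint)
  write_plane <- function(pix, z, k) {
    off <- (z - 1L) * d[1] * d[2]
    thr <- thr_of_plane(z)
    ix <- ((pix - 1L) %% d[1]) + 1L
    iy <- ((pix - 1L) %/% d[1]) + 1L
    x0 <- min(ix) - 2L; y0 <- min(iy) - 2L
    M <- matrix(FALSE, max(ix) - x0 + 2L, max(iy) - y0 + 2L)
    sub <- cbind(ix - x0, iy - y0)
    M[sub] <- TRUE
    B <- matrix(FALSE, nrow(M), ncol(M))
    bright <- vol$intensities[off + pix] > thr
    B[sub] <- bright
    outside <- !M
    band <- M & (
      shift2(outside, 1, 0) | shift2(outside, -1, 0) |
      shift2(outside, 0, 1) | shift2(outside, 0, -1) |
      shift2(outside, 1, 1) | shift2(outside, 1, -1) |
      shift2(outside, -1, 1) | shift2(outside, -1, -1)
    )
    bl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(B * 1)))
    wall_ids <- setdiff(unique(bl[band & B]), 0)
    is_wall <- bright & (bl[sub] %in% wall_ids)
    labels[off + pix[is_wall]] <<- k
    lumen[off + pix[!is_wall]] <<- k
  }

  for (ki in seq_along(keep)) {
    ch <- chains[[keep[ki]]]
    rows <- unlist(ch$rows)
    zi <- sections$z_index[rows]
    ord <- order(zi)
    rows <- rows[ord]; zi <- zi[ord]
    # sampled planes + interpolated in-between planes
    for (q in seq_along(rows)) {
      write_plane(sections$pixels[[rows[q]]], zi[q], ki)
      if (q < length(rows)) {
        z0 <- zi[q]; z1 <- zi[q + 1]
        if (z1 - z0 > 1L) {
          c0 <- c(sections$x_um[rows[q]], sections$y_um[rows[q]])
          c1 <- c(sections$x_um[rows[q + 1]], sections$y_um[rows[q + 1]])
          for (z in (z0 + 1L):(z1 - 1L)) {
            f <- (z - z0) / (z1 - z0)
            src <- if (f <= 0.5) rows[q] else rows[q + 1]
            csrc <- if (f <= 0.5) c0 else c1
            cint <- c0 + f * (c1 - c0)
            dxy <- as.integer(round((cint - csrc) / vx[1:2]))
            write_plane(shift_pixels(sections$pixels[[src]], dxy, d), z, ki)
          }
        }
      }
    }
    # extend beyond terminal sampled slices while the intensity under the
    # terminal section stays comparable; the section is advected along the
    # centroid drift extrapolated from the last two sampled sections
    step <- if (length(zs) > 1) zs[2] - zs[1] else 1L
    extend <- function(q_end, q_prev, dir) {
      z_from <- zi[q_end]
      pix0 <- sections$pixels[[rows[q_end]]]
      ref <- mean(vol$intensities[(z_from - 1L) * d[1] * d[2] + pix0])
      drift <- if (q_prev >= 1 && q_prev <= length(rows) && zi[q_end] != zi[q_prev]) {
        (c(sections$x_um[rows[q_end]], sections$y_um[rows[q_end]]) -
         c(sections$x_um[rows[q_prev]], sections$y_um[rows[q_prev]])) /
          (zi[q_end] - zi[q_prev])
      } else c(0, 0)
      z <- z_from + dir
      n <- 0L
      while (z >= 1L && z <= d[3] && n < step) {
        dxy <- as.integer(round(drift * (z - z_from) / vx[1:2]))
        pix <- shift_pixels(pix0, dxy, d)
        m <- mean(vol$intensities[(z - 1L) * d[1] * d[2] + pix])
        if (m < 0.5 * ref) break
        write_plane(pix, z, ki)
        z <- z + dir
        n <- n + 1L
      }
    }
    extend(1L, 2L, -1L)
    extend(length(rows), length(rows) - 1L, +1L)
  }

  map$labels <- labels
  map$lumen_labels <- lumen
  map
}

#' @export
print.crypt_label_map <- function(x, ...) {
  ids <- setdiff(unique(as.integer(x$labels)), 0L)
  cat(sprintf("<crypt_label_map> %d crypt(s), %.0f-um slice interval\n",
              length(ids), x$slice_interval))
  invisible(x)
}

#' Segment crypts from a PAFhy volume
#'
#' Convenience wrapper: [extract_crypt_sections()] followed by
#' [link_sections()].
#'
#' @inheritParams extract_crypt_sections
#' @inheritParams link_sections
#' @param ... Passed to [extract_crypt_sections()].
#' @return A `crypt_label_map`.
#' @export
segment_crypts <- function(vol, slice_interval = 13, min_span_frac = 0.6, ...) {
  sec <- extract_crypt_sections(vol, slice_interval = slice_interval, ...)
  link_sections(sec, vol, min_span_frac = min_span_frac)
}
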