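#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero ("half-up" for positive
#' values), matching how percentages and scores are conventionally printed in
#' clinical tables. Base R's `round()` rounds ties to even, which would print
#' 0.125 as 0.12 instead of 0.13.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(13 / 28 * 100, 2) # 46.43
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Wrap angles (degrees) into (-180, 180]
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- union-find ------------------------------------------------------------

uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Label 26-connected components of a 3D binary mask
#'
#' Connected-component labeling on a logical 3D array using 26-connectivity
#' (all face, edge and corner neighbours). Implemented as 8-connected 2D
#' labeling per z-slice followed by union-find merging of labels whose
#' dilated footprints overlap between consecutive slices, which is exactly
#' 26-connectivity across the slice direction.
#'
#' @param mask Logical (or 0/1 numeric) 3D array, `dim = c(nx, ny, nz)`.
#' @return Integer array of the same dimension; 0 is background, components
#'   are numbered 1..k in arbitrary order.
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  mask <- mask != 0
  lab <- array(0L, d)
  offset <- 0L
  nlab_slice <- integer(d[3])
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    l2 <- EBImage::bwlabel(EBImage::Image(sl * 1))
    l2 <- as.integer(round(as.numeric(EBImage::imageData(l2))))
    nlab_slice[z] <- max(l2)
    l2[l2 > 0L] <- l2[l2 > 0L] + offset
    lab[, , z] <- l2
    offset <- offset + nlab_slice[z]
  }
  if (offset == 0L) return(lab)

  parent <- uf_new(offset)
  kern <- matrix(1, 3, 3)
  for (z in seq_len(d[3] - 1L)) {
    a <- lab[, , z]
    b <- lab[, , z + 1L]
    if (!any(a > 0L) || !any(b > 0L)) next
    # dilate slice z footprint by a 3x3 square: 26-neighbourhood across z
    da <- EBImage::imageData(EBImage::dilate(EBImage::Image((a > 0L) * 1), kern)) > 0
    touch <- which(da & b > 0L)
    if (!length(touch)) next
    # each touching voxel in slice z+1 may meet several labels in slice z;
    # check its 3x3 in-plane neighbourhood in slice z
    nx <- d[1]; ny <- d[2]
    ix <- ((touch - 1L) %% nx) + 1L
    iy <- ((touch - 1L) %/% nx) + 1L
    for (k in seq_along(touch)) {
      xs <- max(1L, ix[k] - 1L):min(nx, ix[k] + 1L)
      ys <- max(1L, iy[k] - 1L):min(ny, iy[k] + 1L)
      nb <- unique(a[xs, ys])
      nb <- nb[nb > 0L]
      for (lb in nb) parent <- uf_union(parent, lb, b[touch[k]])
    }
  }
  roots <- vapply(seq_len(offset), function(i) uf_find(parent, i), integer(1))
  relab <- match(roots, unique(roots))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Flood fill over a 3D mask from seed voxels (26-connectivity)
#'
#' Returns the subset of `mask` reachable from any seed through 26-connected
#' steps within the mask. Used for crypt-abscess continuity.
#'
#' @param mask Logical 3D array to move through.
#' @param seeds Integer vector of linear indices (seed voxels; need not lie
#'   inside `mask` — seeds outside it are dropped).
#' @return Logical array of the reachable subset.
#' @export
flood_fill_3d <- function(mask, seeds) {
  lab <- label_components_3d(mask)
  seeds <- seeds[seeds >= 1 & seeds <= length(lab)]
  hit <- unique(lab[seeds])
  hit <- hit[hit > 0L]
  out <- array(FALSE, dim(mask))
  if (length(hit)) out[lab %in% hit] <- TRUE
  out
}

# component summary on physical coordinates
component_table <- function(lab, voxel_size) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(tibble::tibble(
      cell_id = integer(), n_voxels = integer(),
      volume_um3 = numeric(), x_um = numeric(), y_um = numeric(), z_um = numeric()
    ))
  }
  d <- dim(lab)
  co <- arrayInd(idx, d)
  vx <- voxel_size
  df <- tibble::tibble(
    cell_id = lab[idx],
    x = (co[, 1] - 0.5) * vx[1],
    y = (co[, 2] - 0.5) * vx[2],
    z = (co[, 3] - 0.5) * vx[3]
  )
  vol1 <- prod(vx)
  df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      volume_um3 = dplyr::n() * vol1,
      x_um = mean(.data$x), y_um = mean(.data$y), z_um = mean(.data$z),
      .groups = "drop"
    )
}
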