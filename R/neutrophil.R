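#' Default neutrophil size window
#'
#' Physical volume window (um^3) corresponding to spheres of the given
#' diameter range; the default 6-14 um brackets human neutrophils and
#' excludes both small debris and large goblet-mucus blobs.
#'
#' @param diameter_um Length-2 diameter range in um.
#' @return Length-2 volume window in um^3.
#' @export
neutrophil_size_window <- function(diameter_um = c(6, 14)) {
  4 / 3 * pi * (diameter_um / 2)^3
}

#' Detect neutrophils by intensity and cell size
#'
#' Thresholds the PAFhy channel, labels 26-connected components, and keeps
#' components whose physical volume lies inside the size window and which
#' are disjoint from crypt-wall voxels (neutrophil granules and the
#' basement membrane share the stain, so anything contiguous with a wall is
#' treated as wall, and goblet mucus falls outside the size gate).
#'
#' @param vol A [voxel_volume()].
#' @param label_map Optional `crypt_label_map`; components intersecting its
#'   wall voxels (`labels > 0`) are discarded.
#' @param intensity_threshold Absolute intensity threshold (default: Otsu
#'   over the whole volume, the same policy family as segmentation).
#' @param size_window Length-2 physical volume window in um^3
#'   (default [neutrophil_size_window()]).
#' @return A `neutrophil_cells` tibble: `cell_id`, `n_voxels`,
#'   `volume_um3`, centroid `x_um`/`y_um`/`z_um`; the full component label
#'   array and threshold ride along as attributes.
#' @export
detect_neutrophils <- function(vol, label_map = NULL, intensity_threshold = NULL,
                               size_window = neutrophil_size_window()) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.null(intensity_threshold)) {
    rng <- range(vol$intensities)
    intensity_threshold <- if (rng[2] - rng[1] < 1e-9) rng[2] + 1 else
      EBImage::otsu(EBImage::Image(vol$intensities), range = rng)
  }
  mask <- vol$intensities > intensity_threshold
  lab <- label_components_3d(mask)
  cells <- component_table(lab, vol$voxel_size)
  keep <- cells$volume_um3 >= size_window[1] & cells$volume_um3 <= size_window[2]
  if (!is.null(label_map)) {
    wall_ids <- unique(lab[label_map$labels > 0L & lab > 0L])
    keep <- keep & !(cells$cell_id %in% wall_ids)
  }
  kept <- cells[keep, , drop = FALSE]
  structure(kept,
    class = c("neutrophil_cells", class(kept)),
    component_labels = lab, threshold = intensity_threshold,
    voxel_size = vol$voxel_size
  )
}

#' Restrict detected cells to those continuous with a crypt abscess
#'
#' Keeps the cells whose component is 26-connected, through
#' neutrophil-positive voxels, to the lumen voxel set of the given crypt —
#' the operational form of "only neutrophils continuous with the
#' micro-abscess site". Connectivity is evaluated on the thresholded mask
#' with crypt walls removed, so stromal cells reach the lumen only through
#' a breach in the wall (disrupted epithelium) or an explicit bridge.
#'
#' @param cells A `neutrophil_cells` result from [detect_neutrophils()].
#' @param vol The [voxel_volume()] the cells were detected in.
#' @param label_map `crypt_label_map` providing lumen voxels.
#' @param crypt_id Crypt whose lumen defines the abscess site.
#' @return The subset of `cells` connected to the lumen (always a subset of
#'   the input).
#' @export
restrict_to_abscess <- function(cells, vol, label_map, crypt_id) {
  stopifnot(inherits(cells, "neutrophil_cells"))
  if (!crypt_id %in% setdiff(unique(as.integer(label_map$labels)), 0L)) {
    stop("unknown crypt_id: ", crypt_id, call. = FALSE)
  }
  thr <- attr(cells, "threshold")
  # traversable space: neutrophil-positive voxels outside walls, plus the
  # crypt's own lumen; walls block unless breached
  mask <- (vol$intensities > thr & label_map$labels == 0L) |
    label_map$lumen_labels == crypt_id
  seeds <- which(label_map$lumen_labels == crypt_id)
  if (!length(seeds)) return(cells[integer(0), , drop = FALSE])
  reach <- flood_fill_3d(mask, seeds)
  lab <- attr(cells, "component_labels")
  hit_ids <- unique(lab[reach & lab > 0L])
  out <- cells[cells$cell_id %in% hit_ids, , drop = FALSE]
  attr(out, "component_labels") <- lab
  attr(out, "threshold") <- thr
  attr(out, "voxel_size") <- attr(cells, "voxel_size")
  out
}

#' Depth distribution of neutrophils within a crypt
#'
#' Fraction of cell centroids lying in the deepest third of the crypt's
#' clipped extent — the summary behind "neutrophils tended to infiltrate
#' at the bottoms of crypts".
#'
#' @param cells A `neutrophil_cells` tibble (needs `z_um`).
#' @param crypt_z_range Length-2 physical z extent (um) of the crypt, e.g.
#'   `range((clip_to_depth(...)[, 3] - 0.5) * voxel_size[3])`.
#' @return Fraction in `[0, 1]`.
#' @export
depth_distribution <- function(cells, crypt_z_range) {
  if (!nrow(cells)) stop("no cells", call. = FALSE)
  z0 <- crypt_z_range[1]; z1 <- crypt_z_range[2]
  stopifnot(z1 > z0)
  cutoff <- z0 + 2 / 3 * (z1 - z0)
  mean(cells$z_um > cutoff)
}
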