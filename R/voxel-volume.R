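#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D numeric intensity grid with physical voxel
#' spacing in micrometres. Array dimensions are `(x, y, z)` with `z`
#' measured from the mucosal surface (`z = 0`) into the tissue; a voxel's
#' physical centre is `(i - 0.5) * spacing`. All downstream geometry
#' (slice intervals, depth clipping, adjacency radii) is in micrometres.
#'
#' @param intensities Numeric 3D array, finite and non-negative.
#' @param voxel_size Numeric length-3 spacing `(x, y, z)` in um, all > 0.
#' @param channel Channel name, e.g. `"PAFhy"` or `"nuclear"`.
#' @return A `voxel_volume` object.
#' @export
voxel_volume <- function(intensities, voxel_size, channel = "PAFhy") {
  if (length(dim(intensities)) != 3) {
    stop("`intensities` must be a 3D array", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive spacings (x, y, z) in um", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(intensities = intensities, voxel_size = voxel_size, channel = channel),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<voxel_volume '%s'> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um (%.0f x %.0f x %.0f um)\n",
    x$channel, d[1], d[2], d[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    d[1] * x$voxel_size[1], d[2] * x$voxel_size[2], d[3] * x$voxel_size[3]
  ))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$intensities)

# physical z (um) of the centre of voxel plane k
plane_z_um <- function(vol, k) (k - 0.5) * vol$voxel_size[3]

# nearest voxel plane to physical depth z_um
z_to_plane <- function(vol, z_um) {
  pmin(dim(vol$intensities)[3], pmax(1L, as.integer(round(z_um / vol$voxel_size[3] + 0.5))))
}

#' Read an image stack from a multi-page TIFF
#'
#' Pages are stacked along `z`. Voxel spacing is never assumed: it must be
#' given either through `voxel_size` or through a JSON sidecar file
#' `<path>.json` with a `voxel_size_um` field `(x, y, z)`; otherwise an
#' error is raised.
#'
#' @param path TIFF file path.
#' @param voxel_size Optional `(x, y, z)` spacing in um.
#' @param channel Channel name to record.
#' @return A [voxel_volume()].
#' @export
read_stack <- function(path, voxel_size = NULL, channel = "PAFhy") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(voxel_size)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      voxel_size <- meta$voxel_size_um
      channel <- meta$channel %||% channel
    }
  }
  if (is.null(voxel_size)) {
    stop("voxel spacing not provided and no sidecar '", path,
         ".json' with a voxel_size_um field; refusing to assume spacing",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent page shapes in ", path, call. = FALSE)
  }
  # readTIFF returns row x col matrices; store as (x, y, z) = (col, row, page)
  arr <- array(0, c(dims[2, 1], dims[1, 1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  voxel_volume(arr, voxel_size, channel)
}

#' Write an image stack to a multi-page TIFF with a spacing sidecar
#'
#' Intensities are stored as 16-bit (values scaled by `scale` and clipped to
#' `[0, 65535]`); spacing and channel name go to a `<path>.json` sidecar so
#' that [read_stack()] round-trips losslessly for integer-valued data.
#'
#' @param vol A [voxel_volume()].
#' @param path Output TIFF path.
#' @param scale Multiplier applied before integer storage (default 1).
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path, scale = 1) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$intensities)
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- t(vol$intensities[, , k]) * scale
    pmax(pmin(m, 65535), 0) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(voxel_size_um = vol$voxel_size, channel = vol$channel, scale = scale),
    paste0(path, ".json"),
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}
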