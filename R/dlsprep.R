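#' Export 2D plane images from a volume
#'
#' Sagittal planes are fixed-y sections (x-z images), horizontal planes are
#' fixed-z sections (x-y images); only the PAFhy channel is used, converted
#' to grayscale as-is.
#'
#' @param vol A [voxel_volume()] (or a `specimen_phantom`, whose PAFhy
#'   channel is taken).
#' @param plane `"sagittal"` or `"horizontal"`.
#' @param stride Take every `stride`-th plane (>= 1).
#' @param specimen_id,class_label Metadata carried on each image.
#' @return Tibble with `plane_index`, `plane`, `specimen_id`, `class_label`
#'   and a `pixels` list-column of raw 2D matrices (pre-crop).
#' @export
export_planes <- function(vol, plane = c("sagittal", "horizontal"), stride = 1,
                          specimen_id = NA_character_, class_label = NA_character_) {
  if (inherits(vol, "specimen_phantom")) {
    specimen_id <- vol$specimen_id
    class_label <- if (is.na(class_label)) vol$group_label else class_label
    vol <- vol$volumes$PAFhy
  }
  stopifnot(inherits(vol, "voxel_volume"), stride >= 1)
  plane <- match.arg(plane)
  d <- dim(vol$intensities)
  if (any(d == 0)) stop("empty volume", call. = FALSE)
  n <- if (plane == "sagittal") d[2] else d[3]
  idx <- seq(1L, n, by = as.integer(stride))
  imgs <- lapply(idx, function(k) {
    if (plane == "sagittal") vol$intensities[, k, ] else vol$intensities[, , k]
  })
  tibble::tibble(
    plane_index = idx, plane = plane,
    specimen_id = specimen_id, class_label = class_label,
    pixels = imgs
  )
}

#' Preprocess a plane image for classification
#'
#' Sagittal images (inconsistent slice sizes) are cropped to a centred
#' square at the maximum possible size and resized to 256 x 256; horizontal
#' images are resized to 256 x 256 directly. Pixel values are rescaled to
#' `[0, 1]` by division by `max_value` (255 for 8-bit input; pass 1 for
#' data already on a 0-1 scale). Resizing is bilinear.
#'
#' @param img 2D numeric matrix.
#' @param plane `"sagittal"` or `"horizontal"`.
#' @param size Output side length (default 256).
#' @param max_value Intensity full scale (default 255).
#' @return `size` x `size` matrix with values in `[0, 1]`.
#' @export
preprocess_plane <- function(img, plane = c("sagittal", "horizontal"),
                             size = 256, max_value = 255) {
  plane <- match.arg(plane)
  d <- dim(img)
  if (is.null(d) || any(d < 8)) stop("image smaller than 8 px on a side", call. = FALSE)
  if (plane == "sagittal" && d[1] != d[2]) {
    side <- min(d)
    r0 <- floor((d[1] - side) / 2)
    c0 <- floor((d[2] - side) / 2)
    img <- img[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
  }
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(img), w = size, h = size))
  out <- out / max_value
  pmin(pmax(out, 0), 1)
}

#' Seeded augmentation of a preprocessed plane image
#'
#' Independently applies a horizontal flip (p = 0.5), a vertical flip
#' (p = 0.5), a uniform random rotation in `[-20, 20]` degrees with
#' reflective padding, and random erasing of one rectangle (area fraction
#' drawn in `erase_frac`, filled with the image mean).
#'
#' @param img 2D matrix in `[0, 1]`.
#' @param seed RNG seed; identical seeds reproduce the output exactly.
#' @param rotation_range Degrees (default `c(-20, 20)`).
#' @param erase_frac Erased-area fraction bounds (default `c(0.02, 0.2)`).
#' @param p_flip Flip probability for each axis.
#' @return Augmented matrix, same shape.
#' @export
augment_plane <- function(img, seed, rotation_range = c(-20, 20),
                          erase_frac = c(0.02, 0.2), p_flip = 0.5) {
  set.seed(seed)
  d <- dim(img)
  if (stats::runif(1) < p_flip) img <- img[d[1]:1, , drop = FALSE]
  if (stats::runif(1) < p_flip) img <- img[, d[2]:1, drop = FALSE]
  ang <- stats::runif(1, rotation_range[1], rotation_range[2])
  if (abs(ang) > 1e-12) {
    # reflective padding so rotation introduces no empty corners
    m <- ceiling(max(d) * (sqrt(2) - 1) / 2) + 2
    mirror_idx <- function(i, n) {
      i <- ((i - 1) %% (2 * n)) + 1
      ifelse(i > n, 2 * n - i + 1, i)
    }
    pad <- img[mirror_idx(seq(1 - m, d[1] + m), d[1]),
               mirror_idx(seq(1 - m, d[2] + m), d[2]), drop = FALSE]
    rot <- EBImage::rotate(EBImage::Image(pad), ang,
                           output.dim = dim(pad), bg.col = 0)
    rotm <- EBImage::imageData(rot)
    img <- rotm[(m + 1):(m + d[1]), (m + 1):(m + d[2]), drop = FALSE]
  }
  if (erase_frac[2] <= 0) return(pmin(pmax(img, 0), 1))
  frac <- stats::runif(1, erase_frac[1], erase_frac[2])
  aspect <- exp(stats::runif(1, log(0.5), log(2)))
  eh <- max(1L, min(d[1], round(sqrt(frac * prod(d) * aspect))))
  ew <- max(1L, min(d[2], round(frac * prod(d) / eh)))
  r0 <- sample.int(d[1] - eh + 1L, 1)
  c0 <- sample.int(d[2] - ew + 1L, 1)
  img[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L)] <- mean(img)
  pmin(pmax(img, 0), 1)
}

#' Stratified-group k-fold assignment
#'
#' Assigns whole specimens (groups) to folds so that no specimen's images
#' are split across folds, while greedily balancing per-fold class counts:
#' specimens are processed class by class (largest class first) and each
#' goes to the fold currently holding the fewest specimens of its class
#' (ties: fewest specimens overall, then lowest fold index).
#'
#' @param images Tibble with one row per image, columns `specimen_id` and
#'   `class_label`.
#' @param k Number of folds (default 10); must not exceed the number of
#'   specimens.
#' @return `images` with an added integer `fold` column (0 to k-1).
#' @export
stratified_group_kfold <- function(images, k = 10) {
  specs <- images |>
    dplyr::distinct(.data$specimen_id, .data$class_label)
  if (any(duplicated(specs$specimen_id))) {
    stop("a specimen carries more than one class label", call. = FALSE)
  }
  if (k > nrow(specs)) stop("k exceeds the number of specimens", call. = FALSE)
  fold_class <- matrix(0L, nrow = k, ncol = length(unique(specs$class_label)),
                       dimnames = list(NULL, sort(unique(specs$class_label))))
  fold_of <- stats::setNames(integer(nrow(specs)), specs$specimen_id)
  class_sizes <- sort(table(specs$class_label), decreasing = TRUE)
  for (cl in names(class_sizes)) {
    ids <- specs$specimen_id[specs$class_label == cl]
    for (id in ids) {
      load_cl <- fold_class[, cl]
      total <- rowSums(fold_class)
      best <- order(load_cl, total, seq_len(k))[1]
      fold_class[best, cl] <- fold_class[best, cl] + 1L
      fold_of[id] <- best - 1L
    }
  }
  dplyr::mutate(images, fold = unname(fold_of[as.character(.data$specimen_id)]))
}
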