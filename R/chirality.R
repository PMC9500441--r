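#' Net twist of a crypt centerline
#'
#' Signed total rotation of the centerline about its own axis, estimated
#' from the surface-view (xy) projection of the sampled points: the
#' azimuth increments of the second differences of the projected points
#' (each wrapped to (-180, 180] degrees) are summed and rescaled to the
#' full point span. Second differencing cancels the constant lateral step
#' a tilted axis contributes, so the estimate is exact for a uniformly
#' sampled helix at any axis tilt and any number of turns. Sign
#' convention: positive = counterclockwise as seen from the mucosal
#' surface looking into the tissue (increasing `atan2(y, x)` with depth);
#' crypts completing more than one revolution accumulate more than 360
#' degrees.
#'
#' @param cl Centerline tibble (`x_um`, `y_um`, `z_um`) or n x 3 matrix,
#'   n >= 3.
#' @param straight_eps Projected radius (um) below which a point is treated
#'   as lying on the axis; if all points are within it the crypt is
#'   straight and the twist is 0.
#' @return Net twist in signed degrees.
#' @export
net_twist <- function(cl, straight_eps = 1) {
  pts <- if (is.data.frame(cl)) cbind(cl$x_um, cl$y_um, cl$z_um) else as.matrix(cl)
  n <- nrow(pts)
  if (n < 3) stop("need >= 3 centerline points", call. = FALSE)
  # Twist is read from the winding of the surface-view (xy) projection.
  # Second differences of the projected points cancel the constant drift a
  # tilted axis adds to every step, so their azimuth increments equal the
  # per-step rotation about the crypt's own axis exactly for a uniformly
  # sampled helix, at any tilt and any number of turns. N points give N-3
  # azimuth increments over a twist spanning N-1 steps, hence the scaling.
  # Increasing atan2(y, x) with depth is CCW seen from the mucosal surface.
  d1 <- diff(pts[, 1:2, drop = FALSE])
  m <- if (n >= 5) diff(d1) else d1
  span <- n - 1L
  mag <- sqrt(rowSums(m^2))
  keep <- mag >= straight_eps
  if (sum(keep) < 2) return(0)
  phi <- atan2(m[keep, 2], m[keep, 1]) * 180 / pi
  inc <- wrap_angle(diff(phi))
  sum(inc) * span / length(inc)
}

#' Classify twist chirality
#'
#' @param net_twist_deg Signed net twist in degrees.
#' @param threshold Minimum |twist| (degrees) to call a direction
#'   (default 90, a quarter turn — robust to centroid jitter on straight
#'   crypts).
#' @return `"CCW"`, `"CW"` or `"none"`.
#' @export
classify_chirality <- function(net_twist_deg, threshold = 90) {
  stopifnot(threshold > 0)
  dplyr::case_when(
    net_twist_deg > threshold ~ "CCW",
    net_twist_deg < -threshold ~ "CW",
    .default = "none"
  )
}

#' Detect spiral staircase-like crypts (SSCs) in one specimen
#'
#' An SSC group is a set of two or more adjacent crypts twisted in the same
#' direction. Adjacency is an edge between crypt surface anchors closer
#' than `adjacency_radius`; SSC groups are the connected components of the
#' adjacency graph restricted to each non-none chirality class, kept when
#' they have at least two members.
#'
#' @param morph Morphometry tibble from [measure_crypts()] (needs
#'   `crypt_id`, `chirality`, `surface_x_um`, `surface_y_um`; optionally
#'   `specimen_id`).
#' @param adjacency_radius Neighbour distance in um (default 150, about two
#'   crypt diameters).
#' @return An `ssc_report`: list with `specimen_id`, `crypt_chiralities`
#'   (tibble), `ssc_groups` (list of integer crypt-id vectors) and
#'   `ssc_positive`.
#' @export
detect_ssc <- function(morph, adjacency_radius = 150) {
  stopifnot(adjacency_radius > 0)
  sid <- if ("specimen_id" %in% names(morph) && nrow(morph)) morph$specimen_id[1] else NA_character_
  groups <- list()
  for (cls in c("CCW", "CW")) {
    sub <- morph[morph$chirality == cls, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    parent <- uf_new(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt((sub$surface_x_um[i] - sub$surface_x_um[j])^2 +
                (sub$surface_y_um[i] - sub$surface_y_um[j])^2)
      if (d <= adjacency_radius) parent <- uf_union(parent, i, j)
    }
    roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    for (rt in unique(roots)) {
      mem <- sub$crypt_id[roots == rt]
      if (length(mem) >= 2) groups <- c(groups, list(sort(mem)))
    }
  }
  structure(
    list(
      specimen_id = sid,
      crypt_chiralities = tibble::tibble(
        crypt_id = morph$crypt_id, chirality = morph$chirality
      ),
      ssc_groups = groups,
      ssc_positive = length(groups) > 0
    ),
    class = "ssc_report"
  )
}

#' @export
print.ssc_report <- function(x, ...) {
  cat(sprintf("<ssc_report '%s'> %s (%d group(s))\n", x$specimen_id,
              if (x$ssc_positive) "SSC-positive" else "SSC-negative",
              length(x$ssc_groups)))
  invisible(x)
}

#' Cohort SSC rate per group
#'
#' Percentage of SSC-positive specimens in each group, rounded half-up to
#' two decimals (so 13 of 28 prints 46.43 and 4 of 18 prints 22.22).
#'
#' @param reports Either a list of [detect_ssc()] reports plus a `groups`
#'   vector (same length), or a tibble with columns `group` and
#'   `ssc_positive`.
#' @param groups Group label per report (ignored for tibble input).
#' @return Tibble `(group, n_specimens, n_positive, ssc_rate_pct)`.
#' @export
cohort_ssc_rate <- function(reports, groups = NULL) {
  if (is.data.frame(reports)) {
    df <- reports
  } else {
    stopifnot(length(reports) == length(groups))
    df <- tibble::tibble(
      group = groups,
      ssc_positive = vapply(reports, function(r) r$ssc_positive, logical(1))
    )
  }
  if (!nrow(df)) stop("empty cohort", call. = FALSE)
  df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_specimens = dplyr::n(),
      n_positive = sum(.data$ssc_positive),
      ssc_rate_pct = round_half_up(100 * sum(.data$ssc_positive) / dplyr::n(), 2),
      .groups = "drop"
    )
}
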