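#' Group-level generator parameters
#'
#' Distributions of crypt geometry per clinical group, encoding the
#' qualitative directions reported for 3D crypt architecture: UC crypts
#' are dilated (larger volume), strongly distorted (higher tortuosity,
#' partial-to-full twists, lower prolate ellipticity); CD crypts keep a
#' near-normal volume but are moderately distorted; non-IBD crypts are
#' straight, elongated tubes. SSC prevalence defaults to the observed
#' specimen rates 13/28 (UC), 4/18 (CD) and 0/22 (non-IBD), realized as
#' exact per-specimen flags.
#'
#' Each group entry holds: `radius_mean`/`radius_sd` (um), `depth_range`
#' (um; depths beyond the 250-um normalization are clipped by analysis),
#' `helix_radius_mean`/`helix_radius_sd` (um), `turns_mean`/`turns_sd`
#' (revolutions; sign is drawn at random per crypt), `tilt_sd` (degrees),
#' `ssc_prevalence`, and inflammatory-cell count parameters
#' (`count_base`, `count_slope` on the within-group volume z-score,
#' `count_sd`, per high-power field).
#'
#' @return Named list of per-group parameter lists.
#' @export
cohort_group_params <- function() {
  list(
    "UC" = list(
      radius_mean = 45, radius_sd = 5, depth_range = c(255, 280),
      helix_radius_mean = 28, helix_radius_sd = 8,
      turns_mean = 0.8, turns_sd = 0.2, tilt_sd = 5,
      ssc_prevalence = 13 / 28,
      count_base = 110, count_slope = 25, count_sd = 8,
      neut_frac = 0.35
    ),
    "CD" = list(
      radius_mean = 33, radius_sd = 3.5, depth_range = c(255, 280),
      helix_radius_mean = 18, helix_radius_sd = 6,
      turns_mean = 0.45, turns_sd = 0.12, tilt_sd = 4,
      ssc_prevalence = 4 / 18,
      count_base = 95, count_slope = -10, count_sd = 8,
      neut_frac = 0.25
    ),
    "non-IBD" = list(
      radius_mean = 32, radius_sd = 3, depth_range = c(255, 280),
      helix_radius_mean = 2, helix_radius_sd = 1.5,
      turns_mean = 0, turns_sd = 0.05, tilt_sd = 1.5,
      ssc_prevalence = 0,
      count_base = 40, count_slope = 0, count_sd = 8,
      neut_frac = 0.1
    )
  )
}

# crypt surface anchors: a coarse grid whose pitch exceeds the SSC
# adjacency radius by twice the maximum helix offset, so only the
# deliberately co-located pair of an SSC-flagged specimen is "adjacent"
crypt_anchor_grid <- function(n_crypts, pitch = 250, origin = c(170, 170)) {
  per_row <- ceiling(sqrt(n_crypts))
  i <- seq_len(n_crypts) - 1L
  cbind(
    x = origin[1] + (i %% per_row) * pitch,
    y = origin[2] + (i %/% per_row) * pitch
  )
}

draw_specimen_specs <- function(gp, n_crypts, ssc_flag, pitch = 250) {
  anchors <- crypt_anchor_grid(n_crypts, pitch)
  specs <- vector("list", n_crypts)
  signs <- sample(c(-1, 1), n_crypts, replace = TRUE)
  ssc_sign <- sample(c(-1, 1), 1)
  ssc_phase <- stats::runif(1, 0, 360)
  tubes_clash <- function(a, b) {
    z <- seq(0, min(a$depth, b$depth), by = 10)
    pa <- centerline_xy(as.list(a), z); pb <- centerline_xy(as.list(b), z)
    gap <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
    lim <- tube_radius_at(as.list(a), z) + tube_radius_at(as.list(b), z)
    any(gap < lim)
  }
  for (i in seq_len(n_crypts)) {
    is_pair <- ssc_flag && i <= 2
    for (try in 1:30) {
      # caps keep every crypt inside the anchor grid margin (the
      # truncation is mild: 2.5 SD on radius, 12 degrees of tilt)
      r <- min(max(stats::rnorm(1, gp$radius_mean, gp$radius_sd), 15),
               gp$radius_mean + 2.5 * gp$radius_sd)
      depth <- stats::runif(1, gp$depth_range[1], gp$depth_range[2])
      hr <- min(max(stats::rnorm(1, gp$helix_radius_mean, gp$helix_radius_sd), 0), 40)
      turns <- signs[i] * max(stats::rnorm(1, gp$turns_mean, gp$turns_sd), 0)
      tilt <- min(abs(stats::rnorm(1, 0, gp$tilt_sd)), 12)
      bx <- anchors[i, 1]; by <- anchors[i, 2]
      phase <- stats::runif(1, 0, 360)
      if (is_pair) {
        # co-located, co-chiral full-twist pair; shared phase, capped
        # radius and zero tilt keep the pair adjacent but non-overlapping
        bx <- anchors[1, 1] + (i - 1) * 100
        by <- anchors[1, 2]
        turns <- ssc_sign * stats::runif(1, 0.9, 1.2)
        hr <- stats::runif(1, 15, 20)
        phase <- ssc_phase
        tilt <- 0
        r <- min(r, 40)
      }
      if (try == 30) { hr <- 0; tilt <- 0 }  # last resort: straight tube
      cand <- crypt_spec(
        crypt_id = i, base_x = bx, base_y = by, depth = depth,
        tube_radius = r, helix_radius = hr, helix_turns = turns,
        axis_tilt = tilt, tilt_azimuth = stats::runif(1, 0, 360),
        phase = phase
      )
      ok <- TRUE
      if (i > 1) for (j in seq_len(i - 1)) {
        if (tubes_clash(cand, specs[[j]])) { ok <- FALSE; break }
      }
      if (ok) { specs[[i]] <- cand; break }
    }
  }
  dplyr::bind_rows(specs)
}

#' Generate a synthetic cohort of specimens
#'
#' Draws per-specimen, per-crypt geometry from the group distributions in
#' [cohort_group_params()] and assembles the analytic truth table; with
#' `rasterize = TRUE` each specimen is also rendered to voxels (use small
#' shapes for quick runs). SSC-positive specimens are realized by explicit
#' flags — exactly `round(prevalence * n)` specimens per group (overridable
#' via `n_ssc`) contain a pair of adjacent co-chiral full-twist crypts;
#' crypt anchors are otherwise spaced beyond the default adjacency radius.
#'
#' @param n_per_group Named counts, e.g. `c(UC = 28, CD = 18, "non-IBD" = 22)`.
#' @param group_params See [cohort_group_params()].
#' @param seed Master seed; all randomness derives from it.
#' @param n_crypts Crypts per specimen (default 5).
#' @param rasterize Render voxel volumes per specimen.
#' @param shape,voxel_size Grid for rasterization.
#' @param noise [noise_model()] for rasterization.
#' @param n_ssc Optional named vector of exact SSC-positive counts per group.
#' @param out_dir Optional directory; rasterized stacks are written there as
#'   TIFFs and the manifest gains their paths.
#' @return A `crypt_cohort` list: `manifest` (specimen_id, group, ssc_flag,
#'   path), `truth` (per-crypt analytic morphometry with surface anchors),
#'   `cell_counts` (per-specimen inflammatory-cell counts per HPF, averaged
#'   over 3 areas), `phantoms` (list or NULL), `seed`.
#' @export
generate_cohort <- function(n_per_group = c(UC = 28, CD = 18, "non-IBD" = 22),
                            group_params = cohort_group_params(),
                            seed = 1, n_crypts = 5,
                            rasterize = FALSE,
                            shape = c(224, 224, 96), voxel_size = 4,
                            noise = noise_model(), n_ssc = NULL,
                            out_dir = NULL) {
  if (any(n_per_group < 1)) stop("empty group requested", call. = FALSE)
  set.seed(seed)
  manifest <- list(); truth <- list(); counts <- list(); phantoms <- list()
  for (g in names(n_per_group)) {
    gp <- group_params[[g]]
    if (is.null(gp)) stop("no parameters for group ", g, call. = FALSE)
    n <- n_per_group[[g]]
    k_ssc <- if (!is.null(n_ssc) && g %in% names(n_ssc)) n_ssc[[g]] else
      round_half_up(gp$ssc_prevalence * n)
    flags <- logical(n)
    if (k_ssc > 0) flags[sample.int(n, k_ssc)] <- TRUE
    spec_seeds <- sample.int(.Machine$integer.max - 1L, n)
    for (i in seq_len(n)) {
      sid <- sprintf("%s-%02d", g, i)
      specs <- draw_specimen_specs(gp, n_crypts, flags[i])
      tr <- dplyr::bind_rows(lapply(seq_len(nrow(specs)), function(k) {
        analytic_truth(specs[k, ])
      }))
      surf <- centerline_xy_df(specs)
      tr <- tr |>
        dplyr::mutate(
          specimen_id = sid, group = g, .before = 1
        ) |>
        dplyr::left_join(surf, by = "crypt_id")
      truth[[sid]] <- tr
      path <- NA_character_
      if (rasterize) {
        ph <- rasterize_specimen(
          specs, shape = shape, voxel_size = voxel_size, noise = noise,
          seed = spec_seeds[i], group_label = g, specimen_id = sid
        )
        phantoms[[sid]] <- ph
        if (!is.null(out_dir)) {
          dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
          path <- file.path(out_dir, paste0(sid, ".tif"))
          write_stack(ph$volumes$PAFhy, path, scale = 65535)
        }
      }
      manifest[[sid]] <- tibble::tibble(
        specimen_id = sid, group = g, ssc_flag = flags[i], path = path
      )
      zv <- (mean(tr$volume_um3) - pi * gp$radius_mean^2 * 250) /
        max(pi * 2 * gp$radius_mean * gp$radius_sd * 250, 1)
      total <- max(stats::rnorm(1, gp$count_base + gp$count_slope * zv, gp$count_sd), 5)
      counts[[sid]] <- tibble::tibble(
        specimen_id = sid,
        total_cells_hpf = round(total, 1),
        neutrophils_hpf = round(max(total * gp$neut_frac + stats::rnorm(1, 0, 3), 0), 1),
        lymphocytes_hpf = round(max(total * 0.4 + stats::rnorm(1, 0, 3), 0), 1),
        plasma_cells_hpf = round(max(total * 0.15 + stats::rnorm(1, 0, 2), 0), 1)
      )
    }
  }
  structure(
    list(
      manifest = dplyr::bind_rows(manifest),
      truth = dplyr::bind_rows(truth),
      cell_counts = dplyr::bind_rows(counts),
      phantoms = if (rasterize) phantoms else NULL,
      seed = seed
    ),
    class = "crypt_cohort"
  )
}

# surface anchor (z = 0 centerline position) per crypt of a spec table
centerline_xy_df <- function(specs) {
  dplyr::bind_rows(lapply(seq_len(nrow(specs)), function(k) {
    s <- as.list(specs[k, ])
    p <- centerline_xy(s, 0)
    tibble::tibble(crypt_id = s$crypt_id, surface_x_um = p$x, surface_y_um = p$y)
  }))
}

#' @export
print.crypt_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat("<crypt_cohort> ", paste(names(tab), tab, sep = ": ", collapse = ", "),
      if (is.null(x$phantoms)) " (truth tables only)" else " (rasterized)",
      "\n", sep = "")
  invisible(x)
}
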