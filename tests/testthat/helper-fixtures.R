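# Shared phantom fixtures, built once per test run (all synthetic, seeded).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a straight vertical crypt, 2-um voxels, zero noise
straight_phantom <- function() fixture("straight", function() {
  rasterize_specimen(
    crypt_spec(1, 110, 110, depth = 250, tube_radius = 50,
               goblet_density = 0),
    shape = c(110, 110, 132), voxel_size = 2, seed = 101
  )
})

# one full counterclockwise turn, 2-um voxels, zero noise
helix_phantom <- function() fixture("helix", function() {
  rasterize_specimen(
    crypt_spec(1, 110, 110, depth = 250, tube_radius = 40,
               helix_radius = 25, helix_turns = 1, goblet_density = 0),
    shape = c(110, 110, 132), voxel_size = 2, seed = 102
  )
})

segmented <- function(ph, interval = 13) {
  key <- paste0("seg-", ph$specimen_id, "-", ph$seed, "-", interval)
  fixture(key, function() segment_crypts(ph$volumes$PAFhy,
                                         slice_interval = interval))
}

# small coarse-voxel helical crypt for batch runs
small_helix <- function(seed, turns = 1, helix_radius = 25) {
  rasterize_specimen(
    crypt_spec(1, 90, 90, depth = 250, tube_radius = 35,
               helix_radius = helix_radius, helix_turns = turns,
               goblet_density = 0),
    shape = c(64, 64, 66), voxel_size = 4, seed = seed
  )
}

# rasterize the two-crypt specimen used for SSC cohort construction:
# either a co-chiral adjacent pair (ssc = TRUE) or two straight crypts
two_crypt_specimen <- function(seed, ssc, specimen_id = "S", group = "UC") {
  specs <- if (ssc) {
    dplyr::bind_rows(
      crypt_spec(1, 90, 90, depth = 250, tube_radius = 35,
                 helix_radius = 18, helix_turns = 1, goblet_density = 0),
      crypt_spec(2, 190, 90, depth = 250, tube_radius = 35,
                 helix_radius = 18, helix_turns = 1, goblet_density = 0)
    )
  } else {
    dplyr::bind_rows(
      crypt_spec(1, 90, 90, depth = 250, tube_radius = 35, goblet_density = 0),
      crypt_spec(2, 190, 90, depth = 250, tube_radius = 35, goblet_density = 0)
    )
  }
  rasterize_specimen(specs, shape = c(72, 48, 66), voxel_size = 4, seed = seed,
                     specimen_id = specimen_id, group_label = group)
}

# per-crypt chirality/SSC summary of one rasterized specimen
specimen_ssc <- function(ph, interval = 13) {
  lm <- segment_crypts(ph$volumes$PAFhy, slice_interval = interval)
  m <- measure_crypts(lm, specimen_id = ph$specimen_id, group = ph$group_label)
  detect_ssc(m)
}
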