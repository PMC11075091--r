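# Shared fixtures, built lazily and cached for the whole test run.
.fix <- new.env(parent = emptyenv())

fix_system <- function() {
  if (is.null(.fix$sys)) .fix$sys <- default_system()
  .fix$sys
}

fix_curve <- function(band_id = "slit20") {
  key <- paste0("curve_", band_id)
  if (is.null(.fix[[key]])) {
    sys <- fix_system()
    .fix[[key]] <- simulate_illumination_curve(sys$geometry, sys$bands[[band_id]],
                                               sys$detector, i0_rate = 1e4)
  }
  .fix[[key]]
}

fix_wp <- function(band_id = "slit20") {
  key <- paste0("wp_", band_id)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- choose_working_point(fix_curve(band_id), 0.5)
  }
  .fix[[key]]
}

rel_rmse <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))

# uniform disc phantom (beta only unless gamma given), centred
disc_phantom <- function(n = 96, voxel_um = 2, radius_um = 70, beta = 3e-9,
                         delta = 0) {
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_um
  R <- sqrt(outer(ax^2, ax^2, "+"))
  B <- matrix(0, n, n); B[R <= radius_um] <- beta
  D <- matrix(0, n, n); D[R <= radius_um] <- delta
  optical_map(D, B, voxel_um)
}

# full simulate -> assemble pipeline for a dithered scan
run_dithered <- function(map, band_id = "slit20", n_angles = 60,
                         jitter_seed = NULL, noise = "none", seed = 1,
                         exposure_s = 1) {
  sys <- fix_system()
  band <- sys$bands[[band_id]]
  wp <- fix_wp(band_id)
  traj <- dithered_trajectory(n_angles, band, sys$geometry,
                              jitter_seed = jitter_seed,
                              exposure_s = exposure_s)
  fs <- simulate_scan(sys$geometry, band, map, traj, wp, noise = noise,
                      seed = seed)
  interleave_dithered(flat_dark_correct(fs))
}
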