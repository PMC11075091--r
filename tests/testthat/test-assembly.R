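make_frameset <- function(intensities, types, exposure_s = 1,
                          beamlets = seq_len(ncol(intensities))) {
  structure(list(
    intensities = intensities,
    meta = data.frame(type = types, angle_deg = NA, angle_index = seq_along(types),
                      offset_um = 0, exposure_s = exposure_s,
                      entry_index = NA),
    beamlets_um = beamlets, band_id = "t", scheme = "dithered",
    trajectory = NULL, seed = 1, noise = "none"),
    class = "ei_frameset")
}

test_that("flat/dark correction maps flats to 1 and darks to 0", {
  nb <- 8
  flat <- rep(200, nb); dark <- rep(10, nb)
  fs <- make_frameset(rbind(dark, flat, flat, dark, flat),
                      c("dark", "flat", "sample", "sample", "flat"))
  norm <- flat_dark_correct(fs)
  expect_equal(norm$values[1, ], rep(1, nb))
  expect_equal(norm$values[2, ], rep(0, nb))
  # flats below dark are an error naming the pixel
  bad <- make_frameset(rbind(dark, rep(5, nb), flat),
                       c("dark", "flat", "sample"))
  expect_error(flat_dark_correct(bad), "flat <= dark")
  expect_error(flat_dark_correct(make_frameset(rbind(flat, flat),
                                               c("flat", "sample"))),
               "no dark")
})

test_that("time interpolation of flats removes a linear illumination drift", {
  nb <- 6
  n_sample <- 40
  drift <- function(i) 100 * (1 + 0.02 * i / (n_sample + 2))  # 2% linear drift
  rows <- list(rep(0, nb), rep(drift(0), nb))
  types <- c("dark", "flat")
  for (i in seq_len(n_sample)) {
    rows <- c(rows, list(rep(drift(i + 1), nb)))   # background frames follow the drift
    types <- c(types, "sample")
  }
  rows <- c(rows, list(rep(drift(n_sample + 2), nb)))
  types <- c(types, "flat")
  fs <- make_frameset(do.call(rbind, rows), types)
  norm <- flat_dark_correct(fs)
  expect_equal(mean(norm$values), 1, tolerance = 2e-3)
  expect_lt(max(abs(norm$values - 1)), 2e-3)
})

test_that("flat/dark correction works across different exposures (rates)", {
  nb <- 4
  # flat at 10 s, samples at 1 s, same rate 100/s; dark rate 2/s
  fs <- make_frameset(rbind(rep(20, nb), rep(1020, nb), rep(102, nb), rep(52, nb)),
                      c("dark", "flat", "sample", "sample"),
                      exposure_s = c(10, 10, 1, 1))
  norm <- flat_dark_correct(fs)
  expect_equal(norm$values[1, ], rep(1, nb))
  expect_equal(norm$values[2, ], rep(0.5, nb))
})

test_that("vacuum scans interleave to a constant unit sinogram", {
  vac <- optical_map(matrix(0, 48, 48), matrix(0, 48, 48), 4)
  sino <- run_dithered(vac, n_angles = 4, jitter_seed = 5)
  expect_equal(max(abs(sino$values - 1)), 0, tolerance = 1e-9)
  expect_true(all(diff(sino$lateral_um) > 0))
  expect_equal(sd(diff(sino$lateral_um)), 0, tolerance = 1e-9)
})

test_that("jitter reversal reproduces the unjittered sinogram (commensurate band)", {
  # with p = 4 w the jittered lateral sampling positions coincide exactly
  # with the unjittered lattice, so reversal must be exact in the interior
  sys <- fix_system(); g <- sys$geometry
  band <- mask_band("slit", 20, period_um = 80)
  cur <- simulate_illumination_curve(g, band, sys$detector, i0_rate = 1e4)
  wp <- choose_working_point(cur, 0.5)
  ph <- soft_tissue_phantom(seed = 6, n = 80, voxel_size_um = 2)
  run <- function(jseed) {
    traj <- dithered_trajectory(6, band, g, jitter_seed = jseed)
    fs <- simulate_scan(g, band, ph, traj, wp)
    interleave_dithered(flat_dark_correct(fs))
  }
  s0 <- run(NULL)
  s1 <- run(31)
  nd <- dither_steps(band)
  interior <- (nd + 1):(ncol(s0$values) - nd)
  expect_equal(s1$values[, interior], s0$values[, interior], tolerance = 1e-12)
})

test_that("missing frames are reported as gaps", {
  m <- disc_phantom(n = 48, voxel_um = 3, radius_um = 40)
  sys <- fix_system()
  traj <- dithered_trajectory(3, sys$bands$slit20, sys$geometry)
  fs <- simulate_scan(sys$geometry, sys$bands$slit20, m, traj, fix_wp("slit20"))
  norm <- flat_dark_correct(fs)
  norm$values <- norm$values[-2, , drop = FALSE]
  norm$meta <- norm$meta[-2, , drop = FALSE]
  expect_error(interleave_dithered(norm, traj), "missing frame")
})

test_that("an off-centre rod traces the expected sinusoid", {
  n <- 96; v <- 2
  ax <- (seq_len(n) - (n + 1) / 2) * v
  r0 <- 50; phi0 <- 30 * pi / 180
  cx <- r0 * cos(phi0); cy <- r0 * sin(phi0)
  R <- sqrt(outer((ax - cy)^2, (ax - cx)^2, "+"))   # rows=y, cols=x
  B <- matrix(0, n, n); B[R <= 8] <- 2e-8
  rod <- optical_map(matrix(0, n, n), B, v)
  sino <- run_dithered(rod, n_angles = 24)
  # attenuation trace minimum at t = r0 cos(theta - phi0)
  att <- -log(pmax(sino$values, 1e-12))
  t_peak <- sino$lateral_um[apply(att, 1, which.max)]
  expected <- r0 * cos(sino$angles_deg * pi / 180 - phi0)
  expect_lt(max(abs(t_peak - expected)), 1.2 * sino$pitch_um)
})

test_that("sinogram mass is conserved across angles for a contained phantom", {
  ph <- soft_tissue_phantom(seed = 9, n = 96, voxel_size_um = 2)
  sino <- run_dithered(ph, n_angles = 16)
  mass <- rowSums(-log(pmax(sino$values, 1e-12)))
  expect_lt((max(mass) - min(mass)) / mean(mass), 0.01)
})

make_cyc_normframes <- function(traj, beamlets, f) {
  ent <- traj$entries
  vals <- t(vapply(seq_len(nrow(ent)),
                   function(i) f(ent$angle_deg[i], beamlets - ent$offset_um[i]),
                   numeric(length(beamlets))))
  structure(list(values = vals,
                 meta = data.frame(entry_index = seq_len(nrow(ent))),
                 beamlets_um = beamlets, band_id = traj$band_id,
                 scheme = traj$scheme, trajectory = traj),
            class = "ei_normframes")
}

test_that("cycloidal regridding reproduces constant and linear fields", {
  sys <- fix_system(); g <- sys$geometry
  band <- sys$bands$slit20
  pitch <- band$period_um * g$m_s
  beamlets <- seq(0, 40) * pitch
  # span large enough that the back-and-forth never folds
  traj <- cycloidal_type1_trajectory(25, band, g, span_periods = 40)
  latgrid <- seq(200, 1200, by = traj$step_um)

  sc <- regrid_cycloidal(make_cyc_normframes(traj, beamlets,
                                             function(a, x) rep(2.5, length(x))),
                         traj, lateral_grid_um = latgrid)
  expect_equal(max(abs(sc$values - 2.5)), 0, tolerance = 1e-12)

  # linear field: splines reproduce it exactly away from the 0/360 wrap
  # (the angle axis is treated as periodic, which a linear-in-angle test
  # function deliberately violates at the boundary)
  lin <- function(a, x) 0.01 * a + 0.002 * x
  sl <- regrid_cycloidal(make_cyc_normframes(traj, beamlets, lin), traj,
                         lateral_grid_um = latgrid)
  want <- outer(sl$angles_deg, sl$lateral_um, lin)
  interior <- sl$angles_deg > 120 & sl$angles_deg < 240
  expect_lt(max(abs(sl$values[interior, ] - want[interior, ])) /
              max(abs(want)), 1e-5)
  # the wrap-induced error decays away from the boundary rows
  err_by_row <- apply(abs(sl$values - want), 1, max)
  expect_lt(min(err_by_row), 1e-3 * max(err_by_row))
})

test_that("regridding rejects a target grid beyond the sampled span", {
  sys <- fix_system(); g <- sys$geometry
  band <- sys$bands$slit20
  traj <- cycloidal_type1_trajectory(10, band, g)
  beamlets <- seq(0, 30) * band$period_um * g$m_s
  nf <- make_cyc_normframes(traj, beamlets, function(a, x) rep(1, length(x)))
  expect_error(regrid_cycloidal(nf, traj,
                                lateral_grid_um = seq(-2000, 100, by = traj$step_um)),
               "exceeds the sampled")
})
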