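test_that("projected attenuation: vacuum, slab and analytic square oracle", {
  # vacuum
  vac <- optical_map(matrix(0, 64, 64), matrix(0, 64, 64), 2)
  expect_true(all(projected_attenuation(vac, 33, seq(-50, 50, 10)) == 0))

  # uniform disc: central ray sees beta * diameter
  m <- disc_phantom(n = 96, voxel_um = 2, radius_um = 70, beta = 3e-9)
  expect_equal(projected_attenuation(m, 0, 0), 3e-9 * 140e-6, tolerance = 0.02)

  # axis-aligned square rotated by 30 degrees vs exact chord-length oracle
  n <- 128; v <- 1; a <- 30  # half-size um
  ax <- (seq_len(n) - (n + 1) / 2) * v
  inside <- outer(abs(ax) <= a, abs(ax) <= a, "&")  # rows=y, cols=x
  B <- matrix(0, n, n); B[inside] <- 4e-9
  sq <- optical_map(matrix(0, n, n), B, v)
  chord <- function(theta_deg, t_um) {
    # exact intersection length of the ray {(t c - s S, t S + s c)} with the square
    th <- theta_deg * pi / 180; cc <- cos(th); ss <- sin(th)
    # x(s) = t*cc - s*ss in [-a, a]; y(s) = t*ss + s*cc in [-a, a]
    lims <- function(p0, d) {
      if (abs(d) < 1e-15) {
        if (abs(p0) <= a) c(-Inf, Inf) else c(Inf, -Inf)
      } else sort(c((-a - p0) / d, (a - p0) / d))
    }
    lx <- lims(t_um * cc, -ss); ly <- lims(t_um * ss, cc)
    max(0, min(lx[2], ly[2]) - max(lx[1], ly[1]))
  }
  ts <- seq(-45, 45, by = 3.7)
  got <- projected_attenuation(sq, 30, ts)
  want <- vapply(ts, function(t) chord(30, t), 0) * 4e-9 * 1e-6
  expect_lt(max(abs(got - want)) / max(want), 0.005)
})

test_that("refraction gradient: slab interior, wedge and cylinder symmetry", {
  n <- 96; v <- 2
  ax <- (seq_len(n) - (n + 1) / 2) * v
  # slab (uniform delta): zero gradient in the interior
  slab <- optical_map(matrix(1e-7, n, n), matrix(0, n, n), v)
  expect_equal(refraction_gradient(slab, 0, c(-20, 0, 20)), rep(0, 3))
  # wedge: delta linear in x -> gradient = slope * thickness
  slope <- 1e-9                                  # delta per um
  D <- matrix(rep(ax * slope + 2e-7, each = n), n, n)
  wed <- optical_map(D, matrix(0, n, n), v)
  expect_equal(refraction_gradient(wed, 0, 0), slope * n * v,
               tolerance = 0.02)
  # centred cylinder: antisymmetric, zero at the centre
  R <- sqrt(outer(ax^2, ax^2, "+"))
  D2 <- matrix(0, n, n); D2[R <= 60] <- 5e-7
  cyl <- optical_map(D2, matrix(0, n, n), v)
  expect_equal(refraction_gradient(cyl, 0, 0), 0)
  expect_equal(refraction_gradient(cyl, 0, 30),
               -refraction_gradient(cyl, 0, -30))
})

test_that("detect_frame reproduces the image-formation factors", {
  sys <- fix_system(); g <- sys$geometry
  band <- sys$bands$slit20
  wp <- fix_wp("slit20")
  n <- 96; v <- 2
  beamlets <- beamlet_positions(band, g, c(-n * v / 2, n * v / 2))

  # no sample: flat field at the working-point rate
  flat <- detect_frame(g, band, NULL, 0, 0, wp, exposure_s = 2,
                       beamlets = beamlets)
  expect_true(all(flat$intensities == predict(wp$curve, wp$x_m_um) * 2))

  # pure absorber: I = flat * exp(-2k int beta), C factor unchanged
  m <- disc_phantom(n = n, voxel_um = v, radius_um = 70, beta = 3e-9)
  fr <- detect_frame(g, band, m, 0, 0, wp, exposure_s = 2,
                     beamlets = beamlets, beamlet_averaging = FALSE)
  bl <- projected_attenuation(m, 0, beamlets)
  k <- wave_number(m$energy_kev)
  expect_equal(fr$intensities,
               predict(wp$curve, wp$x_m_um) * 2 * exp(-2 * k * bl),
               tolerance = 1e-10)

  # wedge: intensity offset equals the curve evaluated at the shifted point
  ax <- (seq_len(n) - (n + 1) / 2) * v
  D <- matrix(rep(pmax(ax, 0) * 1e-9 + 1e-8, each = n), n, n)
  wmap <- optical_map(D, matrix(0, n, n), v)
  frw <- detect_frame(g, band, wmap, 0, 0, wp, beamlets = beamlets,
                      beamlet_averaging = FALSE)
  gvec <- refraction_gradient(wmap, 0, beamlets)
  expect_equal(frw$intensities,
               predict(wp$curve, wp$x_m_um - g$z_od * gvec * 1e6),
               tolerance = 1e-10)

  # linearity in exposure
  f1 <- detect_frame(g, band, m, 10, 0, wp, exposure_s = 1, beamlets = beamlets)
  f2 <- detect_frame(g, band, m, 10, 0, wp, exposure_s = 2, beamlets = beamlets)
  expect_equal(f2$intensities, 2 * f1$intensities)
})

test_that("beamlet sampling is periodic: shifting by one mask period remaps columns", {
  sys <- fix_system(); g <- sys$geometry
  band <- sys$bands$slit20
  wp <- fix_wp("slit20")
  ph <- bar_pattern_phantom(line_widths_um = c(20, 30), n_bars = 3,
                            bar_length_um = 60, voxel_size_um = 2.5,
                            field_um = 400)
  beamlets <- beamlet_positions(band, g, c(-250, 250))
  period <- band$period_um * g$m_s
  f0 <- detect_frame(g, band, ph, 0, 0, wp, beamlets = beamlets)
  f1 <- detect_frame(g, band, ph, 0, period, wp, beamlets = beamlets)
  # beamlet b of the shifted frame sees what beamlet b-1 saw
  nb <- length(beamlets)
  expect_equal(f1$intensities[2:nb], f0$intensities[1:(nb - 1)],
               tolerance = 1e-9)
})

test_that("poisson noise has the right statistics and is seeded per frame", {
  sys <- fix_system(); g <- sys$geometry
  band <- sys$bands$slit20
  wp <- fix_wp("slit20")
  fake_beamlets <- seq(-2000, 2000, length.out = 2000)
  f <- function(seed, fidx = 0L) {
    detect_frame(g, band, NULL, 0, 0, wp,
                 exposure_s = 1e4 / predict(wp$curve, wp$x_m_um),
                 noise = "poisson", seed = seed, frame_index = fidx,
                 beamlets = fake_beamlets)$intensities
  }
  x <- f(1)
  expect_equal(mean(x), 1e4, tolerance = 0.01)
  # relative std ~ 1/sqrt(counts) = 1% at 1e4 counts
  expect_equal(sd(x) / mean(x), 0.01, tolerance = 0.1)
  expect_identical(x, f(1))            # deterministic per (seed, counters)
  expect_false(identical(x, f(2)))     # master seed changes the stream
  expect_false(identical(x, f(1, fidx = 1L)))  # so does the frame counter
})

test_that("simulate_scan is deterministic without noise and structures its output", {
  m <- disc_phantom(n = 64, voxel_um = 2, radius_um = 40)
  sys <- fix_system()
  band <- sys$bands$slit20
  traj <- dithered_trajectory(3, band, sys$geometry, jitter_seed = 2)
  fs1 <- simulate_scan(sys$geometry, band, m, traj, fix_wp("slit20"))
  fs2 <- simulate_scan(sys$geometry, band, m, traj, fix_wp("slit20"))
  expect_identical(fs1$intensities, fs2$intensities)
  expect_equal(sum(fs1$meta$type == "sample"), nrow(traj$entries))
  expect_gte(sum(fs1$meta$type == "flat"), 2)   # initial + final
  expect_gte(sum(fs1$meta$type == "dark"), 1)
  empty <- traj
  empty$entries <- traj$entries[0, ]
  expect_error(simulate_scan(sys$geometry, band, m, empty, fix_wp("slit20")),
               "empty trajectory")
})

test_that("attenuation round trip: -log(I/flat) recovers 2k int beta for an absorber", {
  sys <- fix_system(); g <- sys$geometry
  band <- sys$bands$slit20
  wp <- fix_wp("slit20")
  m <- disc_phantom(n = 96, voxel_um = 2, radius_um = 70, beta = 3e-9)
  beamlets <- beamlet_positions(band, g, c(-96, 96))
  fr <- detect_frame(g, band, m, 20, 0, wp, beamlets = beamlets,
                     beamlet_averaging = FALSE)
  flat <- predict(wp$curve, wp$x_m_um)
  k <- wave_number(m$energy_kev)
  expect_equal(-log(fr$intensities / flat) / (2 * k),
               projected_attenuation(m, 20, beamlets), tolerance = 1e-9)
})
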