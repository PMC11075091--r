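test_that("retrieval transfer is a low-pass filter: |H| <= 1 everywhere", {
  set.seed(11)
  nu <- c(0, 10^runif(200, 0, 6), -(10^runif(200, 0, 6)))
  for (i in 1:30) {
    s <- retrieval_settings(gamma_m = 10^runif(1, -12, -6),
                            z_od_m = runif(1, 0.01, 1),
                            k = 10^runif(1, 10, 12),
                            cp_over_c_per_m = sample(c(-1, 1), 1) * 10^runif(1, 3, 7))
    expect_true(all(Mod(retrieval_transfer(nu, s)) <= 1 + 1e-12))
    expect_equal(Mod(retrieval_transfer(0, s)), 1)
  }
})

test_that("gamma = 0 reduces retrieval to pure attenuation; flat input gives 0", {
  g <- ei_geometry()
  wp <- fix_wp("slit20")
  s0 <- retrieval_settings(0, geom = g, wp = wp)
  V <- matrix(runif(5 * 32, 0.5, 1), 5, 32)
  sino <- eictsim:::new_sinogram(V, seq(0, 288, by = 72), seq_len(32) * 10,
                                 "dithered", "t")
  ret <- phase_retrieve(sino, s0)
  expect_equal(ret$values, -log(V) / (2 * g$k), tolerance = 1e-12)

  flat <- eictsim:::new_sinogram(matrix(1, 4, 32), c(0, 90, 180, 270),
                                 seq_len(32) * 10, "dithered", "t")
  sflt <- retrieval_settings(1e-9, geom = g, wp = wp)
  expect_equal(max(abs(phase_retrieve(flat, sflt)$values)), 0,
               tolerance = 1e-12)
})

test_that("retrieval inverts the linearized forward model", {
  g <- ei_geometry()
  wp <- choose_working_point(fix_curve("slit20"), 0.5,
                             slope_method = "finite_diff")
  k <- g$k
  gam <- 9e-10
  L <- 512; pitch_um <- 2
  x_m <- (seq_len(L) - L / 2) * pitch_um * 1e-6
  blin <- 1.5e-12 * exp(-x_m^2 / (2 * (60e-6)^2))
  A <- exp(-2 * k * blin)
  gvec <- 2 * k * gam * eictsim:::gradient_central(blin, x_m)
  cpc <- (wp$Cprime_per_um / wp$C_xm) * 1e6
  I_lin <- A * (1 - cpc * g$z_od * gvec)
  sino <- eictsim:::new_sinogram(matrix(I_lin, 1), 0, x_m * 1e6, "dithered", "t")
  st <- retrieval_settings(gam, geom = g, cp_over_c_per_m = cpc,
                           z_od_m = g$z_od, k = k)
  ret <- phase_retrieve(sino, st)
  expect_lt(rel_rmse(ret$values[1, ], blin), 1e-3)
})

test_that("non-positive filtered intensities abort with a pixel report", {
  g <- ei_geometry()
  s0 <- retrieval_settings(0, geom = g, wp = fix_wp("slit20"))
  V <- matrix(1, 2, 16); V[2, 5] <- 0
  sino <- eictsim:::new_sinogram(V, c(0, 180), seq_len(16) * 10, "dithered", "t")
  expect_error(phase_retrieve(sino, s0), "non-positive")
})

test_that("FBP reconstructs an analytic disc sinogram", {
  # parallel projections of a uniform disc: P(t) = 2 beta sqrt(R^2 - t^2)
  L <- 101
  pitch <- 4
  t_um <- (seq_len(L) - (L + 1) / 2) * pitch
  R <- 120; beta <- 3e-9
  angles <- seq(0, 360, length.out = 181)[1:180]
  P <- 2 * beta * sqrt(pmax(R^2 - t_um^2, 0)) * 1e-6
  sino <- eictsim:::new_sinogram(matrix(P, length(angles), L, byrow = TRUE),
                                 angles, t_um, "dithered", "t")
  sl <- fbp_reconstruct(sino)
  ax <- sl$axis_um
  RR <- sqrt(outer(ax^2, ax^2, "+"))
  expect_equal(mean(sl$values[RR < 0.8 * R]), beta, tolerance = 0.02)
  # exterior holds only the usual FBP halo, far below the disc level
  expect_lt(mean(abs(sl$values[RR > 1.3 * R])), 0.04 * beta)

  # zero sinogram reconstructs to zero
  z <- eictsim:::new_sinogram(matrix(0, 10, 21), seq(0, 324, by = 36),
                              (seq_len(21) - 11) * 5, "dithered", "t")
  expect_equal(max(abs(fbp_reconstruct(z)$values)), 0)
  expect_error(fbp_reconstruct(eictsim:::new_sinogram(matrix(0, 1, 5), 0,
                                                      1:5, "d", "t")),
               "at least 2")
})

test_that("FBP localises an off-centre point at its polar position", {
  L <- 81; pitch <- 4
  t_um <- (seq_len(L) - (L + 1) / 2) * pitch
  angles <- seq(0, 360, length.out = 121)[1:120]
  r0 <- 80; phi0 <- 55 * pi / 180
  trace <- r0 * cos(angles * pi / 180 - phi0)
  V <- t(vapply(trace, function(tc) exp(-(t_um - tc)^2 / (2 * 6^2)),
                numeric(L)))
  sino <- eictsim:::new_sinogram(V * 1e-9, angles, t_um, "dithered", "t")
  sl <- fbp_reconstruct(sino)
  idx <- which(sl$values == max(sl$values), arr.ind = TRUE)
  got_x <- sl$axis_um[idx[1, 2]]
  got_y <- sl$axis_um[idx[1, 1]]
  expect_lt(abs(got_x - r0 * cos(phi0)), 1.5 * pitch)
  expect_lt(abs(got_y - r0 * sin(phi0)), 1.5 * pitch)
})

test_that("FBP is linear in the sinogram", {
  set.seed(4)
  L <- 33
  angles <- seq(0, 350, by = 10)
  lat <- (seq_len(L) - 17) * 8
  s1 <- eictsim:::new_sinogram(matrix(rnorm(36 * L), 36, L), angles, lat, "d", "t")
  s2 <- eictsim:::new_sinogram(matrix(rnorm(36 * L), 36, L), angles, lat, "d", "t")
  s12 <- eictsim:::new_sinogram(2 * s1$values - 3 * s2$values, angles, lat, "d", "t")
  expect_equal(fbp_reconstruct(s12)$values,
               2 * fbp_reconstruct(s1)$values - 3 * fbp_reconstruct(s2)$values,
               tolerance = 1e-12)
})

test_that("modulation analysis: perfect bars give 1, uniform regions give 0", {
  n <- 120; pitch <- 2
  ax <- (seq_len(n) - (n + 1) / 2) * pitch
  vals <- matrix(0, n, n)
  width <- 12
  x0 <- -36
  u <- (ax - x0) / width
  bars <- u >= 0 & u < 6 & (floor(u) %% 2 == 0)
  vals[ax >= -40 & ax <= 40, bars] <- 1
  slice <- structure(list(values = vals, axis_um = ax, pixel_size_um = pitch,
                          band_id = "t", scheme = "d"),
                     class = "ei_reconslice")
  grp <- list(width_um = width, n_bars = 3, x0_um = x0, x1_um = x0 + 6 * width,
              y0_um = -40, y1_um = 40, frequency_lpmm = 1000 / (2 * width))
  expect_equal(modulation_analysis(slice, list(grp))$modulation, 1)

  uni <- slice; uni$values <- matrix(5, n, n)
  expect_equal(modulation_analysis(uni, list(grp))$modulation, 0)
  # clipped at 0 for inverted contrast
  inv <- slice; inv$values <- 1 - vals
  expect_equal(modulation_analysis(inv, list(grp))$modulation, 0)
  # box outside the slice errors
  far <- grp; far$x0_um <- 500; far$x1_um <- 600
  expect_error(modulation_analysis(slice, list(far)), "outside")
})

test_that("beta converts to the linear attenuation coefficient", {
  expect_equal(beta_to_mu(1e-9, 18), 2 * wave_number(18) * 1e-9)
})
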