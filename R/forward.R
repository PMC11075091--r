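# Bilinear interpolation on a matrix at fractional (row, col) coordinates;
# points outside the grid evaluate to 0 (vacuum).
bilinear_mat <- function(M, row_f, col_f) {
  nr <- nrow(M); nc <- ncol(M)
  out <- numeric(length(row_f))
  ok <- row_f >= 1 & row_f <= nr & col_f >= 1 & col_f <= nc
  if (!any(ok)) return(out)
  r <- row_f[ok]; c <- col_f[ok]
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  v00 <- M[cbind(r0, c0)]
  v10 <- M[cbind(r0 + 1, c0)]
  v01 <- M[cbind(r0, c0 + 1)]
  v11 <- M[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

# Parallel-beam projections of delta and beta through the rotated map on a
# fine lateral grid (pitch = one voxel). Returns line integrals in metres
# (dimensionless index times path length).
project_profiles <- function(map, angle_deg) {
  n <- nrow(map$delta)
  v <- map$voxel_size_um
  th <- angle_deg * pi / 180
  nt <- 2L * ceiling(sqrt(2) * n / 2) + 1L     # odd, covers the diagonal
  t_um <- (seq_len(nt) - (nt + 1) / 2) * v
  s_um <- t_um
  ct <- cos(th); st <- sin(th)
  X <- outer(t_um, s_um, function(t, s) t * ct - s * st)
  Y <- outer(t_um, s_um, function(t, s) t * st + s * ct)
  col_f <- X / v + (n + 1) / 2
  row_f <- Y / v + (n + 1) / 2
  ds_m <- v * 1e-6
  beta_line <- matrix(bilinear_mat(map$beta, row_f, col_f), nt, nt)
  delta_line <- matrix(bilinear_mat(map$delta, row_f, col_f), nt, nt)
  list(t_um = t_um,
       beta_line_m = rowSums(beta_line) * ds_m,
       delta_line_m = rowSums(delta_line) * ds_m)
}

#' Projected attenuation line integrals
#'
#' Parallel-ray line integrals of the absorption index beta through the map
#' rotated by `angle_deg`, evaluated at the requested lateral sample-plane
#' positions. Positions outside the (padded) support see vacuum and return
#' 0.
#'
#' @param map an [optical_map()].
#' @param angle_deg projection angle (degrees).
#' @param positions_um lateral positions at the sample plane (micrometres).
#' @return integral of beta along z, in metres.
#' @export
projected_attenuation <- function(map, angle_deg, positions_um) {
  pr <- project_profiles(map, angle_deg)
  interp_zero(pr$t_um, pr$beta_line_m, positions_um)
}

#' Transverse gradient of the projected phase term
#'
#' Central-difference derivative (with respect to the lateral coordinate x)
#' of the projected refractive-index decrement delta, evaluated at the
#' requested positions. This is the refraction angle the beamlets pick up.
#'
#' @inheritParams projected_attenuation
#' @return d/dx of the delta line integral (dimensionless, radians).
#' @export
refraction_gradient <- function(map, angle_deg, positions_um) {
  pr <- project_profiles(map, angle_deg)
  g <- gradient_central(pr$delta_line_m, pr$t_um * 1e-6)
  interp_zero(pr$t_um, g, positions_um)
}

gradient_central <- function(y, x_m) {
  n <- length(y)
  g <- numeric(n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x_m[3:n] - x_m[1:(n - 2)])
  g[1] <- (y[2] - y[1]) / (x_m[2] - x_m[1])
  g[n] <- (y[n] - y[n - 1]) / (x_m[n] - x_m[n - 1])
  g
}

#' Beamlet centre positions at the sample plane
#'
#' The sample mask provides one beamlet per mask period; projected to the
#' sample plane the beamlets sit on a lattice of pitch `p * m_s` (absolute,
#' containing 0). The lattice must cover the phantom support plus the full
#' lateral translation range of the scan.
#'
#' @param band an [mask_band()].
#' @param geom an [ei_geometry()].
#' @param extent_um lateral half-open interval `c(lo, hi)` (micrometres,
#'   sample plane) the beamlets must cover.
#' @return numeric vector of beamlet centre positions (micrometres).
#' @export
beamlet_positions <- function(band, geom, extent_um) {
  pitch <- band$period_um * geom$m_s
  j <- seq(floor(extent_um[1] / pitch), ceiling(extent_um[2] / pitch))
  j * pitch
}

# Detected count rate as a function of lateral sample-plane position for
# one projection angle: exp(-2 k int beta dz) * C(x_m - z_od g), averaged
# over the beamlet footprint (top-hat of width w * m_s) when averaging is
# on. The footprint average is what gives EI its aperture-driven
# resolution: each beamlet reports the mean transmitted intensity of the
# sample strip it traverses, so structure finer than the aperture is
# blurred away rather than aliased.
detection_profile <- function(geom, band, map, angle_deg, wp,
                              beamlet_averaging = TRUE, profiles = NULL) {
  if (is.null(profiles)) profiles <- project_profiles(map, angle_deg)
  curve <- wp$curve
  k <- wave_number(map$energy_kev)
  g <- gradient_central(profiles$delta_line_m, profiles$t_um * 1e-6)
  arg <- wp$x_m_um - geom$z_od * g * 1e6
  lo <- min(curve$offsets_um); hi <- max(curve$offsets_um)
  n_clamped <- sum(arg < lo | arg > hi)
  if (n_clamped > 0) arg <- pmin(pmax(arg, lo), hi)
  rate <- exp(-2 * k * profiles$beta_line_m) * predict(curve, arg)
  if (beamlet_averaging) {
    v_um <- profiles$t_um[2] - profiles$t_um[1]
    n_box <- max(1L, round(band$aperture_um * geom$m_s / v_um))
    if (n_box > 1L) {
      kern <- rep(1 / n_box, n_box)
      # pad with vacuum (flat) rate so edges stay physical
      padded <- c(rep(rate[1], n_box), rate, rep(rate[length(rate)], n_box))
      sm <- stats::filter(padded, kern, sides = 2)
      rate <- as.numeric(sm[(n_box + 1):(n_box + length(rate))])
    }
  }
  list(t_um = profiles$t_um, rate = rate, n_clamped = n_clamped)
}

#' Detect one EI frame
#'
#' Implements the EI image-formation model for one frame: per illuminated
#' column, `I = exposure * exp(-2 k int beta dz) * C(x_m - z_od * g)`, with
#' `g` the refraction gradient at the beamlet position and C(.) the
#' illumination curve in counts per second (the upstream beamlet intensity
#' I0 is carried by the curve normalisation). The detected rate is averaged
#' over the beamlet footprint (a top-hat of width `w * m_s` at the sample
#' plane) -- the mechanism behind aperture-driven resolution; set
#' `beamlet_averaging = FALSE` for point evaluation at the beamlet centre.
#' The sample sits shifted by `lateral_offset_um`, so beamlet b probes the
#' sample at `x_b - offset`. Refraction shifts beyond the measured curve
#' support are clamped (the clamp count is returned in the frame).
#'
#' @param geom an [ei_geometry()].
#' @param band an [mask_band()].
#' @param map an [optical_map()]; `NULL` simulates a flat field.
#' @param angle_deg projection angle.
#' @param lateral_offset_um lateral sample shift (sample plane).
#' @param wp an `ei_workingpoint` from [choose_working_point()].
#' @param exposure_s exposure time.
#' @param noise `"none"` or `"poisson"`.
#' @param seed,angle_index,frame_index determine the per-frame noise
#'   substream (counter-based, order independent).
#' @param beamlets beamlet positions; default from the map extent.
#' @param beamlet_averaging average the detected rate over the beamlet
#'   footprint (default) or point-sample at the beamlet centre.
#' @param detection optional precomputed [detection_profile()] for this
#'   angle (used by [simulate_scan()] to share work across dither steps).
#' @return an `ei_frame` list.
#' @export
detect_frame <- function(geom, band, map, angle_deg, lateral_offset_um, wp,
                         exposure_s = 1, noise = c("none", "poisson"),
                         seed = 1L, angle_index = 0L, frame_index = 0L,
                         beamlets = NULL, beamlet_averaging = TRUE,
                         detection = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(wp, "ei_workingpoint"))
  curve <- wp$curve
  if (is.null(beamlets)) {
    if (is.null(map)) stop("beamlets must be given when no map is provided")
    half <- nrow(map$delta) * map$voxel_size_um / 2
    beamlets <- beamlet_positions(band, geom, c(-half, half + lateral_offset_um))
  }
  n_clamped <- 0L
  if (is.null(map)) {
    I_rate <- rep(predict(curve, wp$x_m_um), length(beamlets))
  } else {
    pos <- beamlets - lateral_offset_um
    if (is.null(detection)) {
      detection <- detection_profile(geom, band, map, angle_deg, wp,
                                     beamlet_averaging = beamlet_averaging)
    }
    n_clamped <- detection$n_clamped
    if (n_clamped > 0) {
      warning(sprintf("%d refraction shift(s) exceed the measured curve support; clamped", n_clamped))
    }
    flat_rate <- predict(curve, wp$x_m_um)
    # outside the projected support the sample is vacuum: flat rate
    I_rate <- interp_zero(detection$t_um, detection$rate - flat_rate, pos) + flat_rate
  }
  I <- I_rate * exposure_s
  if (noise == "poisson") {
    rs <- local_rng(frame_seed(seed, angle_index, frame_index))
    on.exit(restore_rng(rs))
    I <- as.numeric(stats::rpois(length(I), I))
  }
  structure(list(intensities = I, beamlets_um = beamlets,
                 angle_deg = angle_deg, lateral_offset_um = lateral_offset_um,
                 exposure_s = exposure_s, band_id = band$id,
                 type = if (is.null(map)) "flat" else "sample",
                 n_clamped = n_clamped),
            class = "ei_frame")
}

#' Simulate a full scan into a frame set
#'
#' Runs [detect_frame()] for every trajectory entry (sharing the projection
#' of each distinct angle across its dither steps), interleaving flat-field
#' frames every `flat_cadence` distinct angles (plus one final flat) and
#' prepending dark frames. All noise is seeded deterministically per frame
#' from `seed` and the frame counters.
#'
#' @param geom,band,map,wp see [detect_frame()].
#' @param traj an `ei_trajectory`.
#' @param noise `"none"` or `"poisson"`.
#' @param seed master seed.
#' @param flat_cadence acquire a flat every this many distinct angles.
#' @param flat_exposure_s exposure of each flat acquisition; defaults to 10x
#'   the median frame exposure, emulating the usual practice of averaging a
#'   burst of flat frames so the correction adds little noise.
#' @param n_darks number of dark frames (detector offset level
#'   `dark_rate * exposure`).
#' @param dark_rate dark counts per second per column.
#' @param pad_um extra beamlet coverage beyond the phantom support.
#' @param beamlet_averaging see [detect_frame()].
#' @return an `ei_frameset`: intensity matrix (frame x beamlet), a metadata
#'   data frame, and the beamlet lattice.
#' @export
simulate_scan <- function(geom, band, map, traj, wp,
                          noise = c("none", "poisson"), seed = 1L,
                          flat_cadence = 100, flat_exposure_s = NULL,
                          n_darks = 1, dark_rate = 0,
                          pad_um = 0, beamlet_averaging = TRUE) {
  noise <- match.arg(noise)
  stopifnot(inherits(traj, "ei_trajectory"))
  ent <- traj$entries
  if (nrow(ent) == 0) stop("empty trajectory")
  half <- nrow(map$delta) * map$voxel_size_um / 2
  beamlets <- beamlet_positions(band, geom,
                                c(-half - pad_um,
                                  half + max(ent$offset_um) + pad_um))
  nb <- length(beamlets)
  flat_rate <- predict(wp$curve, wp$x_m_um)
  exp_flat <- if (is.null(flat_exposure_s)) {
    10 * stats::median(ent$exposure_s)
  } else flat_exposure_s

  rows <- list(); meta <- list(); fi <- 0L
  push <- function(int, type, angle_deg, angle_index, offset, expo, entry_index) {
    fi <<- fi + 1L
    rows[[fi]] <<- int
    meta[[fi]] <<- data.frame(type = type, angle_deg = angle_deg,
                              angle_index = angle_index, offset_um = offset,
                              exposure_s = expo, entry_index = entry_index)
  }
  noisy <- function(I, aidx, fidx) {
    if (noise == "poisson") {
      rs <- local_rng(frame_seed(seed, aidx, fidx))
      on.exit(restore_rng(rs))
      as.numeric(stats::rpois(length(I), I))
    } else I
  }
  for (d in seq_len(n_darks)) {
    push(noisy(rep(dark_rate * exp_flat, nb), -1L, d), "dark", NA, -1L, 0, exp_flat, NA)
  }
  push(noisy(rep(flat_rate * exp_flat, nb), -2L, 0L), "flat", NA, -2L, 0, exp_flat, NA)

  angle_groups <- split(seq_len(nrow(ent)), ent$angle_index)
  n_since_flat <- 0L
  for (gi in seq_along(angle_groups)) {
    idx <- angle_groups[[gi]]
    a <- ent$angle_deg[idx[1]]
    aidx <- ent$angle_index[idx[1]]
    det <- detection_profile(geom, band, map, a, wp,
                             beamlet_averaging = beamlet_averaging)
    for (i in idx) {
      fr <- detect_frame(geom, band, map, a, ent$offset_um[i], wp,
                         exposure_s = ent$exposure_s[i], noise = "none",
                         beamlets = beamlets, detection = det)
      push(noisy(fr$intensities + dark_rate * ent$exposure_s[i], aidx, i),
           "sample", a, aidx, ent$offset_um[i], ent$exposure_s[i], i)
    }
    n_since_flat <- n_since_flat + 1L
    if (n_since_flat >= flat_cadence && gi < length(angle_groups)) {
      push(noisy(rep(flat_rate * exp_flat, nb), -2L, gi), "flat", NA, -2L, 0,
           exp_flat, NA)
      n_since_flat <- 0L
    }
  }
  push(noisy(rep(flat_rate * exp_flat, nb), -2L, length(angle_groups) + 1L),
       "flat", NA, -2L, 0, exp_flat, NA)

  structure(list(intensities = do.call(rbind, rows),
                 meta = do.call(rbind, meta),
                 beamlets_um = beamlets,
                 band_id = band$id, scheme = traj$scheme,
                 trajectory = traj, seed = seed, noise = noise),
            class = "ei_frameset")
}

#' @export
print.ei_frameset <- function(x, ...) {
  tab <- table(x$meta$type)
  cat(sprintf("EI frame set (band '%s', scheme '%s'): %s; %d beamlets\n",
              x$band_id, x$scheme,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              length(x$beamlets_um)))
  invisible(x)
}
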