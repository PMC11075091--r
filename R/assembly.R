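#' Flat-field and dark-field correction
#'
#' First processing step for any frame set: each sample frame becomes
#' `(I - dark) / (flat - dark)`, with the dark level averaged over all dark
#' frames and the flats linearly interpolated in acquisition time between
#' flat acquisitions (so slow illumination drifts are tracked). Frames and
#' flats may have different exposures; the correction is applied on count
#' rates. The output is dimensionless, ~1 in the background.
#'
#' @param fs an `ei_frameset` from [simulate_scan()].
#' @return an `ei_normframes` list: `values` (sample frame x beamlet matrix
#'   of normalized intensities), `meta`, `beamlets_um`, and provenance.
#' @export
flat_dark_correct <- function(fs) {
  stopifnot(inherits(fs, "ei_frameset"))
  types <- fs$meta$type
  if (!any(types == "flat")) stop("frame set contains no flat frames")
  if (!any(types == "dark")) stop("frame set contains no dark frames")
  dark_rate <- colMeans(sweep(fs$intensities[types == "dark", , drop = FALSE],
                              1, fs$meta$exposure_s[types == "dark"], "/"))
  flat_rows <- which(types == "flat")
  flat_rates <- sweep(fs$intensities[flat_rows, , drop = FALSE], 1,
                      fs$meta$exposure_s[flat_rows], "/")
  sample_rows <- which(types == "sample")
  nb <- ncol(fs$intensities)
  # time axis = frame row index; interpolate each beamlet's flat rate
  flat_at <- matrix(0, length(sample_rows), nb)
  if (length(flat_rows) == 1L) {
    flat_at <- matrix(flat_rates, length(sample_rows), nb, byrow = TRUE)
  } else {
    for (b in seq_len(nb)) {
      flat_at[, b] <- stats::approx(flat_rows, flat_rates[, b],
                                    xout = sample_rows,
                                    rule = 2, ties = "ordered")$y
    }
  }
  denom <- sweep(flat_at, 2, dark_rate, "-")
  if (any(denom <= 0)) {
    bad <- which(denom <= 0, arr.ind = TRUE)
    stop(sprintf("flat <= dark at %d pixel(s), first at frame %d beamlet %d",
                 nrow(bad), sample_rows[bad[1, 1]], bad[1, 2]))
  }
  sample_rates <- sweep(fs$intensities[sample_rows, , drop = FALSE], 1,
                        fs$meta$exposure_s[sample_rows], "/")
  values <- (sample_rates -
               matrix(dark_rate, length(sample_rows), nb, byrow = TRUE)) / denom
  structure(list(values = values, meta = fs$meta[sample_rows, , drop = FALSE],
                 beamlets_um = fs$beamlets_um, band_id = fs$band_id,
                 scheme = fs$scheme, trajectory = fs$trajectory),
            class = "ei_normframes")
}

new_sinogram <- function(values, angles_deg, lateral_um, scheme, band_id,
                         provenance = list()) {
  stopifnot(nrow(values) == length(angles_deg),
            ncol(values) == length(lateral_um))
  structure(list(values = values, angles_deg = angles_deg,
                 lateral_um = lateral_um,
                 pitch_um = if (length(lateral_um) > 1) diff(lateral_um[1:2]) else NA_real_,
                 scheme = scheme, band_id = band_id, provenance = provenance),
            class = "ei_sinogram")
}

#' @export
print.ei_sinogram <- function(x, ...) {
  cat(sprintf("EI sinogram (%s, band '%s'): %d angles x %d lateral samples, pitch %.3f um\n",
              x$scheme, x$band_id, length(x$angles_deg), length(x$lateral_um),
              x$pitch_um))
  invisible(x)
}

#' Interleave dithered frames into a rectangular sinogram
#'
#' For each angle the `N_dith` frames are placed at the lateral sample-plane
#' position actually probed: beamlet position minus the applied offset,
#' i.e. the per-angle jitter is reversed exactly (offsets are reconstructed
#' from the stored integer step and jitter indices). Because the mask period
#' is not an exact multiple of the dither step (79 vs 4 x 20 um), the true
#' positions are uniform only within each period; the assembled row is
#' therefore resampled onto an exactly uniform grid of pitch `w * m_s` by a
#' cubic spline, which removes the cumulative sub-micrometre coordinate
#' distortion a purely index-based interleave would carry into the
#' reconstruction.
#'
#' @param norm an `ei_normframes` from [flat_dark_correct()].
#' @param traj the dithered `ei_trajectory` used for the scan.
#' @return an `ei_sinogram` of normalized intensities.
#' @export
interleave_dithered <- function(norm, traj = norm$trajectory) {
  stopifnot(inherits(norm, "ei_normframes"), inherits(traj, "ei_trajectory"))
  if (traj$scheme != "dithered") stop("interleave_dithered() needs a dithered trajectory")
  ent <- traj$entries
  meta <- norm$meta
  nd <- traj$n_dith
  step <- traj$step_um
  angle_idx <- sort(unique(ent$angle_index))
  # completeness check
  have <- paste(meta$angle_index, ent$dither_index[meta$entry_index], sep = ":")
  want <- as.vector(outer(angle_idx, 0:(nd - 1), paste, sep = ":"))
  gaps <- setdiff(want, have)
  if (length(gaps)) {
    stop("missing frame(s) for (angle, step): ", paste(utils::head(gaps, 10), collapse = ", "))
  }
  b <- norm$beamlets_um
  lat <- seq(min(b) - (nd - 1) * step, max(b), by = step)
  values <- matrix(0, length(angle_idx), length(lat))
  angles <- numeric(length(angle_idx))
  n_extrap <- 0L
  for (ai in seq_along(angle_idx)) {
    rows <- which(meta$angle_index == angle_idx[ai])
    e <- ent[meta$entry_index[rows], ]
    angles[ai] <- e$angle_deg[1]
    # true probed positions (geometric jitter reversal: each frame is placed
    # at the coordinate it actually measured, via the integer step indices)
    pos <- rep(b, times = length(rows)) -
      rep((e$dither_index + e$jitter_index) * step, each = length(b))
    val <- as.vector(t(norm$values[rows, , drop = FALSE]))
    ord <- order(pos)
    pos <- pos[ord]; val <- val[ord]
    sf <- stats::splinefun(pos, val, method = "natural")
    values[ai, ] <- sf(lat)
    n_extrap <- n_extrap + sum(lat < pos[1] | lat > pos[length(pos)])
  }
  ord <- order(angles)
  new_sinogram(values[ord, , drop = FALSE], angles[ord], lat, "dithered",
               norm$band_id,
               provenance = list(n_dith = nd, step_um = step,
                                 jitter_reversed = TRUE,
                                 n_extrapolated = n_extrap))
}

#' Regrid a cycloidal fly scan onto a rectangular sinogram
#'
#' Cycloidal frames are scattered samples in the angle-lateral plane, lying
#' on a sheared regular lattice (the beamlet lattice swept by the
#' back-and-forth translation). Regridding is shear-aligned and separable:
#' (1) each beamlet's measured values are splined along the angle direction;
#' (2) for every target lateral column the angles at which each beamlet's
#' trajectory crosses that column are computed in closed form from the
#' triangle-wave translation, the beamlet splines are evaluated at those
#' crossing angles, and a second (periodic) cubic spline through the
#' crossing samples yields the column at all target angles. For a type 1
#' scan the crossing density per column equals the dithered angular
#' sampling, so full in-slice resolution is preserved; for a type 2 scan
#' the wider shift per frame means each beamlet spline low-passes the
#' lateral detail between frames -- the intrinsic anti-aliasing of the
#' scheme. Duplicate crossings at translation turnarounds are averaged.
#'
#' @param norm an `ei_normframes` from [flat_dark_correct()].
#' @param traj the cyc1/cyc2 `ei_trajectory` used.
#' @param target_angles_deg target angle grid; default: `n/N_dith`
#'   equispaced angles for type 1 (the dithered-equivalent grid), all
#'   acquired angles for type 2.
#' @param lateral_grid_um target lateral grid; default: pitch `w * m_s`
#'   over the fully swept region `[min(beamlets), max(beamlets) - span]`.
#' @return an `ei_sinogram`.
#' @export
regrid_cycloidal <- function(norm, traj = norm$trajectory,
                             target_angles_deg = NULL,
                             lateral_grid_um = NULL) {
  stopifnot(inherits(norm, "ei_normframes"), inherits(traj, "ei_trajectory"))
  if (!traj$scheme %in% c("cyc1", "cyc2")) {
    stop("regrid_cycloidal() needs a cyc1 or cyc2 trajectory")
  }
  ent <- traj$entries
  meta <- norm$meta
  ord <- order(meta$entry_index)
  vals <- norm$values[ord, , drop = FALSE]
  e <- ent[meta$entry_index[ord], ]
  n <- nrow(e)
  b <- norm$beamlets_um
  step <- traj$step_um
  span <- traj$span_um
  adv <- traj$adv_um                    # lateral advance per frame, sample plane
  dtheta <- 360 / n
  if (is.null(target_angles_deg)) {
    n_t <- if (traj$scheme == "cyc1") n / traj$n_dith else n
    n_t <- as.integer(round(n_t))
    target_angles_deg <- seq(0, 360, length.out = n_t + 1)[seq_len(n_t)]
  }
  if (is.null(lateral_grid_um)) {
    lateral_grid_um <- seq(min(b), max(b) - span, by = step)
  }
  o_max <- max(e$offset_um)
  if (min(lateral_grid_um) < min(b) - o_max - traj$period_um ||
      max(lateral_grid_um) > max(b) + traj$period_um) {
    stop("target grid exceeds the sampled lateral span by more than one period")
  }
  # pass 1: per-beamlet splines along angle (periodic padding)
  th <- e$angle_deg
  beam_spl <- vector("list", length(b))
  for (j in seq_along(b)) {
    beam_spl[[j]] <- stats::splinefun(c(th - 360, th, th + 360),
                                      rep(vals[, j], 3), method = "natural")
  }
  # crossing angles: travel m(theta) = adv * theta/dtheta, folded into
  # [0, span] with period 2*span; beamlet j crosses column xi when the
  # folded travel equals b[j] - xi.
  m_max <- adv * (n - 1)
  values <- matrix(NA_real_, length(target_angles_deg), length(lateral_grid_um))
  n_dup <- 0L
  for (ci in seq_along(lateral_grid_um)) {
    xi <- lateral_grid_um[ci]
    o_star <- b - xi
    cross_th <- numeric(0)
    cross_v <- numeric(0)
    for (j in seq_along(b)) {
      os <- o_star[j]
      if (os < 0 || os > span) next
      q_max <- floor((m_max - os) / (2 * span))
      ms <- if (q_max >= 0) os + 2 * span * (0:q_max) else numeric(0)
      q2 <- floor((m_max - (2 * span - os)) / (2 * span))
      ms2 <- if (q2 >= 0) (2 * span - os) + 2 * span * (0:q2) else numeric(0)
      mm <- sort(unique(c(ms, ms2)))
      if (!length(mm)) next
      tt <- mm / adv * dtheta
      cross_th <- c(cross_th, tt)
      cross_v <- c(cross_v, beam_spl[[j]](tt))
    }
    if (length(cross_th) < 4) {
      stop(sprintf("lateral column %.1f um has only %d crossing sample(s); narrow the target grid",
                   xi, length(cross_th)))
    }
    o2 <- order(cross_th)
    cross_th <- cross_th[o2]; cross_v <- cross_v[o2]
    dup <- c(FALSE, diff(cross_th) < 1e-9)
    if (any(dup)) {
      n_dup <- n_dup + sum(dup)
      keep <- !dup
      agg <- tapply(cross_v, cumsum(keep), mean)
      cross_th <- cross_th[keep]
      cross_v <- as.numeric(agg)
    }
    colspl <- stats::splinefun(c(cross_th - 360, cross_th, cross_th + 360),
                               rep(cross_v, 3), method = "natural")
    values[, ci] <- colspl(target_angles_deg)
  }
  new_sinogram(values, target_angles_deg, lateral_grid_um, traj$scheme,
               norm$band_id,
               provenance = list(step_um = step, span_um = span,
                                 shift_um = traj$shift_um,
                                 n_duplicate_crossings = n_dup))
}
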