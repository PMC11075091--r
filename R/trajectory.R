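#' Number of dithering steps for a mask band
#'
#' Frames per angle needed to fully sample one mask period with apertures of
#' width w: `N_dith = p/w`, rounded up since the printed period is not an
#' integer multiple of any band's aperture (79/20 = 3.95 -> 4, 79/10 = 7.9
#' -> 8, 79/5 = 15.8 -> 16).
#'
#' @param band an [mask_band()].
#' @return integer number of dithering steps.
#' @export
dither_steps <- function(band) {
  stopifnot(inherits(band, "ei_maskband"))
  if (band$aperture_um >= band$period_um) stop("aperture width must be < period")
  as.integer(ceiling(band$period_um / band$aperture_um))
}

new_trajectory <- function(entries, scheme, band, geom, extra = list()) {
  entries$index <- seq_len(nrow(entries)) - 1L
  entries <- entries[, c("index", "angle_deg", "offset_um", "exposure_s",
                         setdiff(names(entries), c("index", "angle_deg",
                                                   "offset_um", "exposure_s")))]
  structure(c(list(entries = entries, scheme = scheme, band_id = band$id,
                   step_um = band$aperture_um * geom$m_s,
                   period_um = band$period_um * geom$m_s,
                   n_dith = dither_steps(band)),
              extra),
            class = "ei_trajectory")
}

#' @export
print.ei_trajectory <- function(x, ...) {
  cat(sprintf("EI trajectory: scheme '%s', band '%s', %d entries, %d distinct angles\n",
              x$scheme, x$band_id, nrow(x$entries),
              length(unique(x$entries$angle_deg))))
  invisible(x)
}

#' Dithered (step-and-shoot) acquisition trajectory
#'
#' For each of `n_angles` equispaced angles in \[0, 360) the sample is
#' stepped through `N_dith = ceiling(p/w)` lateral positions spaced by one
#' dither step `w * m_s` (the aperture width projected to the sample plane).
#' Optionally a pseudo-random per-angle jitter -- an integer multiple of the
#' dither step spanning one period -- is added to every offset of that
#' angle; the jitter table is stored on the trajectory so that assembly can
#' reverse it exactly. Jitter decorrelates mask-defect ring artefacts.
#'
#' @param n_angles number of distinct projection angles (>= 1).
#' @param band an [mask_band()].
#' @param geom an [ei_geometry()].
#' @param jitter_seed integer seed for the jitter table, or `NULL` for no
#'   jitter.
#' @param exposure_s exposure per frame (seconds).
#' @param overhead_per_step_s step-and-shoot overhead per frame (seconds),
#'   used by [scan_duration()].
#' @return an `ei_trajectory` whose `entries` data frame has one row per
#'   frame with columns `index`, `angle_deg`, `offset_um` (sample plane),
#'   `exposure_s`, `angle_index`, `dither_index`, `jitter_index`.
#' @export
dithered_trajectory <- function(n_angles, band, geom, jitter_seed = NULL,
                                exposure_s = 1, overhead_per_step_s = 0) {
  stopifnot(n_angles >= 1)
  nd <- dither_steps(band)
  step <- band$aperture_um * geom$m_s
  angles <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]
  jitter_idx <- rep(0L, n_angles)
  if (!is.null(jitter_seed) && nd > 1) {
    rs <- local_rng(jitter_seed)
    on.exit(restore_rng(rs))
    jitter_idx <- sample.int(nd, n_angles, replace = TRUE) - 1L
  }
  entries <- data.frame(
    angle_deg = rep(angles, each = nd),
    angle_index = rep(seq_len(n_angles) - 1L, each = nd),
    dither_index = rep(seq_len(nd) - 1L, times = n_angles),
    jitter_index = rep(jitter_idx, each = nd),
    exposure_s = exposure_s
  )
  entries$offset_um <- (entries$dither_index + entries$jitter_index) * step
  new_trajectory(entries, "dithered", band, geom,
                 extra = list(jitter_table = jitter_idx,
                              jitter_seed = jitter_seed,
                              overhead_per_step_s = overhead_per_step_s))
}

# triangle fold of a cumulative travel m into [0, span]
fold_back_and_forth <- function(m, span) {
  m2 <- m %% (2 * span)
  span - abs(m2 - span)
}

#' Cycloidal type 1 (fully sampled fly-scan) trajectory
#'
#' Rotation and lateral translation proceed simultaneously: data are
#' acquired at `n_angles_base * N_dith` equispaced angles with exactly one
#' frame per angle, the lateral offset advancing by one dither step
#' (`w * m_s`) per angular increment. The sampling density in the
#' angle-offset plane equals that of the dithered scheme; the grid is merely
#' sheared. The translation follows a back-and-forth (triangle-wave)
#' trajectory with a total span of `span_periods` projected mask periods so
#' the field of view is preserved.
#'
#' @param n_angles_base base number of angles N (the dithered-equivalent
#'   angle count).
#' @inheritParams dithered_trajectory
#' @param span_periods back-and-forth span in projected mask periods.
#' @return an `ei_trajectory` (one entry per angle).
#' @export
cycloidal_type1_trajectory <- function(n_angles_base, band, geom,
                                       exposure_s = 1, span_periods = 10) {
  stopifnot(n_angles_base >= 1)
  nd <- dither_steps(band)
  cycloidal_trajectory(n_angles_base * nd, shift_um = band$aperture_um,
                       band = band, geom = geom, exposure_s = exposure_s,
                       span_periods = span_periods, scheme = "cyc1")
}

#' Cycloidal type 2 (under-sampled fly-scan) trajectory
#'
#' Like type 1 but with a larger lateral advance per frame (implemented on
#' the instrument by speeding rotation and translation up relative to the
#' detector frame rate), so the angle-offset plane is sampled more sparsely.
#' The continuous roto-translation acts as a low-pass filter, giving the
#' scheme an intrinsic anti-aliasing character.
#'
#' @param n_angles number of angles (= frames).
#' @param shift_um lateral advance per frame, stated at the sample-mask
#'   scale (the sample moves by `shift_um * m_s`); must exceed the aperture
#'   width, otherwise the scan is type 1.
#' @inheritParams cycloidal_type1_trajectory
#' @return an `ei_trajectory` (one entry per angle).
#' @export
cycloidal_type2_trajectory <- function(n_angles, shift_um, band, geom,
                                       exposure_s = 1, span_periods = 10) {
  stopifnot(n_angles >= 1)
  if (shift_um < band$aperture_um) {
    stop("shift per frame below the dither step; use cycloidal_type1_trajectory()")
  }
  cycloidal_trajectory(n_angles, shift_um = shift_um, band = band, geom = geom,
                       exposure_s = exposure_s, span_periods = span_periods,
                       scheme = "cyc2")
}

cycloidal_trajectory <- function(n_angles, shift_um, band, geom, exposure_s,
                                 span_periods, scheme) {
  angles <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]
  span <- span_periods * band$period_um * geom$m_s
  travel <- (seq_len(n_angles) - 1) * shift_um * geom$m_s
  entries <- data.frame(
    angle_deg = angles,
    angle_index = seq_len(n_angles) - 1L,
    dither_index = 0L,
    jitter_index = 0L,
    exposure_s = exposure_s
  )
  entries$offset_um <- fold_back_and_forth(travel, span)
  new_trajectory(entries, scheme, band, geom,
                 extra = list(shift_um = shift_um,
                              adv_um = shift_um * geom$m_s,
                              span_um = span, span_periods = span_periods,
                              overhead_per_step_s = 0))
}

#' Total scan duration of a trajectory
#'
#' Fly schemes (cycloidal) take the summed exposure; step-and-shoot
#' (dithered) scans additionally pay a per-step motion/readout overhead.
#' E.g. 2400 frames at 1.2 s in fly mode take 2880 s = 48 min.
#'
#' @param traj an `ei_trajectory`.
#' @return duration in seconds.
#' @export
scan_duration <- function(traj) {
  stopifnot(inherits(traj, "ei_trajectory"))
  total <- sum(traj$entries$exposure_s)
  if (traj$scheme == "dithered") {
    oh <- if (is.null(traj$overhead_per_step_s)) 0 else traj$overhead_per_step_s
    total <- total + oh * nrow(traj$entries)
  }
  total
}

#' Serialize / read a trajectory as CSV with a JSON header
#'
#' The CSV holds the per-frame entries; scheme, band, step and jitter
#' metadata go to `<path>.json`.
#'
#' @param traj an `ei_trajectory`.
#' @param path CSV output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj$entries, path, row.names = FALSE)
  head <- traj[setdiff(names(traj), "entries")]
  jsonlite::write_json(head, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  entries <- utils::read.csv(path)
  head <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- c(list(entries = entries), head)
  class(out) <- "ei_trajectory"
  out
}
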