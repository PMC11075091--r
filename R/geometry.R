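#' Edge-illumination system geometry
#'
#' Describes the optical chain of an edge-illumination (EI) micro-CT system:
#' x-ray source, sample mask, sample, detector mask and detector, all on a
#' common optical axis. Distances are given from the source; the constructor
#' derives the sample-to-detector distance `z_od`, the sample-mask-to-sample
#' magnification `m_s`, the sample-to-detector magnification `M` and the wave
#' number `k = 2*pi/lambda` at the effective (monochromatic) energy.
#'
#' Lengths are stored internally in metres; constructor arguments carry
#' explicit unit suffixes.
#'
#' @param d_source_samplemask_cm distance source -> sample mask (cm).
#' @param d_samplemask_sample_cm distance sample mask -> sample (cm).
#' @param d_source_detmask_cm distance source -> detector mask (cm).
#' @param d_source_detector_cm distance source -> detector (cm).
#' @param effective_energy_kev effective monochromatic energy (keV).
#' @param sample_magnification optional override for the sample-mask-to-sample
#'   magnification `m_s`. By default `m_s` is derived from the distances as
#'   `(d_source_samplemask + d_samplemask_sample) / d_source_samplemask`; an
#'   instrument may quote a calibrated value instead, in which case the
#'   override is stored and flagged in the object (`m_s_overridden`).
#' @return an object of class `ei_geometry`.
#' @examples
#' g <- ei_geometry()
#' geometric_magnification(g)  # ~1.2 for the default distances
#' @export
ei_geometry <- function(d_source_samplemask_cm = 69,
                        d_samplemask_sample_cm = 3,
                        d_source_detmask_cm = 84,
                        d_source_detector_cm = 86,
                        effective_energy_kev = 18,
                        sample_magnification = NULL) {
  d_sm <- d_source_samplemask_cm / 100
  d_ss <- d_samplemask_sample_cm / 100
  d_dm <- d_source_detmask_cm / 100
  d_dd <- d_source_detector_cm / 100
  if (!(is.finite(d_sm) && is.finite(d_dm) && is.finite(d_dd)) ||
      !(d_sm > 0 && d_sm < d_dm && d_dm < d_dd)) {
    stop("configuration error: distances must satisfy 0 < source-samplemask < source-detmask < source-detector")
  }
  if (!is.finite(d_ss) || d_ss < 0) {
    stop("configuration error: sample mask to sample distance must be >= 0")
  }
  d_sample <- d_sm + d_ss
  z_od <- d_dd - d_sample
  if (z_od <= 0) stop("configuration error: sample must lie upstream of the detector (z_od > 0)")
  if (!is.finite(effective_energy_kev) || effective_energy_kev <= 0) {
    stop("configuration error: effective_energy_kev must be > 0")
  }
  m_s_derived <- d_sample / d_sm
  m_s <- if (is.null(sample_magnification)) m_s_derived else sample_magnification
  if (m_s < 1) stop("configuration error: sample magnification m_s must be >= 1")
  M <- d_dd / d_sample
  if (M < 1) stop("configuration error: sample-to-detector magnification must be >= 1")
  structure(
    list(
      d_source_samplemask = d_sm,
      d_samplemask_sample = d_ss,
      d_source_detmask = d_dm,
      d_source_detector = d_dd,
      d_source_sample = d_sample,
      z_od = z_od,
      m_s = m_s,
      m_s_derived = m_s_derived,
      m_s_overridden = !is.null(sample_magnification),
      magnification = M,
      effective_energy_kev = effective_energy_kev,
      wavelength_m = wavelength_m(effective_energy_kev),
      k = wave_number(effective_energy_kev)
    ),
    class = "ei_geometry"
  )
}

#' @export
print.ei_geometry <- function(x, ...) {
  cat("EI system geometry\n")
  cat(sprintf("  source -> sample mask : %.1f cm\n", 100 * x$d_source_samplemask))
  cat(sprintf("  sample mask -> sample : %.1f cm\n", 100 * x$d_samplemask_sample))
  cat(sprintf("  source -> det. mask   : %.1f cm\n", 100 * x$d_source_detmask))
  cat(sprintf("  source -> detector    : %.1f cm\n", 100 * x$d_source_detector))
  cat(sprintf("  z_od (sample->det.)   : %.1f cm\n", 100 * x$z_od))
  cat(sprintf("  magnification M       : %.4f\n", x$magnification))
  cat(sprintf("  m_s (mask->sample)    : %.4f%s\n", x$m_s,
              if (x$m_s_overridden) sprintf(" [override; derived %.4f]", x$m_s_derived) else ""))
  cat(sprintf("  effective energy      : %.1f keV (k = %.3e 1/m)\n",
              x$effective_energy_kev, x$k))
  invisible(x)
}

#' X-ray wavelength and wave number at an effective energy
#'
#' `lambda[Angstrom] = 12.398 / E[keV]`; `k = 2*pi/lambda`.
#'
#' @param energy_kev photon energy in keV.
#' @return wavelength in metres / wave number in 1/m.
#' @export
wavelength_m <- function(energy_kev) 12.398e-10 / energy_kev

#' @rdname wavelength_m
#' @export
wave_number <- function(energy_kev) 2 * pi / wavelength_m(energy_kev)

.ei_planes <- c("source", "sample-mask", "sample", "detector-mask", "detector")

plane_distance <- function(geom, plane) {
  plane <- match.arg(plane, .ei_planes)
  switch(plane,
         "source" = 0,
         "sample-mask" = geom$d_source_samplemask,
         "sample" = geom$d_source_sample,
         "detector-mask" = geom$d_source_detmask,
         "detector" = geom$d_source_detector)
}

#' Sample-to-detector geometric magnification
#'
#' Ratio of the source-to-detector and source-to-sample distances; ~1.2 for
#' the default geometry (86 cm / 72 cm).
#'
#' @param geom an [ei_geometry()].
#' @return magnification (dimensionless).
#' @export
geometric_magnification <- function(geom) {
  stopifnot(inherits(geom, "ei_geometry"))
  geom$d_source_detector / geom$d_source_sample
}

#' Project a length between planes of the cone beam
#'
#' In a point-source cone geometry a transverse length at one plane maps to
#' another plane by the ratio of the planes' source distances (similar
#' triangles). E.g. the 79 micrometre sample-mask period projects to
#' ~98.45 micrometres at the detector plane.
#'
#' @param geom an [ei_geometry()].
#' @param length a transverse length (any unit; the result keeps it).
#' @param from,to plane labels among `"source"`, `"sample-mask"`, `"sample"`,
#'   `"detector-mask"`, `"detector"`.
#' @return the projected length.
#' @export
project_length <- function(geom, length, from, to) {
  stopifnot(inherits(geom, "ei_geometry"))
  if (!from %in% .ei_planes) stop("unknown plane label: ", from)
  if (!to %in% .ei_planes) stop("unknown plane label: ", to)
  d_from <- plane_distance(geom, from)
  d_to <- plane_distance(geom, to)
  if (d_from == 0 && d_to != 0) {
    stop("cannot project a finite length away from the source plane (point source)")
  }
  if (d_from == 0 && d_to == 0) return(length)
  length * d_to / d_from
}
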