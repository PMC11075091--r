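#' Load and validate a system configuration file
#'
#' A configuration file (JSON or YAML, by extension) describes the optical
#' chain in four sections: `geometry`, `sample_mask` (a list of aperture
#' bands), `detector` and `source`, plus optional `acquisition` defaults.
#' All lengths carry explicit unit suffixes in their field names (`_cm`,
#' `_um`, `_kev`, `_s`). The packaged default configuration describes the
#' reference instrument: a rotating-anode source (70 um horizontal focal
#' spot FWHM, effective energy 18 keV), a multi-band sample mask at 69 cm
#' with 79 um period and 20/10/5 um slit plus 10 um circular aperture bands,
#' a detector mask (17 um apertures, 98 um period) at 84 cm, and a 50 um
#' pixel pitch flat panel at 86 cm.
#'
#' @param path path to a `.json`, `.yaml`/`.yml` config; `NULL` loads the
#'   packaged default.
#' @return a validated `ei_system` list with elements `geometry`
#'   ([ei_geometry()]), `bands` (named list of [mask_band()]), `detector`
#'   ([detector_spec()]), `source` and `acquisition`.
#' @export
load_system_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_system.json", package = "eictsim")
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                "json" = jsonlite::read_json(path, simplifyVector = TRUE,
                                             simplifyDataFrame = FALSE),
                "yaml" = ,
                "yml" = yaml::read_yaml(path),
                stop("unsupported config extension: ", ext))
  validate_system_config(cfg)
  build_system(cfg)
}

#' @rdname load_system_config
#' @param cfg a raw configuration list.
#' @export
validate_system_config <- function(cfg) {
  req <- c("geometry", "sample_mask", "detector", "source")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) stop("config missing section(s): ", paste(missing, collapse = ", "))
  gfields <- c("d_source_samplemask_cm", "d_samplemask_sample_cm",
               "d_source_detmask_cm", "d_source_detector_cm",
               "effective_energy_kev")
  gm <- setdiff(gfields, names(cfg$geometry))
  if (length(gm)) stop("config [geometry] missing field(s): ", paste(gm, collapse = ", "))
  if (!length(cfg$sample_mask)) stop("config [sample_mask] must list at least one band")
  for (b in cfg$sample_mask) {
    bm <- setdiff(c("shape", "aperture_um", "period_um"), names(b))
    if (length(bm)) stop("config band missing field(s): ", paste(bm, collapse = ", "))
    if (!b$shape %in% c("slit", "circle")) stop("band shape must be 'slit' or 'circle'")
    if (b$aperture_um >= b$period_um) stop("band aperture must be < period")
  }
  dm <- setdiff(c("pixel_pitch_um", "detmask_aperture_um", "detmask_period_um"),
                names(cfg$detector))
  if (length(dm)) stop("config [detector] missing field(s): ", paste(dm, collapse = ", "))
  if (!"horizontal_fwhm_um" %in% names(cfg$source)) {
    stop("config [source] missing field: horizontal_fwhm_um")
  }
  invisible(TRUE)
}

build_system <- function(cfg) {
  g <- cfg$geometry
  geom <- ei_geometry(
    d_source_samplemask_cm = g$d_source_samplemask_cm,
    d_samplemask_sample_cm = g$d_samplemask_sample_cm,
    d_source_detmask_cm = g$d_source_detmask_cm,
    d_source_detector_cm = g$d_source_detector_cm,
    effective_energy_kev = g$effective_energy_kev,
    sample_magnification = if (is.null(g$sample_magnification)) NULL else g$sample_magnification
  )
  bands <- lapply(cfg$sample_mask, function(b) {
    mask_band(shape = b$shape, aperture_um = b$aperture_um,
              period_um = b$period_um,
              band_height_cm = if (is.null(b$band_height_cm)) 1 else b$band_height_cm,
              septa_transmission = if (is.null(b$septa_transmission)) 0 else b$septa_transmission,
              id = b$id)
  })
  names(bands) <- vapply(bands, `[[`, "", "id")
  det <- detector_spec(
    pixel_pitch_um = cfg$detector$pixel_pitch_um,
    n_cols = if (is.null(cfg$detector$n_cols)) 2400 else cfg$detector$n_cols,
    n_rows = if (is.null(cfg$detector$n_rows)) 2400 else cfg$detector$n_rows,
    detmask_aperture_um = cfg$detector$detmask_aperture_um,
    detmask_period_um = cfg$detector$detmask_period_um,
    line_skipping = isTRUE(cfg$detector$line_skipping)
  )
  acq_defaults <- list(i0_rate = 1e4, working_fraction = 0.5, flank = "positive",
                       flat_cadence = 100, n_darks = 1, overhead_per_step_s = 0,
                       back_and_forth_span_periods = 10)
  acq <- utils::modifyList(acq_defaults, if (is.null(cfg$acquisition)) list() else cfg$acquisition)
  det$effective_pixel_height_um <-
    if (is.null(cfg$detector$effective_pixel_height_um)) 40 else cfg$detector$effective_pixel_height_um
  structure(list(geometry = geom, bands = bands, detector = det,
                 source = cfg$source, acquisition = acq),
            class = "ei_system")
}

#' Default reference system
#'
#' Shorthand for `load_system_config(NULL)`.
#' @return an `ei_system`.
#' @export
default_system <- function() load_system_config(NULL)

#' @export
print.ei_system <- function(x, ...) {
  cat("EI system configuration\n")
  print(x$geometry)
  cat("  bands:", paste(names(x$bands), collapse = ", "), "\n")
  cat(sprintf("  detector: %g um pixels, det-mask %g/%g um%s\n",
              x$detector$pixel_pitch_um, x$detector$detmask_aperture_um,
              x$detector$detmask_period_um,
              if (x$detector$line_skipping) " (line-skipping)" else ""))
  cat(sprintf("  source: %g um horizontal FWHM\n", x$source$horizontal_fwhm_um))
  invisible(x)
}
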