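#' Simulate the illumination curve of an EI system
#'
#' The illumination curve C(.) is the detected intensity versus lateral
#' sample-mask offset, measured without a sample: the sample mask is stepped
#' along x and for each offset the transmitted beamlet flux falling into the
#' detector-mask aperture window is recorded. Here it is computed from the
#' overlap integral of the beamlet profile (aperture top-hat convolved with
#' the geometrically projected Gaussian source blur) with the detector-mask
#' aperture, evaluated in closed form at the detector plane. The curve is
#' periodic in the projected mask period and, for symmetric profiles, peaks
#' at the aligned position.
#'
#' Only the horizontal (slit-normal) direction is modelled; slits are
#' vertical and the physics is one-dimensional per axial row. For circular
#' apertures the same 1D profile is used with the flux scaled by the band's
#' open-area fraction, which leaves the curve shape approximate but the
#' relative modulation (the quantity that matters for retrieval) intact.
#'
#' @param geom an [ei_geometry()].
#' @param band an [mask_band()].
#' @param det a [detector_spec()].
#' @param offsets_um sample-mask offsets (micrometres, sample-mask plane) at
#'   which to sample the curve; default: one period in 0.25 um steps.
#' @param source_fwhm_um horizontal source focal-spot FWHM (micrometres).
#' @param i0_rate counts per second carried by one fully transmitted beamlet.
#' @return an object of class `ei_curve` with sampled offsets/intensities,
#'   the analytic model parameters, the curve maximum `C_max` and a Gaussian
#'   fit of the sampled curve.
#' @export
simulate_illumination_curve <- function(geom, band, det, offsets_um = NULL,
                                        source_fwhm_um = 70, i0_rate = 1) {
  stopifnot(inherits(geom, "ei_geometry"), inherits(band, "ei_maskband"),
            inherits(det, "ei_detector"))
  if (source_fwhm_um < 0) stop("source_fwhm_um must be >= 0")
  if (band$aperture_um <= 0) stop("band fully opaque (w = 0): no beamlets")
  if (is.null(offsets_um)) {
    offsets_um <- seq(-band$period_um / 2, band$period_um / 2, by = 0.25)
  }
  if (length(offsets_um) == 0) stop("offsets_um is empty")
  if (diff(range(offsets_um)) < band$period_um - 1e-9) {
    stop("offsets must span at least one mask period")
  }
  mag_mask <- geom$d_source_detector / geom$d_source_samplemask
  params <- list(
    w_p = band$aperture_um * mag_mask,
    period_p = band$period_um * mag_mask,
    sigma_p = source_fwhm_um *
      (geom$d_source_detector - geom$d_source_samplemask) /
      geom$d_source_samplemask / (2 * sqrt(2 * log(2))),
    a_p = det$detmask_aperture_um * geom$d_source_detector / geom$d_source_detmask,
    t_s = band$septa_transmission,
    mag_mask = mag_mask,
    i0_rate = i0_rate,
    density = i0_rate / (band$aperture_um * mag_mask)
  )
  intensity <- .curve_eval(offsets_um, params)
  curve <- structure(
    list(offsets_um = offsets_um, intensity = intensity, params = params,
         period_um = band$period_um, band_id = band$id),
    class = "ei_curve"
  )
  curve$C_max <- stats::optimize(function(x) .curve_eval(x, params),
                                 range(offsets_um), maximum = TRUE,
                                 tol = 1e-10)$objective
  curve$gaussian_fit <- .fit_curve_gaussian(offsets_um, intensity)
  curve
}

# integral of the standard normal CDF: G(t) = t*pnorm(t) + dnorm(t)
.int_pnorm <- function(t) t * stats::pnorm(t) + stats::dnorm(t)

# Overlap of the blurred top-hat beamlet (width w_p, blur sigma_p) centred at
# `centre` with the window [-a_p/2, a_p/2]; all lengths at the detector plane.
.beamlet_overlap <- function(centre, w_p, sigma_p, a_p) {
  l <- -a_p / 2 - centre
  h <- a_p / 2 - centre
  if (sigma_p <= 0) {
    # plain interval overlap
    pmax(0, pmin(h, w_p / 2) - pmax(l, -w_p / 2))
  } else {
    s <- sigma_p
    s * (.int_pnorm((h + w_p / 2) / s) - .int_pnorm((l + w_p / 2) / s)) -
      s * (.int_pnorm((h - w_p / 2) / s) - .int_pnorm((l - w_p / 2) / s))
  }
}

# blurred top-hat profile (transmission in [0,1]) at detector-plane coordinate u
.beamlet_profile <- function(u, w_p, sigma_p) {
  if (sigma_p <= 0) {
    as.numeric(abs(u) <= w_p / 2)
  } else {
    stats::pnorm((u + w_p / 2) / sigma_p) - stats::pnorm((u - w_p / 2) / sigma_p)
  }
}

.curve_eval <- function(x_um, p, deriv = 0) {
  centres0 <- x_um * p$mag_mask
  out <- numeric(length(x_um))
  for (m in -3:3) {
    cm <- centres0 + m * p$period_p
    if (deriv == 0) {
      out <- out + .beamlet_overlap(cm, p$w_p, p$sigma_p, p$a_p)
    } else {
      out <- out + p$mag_mask *
        (.beamlet_profile(-p$a_p / 2 - cm, p$w_p, p$sigma_p) -
         .beamlet_profile(p$a_p / 2 - cm, p$w_p, p$sigma_p))
    }
  }
  if (deriv == 0) {
    p$density * ((1 - p$t_s) * out + p$t_s * p$a_p)
  } else {
    p$density * (1 - p$t_s) * out
  }
}

#' Evaluate an illumination curve (or its slope) at arbitrary offsets
#'
#' @param object an `ei_curve`.
#' @param x_um sample-mask offsets (micrometres).
#' @param deriv 0 for C(x), 1 for C'(x) (counts/s per micrometre).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.ei_curve <- function(object, x_um, deriv = 0, ...) {
  .curve_eval(x_um, object$params, deriv = deriv)
}

#' @export
print.ei_curve <- function(x, ...) {
  cat(sprintf("EI illumination curve (band '%s'): %d samples over [%g, %g] um, C_max = %.4g counts/s\n",
              x$band_id, length(x$offsets_um), min(x$offsets_um),
              max(x$offsets_um), x$C_max))
  invisible(x)
}

# Gaussian + baseline fit of the sampled curve (the curve is approximately
# Gaussian shaped); used for the slope estimate at the working point.
.fit_curve_gaussian <- function(x, y) {
  c0 <- min(y)
  A0 <- max(y) - c0
  mu0 <- x[which.max(y)]
  yc <- pmax(y - c0, 0)
  s0 <- sqrt(sum(yc * (x - mu0)^2) / max(sum(yc), .Machine$double.eps))
  obj <- function(th) {
    sum((th[1] * exp(-(x - th[2])^2 / (2 * th[3]^2)) + th[4] - y)^2)
  }
  fit <- stats::optim(c(A0, mu0, max(s0, 1e-3), c0), obj,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  list(A = fit$par[1], mu = fit$par[2], sigma = abs(fit$par[3]),
       baseline = fit$par[4], sse = fit$value)
}

.gaussian_fit_value <- function(fit, x, deriv = 0) {
  g <- fit$A * exp(-(x - fit$mu)^2 / (2 * fit$sigma^2))
  if (deriv == 0) g + fit$baseline else -g * (x - fit$mu) / fit$sigma^2
}

#' Choose the imaging working point on the illumination curve
#'
#' Finds the sample-mask offset `x_m` on one flank of the illumination curve
#' where the detected intensity equals `target_fraction` of the curve
#' maximum (the edge-illumination condition; ~50% is the usual choice, i.e.
#' half of each beamlet falls on the exposed pixel area). The offset is
#' located by root finding on the curve model; the slope `C'(x_m)` is
#' estimated by default from a Gaussian fit of the sampled curve, or by
#' central finite differences.
#'
#' @param curve an `ei_curve` from [simulate_illumination_curve()].
#' @param target_fraction required `C(x_m)/C_max`, in (0, 1).
#' @param flank `"positive"` (C' > 0, offsets below the peak) or
#'   `"negative"`.
#' @param slope_method `"gaussian"` (default) or `"finite_diff"`.
#' @return an object of class `ei_workingpoint` with elements `x_m_um`,
#'   `C_xm`, `C_max`, `fraction`, `Cprime_per_um` and the curve.
#' @export
choose_working_point <- function(curve, target_fraction = 0.5,
                                 flank = c("positive", "negative"),
                                 slope_method = c("gaussian", "finite_diff")) {
  stopifnot(inherits(curve, "ei_curve"))
  flank <- match.arg(flank)
  slope_method <- match.arg(slope_method)
  if (!is.finite(target_fraction) || target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must lie strictly inside (0, 1); the aligned maximum is not a slope working point")
  }
  p <- curve$params
  C_max <- curve$C_max
  C_min <- min(predict(curve, curve$offsets_um))
  if (C_max - C_min <= 1e-12 * max(C_max, 1)) stop("illumination curve is flat")
  if (target_fraction <= C_min / C_max) {
    stop("target fraction below the curve's minimum relative intensity")
  }
  x_peak <- stats::optimize(function(x) predict(curve, x),
                            range(curve$offsets_um), maximum = TRUE,
                            tol = 1e-10)$maximum
  half_period <- curve$period_um / 2
  interval <- if (flank == "positive") {
    c(x_peak - half_period, x_peak)
  } else {
    c(x_peak, x_peak + half_period)
  }
  root <- stats::uniroot(function(x) predict(curve, x) - target_fraction * C_max,
                         interval = interval, tol = 1e-10)
  x_m <- root$root
  C_xm <- predict(curve, x_m)
  Cp <- switch(slope_method,
               gaussian = .gaussian_fit_value(curve$gaussian_fit, x_m, deriv = 1),
               finite_diff = {
                 h <- 0.05
                 (predict(curve, x_m + h) - predict(curve, x_m - h)) / (2 * h)
               })
  if (abs(Cp) < 1e-9 * C_max) {
    stop("slope at the selected offset is ~0; not a usable working point")
  }
  structure(
    list(x_m_um = x_m, C_xm = C_xm, C_max = C_max, fraction = C_xm / C_max,
         Cprime_per_um = Cp, flank = flank, slope_method = slope_method,
         curve = curve),
    class = "ei_workingpoint"
  )
}

#' @export
print.ei_workingpoint <- function(x, ...) {
  cat(sprintf("EI working point: x_m = %.3f um (%s flank), C/Cmax = %.3f, C' = %.4g /um\n",
              x$x_m_um, x$flank, x$fraction, x$Cprime_per_um))
  invisible(x)
}

#' Export / import an illumination curve as two-column CSV
#'
#' Columns `offset_um, intensity`.
#' @param curve an `ei_curve`.
#' @param path output file.
#' @export
export_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(offset_um = curve$offsets_um,
                              intensity = curve$intensity),
                   path, row.names = FALSE)
  invisible(path)
}
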