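#' Settings for single-image phase retrieval
#'
#' Bundles the quantities entering the homogeneous-object retrieval filter:
#' the homogeneity ratio `gamma = delta/(2 k beta)` assumed constant across
#' the sample, the sample-to-detector distance `z_od`, the illumination
#' curve value and slope at the working point, and the wave number.
#'
#' @param gamma_m homogeneity ratio gamma (metres); 0 reduces retrieval to
#'   pure attenuation.
#' @param geom an [ei_geometry()] (supplies `z_od` and `k`), or `NULL` if
#'   `z_od_m`/`k` are given directly.
#' @param wp an `ei_workingpoint` (supplies C(x_m) and C'(x_m)), or `NULL`
#'   if `cp_over_c_per_m` is given directly.
#' @param z_od_m,k,cp_over_c_per_m direct overrides; `cp_over_c_per_m` is
#'   C'(x_m)/C(x_m) per metre of sample-mask offset.
#' @return an object of class `ei_retrieval_settings`.
#' @export
retrieval_settings <- function(gamma_m, geom = NULL, wp = NULL,
                               z_od_m = NULL, k = NULL,
                               cp_over_c_per_m = NULL) {
  if (gamma_m < 0) stop("gamma must be >= 0")
  if (is.null(z_od_m)) z_od_m <- geom$z_od
  if (is.null(k)) k <- geom$k
  if (is.null(cp_over_c_per_m)) {
    if (is.null(wp)) stop("need either a working point or cp_over_c_per_m")
    cp_over_c_per_m <- (wp$Cprime_per_um / wp$C_xm) * 1e6
  }
  if (is.null(z_od_m) || is.null(k)) stop("need either a geometry or z_od_m and k")
  structure(list(gamma_m = gamma_m, z_od_m = z_od_m, k = k,
                 cp_over_c_per_m = cp_over_c_per_m),
            class = "ei_retrieval_settings")
}

#' Retrieval filter transfer function
#'
#' `H(nu) = 1 / (1 + i 2 pi nu z_od (C'/C) gamma)`, the Fourier-domain
#' low-pass filter of single-image phase retrieval (frequency variable
#' written out; sign of the imaginary part follows the discrete transform
#' convention used internally). Its magnitude is <= 1 at every frequency
#' for any parameter values.
#'
#' @param nu_per_m spatial frequencies (cycles per metre, conjugate to the
#'   lateral sample-plane coordinate).
#' @param settings an [retrieval_settings()].
#' @return complex transfer values.
#' @export
retrieval_transfer <- function(nu_per_m, settings) {
  1 / (1 + 1i * 2 * pi * nu_per_m * settings$z_od_m *
         settings$cp_over_c_per_m * settings$gamma_m)
}

#' Single-image phase retrieval
#'
#' Converts a sinogram of normalized EI intensities into line integrals of
#' beta under the homogeneous-object assumption: per angle row,
#' `int beta dz = -(1/2k) log( Finv( F(I/I0) * H(nu) ) )` with the low-pass
#' transfer `H` of [retrieval_transfer()]. Rows are mirror-padded to twice
#' their width before filtering and cropped afterwards. With `gamma = 0`
#' the filter is the identity and the result is pure attenuation.
#'
#' Negative input intensities (possible after noise) are clipped to 0
#' before processing; a non-positive filtered intensity aborts with a pixel
#' report since its logarithm is undefined.
#'
#' @param sino an `ei_sinogram` of normalized intensities.
#' @param settings an [retrieval_settings()].
#' @return an `ei_sinogram` whose values are `int beta dz` in metres
#'   (provenance field `content = "beta_line_m"`).
#' @export
phase_retrieve <- function(sino, settings) {
  stopifnot(inherits(sino, "ei_sinogram"),
            inherits(settings, "ei_retrieval_settings"))
  V <- sino$values
  n_clip <- sum(V < 0)
  if (n_clip > 0) V[V < 0] <- 0
  L <- ncol(V)
  pitch_m <- sino$pitch_um * 1e-6
  # mirror padding to 2L
  Vp <- cbind(V, V[, L:1, drop = FALSE])
  N <- 2L * L
  nu <- c(0:(N / 2), -(N / 2 - 1):-1) / (N * pitch_m)
  H <- retrieval_transfer(nu, settings)
  Ft <- t(stats::mvfft(t(Vp)))
  Ft <- sweep(Ft, 2, H, "*")
  filt <- t(stats::mvfft(t(Ft), inverse = TRUE)) / N
  im_res <- max(abs(Im(filt)))
  filt <- Re(filt)[, seq_len(L), drop = FALSE]
  tiny <- 1e-9 * max(filt)
  if (any(filt <= tiny)) {
    bad <- which(filt <= tiny, arr.ind = TRUE)
    stop(sprintf("non-positive intensity after filtering at %d pixel(s), first at angle row %d, column %d",
                 nrow(bad), bad[1, 1], bad[1, 2]))
  }
  out <- -log(filt) / (2 * settings$k)
  new_sinogram(out, sino$angles_deg, sino$lateral_um, sino$scheme,
               sino$band_id,
               provenance = c(sino$provenance,
                              list(content = "beta_line_m",
                                   gamma_m = settings$gamma_m,
                                   n_clipped = n_clip,
                                   imag_residue = im_res)))
}

#' Filtered back projection with a Ram-Lak filter
#'
#' Standard parallel-beam FBP: each sinogram row is ramp-filtered in the
#' Fourier domain (|nu| in physical units, zero-padded to the next power of
#' two of twice the width) and back-projected with linear interpolation;
#' angles may cover \[0, 180) or \[0, 360) (conjugate views average out in
#' the summation weight pi/n_angles). With input line integrals in metres
#' the output is beta itself (dimensionless).
#'
#' @param sino an `ei_sinogram` of line integrals (metres).
#' @return an `ei_reconslice`: square `values` matrix (beta), `axis_um`
#'   pixel-centre coordinates, `pixel_size_um`.
#' @export
fbp_reconstruct <- function(sino) {
  stopifnot(inherits(sino, "ei_sinogram"))
  n_ang <- length(sino$angles_deg)
  if (n_ang < 2) stop("need at least 2 angles for reconstruction")
  L <- length(sino$lateral_um)
  pitch_m <- sino$pitch_um * 1e-6
  N <- 2^ceiling(log2(4 * L))     # generous zero padding for the ramp filter
  nu <- c(0:(N / 2), -(N / 2 - 1):-1) / (N * pitch_m)
  ramp <- abs(nu)
  P <- matrix(0, n_ang, N)
  P[, seq_len(L)] <- sino$values
  Ft <- t(stats::mvfft(t(P)))
  Ft <- sweep(Ft, 2, ramp, "*")
  Q <- Re(t(stats::mvfft(t(Ft), inverse = TRUE)) / N)[, seq_len(L), drop = FALSE]
  ax <- sino$lateral_um
  X <- matrix(ax, L, L, byrow = TRUE)
  Y <- matrix(ax, L, L)
  rec <- matrix(0, L, L)
  th <- sino$angles_deg * pi / 180
  for (a in seq_len(n_ang)) {
    t_um <- X * cos(th[a]) + Y * sin(th[a])
    rec <- rec + matrix(interp_zero(ax, Q[a, ], as.vector(t_um)), L, L)
  }
  rec <- rec * pi / n_ang
  structure(list(values = rec, axis_um = ax, pixel_size_um = sino$pitch_um,
                 band_id = sino$band_id, scheme = sino$scheme),
            class = "ei_reconslice")
}

#' @export
print.ei_reconslice <- function(x, ...) {
  cat(sprintf("EI reconstructed slice: %d x %d px @ %.3f um, beta in [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Convert beta to the linear attenuation coefficient
#'
#' `mu = 2 k beta` (per metre).
#' @param beta absorption index values.
#' @param energy_kev energy.
#' @export
beta_to_mu <- function(beta, energy_kev = 18) 2 * wave_number(energy_kev) * beta

#' Bar-pattern modulation analysis of a reconstructed slice
#'
#' For each bar group (from the phantom metadata) the slice is averaged
#' along the bar direction (y) inside the group's bounding box, yielding a
#' lateral profile. Using the known bar phase, the profile is evaluated (by
#' linear interpolation) at the bar centres (peaks) and gap centres
#' (troughs); the modulation is
#' `(mean(peak) - mean(trough)) / (mean(peak) + mean(trough))`, clipped to
#' \[0, 1\]. Bars finer than the reconstruction pixel are averaged away by
#' the interpolation, correctly yielding ~0 modulation.
#'
#' @param slice an `ei_reconslice`.
#' @param bar_groups list of group descriptors as produced by
#'   [bar_pattern_phantom()] (`meta$bar_groups`).
#' @return data frame with `width_um`, `frequency_lpmm`, `modulation`.
#' @export
modulation_analysis <- function(slice, bar_groups) {
  stopifnot(inherits(slice, "ei_reconslice"))
  ax <- slice$axis_um
  out <- lapply(bar_groups, function(g) {
    rows <- which(ax >= g$y0_um & ax <= g$y1_um)
    if (!length(rows) || g$x0_um < min(ax) || g$x1_um > max(ax)) {
      stop("bar group box lies outside the slice")
    }
    profile <- colMeans(slice$values[rows, , drop = FALSE])
    # evaluate the averaged profile at the known bar and gap centres
    j <- seq_len(g$n_bars) - 1
    bar_centres <- g$x0_um + (2 * j + 0.5) * g$width_um
    gap_centres <- g$x0_um + (2 * j + 1.5) * g$width_um
    mp <- mean(stats::approx(ax, profile, xout = bar_centres, rule = 2)$y)
    mt <- mean(stats::approx(ax, profile, xout = gap_centres, rule = 2)$y)
    mod <- (mp - mt) / (mp + mt)
    data.frame(width_um = g$width_um,
               frequency_lpmm = g$frequency_lpmm,
               modulation = min(max(mod, 0), 1))
  })
  do.call(rbind, out)
}
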