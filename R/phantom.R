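#' Voxelized optical map of a phantom
#'
#' Holds the refractive-index decrement `delta` and absorption index `beta`
#' of a 2D phantom slice (`n = 1 - delta + i*beta`) on a square voxel grid
#' at a stated effective energy. Rows index y, columns index x; the origin
#' is at the grid centre and coordinates refer to pixel centres.
#'
#' @param delta,beta non-negative numeric matrices of equal dimension.
#' @param voxel_size_um voxel edge length (micrometres).
#' @param energy_kev energy at which delta/beta are stated (keV).
#' @param meta optional metadata list (e.g. bar-group boxes).
#' @return an object of class `optical_map`.
#' @export
optical_map <- function(delta, beta, voxel_size_um, energy_kev = 18,
                        meta = list()) {
  stopifnot(is.matrix(delta), is.matrix(beta))
  if (!all(dim(delta) == dim(beta))) stop("delta and beta grids must be congruent")
  if (any(delta < 0) || any(beta < 0)) stop("delta and beta must be non-negative")
  if (!is.finite(voxel_size_um) || voxel_size_um <= 0) stop("voxel_size_um must be > 0")
  structure(list(delta = delta, beta = beta, voxel_size_um = voxel_size_um,
                 energy_kev = energy_kev, meta = meta),
            class = "optical_map")
}

#' @export
print.optical_map <- function(x, ...) {
  cat(sprintf("optical map: %d x %d voxels @ %g um (%.0f x %.0f um), %g keV\n",
              nrow(x$delta), ncol(x$delta), x$voxel_size_um,
              nrow(x$delta) * x$voxel_size_um, ncol(x$delta) * x$voxel_size_um,
              x$energy_kev))
  cat(sprintf("  delta in [%.3g, %.3g], beta in [%.3g, %.3g]\n",
              min(x$delta), max(x$delta), min(x$beta), max(x$beta)))
  invisible(x)
}

# pixel-centre coordinate axis (um), centred on 0
map_axis <- function(n, voxel_size_um) (seq_len(n) - (n + 1) / 2) * voxel_size_um

#' Homogeneity-ratio map gamma = delta / (2 k beta)
#'
#' @param map an [optical_map()].
#' @return matrix of gamma values (metres); `NA` where beta is 0.
#' @export
gamma_map <- function(map) {
  k <- wave_number(map$energy_kev)
  g <- map$delta / (2 * k * map$beta)
  g[map$beta == 0] <- NA_real_
  g
}

#' Bar line width to spatial frequency
#'
#' One line pair spans a bar plus a gap, i.e. twice the line width:
#' `f = 1 / (2 * width)`. 150 um bars correspond to 3.33 lp/mm, 5 um bars to
#' 100 lp/mm.
#'
#' @param width_um line width (micrometres).
#' @return spatial frequency in line pairs per millimetre.
#' @export
linewidth_to_frequency <- function(width_um) {
  if (any(width_um <= 0)) stop("line width must be > 0")
  1000 / (2 * width_um)
}

# evaluate a field function on a supersampled grid and box-average down.
# f(x, y) is vectorised over matrices of coordinates (um).
rasterize_field <- function(n, voxel_size_um, f, supersample = 4L) {
  s <- as.integer(supersample)
  nf <- n * s
  ax <- (seq_len(nf) - (nf + 1) / 2) * voxel_size_um / s
  X <- matrix(ax, nf, nf, byrow = TRUE)
  Y <- matrix(ax, nf, nf)
  fine <- f(X, Y)
  if (s == 1L) return(fine)
  # box down-average s x s blocks
  m <- matrix(0, n, nf)
  for (i in seq_len(s)) m <- m + fine[seq(i, nf, by = s), , drop = FALSE]
  out <- matrix(0, n, n)
  for (j in seq_len(s)) out <- out + m[, seq(j, nf, by = s), drop = FALSE]
  out / s^2
}

#' Bar-pattern resolution phantom
#'
#' A cylinder (disc, in 2D) of substrate material containing groups of
#' vertical bars, one group per requested line width. Each group holds
#' `n_bars` bars separated by gaps of equal width (exactly 50% duty cycle);
#' gaps and surroundings are substrate. Groups are stacked vertically and
#' centred, emulating a chip-in-cylinder resolution insert. Rasterization
#' uses pixel-centre sampling with supersampling and box down-averaging to
#' limit aliasing of thin bars.
#'
#' Bar-group bounding boxes (and the bar phase within each box) are returned
#' in `meta$bar_groups` for use by [modulation_analysis()].
#'
#' @param line_widths_um bar line widths (micrometres), one group each.
#' @param n_bars number of bars per group.
#' @param bar_length_um bar extent along y (micrometres).
#' @param voxel_size_um voxel size; must be at most `min(line_widths_um)/4`.
#' @param field_um full field width; the substrate disc has diameter
#'   `0.9 * field_um`.
#' @param material,substrate lists with elements `delta`, `beta` for the bar
#'   and substrate materials.
#' @param energy_kev stated energy.
#' @param supersample supersampling factor for rasterization.
#' @return an [optical_map()].
#' @export
bar_pattern_phantom <- function(line_widths_um = c(5, 10, 20, 30),
                                n_bars = 3,
                                bar_length_um = 70,
                                voxel_size_um = 1.25,
                                field_um = 400,
                                material = list(delta = 1.2e-6, beta = 4e-9),
                                substrate = list(delta = 4.5e-7, beta = 1.5e-9),
                                energy_kev = 18,
                                supersample = 4L) {
  if (any(line_widths_um <= 0)) stop("line widths must be > 0")
  if (voxel_size_um > min(line_widths_um) / 4) {
    stop(sprintf("voxel too coarse: need voxel_size_um <= %g to represent %g um bars",
                 min(line_widths_um) / 4, min(line_widths_um)))
  }
  n <- as.integer(round(field_um / voxel_size_um))
  radius <- 0.45 * field_um
  k <- length(line_widths_um)
  margin <- 0.15 * bar_length_um
  total_h <- k * bar_length_um + (k - 1) * margin
  if (total_h > 1.9 * radius) stop("bar groups do not fit inside the substrate disc; increase field_um")
  y_centres <- seq(-(total_h - bar_length_um) / 2,
                   (total_h - bar_length_um) / 2, length.out = k)
  groups <- vector("list", k)
  for (i in seq_len(k)) {
    w <- line_widths_um[i]
    gx <- 2 * n_bars * w               # n_bars bars + n_bars gaps
    x0 <- -gx / 2
    groups[[i]] <- list(width_um = w, n_bars = n_bars,
                        x0_um = x0, x1_um = x0 + gx,
                        y0_um = y_centres[i] - bar_length_um / 2,
                        y1_um = y_centres[i] + bar_length_um / 2,
                        frequency_lpmm = linewidth_to_frequency(w))
    half_w <- sqrt(max(radius^2 - max(abs(groups[[i]]$y0_um), abs(groups[[i]]$y1_um))^2, 0))
    if (gx / 2 > half_w) stop("bar group wider than the substrate disc chord; increase field_um or reduce n_bars")
  }
  field_fun <- function(values) {
    function(X, Y) {
      out <- matrix(0, nrow(X), ncol(X))
      inside <- X^2 + Y^2 <= radius^2
      out[inside] <- values$substrate
      for (g in groups) {
        u <- (X - g$x0_um) / g$width_um
        in_bar <- inside & Y >= g$y0_um & Y <= g$y1_um &
          u >= 0 & u < 2 * g$n_bars & (floor(u) %% 2 == 0)
        out[in_bar] <- values$material
      }
      out
    }
  }
  delta <- rasterize_field(n, voxel_size_um,
                           field_fun(list(substrate = substrate$delta,
                                          material = material$delta)),
                           supersample)
  beta <- rasterize_field(n, voxel_size_um,
                          field_fun(list(substrate = substrate$beta,
                                         material = material$beta)),
                          supersample)
  optical_map(delta, beta, voxel_size_um, energy_kev,
              meta = list(kind = "bar_pattern", bar_groups = groups,
                          radius_um = radius,
                          material = material, substrate = substrate))
}

#' Synthetic single-material soft-tissue phantom
#'
#' Smooth random blobs on a tapered cylindrical background, emulating an
#' unstained soft-tissue specimen (e.g. an embryo in a holder) at desk
#' scale. The phantom is single-material in the homogeneity sense: the
#' delta/beta ratio equals `2 k gamma_m` everywhere by construction, so the
#' homogeneous-object assumption of single-image phase retrieval holds
#' exactly. Reproducible for a given seed.
#'
#' @param seed integer RNG seed.
#' @param n_blobs number of Gaussian blobs.
#' @param gamma_m homogeneity ratio gamma = delta/(2 k beta) (metres).
#'   The default corresponds to delta/beta ~ 170 at 18 keV.
#' @param background_beta beta of the bulk cylinder.
#' @param n grid size (voxels per side).
#' @param voxel_size_um voxel size (micrometres).
#' @param blob_sigma_um range of blob Gaussian sigmas (micrometres).
#' @param blob_rel_amp maximum blob amplitude relative to the background.
#' @param energy_kev stated energy.
#' @return an [optical_map()].
#' @export
soft_tissue_phantom <- function(seed = 1, n_blobs = 6,
                                gamma_m = NULL,
                                background_beta = 3e-9,
                                n = 256, voxel_size_um = 2,
                                blob_sigma_um = c(50, 90),
                                blob_rel_amp = 0.5,
                                energy_kev = 18) {
  k <- wave_number(energy_kev)
  if (is.null(gamma_m)) gamma_m <- 5e-7 / (2 * k * background_beta)
  if (gamma_m <= 0) stop("gamma_m must be > 0")
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  field_um <- n * voxel_size_um
  radius <- 0.42 * field_um
  ax <- map_axis(n, voxel_size_um)
  X <- matrix(ax, n, n, byrow = TRUE)
  Y <- matrix(ax, n, n)
  r <- sqrt(X^2 + Y^2)
  # smooth-edged support (cosine taper over 8% of the radius)
  taper <- 0.08 * radius
  support <- pmin(pmax((radius - r) / taper, 0), 1)
  support <- support^2 * (3 - 2 * support)
  beta <- background_beta * support
  if (n_blobs > 0) {
    cx <- stats::runif(n_blobs, -0.55 * radius, 0.55 * radius)
    cy <- stats::runif(n_blobs, -0.55 * radius, 0.55 * radius)
    sg <- stats::runif(n_blobs, blob_sigma_um[1], blob_sigma_um[2])
    am <- stats::runif(n_blobs, -blob_rel_amp, blob_rel_amp) * background_beta
    for (i in seq_len(n_blobs)) {
      beta <- beta + am[i] * exp(-((X - cx[i])^2 + (Y - cy[i])^2) / (2 * sg[i]^2)) * support
    }
  }
  beta <- pmax(beta, 0)
  delta <- 2 * k * gamma_m * beta
  optical_map(delta, beta, voxel_size_um, energy_kev,
              meta = list(kind = "soft_tissue", seed = seed,
                          gamma_m = gamma_m, radius_um = radius))
}
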