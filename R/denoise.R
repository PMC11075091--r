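#' Split a sinogram into odd/even projection subsets
#'
#' Noise2Inverse data path: odd-numbered projections (1st, 3rd, ...) go to
#' subset A, even-numbered to subset B. The two subsets partition the angle
#' list; with an odd total, A receives one more projection (warning). Each
#' half keeps equispaced angles at twice the spacing.
#'
#' @param sino an `ei_sinogram`.
#' @return an `ei_splitpair` with sinograms `A` and `B`.
#' @export
split_projections <- function(sino) {
  stopifnot(inherits(sino, "ei_sinogram"))
  n <- length(sino$angles_deg)
  if (n < 4) stop("need at least 4 projections to split")
  if (n %% 2 == 1) warning("odd number of projections: subset A receives the extra one")
  ia <- seq(1, n, by = 2)
  ib <- seq(2, n, by = 2)
  sub <- function(idx) {
    new_sinogram(sino$values[idx, , drop = FALSE], sino$angles_deg[idx],
                 sino$lateral_um, sino$scheme, sino$band_id,
                 provenance = c(sino$provenance, list(subset_of = n)))
  }
  structure(list(A = sub(ia), B = sub(ib), idx_A = ia, idx_B = ib),
            class = "ei_splitpair")
}

#' Reconstruct both halves of a split pair
#'
#' @param pair an `ei_splitpair`.
#' @return the pair with `recon_A` and `recon_B` slices added.
#' @export
reconstruct_split <- function(pair) {
  stopifnot(inherits(pair, "ei_splitpair"))
  pair$recon_A <- fbp_reconstruct(pair$A)
  pair$recon_B <- fbp_reconstruct(pair$B)
  pair
}

#' Linear convolutional regression denoiser
#'
#' A small learned denoiser satisfying the fit/apply contract: a single
#' `kernel_size x kernel_size` convolution kernel is fit by ridge-regularised
#' least squares to map noisy input slices onto their targets. It is the
#' desk-scale, fully deterministic stand-in for a trained CNN denoiser: one
#' convolutional layer, closed-form "training".
#'
#' @param kernel_size odd kernel width (pixels).
#' @param ridge ridge penalty on the kernel coefficients.
#' @return an `ei_denoiser` with elements `fit(inputs, targets)` returning a
#'   model and `apply(model, slice_values)`.
#' @export
conv_denoiser <- function(kernel_size = 5L, ridge = 1e-8) {
  k <- as.integer(kernel_size)
  if (k %% 2L != 1L) stop("kernel_size must be odd")
  h <- (k - 1L) %/% 2L
  patches <- function(M) {
    nr <- nrow(M); nc <- ncol(M)
    ri <- (1 + h):(nr - h); ci <- (1 + h):(nc - h)
    cols <- vector("list", k * k)
    idx <- 1L
    for (dy in -h:h) for (dx in -h:h) {
      cols[[idx]] <- as.vector(M[ri + dy, ci + dx, drop = FALSE])
      idx <- idx + 1L
    }
    do.call(cbind, cols)
  }
  fit <- function(inputs, targets, ...) {
    XtX <- matrix(0, k * k, k * k)
    Xty <- numeric(k * k)
    for (i in seq_along(inputs)) {
      X <- patches(inputs[[i]])
      M <- targets[[i]]
      y <- as.vector(M[(1 + h):(nrow(M) - h), (1 + h):(ncol(M) - h), drop = FALSE])
      XtX <- XtX + crossprod(X)
      Xty <- Xty + crossprod(X, y)
    }
    # ridge shrinks toward the identity kernel, so a noise-free fit is a
    # no-op rather than an arbitrary smoother
    scale <- mean(diag(XtX))
    e0 <- numeric(k * k)
    e0[(k * k + 1) %/% 2] <- 1
    kernel <- solve(XtX + ridge * scale * diag(k * k),
                    Xty + ridge * scale * e0)
    list(kernel = matrix(kernel, k, k), kernel_size = k)
  }
  apply_fn <- function(model, M) {
    K <- model$kernel
    nr <- nrow(M); nc <- ncol(M)
    # replicate-padded shift-and-add convolution
    pad <- matrix(0, nr + 2 * h, nc + 2 * h)
    pad[(1 + h):(nr + h), (1 + h):(nc + h)] <- M
    pad[1:h, ] <- pad[rep(h + 1, h), ]
    pad[(nr + h + 1):(nr + 2 * h), ] <- pad[rep(nr + h, h), ]
    pad[, 1:h] <- pad[, rep(h + 1, h)]
    pad[, (nc + h + 1):(nc + 2 * h)] <- pad[, rep(nc + h, h)]
    out <- matrix(0, nr, nc)
    idx <- 1L
    for (dy in -h:h) for (dx in -h:h) {
      out <- out + K[idx] * pad[(1 + h + dy):(nr + h + dy),
                                (1 + h + dx):(nc + h + dx)]
      idx <- idx + 1L
    }
    out
  }
  structure(list(fit = fit, apply = apply_fn, name = "conv_regressor"),
            class = "ei_denoiser")
}

#' Non-learned Gaussian smoothing baseline denoiser
#'
#' @param sigma_px Gaussian sigma in pixels.
#' @return an `ei_denoiser`; `fit` is a no-op.
#' @export
smooth_denoiser <- function(sigma_px = 1) {
  h <- max(1L, ceiling(3 * sigma_px))
  x <- (-h):h
  k1 <- exp(-x^2 / (2 * sigma_px^2))
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  base <- conv_denoiser(kernel_size = 2L * h + 1L)
  structure(list(
    fit = function(inputs, targets, ...) list(kernel = K, kernel_size = 2L * h + 1L),
    apply = base$apply, name = "gaussian_smoothing"
  ), class = "ei_denoiser")
}

#' Self-supervised adaptive Wiener denoiser
#'
#' A spatially adaptive (nonlinear) denoiser in the Noise2Inverse setting:
#' the fit step estimates the reconstruction noise variance from the
#' half-data difference `(A - B)/2` -- which contains noise only, since
#' both halves share the same signal -- and the apply step runs a local
#' Wiener (Lee) filter: `out = m + vs/(vs + vn) * (x - m)` with `m`, `v`
#' the local boxcar mean/variance, `vs = max(v - vn, 0)` the excess
#' (signal) variance and `vn` the estimated noise variance. Uniform regions
#' collapse onto the local mean (strong noise suppression); structured
#' regions are preserved. This mimics the spatially adaptive behaviour of
#' a trained CNN denoiser at desk scale, in closed form.
#'
#' @param window boxcar window size (odd, pixels).
#' @return an `ei_denoiser`.
#' @export
wiener_denoiser <- function(window = 7L) {
  w <- as.integer(window)
  if (w %% 2L != 1L) stop("window must be odd")
  h <- (w - 1L) %/% 2L
  boxcar <- function(M) {
    nr <- nrow(M); nc <- ncol(M)
    pad <- matrix(0, nr + 2 * h, nc + 2 * h)
    pad[(1 + h):(nr + h), (1 + h):(nc + h)] <- M
    pad[1:h, ] <- pad[rep(h + 1, h), ]
    pad[(nr + h + 1):(nr + 2 * h), ] <- pad[rep(nr + h, h), ]
    pad[, 1:h] <- pad[, rep(h + 1, h)]
    pad[, (nc + h + 1):(nc + 2 * h)] <- pad[, rep(nc + h, h)]
    out <- matrix(0, nr, nc)
    for (dy in -h:h) for (dx in -h:h) {
      out <- out + pad[(1 + h + dy):(nr + h + dy), (1 + h + dx):(nc + h + dx)]
    }
    out / w^2
  }
  fit <- function(inputs, targets, ...) {
    # inputs/targets are the two cross-directions (A->B, B->A); the noise
    # variance of a single half is var(A - B)/2, and of their mean half
    # that again -- we denoise half or full recons, whose noise var is
    # var(A - B)/4 (full = (A+B)/2 with independent halves).
    d <- (inputs[[1]] - targets[[1]]) / 2
    list(vn_full = stats::var(as.vector(d)), window = w)
  }
  apply_fn <- function(model, M) {
    m <- boxcar(M)
    v <- pmax(boxcar(M^2) - m^2, 0)
    vs <- pmax(v - model$vn_full, 0)
    m + vs / (vs + model$vn_full) * (M - m)
  }
  structure(list(fit = fit, apply = apply_fn, name = "adaptive_wiener"),
            class = "ei_denoiser")
}

#' Fit a denoiser on a Noise2Inverse split and apply it
#'
#' The denoiser is trained on both cross-directions of the half-data
#' reconstructions (A -> B and B -> A), whose signal content is identical
#' but whose noise realisations are independent, then applied to the
#' full-data reconstruction. Deterministic for a fixed seed.
#'
#' @param pair an `ei_splitpair` (reconstructed halves are computed if
#'   absent).
#' @param denoiser an `ei_denoiser` (default [conv_denoiser()]).
#' @param full_recon the full-data `ei_reconslice` to denoise.
#' @param epochs passed to the denoiser's fit (ignored by the closed-form
#'   default).
#' @param seed RNG seed for stochastic denoisers (the default is
#'   deterministic).
#' @param combine `"full"` applies the fitted denoiser to the full-data
#'   reconstruction; `"split_mean"` applies it to each half-data
#'   reconstruction and averages the outputs (the canonical Noise2Inverse
#'   estimator, which additionally averages down the independent noise of
#'   the two halves).
#' @return the denoised `ei_reconslice`.
#' @export
train_and_apply <- function(pair, denoiser = conv_denoiser(), full_recon,
                            epochs = 1L, seed = 1L,
                            combine = c("full", "split_mean")) {
  stopifnot(inherits(pair, "ei_splitpair"), inherits(denoiser, "ei_denoiser"))
  combine <- match.arg(combine)
  if (is.null(pair$recon_A)) pair <- reconstruct_split(pair)
  a <- pair$recon_A$values
  b <- pair$recon_B$values
  if (!all(dim(a) == dim(b))) stop("shape mismatch between split reconstructions")
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  model <- denoiser$fit(list(a, b), list(b, a), epochs = epochs)
  out <- full_recon
  out$values <- if (combine == "full") {
    denoiser$apply(model, full_recon$values)
  } else {
    (denoiser$apply(model, a) + denoiser$apply(model, b)) / 2
  }
  out$denoised_with <- denoiser$name
  out
}

#' Signal-to-noise ratio in a rectangular region of interest
#'
#' `mean / sd` over the ROI pixels, the usual uniform-region SNR estimate.
#'
#' @param slice an `ei_reconslice` or plain matrix.
#' @param rows,cols integer index ranges of the ROI.
#' @export
snr_roi <- function(slice, rows, cols) {
  M <- if (inherits(slice, "ei_reconslice")) slice$values else slice
  v <- M[rows, cols]
  mean(v) / stats::sd(v)
}
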