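# RNG handling: seed locally, restore the caller's stream afterwards.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Counter-based substream seed for one frame: mixes the master seed with the
# angle and frame counters so the noise stream of a frame does not depend on
# trajectory order. Kept within the 32-bit signed integer range.
frame_seed <- function(master_seed, angle_index, frame_index) {
  h <- (as.double(master_seed) %% 2147483647) * 2654435761 +
    as.double(angle_index) * 40503 + as.double(frame_index) * 9973 + 12345
  as.integer(h %% 2147483629)
}

# linear interpolation with 0 outside the support
interp_zero <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", yleft = 0, yright = 0,
                ties = "ordered")$y
}
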