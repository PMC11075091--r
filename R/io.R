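# Raster container convention: float32 TIFF holding the data rescaled to
# [0, 1], with the affine (offset, scale) recorded in the JSON sidecar
# `<path>.json` alongside domain metadata. Multi-frame stacks are written as
# multi-directory TIFFs.

write_raster_tiff <- function(data, path, meta = list()) {
  frames <- if (is.list(data)) data else list(data)
  lo <- min(vapply(frames, min, 0))
  hi <- max(vapply(frames, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(frames, function(M) (M - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- c(list(offset = lo, scale = scale,
                    n_frames = length(frames),
                    n_rows = nrow(frames[[1]]), n_cols = ncol(frames[[1]])),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

read_raster_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(M) M * sidecar$scale + sidecar$offset)
  list(frames = frames, meta = sidecar)
}

#' Write / read an optical map as paired float32 TIFFs with a JSON sidecar
#'
#' Produces `<stem>_delta.tif` and `<stem>_beta.tif` (each with its own
#' scaling sidecar) plus `<stem>.json` carrying voxel size, energy and any
#' phantom metadata (e.g. bar-group boxes).
#'
#' @param map an [optical_map()].
#' @param stem output path stem.
#' @export
write_optical_map <- function(map, stem) {
  stopifnot(inherits(map, "optical_map"))
  write_raster_tiff(map$delta, paste0(stem, "_delta.tif"))
  write_raster_tiff(map$beta, paste0(stem, "_beta.tif"))
  jsonlite::write_json(c(list(voxel_size_um = map$voxel_size_um,
                              energy_kev = map$energy_kev), map$meta),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(stem)
}

#' @rdname write_optical_map
#' @export
read_optical_map <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = FALSE)
  delta <- read_raster_tiff(paste0(stem, "_delta.tif"))$frames[[1]]
  beta <- read_raster_tiff(paste0(stem, "_beta.tif"))$frames[[1]]
  optical_map(delta, beta, voxel_size_um = meta$voxel_size_um,
              energy_kev = meta$energy_kev,
              meta = meta[setdiff(names(meta), c("voxel_size_um", "energy_kev"))])
}

#' Write / read a frame set as a float32 TIFF stack with JSON sidecar
#'
#' One TIFF directory per frame (row dimension 1 x beamlets for the 1D
#' axial-row simulation); the sidecar lists per-frame angle, offset,
#' exposure and type, plus the beamlet lattice.
#'
#' @param fs an `ei_frameset`.
#' @param path output TIFF path.
#' @export
write_frameset <- function(fs, path) {
  stopifnot(inherits(fs, "ei_frameset"))
  frames <- lapply(seq_len(nrow(fs$intensities)),
                   function(i) matrix(fs$intensities[i, ], nrow = 1))
  write_raster_tiff(frames, path,
                    meta = list(kind = "frameset", band_id = fs$band_id,
                                scheme = fs$scheme, noise = fs$noise,
                                seed = fs$seed,
                                beamlets_um = fs$beamlets_um,
                                frames = fs$meta))
  invisible(path)
}

#' @rdname write_frameset
#' @export
read_frameset <- function(path) {
  r <- read_raster_tiff(path)
  meta <- r$meta
  structure(list(intensities = do.call(rbind, r$frames),
                 meta = as.data.frame(meta$frames),
                 beamlets_um = meta$beamlets_um,
                 band_id = meta$band_id, scheme = meta$scheme,
                 trajectory = NULL, seed = meta$seed, noise = meta$noise),
            class = "ei_frameset")
}

#' Write / read a sinogram as float32 TIFF with JSON sidecar
#'
#' @param sino an `ei_sinogram`.
#' @param path output TIFF path.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "ei_sinogram"))
  write_raster_tiff(sino$values, path,
                    meta = list(kind = "sinogram", scheme = sino$scheme,
                                band_id = sino$band_id,
                                angles_deg = sino$angles_deg,
                                lateral_um = sino$lateral_um,
                                pitch_um = sino$pitch_um,
                                provenance = sino$provenance))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  r <- read_raster_tiff(path)
  m <- r$meta
  new_sinogram(r$frames[[1]], m$angles_deg, m$lateral_um, m$scheme, m$band_id,
               provenance = as.list(m$provenance))
}

#' Write / read a reconstructed slice as float32 TIFF with JSON sidecar
#'
#' @param slice an `ei_reconslice`.
#' @param path output TIFF path.
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ei_reconslice"))
  write_raster_tiff(slice$values, path,
                    meta = list(kind = "reconslice",
                                axis_um = slice$axis_um,
                                pixel_size_um = slice$pixel_size_um,
                                band_id = slice$band_id,
                                scheme = slice$scheme))
  invisible(path)
}

#' @rdname write_slice
#' @export
read_slice <- function(path) {
  r <- read_raster_tiff(path)
  m <- r$meta
  structure(list(values = r$frames[[1]], axis_um = m$axis_um,
                 pixel_size_um = m$pixel_size_um, band_id = m$band_id,
                 scheme = m$scheme),
            class = "ei_reconslice")
}
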