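#' Render a cell table into a two-channel image tile
#'
#' Draws each cell as a compact isotropic Gaussian blob (approximately
#' outer-segment sized) into the S and M channels, with peak amplitude equal
#' to the cell's intensity, in each channel where that intensity exceeds the
#' background level. Additive Gaussian noise and a constant background are
#' applied. The planted ground truth (positions and intensities) rides along
#' in the tile metadata so segmentation output can be scored against it.
#'
#' Image rows correspond to the D-V axis (row 1 = dorsal edge), columns to
#' the T-N axis.
#'
#' @param table A cell table.
#' @param pixel_size_um Pixel size (> 0).
#' @param psf_sigma_um Blob standard deviation in micrometres.
#' @param background_level Constant background intensity.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @return An `image_tile`: list with `pixels` (array height x width x 2,
#'   channels S then M), `pixel_size_um`, `orientation`, `background_level`,
#'   `noise_sd`, and `truth` (the planted table).
#' @export
render_tiles <- function(table, pixel_size_um = 0.5, psf_sigma_um = 1.5,
                         background_level = 5, noise_sd = 2, seed = 1L) {
  stopifnot(pixel_size_um > 0, psf_sigma_um > 0, noise_sd >= 0)
  meta <- cell_meta(table)
  len <- meta$strip_length_um %||% (max(table$y_um, 1) * 1.05)
  wid <- meta$strip_width_um %||% (max(table$x_um, 1) * 1.05)
  h <- max(2L, ceiling(len / pixel_size_um))
  w <- max(2L, ceiling(wid / pixel_size_um))
  sigma_px <- psf_sigma_um / pixel_size_um

  channel <- function(intensity) {
    img <- matrix(0, h, w)
    keep <- which(intensity > background_level)
    half <- ceiling(4 * sigma_px)
    for (i in keep) {
      r0 <- table$y_um[i] / pixel_size_um + 0.5
      c0 <- table$x_um[i] / pixel_size_um + 0.5
      rows <- max(1, floor(r0 - half)):min(h, ceiling(r0 + half))
      cols <- max(1, floor(c0 - half)):min(w, ceiling(c0 + half))
      gr <- exp(-((rows - r0)^2) / (2 * sigma_px^2))
      gc <- exp(-((cols - c0)^2) / (2 * sigma_px^2))
      img[rows, cols] <- img[rows, cols] + intensity[i] * outer(gr, gc)
    }
    img
  }
  pixels <- array(0, dim = c(h, w, 2))
  pixels[, , 1] <- channel(table$s_intensity)
  pixels[, , 2] <- channel(table$m_intensity)

  withr::local_seed(as.integer(seed))
  pixels <- pixels + background_level +
    array(rnorm(h * w * 2, 0, noise_sd), dim = c(h, w, 2))
  pixels[pixels < 0] <- 0

  image_tile(
    pixels,
    pixel_size_um = pixel_size_um,
    background_level = background_level,
    noise_sd = noise_sd,
    psf_sigma_um = psf_sigma_um,
    truth = table
  )
}

#' Two-channel image tile
#'
#' Container for a two-channel (S, M) non-negative intensity raster with its
#' pixel size and orientation. Rows follow the D-V axis (row 1 dorsal).
#'
#' @param pixels Array `height x width x 2` (S channel first) or a list of
#'   two equal-shaped matrices.
#' @param pixel_size_um Pixel size (> 0).
#' @param orientation Named axis convention.
#' @param ... Further metadata fields (kept verbatim).
#' @return An `image_tile` object.
#' @export
image_tile <- function(pixels, pixel_size_um,
                       orientation = "rows_dorsal_to_ventral", ...) {
  if (is.list(pixels)) {
    stopifnot(length(pixels) == 2, all(dim(pixels[[1]]) == dim(pixels[[2]])))
    arr <- array(0, dim = c(dim(pixels[[1]]), 2))
    arr[, , 1] <- pixels[[1]]
    arr[, , 2] <- pixels[[2]]
    pixels <- arr
  }
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 2)
  if (any(pixels < 0)) abort("image_tile intensities must be >= 0")
  if (pixel_size_um <= 0) abort("pixel_size_um must be > 0")
  structure(
    list(
      pixels = pixels, pixel_size_um = pixel_size_um,
      orientation = orientation, ...
    ),
    class = "image_tile"
  )
}

#' @export
print.image_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_tile> %d x %d px, 2 channels, %.3g um/px\n",
    d[1], d[2], x$pixel_size_um
  ))
  invisible(x)
}

tile_channel <- function(tile, channel = c("s", "m")) {
  channel <- match.arg(tolower(as.character(channel)), c("s", "m"))
  tile$pixels[, , if (channel == "s") 1 else 2]
}

#' Read and write image tiles as 32-bit TIFF plus JSON sidecar
#'
#' The two channels are written as two pages of a 32-bit float TIFF;
#' metadata (pixel size, orientation, optional planted ground truth) goes to
#' a JSON sidecar `<path>.json`. `read_image_tile()` restores both.
#'
#' @param tile An [image_tile()].
#' @param path TIFF file path.
#' @param truth Include the planted ground-truth table in the sidecar.
#' @return `write_image_tile()` returns `path` invisibly;
#'   `read_image_tile()` returns an `image_tile`.
#' @export
write_image_tile <- function(tile, path, truth = TRUE) {
  stopifnot(inherits(tile, "image_tile"))
  # TIFF storage is [0, 1]; keep a scale factor in the sidecar
  scale <- max(tile$pixels, 1)
  pages <- list(tile$pixels[, , 1] / scale, tile$pixels[, , 2] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    intensity_scale = scale,
    pixel_size_um = tile$pixel_size_um,
    orientation = tile$orientation,
    background_level = tile$background_level,
    noise_sd = tile$noise_sd,
    psf_sigma_um = tile$psf_sigma_um
  )
  if (truth && !is.null(tile$truth)) {
    meta$truth <- as.data.frame(tile$truth)
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_image_tile
#' @export
read_image_tile <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2) abort("expected a two-page (two-channel) TIFF")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(pixel_size_um = 1)
  }
  scale <- meta$intensity_scale %||% 1
  tile <- image_tile(
    list(pages[[1]] * scale, pages[[2]] * scale),
    pixel_size_um = meta$pixel_size_um,
    orientation = meta$orientation %||% "rows_dorsal_to_ventral",
    background_level = meta$background_level,
    noise_sd = meta$noise_sd,
    psf_sigma_um = meta$psf_sigma_um
  )
  if (!is.null(meta$truth)) tile$truth <- tibble::as_tibble(meta$truth)
  tile
}
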