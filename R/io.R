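#' Intensity image container
#'
#' A 2D grayscale pixel grid with a physical pixel pitch, the unit every
#' spatial quantity downstream (radii, densities, window sizes) is derived
#' from. Rows index y, columns index x; pixel centres sit at
#' `(col - 0.5) * pixel_size_um`, `(row - 0.5) * pixel_size_um`.
#'
#' @param pixels numeric matrix of non-negative finite intensities.
#' @param pixel_size_um physical pixel pitch in micrometres.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, pixel_size_um) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("pixels must be finite", call. = FALSE)
  if (any(pixels < 0)) stop("pixels must be non-negative", call. = FALSE)
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("intensity_image: %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask container
#'
#' @param mask logical matrix.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, pixel_size_um) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(mask = mask, pixel_size_um = pixel_size_um),
            class = "binary_mask")
}

#' Write an intensity image as 16-bit TIFF with a JSON sidecar
#'
#' Intensities are linearly rescaled to the 16-bit range; the scale and the
#' pixel size are recorded in `<path>.json` so that [read_intensity_tiff()]
#' restores physical units.
#'
#' @param img an [intensity_image()].
#' @param path output TIFF path.
#' @export
write_intensity_tiff <- function(img, path) {
  stopifnot(inherits(img, "intensity_image"))
  mx <- max(img$pixels)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(img$pixels / scale, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = img$pixel_size_um, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an intensity image written by [write_intensity_tiff()]
#'
#' @param path TIFF path; `<path>.json` must hold `pixel_size_um` and
#'   `intensity_scale`.
#' @return An [intensity_image()].
#' @export
read_intensity_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  intensity_image(px * meta$intensity_scale, meta$pixel_size_um)
}

#' Write a TCSPC decay stack as a multi-page TIFF plus JSON sidecar
#'
#' One page per time bin; counts are stored relative to the stack maximum,
#' with the scale in the sidecar.
#'
#' @param stack a [decay_stack()].
#' @param path output TIFF path.
#' @export
write_decay_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "decay_stack"))
  mx <- max(stack$counts)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(stack$n_bins),
                  function(k) stack$counts[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(bin_width_ps = stack$bin_width_ps, n_bins = stack$n_bins,
         count_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decay stack written by [write_decay_tiff()]
#' @param path TIFF path with `<path>.json` sidecar.
#' @return A [decay_stack()].
#' @export
read_decay_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  counts <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- round(pages[[k]] * meta$count_scale)
  decay_stack(counts, meta$bin_width_ps)
}
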