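# Region maps: integer label rasters (0 = background, k >= 1 = region k)
# on the illumination pixel grid.

new_region_map <- function(labels, pixel_size) {
  regions <- region_table(labels, pixel_size)
  structure(list(labels = labels, pixel_size = pixel_size, regions = regions),
            class = "bali_region_map")
}

region_table <- function(labels, pixel_size) {
  pos <- which(labels > 0L, arr.ind = TRUE)
  if (!nrow(pos)) {
    return(data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  lab <- labels[pos]
  area <- tapply(lab, lab, length)
  crow <- tapply(pos[, 1L], lab, mean)
  ccol <- tapply(pos[, 2L], lab, mean)
  out <- data.frame(label = as.integer(names(area)),
                    area = as.integer(area),
                    centroid_row = as.numeric(crow),
                    centroid_col = as.numeric(ccol))
  out[order(out$label), , drop = FALSE]
}

#' Region map from a segmented label image
#'
#' Converts an integer label raster (as produced by tissue segmentation) into
#' a region map, dropping regions smaller than `min_area` pixels (their pixels
#' are relabelled to background).
#'
#' @param raster Integer matrix; 0 = background, `k >= 1` = region `k`.
#' @param pixel_size Micrometres per pixel.
#' @param min_area Minimum region area in pixels.
#' @return A `bali_region_map` with elements `labels` (the raster),
#'   `pixel_size`, and `regions` (a table of label, area and centroid sorted
#'   by label).
#' @export
regions_from_label_image <- function(raster, pixel_size = 1, min_area = 1L) {
  if (!is.matrix(raster) || !is.numeric(raster)) {
    stop("`raster` must be a numeric matrix of integer labels")
  }
  if (any(is.na(raster)) || any(raster < 0) || any(raster != round(raster))) {
    stop("`raster` must contain non-negative integers")
  }
  labels <- matrix(as.integer(raster), nrow(raster), ncol(raster))
  tab <- table(labels[labels > 0L])
  small <- as.integer(names(tab)[tab < min_area])
  if (length(small)) labels[labels %in% small] <- 0L
  new_region_map(labels, pixel_size)
}

#' Regular grid of square regions
#'
#' Tiles the raster with non-overlapping square regions of side `pitch`
#' pixels, labelled row-major from 1. Edge tiles are truncated so that the
#' labels partition all pixels (no background).
#'
#' @param shape Integer vector `c(nrow, ncol)` of the raster.
#' @param pitch Tile side in pixels.
#' @param pixel_size Micrometres per pixel.
#' @return A `bali_region_map`.
#' @examples
#' make_grid_regions(c(40, 40), 10)  # 16 regions
#' @export
make_grid_regions <- function(shape, pitch, pixel_size = 1) {
  shape <- as.integer(shape)
  pitch <- check_count(pitch, "pitch")
  if (length(shape) != 2L || any(shape < 1L)) {
    stop("`shape` must be c(nrow, ncol) with positive entries")
  }
  if (pitch > shape[1L] || pitch > shape[2L]) {
    stop("`pitch` (", pitch, ") larger than raster ", shape[1L], "x", shape[2L])
  }
  nbc <- ceiling(shape[2L] / pitch)
  rb <- (seq_len(shape[1L]) - 1L) %/% pitch
  cb <- (seq_len(shape[2L]) - 1L) %/% pitch
  labels <- outer(rb, cb, function(r, co) as.integer(r * nbc + co + 1L))
  new_region_map(labels, pixel_size)
}

#' @export
print.bali_region_map <- function(x, ...) {
  cat("Region map:", nrow(x$labels), "x", ncol(x$labels), "px (",
      x$pixel_size, "um/px ),", nrow(x$regions), "regions\n")
  invisible(x)
}

#' Read an integer label image (PNG or TIFF)
#'
#' Single-channel integer rasters; PNG values are rescaled from the [0, 1]
#' storage convention back to integer labels, TIFFs are read as stored.
#'
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @return Integer matrix of labels.
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    bits <- attr(img, "info")$bit.depth %||% 16L
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- round(img * (2^bits - 1))
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- img
  } else {
    stop("unsupported label image format: .", ext)
  }
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Write an integer label image
#'
#' TIFF output is 16-bit (labels up to 65,535); PNG output is 8-bit
#' (labels up to 255).
#'
#' @param labels Integer matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(labels) > 255L) stop("PNG labels limited to 8 bit; use TIFF")
    png::writePNG(matrix(as.numeric(labels), nrow(labels), ncol(labels)) / 255,
                  path)
  } else if (ext %in% c("tif", "tiff")) {
    if (max(labels) > 65535L) stop("TIFF labels limited to 16 bit")
    tiff::writeTIFF(matrix(as.numeric(labels), nrow(labels), ncol(labels)) /
                      65535, path, bits.per.sample = 16L)
  } else {
    stop("unsupported label image format: .", ext)
  }
  invisible(path)
}
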