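#' Read and write boundary annotations
#'
#' Boundary sets are stored as JSON objects mapping boundary names to arrays
#' of per-column depths (pixels).
#'
#' @param path File path.
#' @return [read_boundaries()] returns a [boundary_set()].
#' @export
read_boundaries <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  boundary_set(lapply(obj, as.numeric))
}

#' @rdname read_boundaries
#' @param boundaries A [boundary_set()] (or compatible named list).
#' @export
write_boundaries <- function(boundaries, path) {
  jsonlite::write_json(lapply(unclass(boundaries), as.numeric), path,
                       digits = NA)
  invisible(path)
}

#' Read a grayscale image file as an AO image
#'
#' Single-channel TIFF or PNG; multi-channel input is averaged to gray.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_scale um/pixel.
#' @param fovea_xy Optional fovea coordinates, pixels.
#' @return An [ao_image()].
#' @export
read_ao_image <- function(path, pixel_scale, fovea_xy = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' required to read TIFF files")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' required to read PNG files")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
  ao_image(m, pixel_scale, fovea_xy)
}

#' Write cone positions to CSV
#'
#' @param mosaic A [cone_mosaic()].
#' @param path Output path.
#' @param roi_id Identifier recorded in the `roi_id` column.
#' @export
write_cone_positions <- function(mosaic, path, roi_id = "roi1") {
  df <- mosaic$positions
  df$roi_id <- roi_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
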