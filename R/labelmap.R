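#' Label map
#'
#' A 2-D grid of integer tissue-class codes with physical pixel spacing.
#' Coordinates are 0-based, row-major, pixel-centre; origin at the top-left
#' pixel. If a scheme is supplied, every code in the grid is validated
#' against it.
#'
#' @param grid integer matrix of class codes.
#' @param spacing_um pixel size in micrometres per pixel (default 0.5, the
#'   20x processing resolution).
#' @param scheme optional [tissue_scheme()] to validate codes against.
#' @return object of class `label_map`: the integer matrix with a
#'   `spacing_um` attribute.
#' @export
label_map <- function(grid, spacing_um = 0.5, scheme = NULL) {
  if (!is.matrix(grid) || length(grid) == 0L)
    tsr_stop("tsr_validation_error", "label map grid must be a non-empty matrix")
  storage.mode(grid) <- "integer"
  if (anyNA(grid))
    tsr_stop("tsr_validation_error", "label map grid contains NA")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    tsr_stop("tsr_validation_error", "spacing_um must be a positive number")
  if (!is.null(scheme)) validate_codes(grid, scheme)
  structure(grid, spacing_um = as.numeric(spacing_um), class = "label_map")
}

validate_codes <- function(grid, scheme) {
  known <- scheme$entries$code
  bad <- !(grid %in% known)
  if (any(bad)) {
    i <- which(bad)[1]
    rc <- arrayInd(i, dim(grid))
    tsr_stop("tsr_validation_error", sprintf(
      "unknown class code %d at pixel (row %d, col %d)",
      grid[i], rc[1] - 1L, rc[2] - 1L))
  }
  invisible(TRUE)
}

#' @export
print.label_map <- function(x, ...) {
  sp <- attr(x, "spacing_um")
  cat(sprintf("Label map: %d x %d pixels at %g um/pixel (%.2f x %.2f mm)\n",
              nrow(x), ncol(x), sp,
              nrow(x) * sp / 1000, ncol(x) * sp / 1000))
  tab <- table(as.vector(unclass(x)))
  cat("Code counts:", paste(sprintf("%s:%d", names(tab), tab),
                            collapse = " "), "\n")
  invisible(x)
}

#' Pixel spacing of a label map
#' @param map a [label_map()].
#' @return micrometres per pixel.
#' @export
spacing_um <- function(map) attr(map, "spacing_um")

#' Read a label map from an indexed PNG or TIFF raster
#'
#' The raster must be single-channel with integer codes (stored as 8- or
#' 16-bit). Codes are validated against the scheme; the first offending
#' pixel is reported.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param scheme a [tissue_scheme()].
#' @param spacing_um pixel size; the default 0.5 um/pixel applies when the
#'   raster carries no resolution metadata.
#' @return a [label_map()].
#' @export
read_labelmap <- function(path, scheme, spacing_um = 0.5) {
  if (!file.exists(path))
    tsr_stop("tsr_format_error", sprintf("raster not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    tsr_stop("tsr_format_error", sprintf("unsupported raster format: .%s", ext))
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      tsr_stop("tsr_format_error", "label raster must be single-channel")
    img <- img[, , 1L]
  }
  # readers return intensities in [0,1]; recover the 8-bit integer codes
  grid <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  label_map(grid, spacing_um = spacing_um, scheme = scheme)
}

#' Write a label map as an indexed raster
#'
#' Codes are stored as 8-bit grey values, so codes must be in 0..255.
#' Round-trips through [read_labelmap()] are bit-identical on the grid.
#'
#' @param map a [label_map()].
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(map, path) {
  grid <- unclass(map)
  if (max(grid) > 255L)
    tsr_stop("tsr_format_error", "codes above 255 cannot be stored as 8-bit")
  img <- matrix(grid / 255, nrow(grid), ncol(grid))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, target = path),
    tif = ,
    tiff = tiff::writeTIFF(img, where = path, bits.per.sample = 8L),
    tsr_stop("tsr_format_error", sprintf("unsupported raster format: .%s", ext))
  )
  invisible(path)
}
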