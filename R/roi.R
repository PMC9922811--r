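#' Circular region of interest
#'
#' The circular field of view used for TSR scoring, equivalent to a 100x
#' microscope field: centre in 0-based pixel coordinates plus a physical
#' diameter (default 2.0 mm).
#'
#' @param center_row,center_col 0-based pixel coordinates of the centre.
#' @param diameter_mm physical diameter in millimetres.
#' @return object of class `circular_roi`.
#' @export
circular_roi <- function(center_row, center_col, diameter_mm = 2.0) {
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    tsr_stop("tsr_format_error", "diameter_mm must be positive")
  structure(list(center_row = as.numeric(center_row),
                 center_col = as.numeric(center_col),
                 diameter_mm = as.numeric(diameter_mm)),
            class = "circular_roi")
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("Circular ROI: centre (row %g, col %g), diameter %g mm\n",
              x$center_row, x$center_col, x$diameter_mm))
  invisible(x)
}

# radius in pixels for a given map spacing; must resolve to >= 1 px
roi_radius_px <- function(roi, spacing_um) {
  r <- fov_radius_px(roi$diameter_mm, spacing_um)
  if (r < 1L)
    tsr_stop("tsr_format_error",
             "ROI diameter is below one pixel at this spacing")
  r
}

#' Read a circular ROI from a GeoJSON annotation
#'
#' Expects a FeatureCollection whose first feature is a Point with a
#' `diameter_mm` property; coordinates are `[col, row]` in pixels.
#'
#' @param path path to a GeoJSON file.
#' @return a [circular_roi()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path))
    tsr_stop("tsr_format_error", sprintf("ROI file not found: %s", path))
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats) || !length(feats))
    tsr_stop("tsr_format_error", "ROI file has no features")
  f <- feats[[1]]
  geom <- f$geometry
  if (is.null(geom$type) || !identical(geom$type, "Point"))
    tsr_stop("tsr_format_error", "ROI geometry must be a Point")
  cc <- unlist(geom$coordinates)
  if (length(cc) != 2L || anyNA(suppressWarnings(as.numeric(cc))))
    tsr_stop("tsr_format_error", "malformed Point coordinates in ROI file")
  d <- f$properties$diameter_mm
  if (is.null(d)) d <- 2.0
  circular_roi(center_row = as.numeric(cc[2]),
               center_col = as.numeric(cc[1]),
               diameter_mm = as.numeric(d))
}

#' Write a circular ROI as GeoJSON
#'
#' @param roi a [circular_roi()] (or a list of them, written as one
#'   FeatureCollection).
#' @param path output path.
#' @param properties optional named list merged into each feature's
#'   properties (e.g. rank, stroma_percent).
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path, properties = NULL) {
  rois <- if (inherits(roi, "circular_roi")) list(roi) else roi
  feats <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    props <- c(list(diameter_mm = r$diameter_mm),
               if (is.null(properties)) NULL
               else lapply(properties, function(p)
                 if (length(p) > 1L) p[[i]] else p))
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(r$center_col, r$center_row)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
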