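#' Extract the tumor bulk from a label map
#'
#' The tumor bulk is the region enclosing all predicted tumor glands,
#' including the invasive edge and budding zone. It is obtained from the
#' tumor-gland mask by a deterministic concave-hull surrogate: morphological
#' closing with a disc (default radius = the field-of-view radius, 1.0 mm),
#' hole filling, and removal of connected components smaller than
#' `min_component_area_mm2` (default = one field-of-view area, pi mm^2),
#' which discards small false-positive gland specks.
#'
#' Closing uses the same pixel-centre disc as the rest of the pipeline and
#' is forced extensive (the original gland pixels are always kept), so
#' near-border glands are never eroded away.
#'
#' @param map a [label_map()].
#' @param scheme a [tissue_scheme()].
#' @param min_component_area_mm2 components smaller than this are dropped;
#'   0 keeps everything.
#' @param closing_radius_mm disc radius for the closing; 0 skips closing.
#' @return object of class `tumor_bulk`: list with logical `mask` and
#'   `component_count`.
#' @export
extract_tumor_bulk <- function(map, scheme,
                               min_component_area_mm2 = pi * 1.0^2,
                               closing_radius_mm = 1.0) {
  grid <- unclass(map)
  sp <- spacing_um(map)
  tumor_code <- scheme$entries$code[scheme$entries$name == "tumor glands"]
  if (!length(tumor_code))
    tsr_stop("tsr_format_error", "scheme has no 'tumor glands' class")
  glands <- grid == tumor_code
  if (!any(glands))
    tsr_stop(c("tsr_empty_bulk_error", "tsr_unassessable_error"),
             "no tumor-gland pixels: empty tumor bulk")

  mask <- glands
  r_close <- fov_radius_px(closing_radius_mm, sp)
  if (closing_radius_mm > 0 && r_close >= 1L) {
    area <- sum(disc_kernel(r_close))
    dilated <- disc_counts(mask, r_close) > 0
    closed <- disc_counts(dilated, r_close) == area
    mask <- closed | glands
  }
  mask <- EBImage::fillHull(mask * 1L) > 0

  labels <- EBImage::bwlabel(mask * 1L)
  n_comp <- max(labels)
  if (n_comp > 0 && min_component_area_mm2 > 0) {
    min_px <- min_component_area_mm2 * 1e6 / sp^2
    areas <- tabulate(labels[labels > 0], nbins = n_comp)
    keep <- which(areas >= min_px)
    mask <- matrix(labels %in% keep, nrow(grid), ncol(grid))
    n_comp <- length(keep)
  }
  if (!any(mask))
    tsr_stop(c("tsr_empty_bulk_error", "tsr_unassessable_error"),
             "all tumor components below the minimum area: empty tumor bulk")
  structure(list(mask = mask, component_count = as.integer(n_comp)),
            class = "tumor_bulk")
}

#' @export
print.tumor_bulk <- function(x, ...) {
  cat(sprintf("Tumor bulk: %d component(s), %d pixels\n",
              x$component_count, sum(x$mask)))
  invisible(x)
}

#' Admissible field-of-view centres
#'
#' A centre is valid when the whole field-of-view circle lies inside the
#' tumor bulk and contains no background pixels (lack of tissue or tissue
#' tears). This equals a binary erosion of the bulk, restricted further by
#' background influence, using the circle as structuring element; both
#' conditions are evaluated with the shared disc kernel. Centres closer than
#' one radius to the grid border are never valid (their circle leaves the
#' grid).
#'
#' @param bulk a `tumor_bulk` from [extract_tumor_bulk()].
#' @param map the [label_map()] the bulk was derived from.
#' @param scheme a [tissue_scheme()] (for the background code).
#' @param fov a [circular_roi()] giving the field-of-view diameter; its
#'   centre coordinates are ignored.
#' @return logical matrix of valid centres, same dimension as the map.
#' @export
valid_centers <- function(bulk, map, scheme, fov = circular_roi(0, 0, 2.0)) {
  grid <- unclass(map)
  r <- roi_radius_px(fov, spacing_um(map))
  outside_bulk <- disc_counts(!bulk$mask, r)
  bg <- grid == background_code(scheme)
  bg_in_fov <- disc_counts(bg, r)
  valid <- outside_bulk == 0 & bg_in_fov == 0
  # circles must lie fully on the grid
  nr <- nrow(grid); nc <- ncol(grid)
  if (r >= 1L) {
    border_r <- c(seq_len(min(r, nr)), nr + 1L - seq_len(min(r, nr)))
    border_c <- c(seq_len(min(r, nc)), nc + 1L - seq_len(min(r, nc)))
    valid[border_r, ] <- FALSE
    valid[, border_c] <- FALSE
  }
  valid
}
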