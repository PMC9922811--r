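#' Per-class pixel counts inside a circular ROI
#'
#' Counts pixels of each class code whose centres lie within the ROI circle
#' (Euclidean distance to the centre at most the radius, converted from the
#' physical diameter at the map's spacing). Pixels of the circle that fall
#' outside the grid are ignored.
#'
#' @param map a [label_map()].
#' @param roi a [circular_roi()].
#' @return named integer vector: one count per class code present in the
#'   circle, plus attribute `roi_px` (total circle pixels on the grid).
#' @export
class_counts <- function(map, roi) {
  grid <- unclass(map)
  r <- roi_radius_px(roi, spacing_um(map))
  rows <- seq(floor(roi$center_row - r), ceiling(roi$center_row + r))
  cols <- seq(floor(roi$center_col - r), ceiling(roi$center_col + r))
  rows <- rows[rows >= 0 & rows < nrow(grid)]
  cols <- cols[cols >= 0 & cols < ncol(grid)]
  if (!length(rows) || !length(cols))
    tsr_stop("tsr_empty_roi_error", "ROI lies entirely outside the grid")
  inside <- outer((rows - roi$center_row)^2, (cols - roi$center_col)^2, `+`) <= r^2
  if (!any(inside))
    tsr_stop("tsr_empty_roi_error", "ROI lies entirely outside the grid")
  vals <- grid[as.matrix(expand.grid(rows + 1L, cols + 1L))][as.vector(inside)]
  tab <- table(vals)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(counts, roi_px = sum(inside))
}

#' Semi-automated TSR inside a human-selected hot-spot
#'
#' The stroma percentage within the circular hot-spot: stromal pixels
#' (tumor-associated stroma, lymphocytes, erythrocytes, muscle, healthy
#' stroma, nerve, stroma lamina propria) over all ROI pixels minus mucus,
#' necrosis and background. Fatty tissue stays in the denominator; only the
#' three listed classes are excluded.
#'
#' @param map a [label_map()].
#' @param roi a [circular_roi()] marking the hot-spot.
#' @param scheme a [tissue_scheme()].
#' @param cutoff dichotomization cut-off (default 50: stroma-low if the
#'   percentage is at most 50, stroma-high above).
#' @return object of class `tsr_result` with `stroma_percent`,
#'   `class_pixel_counts`, `denominator_px`, `dichotomy`, `mode = "semi"`.
#' @export
semi_auto_tsr <- function(map, roi, scheme, cutoff = 50) {
  validate_codes(unclass(map), scheme)
  counts <- class_counts(map, roi)
  codes <- as.integer(names(counts))
  roi_px <- attr(counts, "roi_px")
  stroma_px <- sum(counts[codes %in% scheme_codes(scheme, "stroma_semi")])
  excluded_px <- sum(counts[codes %in%
                              scheme_codes(scheme, "denominator_excluded_semi")])
  denom <- roi_px - excluded_px
  if (denom <= 0)
    tsr_stop("tsr_unassessable_error",
             "ROI contains only mucus, necrosis and/or background; TSR undefined")
  pct <- 100 * stroma_px / denom
  tsr_result(stroma_percent = pct, class_pixel_counts = counts,
             denominator_px = denom, mode = "semi", cutoff = cutoff)
}

# shared constructor for semi and fully automated results
tsr_result <- function(stroma_percent, class_pixel_counts = NULL,
                       denominator_px, mode, cutoff = 50,
                       center = NULL, rank = NA_integer_) {
  structure(list(
    stroma_percent = as.numeric(stroma_percent),
    class_pixel_counts = class_pixel_counts,
    denominator_px = as.integer(denominator_px),
    dichotomy = as.character(dichotomize(stroma_percent, cutoff)),
    mode = mode, center = center, rank = rank
  ), class = "tsr_result")
}

#' Round a stroma percentage to the visual 10% grid
#'
#' Convenience view for comparing automated scores with visual estimates,
#' which are given in increments of 10%.
#'
#' @param x a `tsr_result` or a numeric percentage.
#' @return integer percentage on the 10% grid.
#' @export
round_to_grid <- function(x) {
  p <- if (inherits(x, "tsr_result")) x$stroma_percent else x
  as.integer(pmin(100, pmax(0, 10 * round_half_up(p / 10))))
}

#' @export
print.tsr_result <- function(x, digits = 1, ...) {
  lbl <- if (!is.na(x$rank)) sprintf(" (TSR-%d)", x$rank) else ""
  cat(sprintf("TSR [%s]%s: %.*f%% stroma -> %s\n", x$mode, lbl, digits,
              x$stroma_percent, x$dichotomy))
  if (!is.null(x$center))
    cat(sprintf("  centre: (row %g, col %g)\n", x$center[1], x$center[2]))
  cat(sprintf("  denominator: %d px; on 10%% grid: %d%%\n",
              x$denominator_px, round_to_grid(x)))
  invisible(x)
}
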