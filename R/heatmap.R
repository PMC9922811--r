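#' TSR heatmap over valid field-of-view centres
#'
#' For every valid centre, per-class in-circle pixel counts are obtained by
#' convolving each class-indicator grid with the binary disc kernel in the
#' Fourier domain (exact integer counts after rounding; see
#' [disc_counts()]). The stroma percentage at a centre is
#' `100 * stroma_full / (stroma_full + tumor_full)`, with stroma_full =
#' tumor-associated stroma + lymphocytes + nerve + erythrocytes and
#' tumor_full = tumor glands + healthy glands. Centres whose denominator is
#' zero are marked invalid.
#'
#' @param map a [label_map()].
#' @param centers logical matrix of admissible centres
#'   (from [valid_centers()]).
#' @param scheme a [tissue_scheme()].
#' @param fov a [circular_roi()] giving the field-of-view diameter.
#' @return object of class `tsr_heatmap`: list with `values` (matrix,
#'   `NA` where invalid), `valid_mask`, `fov`, `radius_px`, `spacing_um`.
#' @export
tsr_heatmap <- function(map, centers, scheme, fov = circular_roi(0, 0, 2.0)) {
  grid <- unclass(map)
  if (!any(centers))
    tsr_stop("tsr_unassessable_error", "no valid field-of-view centres")
  r <- roi_radius_px(fov, spacing_um(map))
  in_group <- function(group)   # %in% drops the dim attribute
    matrix(grid %in% scheme_codes(scheme, group), nrow(grid), ncol(grid))
  stroma <- disc_counts(in_group("stroma_full"), r)
  tumor <- disc_counts(in_group("tumor_full"), r)
  denom <- stroma + tumor
  valid <- centers & denom > 0
  values <- matrix(NA_real_, nrow(grid), ncol(grid))
  values[valid] <- 100 * stroma[valid] / denom[valid]
  structure(list(values = values, valid_mask = valid, fov = fov,
                 radius_px = r, spacing_um = spacing_um(map)),
            class = "tsr_heatmap")
}

#' Invalidate centres violating tissue-composition rules
#'
#' Good-practice rules from visual assessment: a field of view is valid only
#' if fatty tissue occupies less than 5% of it, erythrocytes less than 10%,
#' and necrosis less than 30%. Thresholds are strict: a field at exactly the
#' threshold is invalid. Fractions are relative to the full disc area and
#' are computed with the same disc kernel as the heatmap.
#'
#' @param heatmap a [tsr_heatmap()].
#' @param map the [label_map()] the heatmap was computed from.
#' @param scheme a [tissue_scheme()].
#' @param thresholds named numeric vector of strict upper bounds on the
#'   in-disc area fraction per nuisance class.
#' @return the heatmap with offending centres invalidated.
#' @export
apply_validity_rules <- function(heatmap, map, scheme,
                                 thresholds = c(fat = 0.05,
                                                erythrocytes = 0.10,
                                                necrosis = 0.30)) {
  grid <- unclass(map)
  r <- heatmap$radius_px
  disc_area <- sum(disc_kernel(r))
  valid <- heatmap$valid_mask
  for (nm in names(thresholds)) {
    ind <- matrix(grid %in% scheme_codes(scheme, nm), nrow(grid), ncol(grid))
    frac <- disc_counts(ind, r) / disc_area
    valid <- valid & frac < thresholds[[nm]]
  }
  heatmap$values[!valid] <- NA_real_
  heatmap$valid_mask <- valid
  heatmap
}

#' Top-k hot-spots of a TSR heatmap
#'
#' Iteratively selects the global maximum among the remaining valid
#' centres; after each selection every centre within one field-of-view
#' radius of it is zeroed (a suppression region as large as the field of
#' view), so successive hot-spots never overlap. Ties are broken towards
#' the smallest row, then the smallest column. Stops after `k` spots or
#' when no valid centre remains (the shorter list is returned with a
#' message, not an error).
#'
#' @param heatmap a [tsr_heatmap()], typically after
#'   [apply_validity_rules()].
#' @param k number of hot-spots to extract (default 3: TSR-1..TSR-3).
#' @return data.frame of class `tsr_hotspots`: columns `rank`, `label`,
#'   `center_row`, `center_col` (0-based), `stroma_percent`.
#' @export
top_k_hotspots <- function(heatmap, k = 3L) {
  vals <- heatmap$values
  vals[!heatmap$valid_mask] <- NA_real_
  if (all(is.na(vals)))
    tsr_stop("tsr_unassessable_error", "heatmap has no valid centres")
  r <- heatmap$radius_px
  nr <- nrow(vals); nc <- ncol(vals)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    if (all(is.na(vals))) {
      message(sprintf("only %d hot-spot(s) available (requested %d)", i - 1L, k))
      break
    }
    m <- max(vals, na.rm = TRUE)
    cand <- which(vals == m, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    ri <- cand[1, 1]; ci <- cand[1, 2]
    out[[i]] <- data.frame(rank = i, label = sprintf("TSR-%d", i),
                           center_row = ri - 1L, center_col = ci - 1L,
                           stroma_percent = m)
    # zero a circular region as large as the field of view
    rows <- max(1L, ri - r):min(nr, ri + r)
    cols <- max(1L, ci - r):min(nc, ci + r)
    supp <- outer((rows - ri)^2, (cols - ci)^2, `+`) <= r^2
    vals[rows, cols][supp] <- NA_real_
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  structure(res, class = c("tsr_hotspots", "data.frame"),
            fov = heatmap$fov)
}

#' Fully automated TSR scoring of a label map
#'
#' End-to-end pipeline: tumor-bulk extraction, valid-centre erosion by the
#' field of view, Fourier-domain TSR heatmap, tissue-composition validity
#' rules, and top-k hot-spot ranking. Each hot-spot is returned as a
#' `tsr_result` (mode `"full"`) with its stroma percentage, dichotomized
#' label, centre and rank.
#'
#' A case whose tumor area is too narrow to fit the circular field of view
#' (no valid centre survives) raises an unassessable-case error; a map with
#' no tumor glands raises an empty-bulk error.
#'
#' @param map a [label_map()].
#' @param scheme a [tissue_scheme()].
#' @param fov_diameter_mm field-of-view diameter (default 2.0 mm).
#' @param k number of ranked hot-spots (default 3).
#' @param min_component_area_mm2,closing_radius_mm bulk-extraction
#'   parameters, see [extract_tumor_bulk()].
#' @param thresholds validity-rule bounds, see [apply_validity_rules()].
#' @param cutoff dichotomization cut-off (default 50).
#' @param stride evaluate only every `stride`-th centre in each direction
#'   (efficiency knob for very large maps; default 1 = every pixel).
#' @return object of class `tsr_analysis`: list with `bulk`, `heatmap`,
#'   `hotspots`, and `results` (list of `tsr_result`).
#' @export
fully_auto_tsr <- function(map, scheme, fov_diameter_mm = 2.0, k = 3L,
                           min_component_area_mm2 = pi * (fov_diameter_mm / 2)^2,
                           closing_radius_mm = fov_diameter_mm / 2,
                           thresholds = c(fat = 0.05, erythrocytes = 0.10,
                                          necrosis = 0.30),
                           cutoff = 50, stride = 1L) {
  validate_codes(unclass(map), scheme)
  fov <- circular_roi(NA, NA, fov_diameter_mm)
  bulk <- extract_tumor_bulk(map, scheme,
                             min_component_area_mm2 = min_component_area_mm2,
                             closing_radius_mm = closing_radius_mm)
  centers <- valid_centers(bulk, map, scheme, fov)
  if (stride > 1L) {
    keep_r <- seq(1L, nrow(centers), by = stride)
    keep_c <- seq(1L, ncol(centers), by = stride)
    strided <- matrix(FALSE, nrow(centers), ncol(centers))
    strided[keep_r, keep_c] <- TRUE
    centers <- centers & strided
  }
  if (!any(centers))
    tsr_stop("tsr_unassessable_error", sprintf(
      "tumor area too narrow to fit the %.1f mm field of view", fov_diameter_mm))
  hm <- tsr_heatmap(map, centers, scheme, fov)
  hm <- apply_validity_rules(hm, map, scheme, thresholds)
  if (!any(hm$valid_mask))
    tsr_stop("tsr_unassessable_error",
             "no field of view passes the tissue-composition validity rules")
  spots <- top_k_hotspots(hm, k)
  disc_area <- sum(disc_kernel(hm$radius_px))
  results <- lapply(seq_len(nrow(spots)), function(i) {
    tsr_result(stroma_percent = spots$stroma_percent[i],
               denominator_px = disc_area, mode = "full", cutoff = cutoff,
               center = c(spots$center_row[i], spots$center_col[i]),
               rank = spots$rank[i])
  })
  structure(list(bulk = bulk, heatmap = hm, hotspots = spots,
                 results = results, fov = fov, cutoff = cutoff),
            class = "tsr_analysis")
}

#' @export
print.tsr_analysis <- function(x, ...) {
  cat(sprintf("Fully automated TSR analysis (%.1f mm field of view)\n",
              x$fov$diameter_mm))
  print(x$bulk)
  cat(sprintf("Valid centres: %d\n", sum(x$heatmap$valid_mask)))
  for (r in x$results) print(r)
  invisible(x)
}

#' @export
summary.tsr_analysis <- function(object, ...) {
  df <- object$hotspots
  df$dichotomy <- vapply(object$results, function(r) r$dichotomy, character(1))
  df
}

#' @export
plot.tsr_heatmap <- function(x, ...) {
  v <- t(x$values)[, rev(seq_len(nrow(x$values))), drop = FALSE]
  graphics::image(v, zlim = c(0, 100), asp = nrow(x$values) / ncol(x$values),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "", ylab = "", axes = FALSE,
                  main = "TSR heatmap (% stroma)", ...)
  invisible(x)
}

#' Write a TSR heatmap as a float TIFF (invalid centres = NaN)
#'
#' @param heatmap a [tsr_heatmap()].
#' @param path output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(heatmap, path) {
  v <- heatmap$values / 100
  v[is.na(v)] <- NaN
  tiff::writeTIFF(v, where = path, bits.per.sample = 32L)
  invisible(path)
}
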