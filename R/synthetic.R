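#' Specification for a synthetic label map
#'
#' Describes a synthetic slide with known ground truth: a roughly circular
#' tumor blob whose interior pixels are drawn tumor-gland vs stroma by a
#' spatially varying planted stroma fraction (base level plus Gaussian
#' bumps), optional solid nuisance patches (fat, erythrocytes, necrosis)
#' with analytically known in-disc fractions, and background outside the
#' blob. Per-pixel Bernoulli labelling keeps expected in-disc counts
#' analytic, so recovery tolerances are derivable.
#'
#' Defaults emulate a desk-scale slide: a 640 x 640 grid at 8 um/pixel
#' (5.12 x 5.12 mm) with a 2.2 mm-radius blob, base stroma fraction 0.4 and
#' one bump of amplitude +0.3 (sigma 0.5 mm), so the 2.0 mm field of view
#' (radius 125 px) fits comfortably inside the eroded bulk.
#'
#' @param dim_px grid size (rows = cols).
#' @param spacing_um pixel size in micrometres.
#' @param blob_center 0-based (row, col) of the blob centre; default grid
#'   centre.
#' @param blob_radius_mm tumor blob radius.
#' @param roughness_amp_mm,roughness_waves sinusoidal boundary roughness:
#'   radial amplitude and number of waves (0 amplitude = perfect disc).
#' @param base_fraction baseline stroma fraction inside the blob.
#' @param bumps list of Gaussian bumps, each
#'   `list(center = c(row, col), amplitude =, sigma_mm =)`.
#' @param patches list of nuisance patches, each
#'   `list(class = "fatty tissue"|..., center = c(row, col), radius_px =)`.
#' @param flip_rate flat label-flip rate emulating segmentation noise
#'   (default 0: clean labels).
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dim_px = 640L, spacing_um = 8,
                           blob_center = NULL, blob_radius_mm = 2.2,
                           roughness_amp_mm = 0.1, roughness_waves = 5L,
                           base_fraction = 0.4,
                           bumps = list(list(center = NULL, amplitude = 0.3,
                                             sigma_mm = 0.5)),
                           patches = list(), flip_rate = 0, seed = 1L) {
  if (is.null(blob_center)) blob_center <- c(dim_px, dim_px) / 2
  blob_radius_px <- blob_radius_mm * 1000 / spacing_um
  if (blob_radius_px + roughness_amp_mm * 1000 / spacing_um >
      min(blob_center, dim_px - 1 - blob_center))
    tsr_stop("tsr_input_error", "tumor blob does not fit the grid")
  for (i in seq_along(bumps)) {
    if (is.null(bumps[[i]]$center)) bumps[[i]]$center <- blob_center
    if (bumps[[i]]$amplitude + base_fraction > 1 ||
        base_fraction + min(0, bumps[[i]]$amplitude) < 0)
      tsr_stop("tsr_input_error", "planted stroma fractions must stay in [0,1]")
  }
  structure(list(dim_px = as.integer(dim_px), spacing_um = spacing_um,
                 blob_center = blob_center, blob_radius_mm = blob_radius_mm,
                 roughness_amp_mm = roughness_amp_mm,
                 roughness_waves = as.integer(roughness_waves),
                 base_fraction = base_fraction, bumps = bumps,
                 patches = patches, flip_rate = flip_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic label map with ground truth
#'
#' Draws each in-blob pixel tumor glands vs tumor-associated stroma from
#' the local planted stroma fraction, stamps nuisance patches, and sets
#' everything outside the blob to background. The returned ground truth
#' carries the analytic fraction field, its disc-smoothed version for the
#' 2.0 mm field of view (computed by direct spatial convolution — the
#' generator's own oracle, independent of the FFT heatmap path), and the
#' location/value of the smoothed optimum restricted to centres whose disc
#' lies fully inside the blob.
#'
#' @param spec a [synthetic_spec()].
#' @param scheme a [tissue_scheme()] (default classes).
#' @param fov_diameter_mm field of view used for the ground-truth optimum.
#' @return list with `map` (a [label_map()]) and `truth` (list:
#'   `fraction_field`, `smoothed`, `argmax` 0-based (row, col),
#'   `max_percent`, `blob_mask`).
#' @export
generate_labelmap <- function(spec, scheme = tissue_scheme(),
                              fov_diameter_mm = 2.0) {
  set.seed(spec$seed)
  n <- spec$dim_px
  sp <- spacing_um <- spec$spacing_um
  code <- function(nm) scheme$entries$code[scheme$entries$name == nm]

  rr <- matrix(0:(n - 1L), n, n)
  cc <- matrix(0:(n - 1L), n, n, byrow = TRUE)
  dr <- rr - spec$blob_center[1]
  dc <- cc - spec$blob_center[2]
  dist <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  radius_px <- (spec$blob_radius_mm +
                  spec$roughness_amp_mm * sin(spec$roughness_waves * theta)) *
    1000 / sp
  blob <- dist <= radius_px

  frac <- matrix(spec$base_fraction, n, n)
  for (b in spec$bumps) {
    d2 <- (rr - b$center[1])^2 + (cc - b$center[2])^2
    sig <- b$sigma_mm * 1000 / sp
    frac <- frac + b$amplitude * exp(-d2 / (2 * sig^2))
  }
  frac <- pmin(pmax(frac, 0), 1)   # pmax(0, m) would drop the dim attribute

  grid <- matrix(code("background"), n, n)
  draw <- matrix(stats::runif(n * n), n, n) < frac
  grid[blob] <- ifelse(draw[blob], code("tumor-associated stroma"),
                       code("tumor glands"))
  for (p in spec$patches) {
    pd <- (rr - p$center[1])^2 + (cc - p$center[2])^2 <= p$radius_px^2
    grid[pd] <- code(p$class)
  }
  if (spec$flip_rate > 0) {
    flip <- blob & matrix(stats::runif(n * n), n, n) < spec$flip_rate
    pool <- scheme$entries$code[scheme$entries$name != "background"]
    grid[flip] <- sample(pool, sum(flip), replace = TRUE)
  }

  # ground truth: disc-smoothed planted fraction, direct convolution
  r_fov <- fov_radius_px(fov_diameter_mm, sp)
  smoothed <- disc_mean_direct(frac, r_fov)
  inside <- disc_counts_direct(!blob, r_fov) == 0
  nr_idx <- c(seq_len(min(r_fov, n)), n + 1L - seq_len(min(r_fov, n)))
  inside[nr_idx, ] <- FALSE; inside[, nr_idx] <- FALSE
  sm <- smoothed; sm[!inside] <- NA_real_
  best <- which(sm == max(sm, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]

  list(map = label_map(grid, spacing_um = sp, scheme = scheme),
       truth = list(fraction_field = frac, smoothed = smoothed,
                    argmax = c(best[[1]], best[[2]]) - 1L,
                    max_percent = 100 * sm[best[[1]], best[[2]]],
                    blob_mask = blob))
}

#' Generate a synthetic observer score table
#'
#' Each rater's score is `clamp(round-to-10(true + bias + noise))`; the
#' consensus column is filled by the majority rule, flagging all-distinct
#' cases as needing a meeting.
#'
#' @param true_percents numeric vector of true per-case stroma percentages
#'   in \[0, 100\].
#' @param n_raters number of raters (default 3).
#' @param bias per-rater systematic offsets (recycled; default 0).
#' @param sd per-rater Gaussian noise standard deviation, in percentage
#'   points (default 5).
#' @param seed RNG seed.
#' @return an [observer_table()] with consensus and dichotomy columns.
#' @export
generate_observer_table <- function(true_percents, n_raters = 3L,
                                    bias = 0, sd = 5, seed = 1L) {
  if (any(true_percents < 0 | true_percents > 100))
    tsr_stop("tsr_input_error", "true percentages must lie in [0, 100]")
  set.seed(seed)
  n <- length(true_percents)
  bias <- rep_len(bias, n_raters)
  sd <- rep_len(sd, n_raters)
  df <- data.frame(case_id = sprintf("case%03d", seq_len(n)))
  for (j in seq_len(n_raters)) {
    raw <- true_percents + bias[j] + stats::rnorm(n, 0, sd[j])
    df[[sprintf("rater%d", j)]] <-
      as.integer(pmin(100, pmax(0, 10 * round_half_up(raw / 10))))
  }
  add_consensus(observer_table(df))
}
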