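# heatmap tests run at 50 um/pixel (FOV radius 20 px) unless stated

all_centers <- function(n, r) {
  v <- matrix(FALSE, n, n)
  v[(r + 1):(n - r), (r + 1):(n - r)] <- TRUE
  v
}

test_that("a uniform stroma map scores 100% at every valid centre", {
  n <- 96; sp <- 50; r <- fov_radius_px(2.0, sp)
  m <- uniform_map("tumor-associated stroma", n = n, spacing = sp)
  hm <- tsr_heatmap(m, all_centers(n, r), scheme0, circular_roi(0, 0, 2.0))
  expect_true(all(hm$values[hm$valid_mask] == 100))
  expect_true(all(is.na(hm$values[!hm$valid_mask])))
})

test_that("a planted 70% disc reads 70.0 at its centre", {
  n <- 96; sp <- 50; r <- fov_radius_px(2.0, sp)
  idx <- circle_pixels(n, n, 48, 48, r)
  k <- length(idx)
  n_stroma <- round(0.7 * k)
  m <- composed_circle_map(c("tumor-associated stroma" = n_stroma),
                           fill = "tumor glands", n = n, spacing = sp,
                           center = c(48, 48), r = r,
                           outside = "tumor glands")
  hm <- tsr_heatmap(m, all_centers(n, r), scheme0, circular_roi(0, 0, 2.0))
  expect_equal(hm$values[49, 49], 100 * n_stroma / k)
})

test_that("FFT heatmap equals direct sliding-window counting everywhere", {
  for (seed in c(4, 17)) {
    n <- 128; sp <- 50; r <- fov_radius_px(2.0, sp)
    m <- random_map(n, spacing = sp, seed = seed)
    grid <- unclass(m)
    centers <- all_centers(n, r)
    hm <- tsr_heatmap(m, centers, scheme0, circular_roi(0, 0, 2.0))
    s_ind <- matrix(grid %in% scheme_codes(scheme0, "stroma_full"), n, n)
    t_ind <- matrix(grid %in% scheme_codes(scheme0, "tumor_full"), n, n)
    s <- disc_counts_direct(s_ind, r)
    t <- disc_counts_direct(t_ind, r)
    ref <- matrix(NA_real_, n, n)
    ok <- centers & (s + t) > 0
    ref[ok] <- 100 * s[ok] / (s[ok] + t[ok])
    expect_equal(hm$values, ref)
  }
})

test_that("tissue-composition validity rules are strict at the boundary", {
  n <- 96; sp <- 50; r <- fov_radius_px(2.0, sp)
  idx <- circle_pixels(n, n, 48, 48, r)
  A <- length(idx)
  centers <- matrix(FALSE, n, n); centers[49, 49] <- TRUE
  run_with <- function(counts) {
    m <- composed_circle_map(counts, fill = "tumor-associated stroma",
                             n = n, spacing = sp, center = c(48, 48), r = r,
                             outside = "tumor glands")
    hm <- tsr_heatmap(m, centers, scheme0, circular_roi(0, 0, 2.0))
    hm <- apply_validity_rules(hm, m, scheme0)
    hm$valid_mask[49, 49]
  }
  frac_count <- function(f) as.integer(round(f * A))
  # ~4% fat kept, ~6% fat excluded
  expect_true(run_with(c("fatty tissue" = frac_count(0.04))))
  expect_false(run_with(c("fatty tissue" = frac_count(0.06))))
  # ~9% erythrocytes kept, ~11% excluded
  expect_true(run_with(c("erythrocytes" = frac_count(0.09))))
  expect_false(run_with(c("erythrocytes" = frac_count(0.11))))
  # ~29% necrosis kept, ~31% excluded
  expect_true(run_with(c("necrosis" = frac_count(0.29))))
  expect_false(run_with(c("necrosis" = frac_count(0.31))))
  # a field below every threshold at once stays valid
  expect_true(run_with(c("erythrocytes" = frac_count(0.09),
                         "necrosis" = frac_count(0.29),
                         "fatty tissue" = frac_count(0.04))))
  # a field exactly AT a threshold is invalid (strict <)
  k <- 50L
  m <- composed_circle_map(c("necrosis" = k),
                           fill = "tumor-associated stroma",
                           n = n, spacing = sp, center = c(48, 48), r = r,
                           outside = "tumor glands")
  hm <- tsr_heatmap(m, centers, scheme0, circular_roi(0, 0, 2.0))
  hm <- apply_validity_rules(hm, m, scheme0, thresholds = c(necrosis = k / A))
  expect_false(hm$valid_mask[49, 49])
})

test_that("top-k ranking selects and suppresses hot-spots correctly", {
  n <- 200; sp <- 50; r <- fov_radius_px(2.0, sp)
  base <- matrix(10, n, n)
  hm <- structure(list(values = base, valid_mask = matrix(TRUE, n, n),
                       fov = circular_roi(0, 0, 2.0), radius_px = r,
                       spacing_um = sp), class = "tsr_heatmap")
  # three well-separated planted maxima 90 > 80 > 70
  hm$values[40, 40] <- 90; hm$values[40, 160] <- 80; hm$values[160, 100] <- 70
  spots <- top_k_hotspots(hm, 3)
  expect_equal(spots$stroma_percent, c(90, 80, 70))
  expect_equal(spots$label, c("TSR-1", "TSR-2", "TSR-3"))
  expect_equal(spots$center_row, c(39, 39, 159))
  expect_equal(spots$center_col, c(39, 159, 99))

  # a second maximum within one FOV radius is suppressed
  hm2 <- hm
  hm2$values[40, 40] <- 90; hm2$values[45, 45] <- 85
  spots2 <- top_k_hotspots(hm2, 3)
  expect_equal(spots2$stroma_percent[1:2], c(90, 80))
  expect_false(any(spots2$center_row == 44 & spots2$center_col == 44))

  # constant heatmap: ties break towards the smallest (row, col)
  hm3 <- structure(list(values = matrix(55, 60, 60),
                        valid_mask = matrix(TRUE, 60, 60),
                        fov = circular_roi(0, 0, 2.0), radius_px = r,
                        spacing_um = sp), class = "tsr_heatmap")
  s3 <- top_k_hotspots(hm3, 1)
  expect_equal(c(s3$center_row, s3$center_col), c(0, 0))

  # suppression enforces pairwise centre distance > one FOV radius
  d <- function(s, i, j) sqrt((s$center_row[i] - s$center_row[j])^2 +
                              (s$center_col[i] - s$center_col[j])^2)
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(d(spots, i, j), r)

  # exhaustion: a small valid region yields fewer than k spots, no error
  hm4 <- hm3
  hm4$valid_mask[,] <- FALSE
  hm4$valid_mask[30, 30] <- TRUE
  expect_message(s4 <- top_k_hotspots(hm4, 3), "only 1 hot-spot")
  expect_equal(nrow(s4), 1)
})

test_that("ranked values are monotone and only rise without suppression", {
  set.seed(8)
  n <- 150; r <- 20
  vals <- matrix(runif(n * n, 0, 100), n, n)
  hm <- structure(list(values = vals, valid_mask = matrix(TRUE, n, n),
                       fov = circular_roi(0, 0, 2.0), radius_px = r,
                       spacing_um = 50), class = "tsr_heatmap")
  spots <- top_k_hotspots(hm, 3)
  expect_true(all(diff(spots$stroma_percent) <= 0))
  # without zeroing, rank j would simply be the j-th largest value, which
  # can only be larger or equal
  top_vals <- sort(vals, decreasing = TRUE)[1:3]
  expect_true(all(top_vals >= spots$stroma_percent))
})
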