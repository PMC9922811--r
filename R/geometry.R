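#' Round half away from zero
#'
#' Physical lengths are converted to integer pixel counts with round-half-up
#' semantics so that all modules agree on circle sizes (base `round()` uses
#' round-half-to-even).
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Field-of-view radius in pixels
#'
#' @param diameter_mm physical diameter of the circular field of view (mm).
#' @param spacing_um pixel size in micrometres per pixel.
#' @return integer radius in pixels (at least 1 enforced by callers).
#' @export
fov_radius_px <- function(diameter_mm, spacing_um) {
  as.integer(round_half_up(diameter_mm * 1000 / (2 * spacing_um)))
}

#' Binary disc kernel
#'
#' A (2r+1) x (2r+1) matrix that is 1 where the pixel centre lies within
#' Euclidean distance `radius_px` of the central pixel (inclusive). This
#' single rasterisation convention is used for the ROI, the heatmap kernel,
#' the tumor-bulk erosion and the hot-spot suppression region.
#'
#' @param radius_px integer radius in pixels.
#' @return 0/1 matrix of dimension `2*radius_px + 1` squared.
#' @export
disc_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  if (r < 1) tsr_stop("tsr_input_error", "disc radius must be >= 1 pixel")
  d <- seq(-r, r)
  dist2 <- outer(d^2, d^2, `+`)
  matrix(as.numeric(dist2 <= r^2), 2L * r + 1L, 2L * r + 1L)
}

# Pad to a size with small prime factors so the mixed-radix FFT stays fast.
good_fft_size <- function(n) stats::nextn(n, c(2L, 3L, 5L))

#' Sliding disc counts via FFT convolution
#'
#' For every pixel position treated as a circle centre, counts the number of
#' TRUE/1 cells of `indicator` whose centres fall within `radius_px` of it.
#' The count map is obtained by convolving the indicator grid with the binary
#' disc kernel in the Fourier domain, which makes sliding a 2 mm circle over
#' a whole slide tractable. Results are rounded back to exact integers and
#' cross-checked: a deviation from integrality larger than `tol_frac` of the
#' disc area raises a numerical-integrity error. Negative round-off
#' artifacts are clipped at zero.
#'
#' Boundary semantics: cells outside the grid count as 0, so centres near the
#' border see truncated discs (callers restrict attention to centres whose
#' disc lies inside the region of interest).
#'
#' @param indicator numeric/logical matrix (0/1).
#' @param radius_px disc radius in pixels.
#' @param tol_frac integrality tolerance as a fraction of the disc area.
#' @return integer-valued numeric matrix, same dimension as `indicator`.
#' @export
disc_counts <- function(indicator, radius_px, tol_frac = 1e-3) {
  x <- indicator * 1.0
  nr <- nrow(x); nc <- ncol(x)
  r <- as.integer(radius_px)
  k <- disc_kernel(r)
  disc_area <- sum(k)
  pr <- good_fft_size(nr + 2L * r)
  pc <- good_fft_size(nc + 2L * r)
  X <- matrix(0, pr, pc); X[seq_len(nr), seq_len(nc)] <- x
  K <- matrix(0, pr, pc); K[seq_len(2L * r + 1L), seq_len(2L * r + 1L)] <- k
  conv <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  # full convolution: centre (i,j) of the input aligns at offset r in the output
  out <- conv[r + seq_len(nr), r + seq_len(nc), drop = FALSE]
  dev <- max(abs(out - round(out)))
  if (dev > tol_frac * disc_area) {
    tsr_stop("tsr_numerical_error", sprintf(
      "FFT disc counts deviate from integers by %.3g (tolerance %.3g)",
      dev, tol_frac * disc_area))
  }
  pmax(round(out), 0)
}

#' Sliding disc counts by direct spatial summation
#'
#' Reference implementation of [disc_counts()] that accumulates shifted
#' copies of the indicator grid over every disc offset. Exact integer
#' arithmetic, no Fourier transform; used as the independent oracle for the
#' FFT path and by the synthetic generator to locate the planted optimum.
#'
#' The disc is decomposed into its row chords: at row offset `dr` the chord
#' spans columns `-w..w` with `w = floor(sqrt(r^2 - dr^2))`, and each chord
#' sum is read off a per-row prefix-sum table. All arithmetic is exact
#' (integer-valued doubles), no transform involved.
#'
#' @inheritParams disc_counts
#' @return integer-valued numeric matrix, same dimension as `indicator`.
#' @export
disc_counts_direct <- function(indicator, radius_px) {
  x <- indicator * 1.0
  nr <- nrow(x); nc <- ncol(x)
  r <- as.integer(radius_px)
  # prefix sums along each row, with a leading zero column
  pre <- cbind(0, t(apply(x, 1L, cumsum)))
  j <- seq_len(nc)
  out <- matrix(0, nr, nc)
  for (dr in seq(-r, r)) {
    w <- floor(sqrt(r * r - dr * dr))
    dst <- max(1L, 1L - dr):min(nr, nr - dr)
    hi <- pmin(j + w, nc) + 1L
    lo <- pmax(j - w - 1L, 0L) + 1L
    out[dst, ] <- out[dst, ] + pre[dst + dr, hi, drop = FALSE] -
      pre[dst + dr, lo, drop = FALSE]
  }
  out
}

# Smooth a real-valued field with the normalised disc kernel (direct
# spatial summation); used by the generator's ground-truth oracle.
disc_mean_direct <- function(field, radius_px) {
  disc_counts_direct(field, radius_px) / sum(disc_kernel(radius_px))
}
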