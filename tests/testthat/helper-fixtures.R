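# Shared fixtures and independent oracles for the test suite.

scheme0 <- tissue_scheme()
code_of <- function(nm) scheme0$entries$code[scheme0$entries$name == nm]

# per-pixel double-loop disc counting: the slowest, most literal oracle
naive_disc_counts <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rows <- max(1, i - r):min(nr, i + r)
    cols <- max(1, j - r):min(nc, j + r)
    d <- outer((rows - i)^2, (cols - j)^2, `+`) <= r^2
    out[i, j] <- sum(x[rows, cols][d])
  }
  out
}

# 0-based in-circle pixel index list for a map, mirroring the package's
# pixel-centre convention
circle_pixels <- function(nr, nc, center_row, center_col, r) {
  idx <- which(outer((seq_len(nr) - 1 - center_row)^2,
                     (seq_len(nc) - 1 - center_col)^2, `+`) <= r^2)
  idx
}

# uniform map of one class, default spacing chosen so a 2 mm ROI is small
uniform_map <- function(class_name, n = 64, spacing = 25) {
  label_map(matrix(code_of(class_name), n, n), spacing_um = spacing,
            scheme = scheme0)
}

# map with prescribed class composition inside a given circle: `counts` is
# a named vector class name -> pixel count; remaining in-circle pixels get
# `fill`; outside the circle everything is `outside`.
composed_circle_map <- function(counts, fill, n = 64, spacing = 25,
                                center = c(32, 32), r = NULL,
                                outside = "tumor glands") {
  if (is.null(r)) r <- fov_radius_px(2, spacing)
  grid <- matrix(code_of(outside), n, n)
  idx <- circle_pixels(n, n, center[1], center[2], r)
  stopifnot(sum(counts) <= length(idx))
  pos <- 1L
  for (nm in names(counts)) {
    k <- counts[[nm]]
    if (k > 0) grid[idx[pos:(pos + k - 1L)]] <- code_of(nm)
    pos <- pos + k
  }
  if (pos <= length(idx)) grid[idx[pos:length(idx)]] <- code_of(fill)
  label_map(grid, spacing_um = spacing, scheme = scheme0)
}

# random label map over the full class set
random_map <- function(n, spacing = 25, seed = 1) {
  set.seed(seed)
  label_map(matrix(sample(scheme0$entries$code, n * n, replace = TRUE), n, n),
            spacing_um = spacing, scheme = scheme0)
}
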