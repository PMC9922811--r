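#' Consensus percentage by majority vote
#'
#' When all raters, or a strict majority of them (2 of 3 in the study
#' design), give the same percentage, that percentage is the consensus.
#' Otherwise no consensus exists and the case must go to a consensus
#' meeting; this is signalled by returning `NA` (never auto-resolved).
#'
#' @param scores numeric vector of one case's rater percentages, on the
#'   10% grid.
#' @return the consensus percentage, or `NA` when a meeting is needed.
#' @export
consensus_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 3L)
    tsr_stop("tsr_input_error", "consensus needs at least 3 raters")
  tab <- table(scores)
  if (max(tab) * 2L > n) as.numeric(names(tab)[which.max(tab)]) else NA_real_
}

#' Dichotomize a stroma percentage
#'
#' Stroma-low when the percentage is at most the cut-off (default 50),
#' stroma-high above it. Stroma-high carries the worse prognosis.
#'
#' @param percent numeric vector in \[0, 100\].
#' @param cutoff the cut-off (default 50).
#' @return character vector, `"stroma-low"` or `"stroma-high"`.
#' @export
dichotomize <- function(percent, cutoff = 50) {
  if (any(!is.na(percent) & (percent < 0 | percent > 100)))
    tsr_stop("tsr_input_error", "percentages must lie in [0, 100]")
  ifelse(percent <= cutoff, "stroma-low", "stroma-high")
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` on categorical labels,
#' with expected agreement from the product of the marginal label
#' distributions. Used here unweighted on the binary stroma-low/high
#' labels.
#'
#' @param a,b label vectors of equal length (factors or characters).
#' @return list with `kappa`, `po` (observed agreement), `pe` (expected
#'   agreement), `n`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b))
    tsr_stop("tsr_input_error", "label vectors must have equal length")
  keep <- !is.na(a) & !is.na(b)
  a <- as.character(a)[keep]; b <- as.character(b)[keep]
  n <- length(a)
  if (n < 2L)
    tsr_stop("tsr_input_error", "kappa needs at least 2 cases")
  lev <- sort(union(a, b))
  tab <- table(factor(a, lev), factor(b, lev))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe == 0)
    tsr_stop("tsr_input_error",
             "kappa undefined: both raters are constant (expected agreement 1)")
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, n = n)
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random effects, absolute agreement, single measures — the
#' standard model when raters are a random sample of interchangeable
#' observers and the question is whether they give the *same* value, not
#' just the same ranking. From the two-way ANOVA mean squares (rows =
#' cases, columns = raters):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the confidence interval from the F-distribution bounds of this
#' model.
#'
#' @param mat numeric matrix, cases in rows, raters in columns; complete.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `icc`, `ci95` (length-2 vector), mean squares `msr`,
#'   `msc`, `mse`, `n`, `k`, and the `model` label.
#' @export
icc_agreement <- function(mat, conf_level = 0.95) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L || n < 5L)
    tsr_stop("tsr_input_error", "ICC needs >= 2 raters and >= 5 cases")
  if (anyNA(mat))
    tsr_stop("tsr_input_error", "ICC needs a complete case x rater matrix")
  gm <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ss_total <- sum((mat - gm)^2)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total == 0)
    tsr_stop("tsr_input_error", "ICC undefined: zero total variance")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based interval (Satterthwaite df for the between-rater term)
  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci95 = c(lower, upper), msr = msr, msc = msc, mse = mse,
       n = n, k = k,
       model = "ICC(2,1): two-way random, absolute agreement, single measures")
}

#' Spearman rank correlation with tie-aware mid-ranks
#'
#' Pearson correlation of mid-ranks, which handles the heavy ties of
#' 10%-grid scores; the p-value uses the t approximation
#' `t = rho * sqrt((n-2) / (1 - rho^2))` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y))
    tsr_stop("tsr_input_error", "vectors must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    tsr_stop("tsr_input_error", "Spearman needs at least 3 cases")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    tsr_stop("tsr_input_error",
             "correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Bland-Altman limits of agreement
#'
#' Mean paired difference `x - y` with 95% limits of agreement at
#' mean +/- 1.96 standard deviations of the differences.
#'
#' @param x,y paired measurement vectors of equal length (at least 2).
#' @return list with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    tsr_stop("tsr_input_error", "vectors must have equal length")
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2L)
    tsr_stop("tsr_input_error", "Bland-Altman needs at least 2 pairs")
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_diff = s, n = n)
}

#' Bland-Altman plot
#'
#' @param x,y paired measurement vectors.
#' @param xlab,ylab,main usual graphics labels.
#' @return the [bland_altman()] list, invisibly.
#' @export
bland_altman_plot <- function(x, y, xlab = "Mean of methods",
                              ylab = "Difference (x - y)",
                              main = "Bland-Altman") {
  ba <- bland_altman(x, y)
  graphics::plot((x + y) / 2, x - y, pch = 19, xlab = xlab, ylab = ylab,
                 main = main)
  graphics::abline(h = c(ba$mean_diff, ba$loa_low, ba$loa_high),
                   lty = c(1, 2, 2))
  invisible(ba)
}

#' Paired / two-sample t-test on method differences
#'
#' Thin wrapper over [stats::t.test()] returning the statistic and p-value;
#' flags the degenerate all-identical paired case instead of erroring.
#'
#' @param x,y numeric vectors.
#' @param paired paired test (default TRUE, the method-comparison setting).
#' @return list with `t`, `p`, `df`, `n`, `degenerate` (TRUE when all
#'   paired differences are zero).
#' @export
t_test <- function(x, y, paired = TRUE) {
  if (length(x) < 2L || (!paired && length(y) < 2L))
    tsr_stop("tsr_input_error", "t-test needs at least 2 observations")
  if (paired && length(x) != length(y))
    tsr_stop("tsr_input_error", "paired t-test needs equal lengths")
  if (paired && all(x - y == 0))
    return(list(t = 0, p = 1, df = length(x) - 1L, n = length(x),
                degenerate = TRUE))
  tt <- stats::t.test(x, y, paired = paired)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(x), degenerate = FALSE)
}

#' Full agreement report between two measurement methods
#'
#' Bundles the study's comparison battery for two per-case score vectors
#' (e.g. visual consensus vs an automated method): Cohen's kappa on the
#' dichotomized labels, ICC(2,1) with 95% CI, tie-aware Spearman
#' correlation, Bland-Altman limits of agreement and a paired t-test.
#' Cases without a resolved consensus (NA) are dropped pairwise.
#'
#' @param x,y numeric percentage vectors of equal length.
#' @param labels length-2 character vector naming the methods.
#' @param cutoff dichotomization cut-off (default 50).
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(x, y, labels = c("method A", "method B"),
                             cutoff = 50) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5L)
    tsr_stop("tsr_input_error", "agreement report needs >= 5 complete cases")
  kap <- tryCatch(cohens_kappa(dichotomize(x, cutoff), dichotomize(y, cutoff)),
                  tsr_error = function(e) list(kappa = NA_real_))
  icc <- icc_agreement(cbind(x, y))
  sp <- spearman_cor(x, y)
  ba <- bland_altman(x, y)
  tt <- t_test(x, y, paired = TRUE)
  structure(list(labels = labels, n_cases = n, kappa = kap$kappa,
                 icc = icc$icc, icc_ci95 = icc$ci95, icc_model = icc$model,
                 spearman_rho = sp$rho, spearman_p = sp$p,
                 bland_altman = c(mean_diff = ba$mean_diff,
                                  loa_low = ba$loa_low,
                                  loa_high = ba$loa_high),
                 t = tt$t, t_p = tt$p, cutoff = cutoff),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement: %s vs %s (n = %d)\n",
              x$labels[1], x$labels[2], x$n_cases))
  cat(sprintf("  Cohen's kappa (low/high at %g%%): %.*f\n",
              x$cutoff, digits, x$kappa))
  cat(sprintf("  %s\n", x$icc_model))
  cat(sprintf("  ICC = %.*f (95%% CI %.*f to %.*f)\n", digits, x$icc,
              digits, x$icc_ci95[1], digits, x$icc_ci95[2]))
  cat(sprintf("  Spearman rho = %.*f (p = %.3g)\n", digits,
              x$spearman_rho, x$spearman_p))
  cat(sprintf("  Bland-Altman: mean diff %.*f (LoA %.*f to %.*f)\n",
              digits, x$bland_altman[["mean_diff"]],
              digits, x$bland_altman[["loa_low"]],
              digits, x$bland_altman[["loa_high"]]))
  cat(sprintf("  Paired t = %.*f (p = %.3g)\n", digits, x$t, x$t_p))
  invisible(x)
}
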