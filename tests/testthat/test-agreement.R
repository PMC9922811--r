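test_that("consensus follows the 2-of-3 majority rule", {
  expect_equal(consensus_score(c(60, 60, 70)), 60)
  expect_equal(consensus_score(c(30, 30, 30)), 30)
  expect_true(is.na(consensus_score(c(40, 50, 60))))  # consensus meeting
  expect_error(consensus_score(c(40, 50)), class = "tsr_input_error")
})

test_that("dichotomization puts the cut-off itself in stroma-low", {
  expect_equal(dichotomize(50), "stroma-low")
  expect_equal(dichotomize(60), "stroma-high")
  expect_equal(dichotomize(0), "stroma-low")
  expect_error(dichotomize(120), class = "tsr_input_error")
})

test_that("Cohen's kappa matches the closed form and a reference", {
  a <- rep(c("low", "high"), c(5, 5))
  expect_equal(cohens_kappa(a, a)$kappa, 1)

  # 2x2 table a=20 b=5 / c=10 d=40 on n=75:
  # po = 60/75, pe = (25*30 + 50*45)/75^2, kappa = 4/7
  x <- rep(c("low", "low", "high", "high"), c(20, 5, 10, 40))
  y <- rep(c("low", "high", "low", "high"), c(20, 5, 10, 40))
  k <- cohens_kappa(x, y)
  expect_equal(k$po, 60 / 75)
  expect_equal(k$pe, (25 * 30 + 50 * 45) / 75^2)
  expect_equal(k$kappa, 4 / 7, tolerance = 1e-12)
  ref <- e1071::classAgreement(table(x, y))$kappa
  expect_equal(k$kappa, ref, tolerance = 1e-12)

  expect_error(cohens_kappa(rep("low", 8), rep("low", 8)),
               class = "tsr_input_error")
})

test_that("kappa of independent labels is near zero for large n", {
  set.seed(99)
  a <- sample(c("low", "high"), 20000, replace = TRUE)
  b <- sample(c("low", "high"), 20000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)$kappa), 0.03)
})

test_that("ICC(2,1) matches an independent ANOVA computation", {
  mat <- matrix(c(9, 2, 5, 8,
                  6, 1, 3, 2,
                  8, 4, 6, 8,
                  7, 1, 2, 6,
                  10, 5, 6, 9,
                  6, 2, 4, 7), nrow = 6, byrow = TRUE)
  res <- icc_agreement(mat)

  # oracle: mean squares from aov on the long layout
  long <- data.frame(y = as.vector(mat),
                     case = factor(rep(seq_len(6), 4)),
                     rater = factor(rep(seq_len(4), each = 6)))
  ms <- anova(stats::aov(y ~ case + rater, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 4
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(res$msr, msr, tolerance = 1e-10)
  expect_equal(res$msc, msc, tolerance = 1e-10)
  expect_equal(res$mse, mse, tolerance = 1e-10)
  # this is the classic Shrout-Fleiss ICC(2,1) example; point estimate 0.29
  expect_equal(round(res$icc, 2), 0.29)
  expect_true(res$ci95[1] <= res$icc && res$icc <= res$ci95[2])
  expect_match(res$model, "two-way random, absolute agreement, single")
})

test_that("identical raters with case variance give ICC of 1", {
  mat <- cbind(c(10, 30, 50, 70, 90, 20), c(10, 30, 50, 70, 90, 20))
  expect_equal(icc_agreement(mat)$icc, 1)
  expect_error(icc_agreement(matrix(5, 6, 3)), class = "tsr_input_error")
})

test_that("ICC of shuffled noise is near zero", {
  set.seed(123)
  x <- rnorm(200)
  mat <- cbind(x, sample(x))
  expect_lt(abs(icc_agreement(mat)$icc), 0.15)
})

test_that("Spearman uses tie-aware mid-ranks and the t approximation", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)       # monotone transform
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  # heavy ties on the 10% grid
  set.seed(7)
  a <- sample(seq(0, 100, 10), 40, replace = TRUE)
  b <- pmin(100, pmax(0, a + sample(c(-10, 0, 10), 40, replace = TRUE)))
  res <- spearman_cor(a, b)
  rho_oracle <- stats::cor(rank(a), rank(b))          # rank-then-Pearson
  expect_equal(res$rho, rho_oracle, tolerance = 1e-12)
  expect_equal(res$rho, unname(stats::cor.test(a, b, method = "spearman",
                                               exact = FALSE)$estimate),
               tolerance = 1e-12)
  t_or <- rho_oracle * sqrt((40 - 2) / (1 - rho_oracle^2))
  expect_equal(res$p, 2 * stats::pt(-abs(t_or), 38), tolerance = 1e-12)
  expect_error(spearman_cor(rep(5, 10), 1:10), class = "tsr_input_error")
})

test_that("Bland-Altman and t-test follow the textbook formulas", {
  x <- c(10, 20, 30, 40)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$mean_diff, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  ba1 <- bland_altman(x + 7, x)
  expect_equal(ba1$mean_diff, 7)
  expect_equal(ba1$loa_high - ba1$loa_low, 0)

  set.seed(55)
  a <- rnorm(30, 50, 10); b <- a + rnorm(30, 2, 4)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)

  tt <- t_test(a, b, paired = TRUE)
  t_or <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(tt$t, t_or, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-abs(t_or), 29), tolerance = 1e-12)
  expect_true(t_test(x, x, paired = TRUE)$degenerate)
})

test_that("agreement statistics are invariant where they should be", {
  set.seed(77)
  x <- sample(seq(0, 100, 10), 30, replace = TRUE)
  y <- pmin(100, pmax(0, x + sample(c(-20, -10, 0, 10, 20), 30, TRUE)))
  # Spearman: strictly monotone transform of either variable
  expect_equal(spearman_cor(x, y)$rho,
               spearman_cor(x^3, 2 * y + 1)$rho, tolerance = 1e-12)
  # kappa: relabeling that preserves the agreement table
  la <- dichotomize(x); lb <- dichotomize(y)
  swap <- function(v) ifelse(v == "stroma-low", "A", "B")
  expect_equal(cohens_kappa(la, lb)$kappa,
               cohens_kappa(swap(la), swap(lb))$kappa, tolerance = 1e-12)
})

test_that("the combined agreement report is internally consistent", {
  set.seed(101)
  x <- sample(seq(10, 90, 10), 40, replace = TRUE)
  y <- pmin(100, pmax(0, x + sample(c(-10, 0, 0, 10), 40, TRUE)))
  rep <- agreement_report(x, y, labels = c("visual", "semi"))
  expect_equal(rep$n_cases, 40)
  expect_true(rep$icc_ci95[1] <= rep$icc && rep$icc <= rep$icc_ci95[2])
  expect_true(rep$bland_altman[["loa_low"]] <= rep$bland_altman[["mean_diff"]])
  expect_equal(rep$kappa,
               cohens_kappa(dichotomize(x), dichotomize(y))$kappa)
  expect_output(print(rep), "ICC")
})
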