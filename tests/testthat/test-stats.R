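test_that("t tests match hand formulas and Bonferroni scaling", {
  ## identical paired samples: no difference, p = 1
  r0 <- tTestBonferroni(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
  ## identical unpaired samples: t = 0
  expect_equal(tTestBonferroni(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  ## pooled-variance hand oracle: means 2.5 vs 4.5, pooled var 5/3
  r <- tTestBonferroni(c(1, 2, 3, 4), c(3, 4, 5, 6), mComparisons = 3)
  expect_equal(r$statistic, -2.1909, tolerance = 1e-4)
  expect_equal(r$df, 6)
  expect_equal(r$p_adjusted, min(1, 3 * r$p_raw))
  ## swapping groups flips the sign, p unchanged
  rs <- tTestBonferroni(c(3, 4, 5, 6), c(1, 2, 3, 4))
  expect_equal(rs$statistic, -r$statistic)
  expect_equal(rs$p_raw, r$p_raw)
  ## Welch variant reports non-integer df in unbalanced heteroscedastic data
  rw <- tTestBonferroni(c(1, 2, 3, 4), c(10, 30, 50), pooled = FALSE)
  expect_match(rw$test_name, "Welch")
  expect_error(tTestBonferroni(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(tTestBonferroni(1:3, 1:4, paired = TRUE), "equal length")
})

test_that("Pearson correlation: exact cases and affine invariance", {
  expect_equal(pearsonCorr(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearsonCorr(c(0, 1, 2), c(0, 1, 0))$r, 0)
  withr::with_seed(3, { x <- rnorm(30); y <- x + rnorm(30) })
  r1 <- pearsonCorr(x, y)
  r2 <- pearsonCorr(5 * x + 2, 0.1 * y - 7)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  expect_error(pearsonCorr(rep(1, 5), 1:5), "constant")
  expect_error(pearsonCorr(1:2, 1:2), "at least 3")
})

test_that("Spearman correlation is Pearson on ranks", {
  expect_equal(spearmanCorr(1:8, exp(1:8))$rho, 1)
  expect_equal(spearmanCorr(1:8, -(1:8))$rho, -1)
  expect_equal(spearmanCorr(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
})

test_that("Cohen's kappa: hand formula, symmetry, chance level", {
  a <- rep(c(TRUE, FALSE), c(23, 7))
  expect_equal(cohenKappa(a, a)$kappa, 1)
  ## 2x2 table [[22,1],[1,6]]: po = 28/30, pe = 578/900
  b <- a; b[23] <- FALSE; b[24] <- TRUE
  k <- cohenKappa(a, b)
  expect_equal(k$kappa, 0.8136, tolerance = 1e-4)
  expect_equal(k$p_o, 28 / 30)
  expect_equal(k$p_e, 578 / 900)
  expect_true(k$ci[1] < k$kappa && k$kappa < k$ci[2])
  ## kappa of the transposed table: swap raters
  expect_equal(cohenKappa(b, a)$kappa, k$kappa)
  ## cross-check the point estimate against an independent implementation
  tab <- table(a, b)
  expect_equal(k$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  ## independent raters are near chance agreement
  withr::with_seed(11, {
    ks <- replicate(200, {
      x <- runif(60) < 0.77; y <- runif(60) < 0.77
      cohenKappa(x, y)$kappa
    })
  })
  expect_lt(abs(mean(ks)), 0.05)
  ## degenerate: both raters constant and identical
  expect_error(cohenKappa(rep(TRUE, 5), rep(TRUE, 5)), "undefined")
})

test_that("delta ESV is the relative ESV reduction in percent", {
  expect_equal(deltaESV(100, 100), 0)
  expect_equal(deltaESV(100, 50), 50)
  expect_equal(deltaESV(80, 100), -25)
  expect_error(deltaESV(0, 10), "positive")
})

test_that("summaries switch between mean/SD and median/IQR by normality", {
  s <- summarizeSample(c(1, 2, 3))
  expect_true(s$normal)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  sc <- summarizeSample(rep(4, 10))
  expect_true(sc$normal)
  expect_equal(sc$sd, 0)
  withr::with_seed(5, x <- rexp(200))
  sk <- summarizeSample(x)
  expect_false(sk$normal)                       # Shapiro-Wilk rejects
  expect_lt(sk$normality_p, 0.05)
  expect_equal(sk$median, median(x))
  expect_equal(sk$iqr, unname(diff(quantile(x, c(0.25, 0.75)))))
  ## matches the standard implementation directly
  expect_equal(sk$normality_p, shapiro.test(x)$p.value)
})

test_that("2x2 contingency utility picks Fisher for sparse tables", {
  sparse <- matrix(c(2, 1, 1, 6), 2)
  expect_equal(contingencyTest(sparse)$method, "fisher")
  dense <- matrix(c(20, 15, 18, 22), 2)
  expect_equal(contingencyTest(dense)$method, "chi-square")
  expect_error(contingencyTest(matrix(1:9, 3)), "2x2")
})
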