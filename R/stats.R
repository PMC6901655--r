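#' Student t test with Bonferroni correction
#'
#' Two-tailed paired or unpaired t test. Unpaired tests use the pooled
#' (Student) variance by default, with Welch available. The adjusted p
#' value is `min(1, m * p)` for a declared family of `m` comparisons.
#'
#' @param a,b numeric samples; equal lengths when `paired`.
#' @param paired logical.
#' @param mComparisons Bonferroni family size `m` (default 1).
#' @param pooled logical; pooled-variance Student test when `TRUE`
#'   (default), Welch otherwise. Ignored for paired tests.
#' @return list with `statistic`, `df`, `p_raw`, `p_adjusted`,
#'   `test_name`, `paired`, `m`.
#' @examples
#' tTestBonferroni(c(1, 2, 3, 4), c(3, 4, 5, 6), mComparisons = 2)
#' @export
tTestBonferroni <- function(a, b, paired = FALSE, mComparisons = 1,
                            pooled = TRUE) {
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length")
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per sample")
  if (paired) {
    if (sd(a - b) == 0 && all(a == b)) {
      ## degenerate identical pairs: no variability, no difference
      return(list(statistic = 0, df = length(a) - 1, p_raw = 1,
                  p_adjusted = 1, test_name = "paired t",
                  paired = TRUE, m = mComparisons))
    }
    if (sd(a - b) == 0)
      stop("paired differences have zero variance")
    tt <- t.test(a, b, paired = TRUE)
  } else {
    if (sd(a) == 0 && sd(b) == 0)
      stop("both samples have zero variance")
    tt <- t.test(a, b, var.equal = pooled)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value,
       p_adjusted = min(1, mComparisons * tt$p.value),
       test_name = if (paired) "paired t" else
         if (pooled) "unpaired t (pooled)" else "unpaired t (Welch)",
       paired = paired, m = mComparisons)
}

.checkCorInput <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: correlation undefined")
}

#' Pearson correlation with two-tailed p value
#'
#' @param x,y numeric samples of equal length `>= 3` with non-zero
#'   variance.
#' @return list with `r`, `p`, `n`, `method`.
#' @examples
#' pearsonCorr(1:10, 2 * (1:10) + 1)$r
#' @export
pearsonCorr <- function(x, y) {
  .checkCorInput(x, y)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = "pearson")
}

#' Spearman rank correlation with two-tailed p value
#'
#' Pearson correlation of the (average-tie) ranks.
#'
#' @inheritParams pearsonCorr
#' @return list with `rho`, `p`, `n`, `method`.
#' @examples
#' spearmanCorr(1:5, exp(1:5))$rho  # monotone transform: 1
#' @export
spearmanCorr <- function(x, y) {
  .checkCorInput(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = "spearman")
}

#' Cohen's kappa for two binary raters
#'
#' Unweighted kappa from the 2x2 agreement table, with the asymptotic
#' standard error of Fleiss, Cohen and Everitt and a normal-quantile
#' confidence interval.
#'
#' @param labelsA,labelsB logical (or coercible) label vectors of equal
#'   length.
#' @param conf confidence level, default 0.95.
#' @return list with `kappa`, `se`, `ci` (length 2), `p_o`, `p_e`, `n`.
#' @examples
#' a <- rep(c(TRUE, FALSE), c(23, 7))
#' b <- a; b[c(3, 28)] <- !b[c(3, 28)]
#' cohenKappa(a, b)$kappa
#' @export
cohenKappa <- function(labelsA, labelsB, conf = 0.95) {
  a <- as.logical(labelsA); b <- as.logical(labelsB)
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 rated subjects")
  tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
  p <- tab / n
  po <- sum(diag(p))
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (1 - pe < 1e-12)
    stop("kappa undefined: both raters are constant and identical")
  kappa <- (po - pe) / (1 - pe)
  ## Fleiss-Cohen-Everitt large-sample variance
  A <- sum(diag(p) * ((1 - pe) - (rowm + colm) * (1 - po))^2)
  B <- 0
  for (i in 1:2) for (j in 1:2) if (i != j)
    B <- B + (1 - po)^2 * p[i, j] * (colm[i] + rowm[j])^2
  C <- (po * pe - 2 * pe + po)^2
  se <- sqrt((A + B - C) / (n * (1 - pe)^4))
  z <- qnorm(1 - (1 - conf) / 2)
  list(kappa = kappa, se = se,
       ci = c(max(-1, kappa - z * se), min(1, kappa + z * se)),
       p_o = po, p_e = pe, n = n)
}

#' Relative change in LV end-systolic volume
#'
#' Volumetric reverse remodeling after CRT:
#' `100 * (esvPre - esvPost) / esvPre` (%), positive for a volume
#' reduction.
#'
#' @param esvPre,esvPost end-systolic volumes (ml); `esvPre` must be
#'   positive.
#' @return ΔLV ESV in percent.
#' @examples
#' deltaESV(100, 50)  # 50%
#' @export
deltaESV <- function(esvPre, esvPost) {
  if (any(esvPre <= 0)) stop("esvPre must be positive")
  100 * (esvPre - esvPost) / esvPre
}

#' Summarize a sample by its normality
#'
#' Shapiro-Wilk test at `alphaNormality`; normally distributed samples
#' are summarized as mean ± SD, others as median and interquartile
#' range. Constant samples are reported as mean ± 0 (the normal branch;
#' Shapiro-Wilk is undefined for them).
#'
#' @param x numeric sample, `n >= 3`.
#' @param alphaNormality significance level of the normality test.
#' @return list with `n`, `normal` (logical), `normality_p`, and either
#'   `mean`/`sd` or `median`/`iqr` (the other pair is `NA`).
#' @examples
#' summarizeSample(c(1, 2, 3))
#' @export
summarizeSample <- function(x, alphaNormality = 0.05) {
  if (length(x) < 3) stop("need at least 3 observations to summarize")
  if (sd(x) == 0) {
    return(list(n = length(x), normal = TRUE, normality_p = NA_real_,
                mean = mean(x), sd = 0,
                median = NA_real_, iqr = NA_real_))
  }
  swp <- shapiro.test(x)$p.value
  if (swp >= alphaNormality) {
    list(n = length(x), normal = TRUE, normality_p = swp,
         mean = mean(x), sd = sd(x), median = NA_real_, iqr = NA_real_)
  } else {
    q <- unname(quantile(x, c(0.25, 0.75)))
    list(n = length(x), normal = FALSE, normality_p = swp,
         mean = NA_real_, sd = NA_real_, median = median(x),
         iqr = q[2] - q[1])
  }
}

#' Generic 2x2 contingency test
#'
#' Chi-square test with Fisher's exact test when any expected cell count
#' falls below 5 (the usual small-sample rule).
#'
#' @param tab a 2x2 table or matrix of counts.
#' @return list with `p`, `method`.
#' @export
contingencyTest <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp < 5)) {
    list(p = fisher.test(tab)$p.value, method = "fisher")
  } else {
    list(p = chisq.test(tab, correct = FALSE)$p.value,
         method = "chi-square")
  }
}
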