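AIF <- makeInputFunction(seq(0, 1800, by = 0.5))
SCHED <- defaultFrameSchedule()

test_that("default frame schedule matches the 22-frame rebinning", {
  expect_equal(nrow(SCHED), 22)
  expect_equal(max(SCHED$frame_end_s), 1800)
  dur <- SCHED$frame_end_s - SCHED$frame_start_s
  expect_equal(dur, c(rep(10, 12), rep(30, 4), rep(120, 3), 180, 420, 600))
  expect_equal(sum(SCHED$frame_end_s <= 600), 19)
})

test_that("forward model: no uptake means pure spillover, and superposition holds", {
  t <- AIF@times
  ca <- metaboliteCorrect(AIF)$arterial
  m0 <- modelTac(list(K1 = 0, k2 = 0.25, k3 = 0.12, spill = 0.3),
                 t, ca, wholeBlood = AIF@wholeBlood)
  expect_true(all(m0$tissue == 0))
  expect_equal(m0$measured, 0.3 * AIF@wholeBlood)
  ## doubling the arterial input doubles the tissue curve
  p <- list(K1 = 0.6, k2 = 0.25, k3 = 0.12, spill = 0)
  m1 <- modelTac(p, t, ca)
  m2 <- modelTac(p, t, 2 * ca)
  expect_equal(m2$tissue, 2 * m1$tissue, tolerance = 1e-12)
  ## full spillover limit: measured curve is the whole-blood curve
  mS <- modelTac(list(K1 = 0.5, k2 = 0.25, k3 = 0.12, spill = 1),
                 t, ca, wholeBlood = AIF@wholeBlood,
                 frameStart = SCHED$frame_start_s,
                 frameEnd = SCHED$frame_end_s)
  W <- dyssyncPET:::.frameAvgMatrix(t, SCHED$frame_start_s,
                                    SCHED$frame_end_s)
  expect_equal(mS$frames$value, as.numeric(W %*% AIF@wholeBlood),
               tolerance = 1e-12)
})

test_that("narrow-pulse response approaches the trapping limit K1*k3/(k2+k3)", {
  dt <- 0.5
  t <- seq(0, 3600, by = dt)
  ca <- numeric(length(t))
  ca[t <= 1] <- 1  # narrow pulse; area from the trapezoid rule below
  area <- sum(dt * (ca[-1] + ca[-length(ca)]) / 2)
  m <- modelTac(list(K1 = 0.6, k2 = 0.2, k3 = 0.1, spill = 0), t, ca)
  limit <- area * 0.6 * 0.1 / (0.2 + 0.1)
  expect_equal(m$tissue[length(t)], limit, tolerance = 0.01)
  ## independent O(n^2) convolution oracle on a shorter window
  t2 <- seq(0, 600, by = dt)
  aif2 <- makeInputFunction(t2)
  ca2 <- metaboliteCorrect(aif2)$arterial
  m2 <- modelTac(list(K1 = 0.6, k2 = 0.25, k3 = 0.12, spill = 0), t2, ca2)
  oracle <- directTissueConv(0.6, 0.25, 0.12, t2, ca2)
  expect_equal(m2$tissue, oracle, tolerance = 1e-4)
})

test_that("k2 + k3 = 0 uses the analytic accumulation limit", {
  t <- seq(0, 600, by = 0.5)
  ca <- rep(1, length(t))
  m <- modelTac(list(K1 = 0.5, k2 = 0, k3 = 0, spill = 0), t, ca)
  expect_equal(m$tissue, 0.5 * t, tolerance = 1e-9)
})

test_that("noiseless synthetic TAC round-trips through the WLS fit to 1e-3", {
  x <- makeNoiselessTac(K1 = 0.6, k2 = 0.25, k3 = 0.12, spill = 0.3,
                        aif = AIF)
  f <- fitRegion(x$tac, x$aif)
  expect_true(f@converged)
  expect_equal(f@nFramesUsed, 19L)
  expect_equal(f@params@K1, 0.6, tolerance = 1e-3)
  expect_equal(f@params@k2, 0.25, tolerance = 1e-3)
  expect_equal(f@params@k3, 0.12, tolerance = 1e-3)
  expect_equal(f@params@spill, 0.3, tolerance = 1e-3)
  expect_equal(mbf(f), f@params@K1)
})

test_that("blood-only and all-zero TACs fit to zero flow", {
  W <- dyssyncPET:::.frameAvgMatrix(AIF@times, SCHED$frame_start_s,
                                    SCHED$frame_end_s)
  bloodTac <- new("TimeActivityCurve",
                  frameStart = SCHED$frame_start_s,
                  frameEnd = SCHED$frame_end_s,
                  values = 0.4 * as.numeric(W %*% AIF@wholeBlood),
                  region = "septal")
  f <- fitRegion(bloodTac, AIF)
  expect_lt(f@params@K1, 1e-3)
  zeroTac <- new("TimeActivityCurve",
                 frameStart = SCHED$frame_start_s,
                 frameEnd = SCHED$frame_end_s,
                 values = numeric(22), region = "septal")
  fz <- fitRegion(zeroTac, AIF)
  expect_true(fz@converged)
  expect_equal(fz@params@K1, 0, tolerance = 1e-6)
})

test_that("only frames ending within 10 min enter the fit", {
  x <- makeNoiselessTac(K1 = 0.7, k2 = 0.2, k3 = 0.1, spill = 0.25,
                        aif = AIF)
  f1 <- fitRegion(x$tac, x$aif)
  ## corrupt the late frames: the fit must not change
  v <- x$tac@values
  v[SCHED$frame_end_s > 600] <- v[SCHED$frame_end_s > 600] * 10
  tac2 <- new("TimeActivityCurve", frameStart = SCHED$frame_start_s,
              frameEnd = SCHED$frame_end_s, values = v, region = "septal")
  f2 <- fitRegion(tac2, x$aif)
  expect_identical(f1@params@K1, f2@params@K1)
  expect_identical(f1@weightedSSE, f2@weightedSSE)
})

test_that("fitted K1 is monotone in true K1 on noiseless data", {
  k1s <- c(0.3, 0.6, 0.9, 1.2)
  fitted <- vapply(k1s, function(k) {
    x <- makeNoiselessTac(K1 = k, aif = AIF)
    fitRegion(x$tac, x$aif)@params@K1
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
  expect_equal(fitted, k1s, tolerance = 1e-3)
})

test_that("WLS fit agrees with a brute-force grid search within grid resolution", {
  x <- makeNoiselessTac(K1 = 0.6, k2 = 0.25, k3 = 0.12, spill = 0.3,
                        aif = AIF)
  f <- fitRegion(x$tac, x$aif)
  g <- gridSearchFit(x$tac, x$aif, nGrid = 41)
  ## nonlinear axes agree within the refined grid resolution, the
  ## linearly-solved amplitude axes to 1e-3
  expect_lt(abs(f@params@k2 - g$par[["k2"]]), g$step[1] + 1e-9)
  expect_lt(abs(f@params@k3 - g$par[["k3"]]), g$step[2] + 1e-9)
  expect_lt(abs(f@params@K1 - g$par[["K1"]]), 1e-3)
  expect_lt(abs(f@params@spill - g$par[["spill"]]), 1e-3)
  ## the smooth optimum cannot be worse than the grid's best point
  expect_lte(f@weightedSSE, g$sse + 1e-9)
})

test_that("mean fitted K1 is within 5% of truth at the default noise level", {
  withr::with_seed(42, {
    fits <- replicate(200, {
      tl <- makeTacs(c(septal = 0.6), AIF,
                     kinetics = list(k2 = 0.25, k3 = 0.12,
                                     spill = c(septal = 0.35)),
                     noiseScale = 1)
      fitRegion(tl$septal, AIF)@params@K1
    })
    expect_equal(mean(fits), 0.6, tolerance = 0.05)
  })
})

test_that("MBF septal-to-lateral ratio behaves", {
  expect_equal(mbfSLR(0.8, 0.8), 1)
  expect_equal(mbfSLR(0.57, 0.92), 0.6196, tolerance = 1e-4)
  expect_error(mbfSLR(0.5, 0), "positive")
})
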