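EV <- c(mvc = 0.034, avo = 0.103, avc = 0.387, mvo = 0.447)
CYC <- 0.86

test_that("pressure template honors its landmarks", {
  p <- estimateLVPressure(134, EV, CYC)
  expect_equal(max(p$pressure_mmHg), 134)
  ## diastolic plateau before mitral valve closure
  expect_true(all(p$pressure_mmHg[p$time_s < EV["mvc"]] == 5))
  expect_true(all(p$pressure_mmHg[p$time_s > EV["mvo"]] == 5))
  ## midpoint of the isovolumic rise: half-cosine gives the landmark mean
  tm <- (EV[["mvc"]] + EV[["avo"]]) / 2
  pm <- estimateLVPressure(134, EV, CYC, times = tm)
  expect_equal(pm$pressure_mmHg, 5 + (134 - 5) * 0.3, tolerance = 1e-9)
  ## event-ordering violations are rejected
  bad <- EV; bad["avo"] <- 0.01
  expect_error(estimateLVPressure(134, bad, CYC), "valve events")
  expect_error(estimateLVPressure(-5, EV, CYC), "positive")
})

test_that("Laplace stress is P/(2*c*h) and scales as expected", {
  expect_equal(laplaceStress(100, 0.025, 10), 200)
  expect_equal(laplaceStress(100, 0.025, 20), 100)  # doubling h halves
  expect_equal(laplaceStress(0, 0.025, 10), 0)
  expect_equal(laplaceStress(100, 0.025, 10, geometry = "cylindrical"), 400)
  expect_error(laplaceStress(100, 0, 10), "curvature")
  expect_error(laplaceStress(100, 0.025, -1), "thickness")
})

test_that("loop area: ellipse oracle, orientation, cyclic shift, closure", {
  th <- seq(0, 2 * pi, length.out = 2001)
  strain <- 10 * cos(th); stress <- 10 * sin(th)
  a <- loopArea(stress, strain)
  expect_equal(a, pi * 100, tolerance = 5e-4 * pi * 100)
  ## 1e5-point shoelace oracle
  expect_equal(a, denseEllipseArea(10, 10), tolerance = 1e-5 * pi * 100)
  ## reversing traversal flips the sign
  expect_equal(loopArea(rev(stress), rev(strain)), -a)
  ## cyclic shift of the starting sample leaves the area unchanged
  k <- 700
  idx <- c(k:2000, 1:k)  # start elsewhere on the loop, still closed
  expect_equal(loopArea(stress[idx], strain[idx]), a, tolerance = 1e-9)
  ## constant strain has zero area
  expect_equal(loopArea(stress, rep(1, length(th))), 0)
  ## open loops are rejected
  expect_error(loopArea(stress[-1], strain[-1]), "open loop")
})

test_that("halving the grid step changes a smooth loop area by < 0.1%", {
  area <- function(n) {
    th <- seq(0, 2 * pi, length.out = n + 1)
    loopArea(120 + 80 * sin(th), -15 + 15 * cos(th))
  }
  expect_lt(abs(area(1000) - area(500)) / abs(area(500)), 0.001)
})

test_that("regional work averages levels and flags wasted septal work", {
  w <- c(SEPT_basal = -200, SEPT_mid = -100, SEPT_apical = 150)
  r <- regionalWork(w)
  expect_equal(r@regional[["septal"]], -50)
  expect_true(r@wastedSeptal)
  ## all segments equal -> every wall equal
  segs <- paste(rep(c("ANT", "ANTSEPT", "INFSEPT", "INF", "INFLAT",
                      "ANTLAT"), each = 3), c("basal", "mid", "apical"),
                sep = "_")
  we <- setNames(rep(1234, 18), segs)
  re <- regionalWork(we)
  expect_equal(unname(re@regional), rep(1234, 4))
  expect_false(re@wastedSeptal)
  ## 18-segment layout: septal region = mean of the two septal walls
  w18 <- we
  w18[grep("^ANTSEPT", names(w18))] <- 100
  w18[grep("^INFSEPT", names(w18))] <- 300
  expect_equal(regionalWork(w18)@regional[["septal"]], 200)
  ## a missing level is an error
  expect_error(regionalWork(we[-1]), "missing")
})

test_that("trace generator round-trips prescribed loop areas within 0.5%", {
  w <- c(SEPT_basal = -500, SEPT_mid = 0, SEPT_apical = 1000)
  tr <- makeWorkTraces(w, sbp = 134, events = EV, cycleLength = CYC)
  got <- computeWork(tr)@segmentWork
  expect_equal(got[["SEPT_basal"]], -500, tolerance = 0.005 * 500)
  expect_equal(got[["SEPT_mid"]], 0, tolerance = 1e-9)
  expect_equal(got[["SEPT_apical"]], 1000, tolerance = 0.005 * 1000)
  ## zero work means constant strain
  expect_equal(diff(range(tr@strain[, "SEPT_mid"])), 0)
  ## +1000 prescription recovered within 0.5% (round-trip oracle)
  w2 <- setNames(rep(1000, 3), paste0("LAT_", c("basal", "mid", "apical")))
  tr2 <- makeWorkTraces(w2, sbp = 120, events = EV, cycleLength = CYC)
  expect_equal(unname(computeWork(tr2)@segmentWork),
               rep(1000, 3), tolerance = 0.005)
})

test_that("unrealizable prescriptions and degenerate stress are rejected", {
  w <- c(SEPT_basal = 1e6, SEPT_mid = 0, SEPT_apical = 0)
  expect_error(makeWorkTraces(w, 134, EV, CYC), "cannot be realized")
  w2 <- c(SEPT_basal = 100, SEPT_mid = 0, SEPT_apical = 0)
  expect_error(makeWorkTraces(w2, 134, EV, CYC, sigma0 = 50,
                              sigmaAmp = 60), "positive")
})

test_that("scaling the pressure scale factor scales all works linearly", {
  w <- c(SEPT_basal = -300, SEPT_mid = 800, SEPT_apical = 2000)
  tr <- makeWorkTraces(w, sbp = 120, events = EV, cycleLength = CYC)
  base <- computeWork(tr)@segmentWork
  k <- 1.5
  ## same geometry, pressure curve scaled by k (sbp and plateau together)
  p2 <- estimateLVPressure(k * 120, EV, CYC, times = tr@time,
                           diastolic = k * 5)
  tr2 <- tr
  tr2@pressure <- p2$pressure_mmHg
  expect_equal(computeWork(tr2)@segmentWork, k * base, tolerance = 1e-9)
})
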