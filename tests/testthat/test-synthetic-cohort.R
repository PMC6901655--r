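test_that("default cohort reproduces the 23/7 split and availability pattern", {
  coh <- generateCohort(cohortConfig(seed = 3), simulateRaw = FALSE)
  p <- patientData(coh)
  expect_equal(sum(p$dyssynchrony), 23)
  expect_equal(sum(!p$dyssynchrony), 7)
  expect_equal(sum(p$has_fdg), 27)
  expect_equal(sum(p$has_fdg & p$dyssynchrony), 21)
  expect_equal(sum(p$has_nh3), 29)
  expect_equal(sum(p$has_post_echo), 28)
  ## structural invariants of the ground truth
  expect_true(all(p$mbf_septal > 0 & p$mbf_lateral > 0))
  expect_true(all(p$esv_pre > 0))
  expect_equal(p$delta_esv,
               100 * (p$esv_pre - p$esv_post) / p$esv_pre,
               tolerance = 1e-12)
  ## septal uptake is the drawn SLR times the drawn lateral uptake
  expect_equal(p$suv_septal, p$fdg_slr_true * p$suv_lateral,
               tolerance = 1e-12)
})

test_that("the seed fully determines the cohort, down to the written files", {
  cfg <- cohortConfig(nDys = 3, nNondys = 2, seed = 17,
                      availability = list(fdgMissingDys = 0,
                                          fdgMissingNondys = 0,
                                          nh3MissingDys = 0,
                                          nh3MissingNondys = 0,
                                          postEchoMissing = 0))
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_equal(c1, c2)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  writeCohort(c1, d1); writeCohort(c2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
  ## a different seed changes the data
  c3 <- generateCohort(cohortConfig(nDys = 3, nNondys = 2, seed = 18),
                       simulateRaw = FALSE)
  expect_false(isTRUE(all.equal(patientData(c1)$mbf_septal,
                                patientData(c3)$mbf_septal)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("large-cohort empirical moments converge to the configured targets", {
  cfg <- cohortConfig(nDys = 5000, nNondys = 5000, seed = 101)
  p <- patientData(generateCohort(cfg, simulateRaw = FALSE))
  d <- p$dyssynchrony
  ## per-wall means within 2% of configuration
  expect_equal(mean(p$mbf_septal[d]), 0.57, tolerance = 0.02)
  expect_equal(mean(p$mbf_lateral[d]), 0.92, tolerance = 0.02)
  expect_equal(mean(p$mbf_septal[!d]), 0.61, tolerance = 0.02)
  expect_equal(mean(p$suv_lateral[d]), 11.19, tolerance = 0.02)
  expect_equal(mean(p$suv_lateral[!d]), 8.31, tolerance = 0.02)
  ## septal uptake mean is the product construction SLRxLateral
  expect_equal(mean(p$suv_septal[d]), 0.5 * 11.19, tolerance = 0.02)
  ## work mixture: mean (within 4 standard errors of the mean at this
  ## n, since the SD is large relative to the mean), SD, and negative
  ## fraction
  expect_lt(abs(mean(p$work_septal[d]) - 370), 4 * 816 / sqrt(5000))
  expect_equal(sd(p$work_septal[d]), 816, tolerance = 0.05)
  expect_equal(mean(p$work_septal[d] < 0), 0.40, tolerance = 0.05)
  expect_equal(mean(p$work_septal[!d] < 0), 0)
  expect_equal(mean(p$work_lateral[d]), 3174, tolerance = 0.02)
  ## outcome coupling: group means and pooled correlation
  expect_equal(mean(p$delta_esv[d]), 47, tolerance = 0.02)
  expect_lt(abs(mean(p$delta_esv[!d]) - (-3)), 4 * 20 / sqrt(5000))
  expect_equal(cor(p$fdg_slr_true, p$delta_esv), -0.62, tolerance = 0.08)
})

test_that("noiseless generator outputs round-trip through every stage", {
  cfg <- cohortConfig(
    nDys = 3, nNondys = 2, seed = 5,
    noise = list(tacNoiseScale = 0, suvJitterSd = 0),
    work = list(
      dys = list(septal = c(370, 816), lateral = c(3174, 1033),
                 negFraction = 0.40),
      nondys = list(septal = c(2017, 685), lateral = c(2267, 572),
                    negFraction = 0),
      otherWallJitterSd = 0, segmentJitterSd = 0, sigmaNeg = 400),
    availability = list(fdgMissingDys = 0, fdgMissingNondys = 0,
                        nh3MissingDys = 0, nh3MissingNondys = 0,
                        postEchoMissing = 0))
  coh <- generateCohort(cfg)
  p <- patientData(coh)
  for (i in seq_len(nrow(p))) {
    id <- p$id[i]
    ## kinetics: fitted K1 recovers the true wall flow to 1e-3 relative
    for (w in c("septal", "lateral")) {
      f <- fitRegion(tacs(coh, id)[[w]], inputFunction(coh, id))
      expect_equal(mbf(f), p[[paste0("mbf_", w)]][i],
                   tolerance = 1e-3)
    }
    ## FDG: wall means and SLR are exact without segment jitter
    wm <- wallMeans(polarMap(coh, id))
    expect_equal(wm[["septal"]], p$suv_septal[i], tolerance = 1e-9)
    expect_equal(fdgSLR(wm[["septal"]], wm[["lateral"]]),
                 p$fdg_slr_true[i], tolerance = 1e-9)
    ## work: loop integration recovers the drawn regional works to 0.5%
    wr <- computeWork(segmentTraces(coh, id))
    expect_equal(wr@regional[["septal"]], p$work_septal[i],
                 tolerance = 0.005)
    expect_equal(wr@regional[["lateral"]], p$work_lateral[i],
                 tolerance = 0.005)
  }
})

test_that("TAC generator limiting cases", {
  aif <- makeInputFunction(seq(0, 1800, by = 0.5))
  kin <- list(k2 = 0.25, k3 = 0.12, spill = c(septal = 0.35))
  ## zero flow: the measured curve is pure spillover
  tl <- makeTacs(c(septal = 0), aif, kin, noiseScale = 0)
  W <- dyssyncPET:::.frameAvgMatrix(aif@times,
                                    tl$septal@frameStart,
                                    tl$septal@frameEnd)
  expect_equal(tl$septal@values,
               0.35 * as.numeric(W %*% aif@wholeBlood),
               tolerance = 1e-12)
  ## noise is reproducible under a seed and zero in the noiseless case
  withr::with_seed(2, a <- makeTacs(c(septal = 0.6), aif, kin))
  withr::with_seed(2, b <- makeTacs(c(septal = 0.6), aif, kin))
  expect_equal(a$septal@values, b$septal@values)
})

test_that("work mixture calibration hits its targets and reports failure", {
  cal <- calibrateWorkMixture(370, 816, 0.40)
  expect_equal(cal$mean, 370, tolerance = 1e-3)
  expect_equal(cal$sd, 816, tolerance = 1e-3)
  ## degenerate request: tiny SD with a large negative fraction
  expect_error(calibrateWorkMixture(370, 10, 0.4), "not reachable")
  ## zero negative fraction degenerates to the truncated normal
  cal0 <- calibrateWorkMixture(2017, 685, 0)
  expect_equal(cal0$mu, 2017)
})

test_that("outcome coupling calibration solves the pooled correlation", {
  cal <- calibrateOutcomeCoupling(cohortConfig())
  expect_true(is.finite(cal$slope))
  expect_true(all(cal$tau > 0))
  ## an unreachable correlation is reported explicitly
  cfg <- cohortConfig(desv = list(dys = c(47, 1), nondys = c(-3, 1),
                                  targetR = -0.999, maxDelta = 95))
  expect_error(calibrateOutcomeCoupling(cfg), "unreachable")
})

test_that("config validation rejects broken configurations", {
  expect_error(cohortConfig(nDys = 1, nNondys = 0), "at least 2")
  expect_error(cohortConfig(readerError = 0.9), "readerError")
  expect_error(
    cohortConfig(kinetics = list(k2 = 0.25, k3 = 0.12,
                                 spill = c(septal = 1.2, lateral = 0.25,
                                           anterior = 0.25,
                                           inferior = 0.25))),
    "spill")
  expect_error(
    cohortConfig(mbf = list(
      dys = list(septal = c(0.57, -0.1), lateral = c(0.92, 0.23)),
      nondys = list(septal = c(0.61, 0.23), lateral = c(0.77, 0.21)),
      otherWallJitterSd = 0.05, lowerBound = 0.1)),
    "SD")
  expect_error(
    cohortConfig(nDys = 2, availability = list(
      fdgMissingDys = 3, fdgMissingNondys = 0, nh3MissingDys = 0,
      nh3MissingNondys = 0, postEchoMissing = 0)),
    "availability")
})
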