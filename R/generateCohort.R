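.WALLS4 <- c("septal", "lateral", "anterior", "inferior")
.WALLS6 <- c("ANT", "ANTSEPT", "INFSEPT", "INF", "INFLAT", "ANTLAT")
.LEVELS <- c("basal", "mid", "apical")

#' Simulate framed regional TACs from true wall flows
#'
#' Forward two-tissue model per wall, driven by the metabolite-corrected
#' input, with `K1` set to the wall's true MBF, mixed with whole-blood
#' spillover, frame-averaged over the schedule, and perturbed with
#' zero-mean Gaussian frame noise whose variance scales with
#' activity / frame duration. With `noiseScale = 0` the analytic forward
#' model is reproduced exactly.
#'
#' @param trueMbf named numeric, true MBF (ml/g/min) per wall.
#' @param inputFn an [InputFunction-class] covering the schedule.
#' @param kinetics list with `k2`, `k3` (1/min) and named per-wall
#'   `spill` fractions.
#' @param noiseScale frame noise scale; frame SD is
#'   `noiseScale * sqrt(max(activity, 0.1) / duration)` (kBq/ml).
#' @param schedule frame schedule data.frame; default
#'   [defaultFrameSchedule()].
#' @return named list of [TimeActivityCurve-class], one per wall.
#' @examples
#' aif <- makeInputFunction(seq(0, 1800, by = 0.5))
#' tl <- makeTacs(c(septal = 0.57, lateral = 0.92), aif,
#'                kinetics = list(k2 = 0.25, k3 = 0.12,
#'                                spill = c(septal = 0.35, lateral = 0.25)),
#'                noiseScale = 0)
#' tl$septal
#' @export
makeTacs <- function(trueMbf, inputFn,
                     kinetics = list(k2 = 0.25, k3 = 0.12,
                                     spill = c(septal = 0.35, lateral = 0.25,
                                               anterior = 0.25,
                                               inferior = 0.25)),
                     noiseScale = 1,
                     schedule = defaultFrameSchedule()) {
  stopifnot(is(inputFn, "InputFunction"))
  if (is.null(names(trueMbf))) stop("trueMbf must be named by wall")
  if (any(trueMbf < 0)) stop("true MBF must be non-negative")
  times <- inputFn@times
  ca <- inputFn@wholeBlood * (1 - inputFn@metaboliteFraction)
  fs <- schedule$frame_start_s; fe <- schedule$frame_end_s
  dur <- fe - fs
  out <- lapply(names(trueMbf), function(w) {
    spill <- kinetics$spill[[w]]
    if (is.null(spill)) stop("no spill fraction configured for wall ", w)
    p <- new("CompartmentParams", K1 = unname(trueMbf[[w]]),
             k2 = kinetics$k2, k3 = kinetics$k3, spill = spill)
    m <- modelTac(p, times, ca, wholeBlood = inputFn@wholeBlood,
                  frameStart = fs, frameEnd = fe)
    v <- m$frames$value
    if (noiseScale > 0)
      v <- v + rnorm(length(v), 0, noiseScale * sqrt(pmax(v, 0.1) / dur))
    new("TimeActivityCurve", frameStart = fs, frameEnd = fe,
        values = v, region = w)
  })
  names(out) <- names(trueMbf)
  out
}

#' Construct segmental traces realizing prescribed loop areas
#'
#' Builds strain, thickness, curvature and pressure traces whose
#' stress-strain loops have exactly the prescribed signed areas. Per
#' segment, the target stress and strain follow a closed ellipse of
#' known area (`|work| = pi * a * b` with stress semi-axis `b =
#' sigmaAmp` and strain semi-axis `a` solved from the prescribed work;
#' negative work reverses the traversal direction). Thickness is held
#' constant and the Laplace relation is inverted to obtain the curvature
#' trace `c(t) = P(t) / (2 * thickness * sigma(t))`, so the downstream
#' work chain ([computeWork()]) recovers the prescription up to
#' integration error.
#'
#' @param segmentWorks named numeric, prescribed work density (mmHg·%)
#'   per segment (names `"<WALL>_<level>"`).
#' @param sbp systolic blood pressure (mmHg).
#' @param events named valve-event times (s).
#' @param cycleLength cycle length (s).
#' @param nSamples samples per cycle (the grid has `nSamples + 1` points
#'   including the closing duplicate).
#' @param thickness constant wall thickness (mm).
#' @param sigma0 baseline stress level (mmHg); must exceed `sigmaAmp`
#'   so stress stays positive.
#' @param sigmaAmp stress semi-amplitude (mmHg).
#' @param strainMax largest admissible strain semi-amplitude (%);
#'   prescriptions requiring more are rejected.
#' @param diastolic diastolic plateau pressure (mmHg).
#' @return a [SegmentTraces-class].
#' @examples
#' ev <- c(mvc = 0.034, avo = 0.103, avc = 0.387, mvo = 0.447)
#' w <- c(SEPT_basal = -200, SEPT_mid = 100, SEPT_apical = 600)
#' tr <- makeWorkTraces(w, sbp = 134, events = ev, cycleLength = 0.86)
#' computeWork(tr)@segmentWork
#' @export
makeWorkTraces <- function(segmentWorks, sbp, events, cycleLength,
                           nSamples = 500, thickness = 8, sigma0 = 120,
                           sigmaAmp = 80, strainMax = 40, diastolic = 5) {
  if (sigmaAmp <= 0 || sigma0 <= sigmaAmp)
    stop("need 0 < sigmaAmp < sigma0 so the stress trace stays positive")
  seg <- .parseSegments(names(segmentWorks))
  tm <- seq(0, cycleLength, length.out = nSamples + 1)
  P <- estimateLVPressure(sbp, events, cycleLength, times = tm,
                          diastolic = diastolic)$pressure_mmHg
  a <- abs(segmentWorks) / (pi * sigmaAmp)
  bad <- a > strainMax
  if (any(bad))
    stop("prescribed work of segment(s) ",
         paste(names(segmentWorks)[bad], collapse = ", "),
         " cannot be realized: required strain amplitude exceeds ",
         strainMax, "% with positive stress throughout")
  theta <- 2 * pi * tm / cycleLength
  nseg <- length(segmentWorks)
  strain <- sigma <- matrix(0, length(tm), nseg,
                            dimnames = list(NULL, names(segmentWorks)))
  for (j in seq_len(nseg)) {
    s <- if (segmentWorks[j] < 0) -1 else 1
    strain[, j] <- -a[j] + a[j] * cos(theta)
    sigma[, j] <- sigma0 + sigmaAmp * s * sin(theta)
  }
  curv <- P / (2 * thickness * sigma)
  th <- matrix(thickness, length(tm), nseg,
               dimnames = list(NULL, names(segmentWorks)))
  new("SegmentTraces", time = tm, strain = strain, thickness = th,
      curvature = curv, pressure = P, sbp = sbp,
      valveEvents = events[c("mvc", "avo", "avc", "mvo")],
      cycleLength = cycleLength)
}

.drawWorkMixture <- function(n, mixture) {
  u <- runif(n)
  val <- numeric(n)
  neg <- u < mixture$negFraction
  ## one further uniform per patient regardless of branch
  val[neg] <- -rtnorm(sum(neg), 0, mixture$sigmaNeg, lower = 0)
  val[!neg] <- rtnorm(sum(!neg), mixture$mu, mixture$sigma, lower = 0)
  val
}

## per-region segment jitter re-centred so the regional mean is exact
.centeredJitter <- function(n, sd) {
  if (sd == 0 || n < 2) return(numeric(n))
  j <- rnorm(n, 0, sd)
  j - mean(j)
}

#' Generate a seeded synthetic dyssynchrony cohort
#'
#' Draws per-patient ground truth from the configured group
#' distributions and forward-simulates every raw input the pipeline
#' consumes: framed 13N-ammonia TACs per wall (two-tissue forward model
#' with spillover and frame noise), the arterial input function with
#' metabolite fraction, 17-segment FDG polar maps, and 18-segment
#' strain/geometry traces realizing the drawn regional works. Septal
#' FDG uptake is constructed as (drawn SLR) x (drawn lateral uptake), so
#' the configured wall means and SLR means hold jointly; septal work in
#' the dyssynchrony group comes from the calibrated mixture of
#' [calibrateWorkMixture()]; ΔLV ESV is coupled to the FDG SLR via
#' [calibrateOutcomeCoupling()] so the pooled correlation matches the
#' configured target in expectation. The seed in `config` fully
#' determines the output.
#'
#' @param config a [cohortConfig()].
#' @param simulateRaw simulate the raw per-patient data (TACs, input
#'   functions, polar maps, traces). `FALSE` draws only the
#'   ground-truth patient table, which is cheap at large n and is what
#'   calibration checks need.
#' @return a [DyssyncCohort-class].
#' @examples
#' \donttest{
#' coh <- generateCohort(cohortConfig(seed = 1))
#' coh
#' head(patientData(coh))
#' }
#' @export
generateCohort <- function(config = cohortConfig(), simulateRaw = TRUE) {
  cfg <- validateCohortConfig(config)
  mixDys <- calibrateWorkMixture(cfg$work$dys$septal[1],
                                 cfg$work$dys$septal[2],
                                 cfg$work$dys$negFraction,
                                 cfg$work$sigmaNeg)
  mixNon <- calibrateWorkMixture(cfg$work$nondys$septal[1],
                                 cfg$work$nondys$septal[2],
                                 cfg$work$nondys$negFraction,
                                 cfg$work$sigmaNeg)
  coupling <- calibrateOutcomeCoupling(cfg)

  withr::with_seed(cfg$seed, {
    n <- cfg$nDys + cfg$nNondys
    dys <- rep(c(TRUE, FALSE), c(cfg$nDys, cfg$nNondys))
    grp <- ifelse(dys, "dys", "nondys")
    ids <- sprintf("P%02d", seq_len(n))

    drawByGroup <- function(param, draw) {
      out <- numeric(n)
      for (g in c("dys", "nondys")) {
        idx <- which(grp == g)
        if (length(idx)) out[idx] <- draw(length(idx), param[[g]])
      }
      out
    }

    ## --- MBF (ml/g/min), truncated normal per wall -------------------
    lbM <- cfg$mbf$lowerBound
    mbfSept <- drawByGroup(cfg$mbf, function(k, p)
      rtnorm(k, p$septal[1], p$septal[2], lower = lbM))
    mbfLat <- drawByGroup(cfg$mbf, function(k, p)
      rtnorm(k, p$lateral[1], p$lateral[2], lower = lbM))
    mbfAnt <- pmax((mbfSept + mbfLat) / 2 +
                     rnorm(n, 0, cfg$mbf$otherWallJitterSd), lbM)
    mbfInf <- pmax((mbfSept + mbfLat) / 2 +
                     rnorm(n, 0, cfg$mbf$otherWallJitterSd), lbM)

    ## --- FDG: lateral uptake and SLR drawn, septal = SLR x lateral ---
    suvLat <- drawByGroup(cfg$fdg, function(k, p)
      rtnorm(k, p$lateral[1], p$lateral[2], lower = cfg$fdg$suvLowerBound))
    slr <- drawByGroup(cfg$fdg, function(k, p)
      rtnorm(k, p$slr[1], p$slr[2], lower = cfg$fdg$slrLowerBound))
    suvSept <- slr * suvLat
    suvAnt <- pmax((suvSept + suvLat) / 2 +
                     rnorm(n, 0, cfg$fdg$otherWallJitterSd),
                   cfg$fdg$suvLowerBound)
    suvInf <- pmax((suvSept + suvLat) / 2 +
                     rnorm(n, 0, cfg$fdg$otherWallJitterSd),
                   cfg$fdg$suvLowerBound)

    ## --- regional myocardial work (mmHg·%) ---------------------------
    workSept <- numeric(n)
    workSept[dys] <- .drawWorkMixture(cfg$nDys, mixDys)
    workSept[!dys] <- .drawWorkMixture(cfg$nNondys, mixNon)
    workLat <- drawByGroup(cfg$work, function(k, p)
      rtnorm(k, p$lateral[1], p$lateral[2], lower = 0))
    workAnt <- (workSept + workLat) / 2 +
      rnorm(n, 0, cfg$work$otherWallJitterSd)
    workInf <- (workSept + workLat) / 2 +
      rnorm(n, 0, cfg$work$otherWallJitterSd)

    ## --- outcome: ΔLV ESV coupled to the FDG SLR ---------------------
    deltaEsv <- numeric(n)
    for (g in c("dys", "nondys")) {
      idx <- which(grp == g)
      mu <- cfg$desv[[g]][1]
      deltaEsv[idx] <- mu +
        coupling$slope * (slr[idx] - coupling$slrMean[[g]]) +
        rnorm(length(idx), 0, coupling$tau[[g]])
    }
    deltaEsv <- pmin(deltaEsv, cfg$desv$maxDelta)
    esvPre <- drawByGroup(cfg$esvPre, function(k, p)
      exp(rnorm(k, p[["meanlog"]], p[["sdlog"]])))
    esvPost <- esvPre * (1 - deltaEsv / 100)

    ## --- haemodynamics, readers, availability ------------------------
    sbp <- drawByGroup(cfg$sbp, function(k, p)
      rtnorm(k, p[1], p[2], lower = cfg$sbp$lowerBound))
    reader1 <- xor(dys, runif(n) < cfg$readerError)
    reader2 <- xor(dys, runif(n) < cfg$readerError)
    av <- cfg$availability
    hasFdg <- rep(TRUE, n); hasNh3 <- rep(TRUE, n)
    hasPost <- rep(TRUE, n)
    pick <- function(idx, k) if (k > 0) sample(idx, k) else integer()
    hasFdg[c(pick(which(dys), av$fdgMissingDys),
             pick(which(!dys), av$fdgMissingNondys))] <- FALSE
    hasNh3[c(pick(which(dys), av$nh3MissingDys),
             pick(which(!dys), av$nh3MissingNondys))] <- FALSE
    hasPost[pick(seq_len(n), av$postEchoMissing)] <- FALSE

    patients <- data.frame(
      id = ids, dyssynchrony = dys,
      mbf_septal = mbfSept, mbf_lateral = mbfLat,
      mbf_anterior = mbfAnt, mbf_inferior = mbfInf,
      suv_septal = suvSept, suv_lateral = suvLat,
      suv_anterior = suvAnt, suv_inferior = suvInf,
      fdg_slr_true = slr,
      work_septal = workSept, work_lateral = workLat,
      work_anterior = workAnt, work_inferior = workInf,
      delta_esv = deltaEsv, esv_pre = esvPre, esv_post = esvPost,
      sbp = sbp, reader1 = reader1, reader2 = reader2,
      has_fdg = hasFdg, has_nh3 = hasNh3, has_post_echo = hasPost,
      stringsAsFactors = FALSE)

    ## --- forward-simulated raw data ----------------------------------
    if (!simulateRaw) {
      new("DyssyncCohort", config = unclass(cfg), patients = patients,
          tacs = list(), inputFunctions = list(), polarMaps = list(),
          traces = list())
    } else {
    sched <- defaultFrameSchedule()
    aifTimes <- seq(0, max(sched$frame_end_s), by = cfg$aif$dt)
    regions <- defaultWallRegions()
    tacsL <- inputL <- mapsL <- tracesL <- vector("list", n)
    names(tacsL) <- names(inputL) <- names(mapsL) <- names(tracesL) <- ids
    events <- cfg$cycle$events

    for (i in seq_len(n)) {
      aif <- makeInputFunction(aifTimes, A = cfg$aif$A,
                               alpha = cfg$aif$alpha, beta = cfg$aif$beta,
                               t0 = cfg$aif$t0,
                               metabOnset = cfg$aif$metabOnset,
                               metabPlateauTime = cfg$aif$metabPlateauTime,
                               metabPlateauValue = cfg$aif$metabPlateauValue)
      inputL[[i]] <- aif
      tacsL[[i]] <- makeTacs(
        c(septal = mbfSept[i], lateral = mbfLat[i],
          anterior = mbfAnt[i], inferior = mbfInf[i]),
        aif, kinetics = cfg$kinetics,
        noiseScale = cfg$noise$tacNoiseScale, schedule = sched)

      wallSuv <- c(septal = suvSept[i], lateral = suvLat[i],
                   anterior = suvAnt[i], inferior = suvInf[i])
      segv <- numeric(17)
      for (w in .WALLS4) segv[regions == w] <- wallSuv[[w]]
      segv[17] <- mean(wallSuv)
      if (cfg$noise$suvJitterSd > 0)
        segv <- segv + rnorm(17, 0, cfg$noise$suvJitterSd)
      mapsL[[i]] <- new("PolarMap17",
                        values = pmax(segv, cfg$fdg$suvLowerBound / 2))

      wall6 <- c(ANT = workAnt[i], ANTSEPT = workSept[i],
                 INFSEPT = workSept[i], INF = workInf[i],
                 INFLAT = workLat[i], ANTLAT = workLat[i])
      segw <- as.numeric(t(matrix(wall6, 6, 3)))
      names(segw) <- paste(rep(.WALLS6, each = 3), .LEVELS, sep = "_")
      jsd <- cfg$work$segmentJitterSd
      segw[paste(rep(c("ANTSEPT", "INFSEPT"), each = 3), .LEVELS,
                 sep = "_")] <-
        segw[paste(rep(c("ANTSEPT", "INFSEPT"), each = 3), .LEVELS,
                   sep = "_")] + .centeredJitter(6, jsd)
      segw[paste(rep(c("INFLAT", "ANTLAT"), each = 3), .LEVELS,
                 sep = "_")] <-
        segw[paste(rep(c("INFLAT", "ANTLAT"), each = 3), .LEVELS,
                   sep = "_")] + .centeredJitter(6, jsd)
      segw[paste("ANT", .LEVELS, sep = "_")] <-
        segw[paste("ANT", .LEVELS, sep = "_")] + .centeredJitter(3, jsd)
      segw[paste("INF", .LEVELS, sep = "_")] <-
        segw[paste("INF", .LEVELS, sep = "_")] + .centeredJitter(3, jsd)

      tracesL[[i]] <- makeWorkTraces(
        segw, sbp = sbp[i], events = events,
        cycleLength = cfg$cycle$length,
        nSamples = cfg$traces$nSamples,
        thickness = cfg$traces$thickness,
        sigma0 = cfg$traces$sigma0, sigmaAmp = cfg$traces$sigmaAmp,
        strainMax = cfg$traces$strainMax,
        diastolic = cfg$traces$diastolic)
    }

    new("DyssyncCohort", config = unclass(cfg), patients = patients,
        tacs = tacsL, inputFunctions = inputL, polarMaps = mapsL,
        traces = tracesL)
    }
  })
}
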