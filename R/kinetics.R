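## Two-tissue irreversible compartment model for 13N-ammonia.
##
## dC1/dt = K1*Ca - (k2 + k3)*C1 ; dC2/dt = k3*C1 ; Ct = C1 + C2.
## Impulse response: h(t) = K1 * (k3 + k2 * exp(-(k2 + k3) t)) / (k2 + k3),
## so Ct = K1/(k2+k3) * (k3 * int_0^t Ca + k2 * int_0^t Ca(s) e^{-(k2+k3)(t-s)} ds).
## Both integrals are computed on a uniform fine grid: the running
## integral by cumulative trapezoid, the exponential convolution by the
## exact one-step recursion E_i = q E_{i-1} + dt/2 (Ca_i + q Ca_{i-1}),
## q = exp(-lambda dt), evaluated in C via stats::filter.

.cumtrapz <- function(dt, y) {
  n <- length(y)
  if (n < 2) return(numeric(n))
  c(0, cumsum(dt * (y[-1] + y[-n]) / 2))
}

.expConv <- function(dt, y, lambda) {
  n <- length(y)
  if (n < 2) return(numeric(n))
  q <- exp(-lambda * dt)
  inc <- c(0, dt / 2 * (y[-1] + q * y[-n]))
  as.numeric(stats::filter(inc, q, method = "recursive"))
}

.checkUniform <- function(times) {
  d <- diff(times)
  if (length(d) == 0 || any(abs(d - d[1]) > 1e-9 * max(d[1], 1)))
    stop("curve must be sampled on a uniform time grid")
  if (d[1] > 1 + 1e-9)
    stop("time step must be <= 1 s for the convolution grid")
  d[1]
}

## frame-averaging weights: trapezoid mean over [start, end] per frame;
## frame boundaries must sit on the fine grid.
.frameAvgMatrix <- function(times, frameStart, frameEnd) {
  dt <- .checkUniform(times)
  W <- matrix(0, length(frameStart), length(times))
  for (j in seq_along(frameStart)) {
    i0 <- which.min(abs(times - frameStart[j]))
    i1 <- which.min(abs(times - frameEnd[j]))
    if (abs(times[i0] - frameStart[j]) > 1e-6 ||
        abs(times[i1] - frameEnd[j]) > 1e-6)
      stop("frame boundaries must align with the fine time grid")
    w <- rep(dt, i1 - i0 + 1)
    w[1] <- w[length(w)] <- dt / 2
    W[j, i0:i1] <- w / (frameEnd[j] - frameStart[j])
  }
  W
}

.tissueCurve <- function(K1, k2, k3, dt, arterial,
                         I = .cumtrapz(dt, arterial)) {
  lambda <- k2 + k3
  if (lambda < 1e-12) return(K1 * I)  # analytic limit h(t) = K1
  K1 / lambda * (k3 * I + k2 * .expConv(dt, arterial, lambda))
}

#' Forward two-tissue model for a regional TAC
#'
#' Computes the tissue curve of the irreversible two-tissue 13N-ammonia
#' model driven by a metabolite-corrected arterial input, mixes in blood
#' spillover (`measured = (1 - spill) * tissue + spill * wholeBlood`),
#' and optionally frame-averages the measured curve over a frame
#' schedule. Rate constants `k2`, `k3` are per minute while the time
#' grid is in seconds; the conversion is internal.
#'
#' @param params a [CompartmentParams-class] (or list with `K1`, `k2`,
#'   `k3`, `spill`).
#' @param times uniform fine time grid (s), step `<= 1` s.
#' @param arterial metabolite-corrected arterial activity on `times`.
#' @param wholeBlood optional uncorrected whole-blood curve on `times`
#'   used for the spillover term; defaults to `arterial`.
#' @param frameStart,frameEnd optional frame schedule (s) for averaging.
#' @return list with `times`, `tissue`, `measured` (fine grid) and, when
#'   a schedule is given, a data.frame `frames` with the frame-averaged
#'   measured model curve.
#' @examples
#' t <- seq(0, 600, by = 0.5)
#' aif <- makeInputFunction(t)
#' ca <- metaboliteCorrect(aif)$arterial
#' p <- new("CompartmentParams", K1 = 0.6, k2 = 0.25, k3 = 0.12, spill = 0.3)
#' m <- modelTac(p, t, ca, wholeBlood = aif@wholeBlood)
#' @export
modelTac <- function(params, times, arterial, wholeBlood = NULL,
                     frameStart = NULL, frameEnd = NULL) {
  if (is(params, "CompartmentParams")) {
    validObject(params)
    K1 <- params@K1; k2 <- params@k2; k3 <- params@k3; spill <- params@spill
  } else {
    K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; spill <- params$spill
  }
  dt <- .checkUniform(times)
  if (is.null(wholeBlood)) wholeBlood <- arterial
  tissue <- .tissueCurve(K1, k2 / 60, k3 / 60, dt, arterial)
  measured <- (1 - spill) * tissue + spill * wholeBlood
  out <- list(times = times, tissue = tissue, measured = measured)
  if (!is.null(frameStart)) {
    W <- .frameAvgMatrix(times, frameStart, frameEnd)
    out$frames <- data.frame(frame_start_s = frameStart,
                             frame_end_s = frameEnd,
                             value = as.numeric(W %*% measured))
  }
  out
}

.defaultStarts <- function() {
  rbind(
    c(K1 = 0.3, k2 = 0.20, k3 = 0.10, spill = 0.20),
    c(K1 = 0.8, k2 = 0.30, k3 = 0.15, spill = 0.30),
    c(K1 = 0.5, k2 = 0.10, k3 = 0.05, spill = 0.10),
    c(K1 = 1.2, k2 = 0.50, k3 = 0.30, spill = 0.40),
    c(K1 = 0.1, k2 = 0.05, k3 = 0.02, spill = 0.05)
  )
}

#' Fit the two-tissue model to one regional TAC
#'
#' Weighted least-squares fit of (`K1`, `k2`, `k3`, `spill`) to the
#' framed regional curve, using the first 10 min of emission data
#' (frames ending within `maxTime`). The whole-blood input is
#' metabolite-corrected internally; the spillover term uses the
#' uncorrected whole-blood curve. Optimization is bounded
#' Levenberg-Marquardt ([minpack.lm::nls.lm]) from deterministic
#' multi-starts; ties are broken by the lowest weighted SSE, then the
#' lowest `K1`. Under the default flow convention the reported MBF
#' equals `K1`.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param inputFn an [InputFunction-class] covering the fit window.
#' @param weighting `"duration"` (frame duration, default) or
#'   `"activity"` (duration divided by frame activity).
#' @param maxTime end of the fit window (s); default 600.
#' @param dt fine convolution grid step (s); default 0.5.
#' @param starts matrix of start points (columns K1, k2, k3, spill).
#' @param lower,upper parameter bounds; defaults `K1` in `[0, 5]`,
#'   `k2`, `k3` in `[0, 2]`, `spill` in `[0, 0.8]`.
#' @param extractionCorrection optional function mapping fitted `K1` to
#'   MBF (e.g. a flow-dependent extraction inversion); `NULL` (default)
#'   reports MBF = K1.
#' @return a [FitResult-class].
#' @examples
#' t <- seq(0, 1800, by = 0.5)
#' aif <- makeInputFunction(t)
#' sched <- defaultFrameSchedule()
#' p <- new("CompartmentParams", K1 = 0.6, k2 = 0.25, k3 = 0.12, spill = 0.3)
#' m <- modelTac(p, t, metaboliteCorrect(aif)$arterial, aif@wholeBlood,
#'               sched$frame_start_s, sched$frame_end_s)
#' tac <- new("TimeActivityCurve", frameStart = sched$frame_start_s,
#'            frameEnd = sched$frame_end_s, values = m$frames$value,
#'            region = "septal")
#' fit <- fitRegion(tac, aif)
#' mbf(fit)
#' @export
fitRegion <- function(tac, inputFn, weighting = c("duration", "activity"),
                      maxTime = 600, dt = 0.5,
                      starts = .defaultStarts(),
                      lower = c(0, 0, 0, 0), upper = c(5, 2, 2, 0.8),
                      extractionCorrection = NULL) {
  stopifnot(is(tac, "TimeActivityCurve"), is(inputFn, "InputFunction"))
  validObject(tac); validObject(inputFn)
  weighting <- match.arg(weighting)

  keep <- tac@frameEnd <= maxTime + 1e-9
  if (!any(keep)) stop("no frames end within the fit window")
  fs <- tac@frameStart[keep]; fe <- tac@frameEnd[keep]
  y <- tac@values[keep]
  if (max(inputFn@times) < max(fe) - 1e-9)
    stop("input function does not cover the fit window")

  times <- seq(0, max(fe), by = dt)
  wb <- approx(inputFn@times, inputFn@wholeBlood, times, rule = 2)$y
  mf <- approx(inputFn@times, inputFn@metaboliteFraction, times, rule = 2)$y
  ca <- wb * (1 - mf)
  I <- .cumtrapz(dt, ca)
  W <- .frameAvgMatrix(times, fs, fe)
  wbFrames <- as.numeric(W %*% wb)

  dur <- fe - fs
  w <- switch(weighting,
    duration = dur,
    activity = dur / pmax(abs(y), 0.05 * max(abs(y), 1e-6)))
  sw <- sqrt(w)

  resid <- function(par) {
    tissue <- .tissueCurve(par[1], par[2] / 60, par[3] / 60, dt, ca, I)
    model <- (1 - par[4]) * as.numeric(W %*% tissue) + par[4] * wbFrames
    sw * (model - y)
  }

  best <- NULL
  anyConverged <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(starts[i, ], lower), upper),
                         lower = lower, upper = upper, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:3
    anyConverged <- anyConverged || ok
    cand <- list(par = fit$par, sse = fit$deviance, ok = ok)
    if (is.null(best) ||
        cand$sse < best$sse - 1e-12 ||
        (abs(cand$sse - best$sse) <= 1e-12 && cand$par[1] < best$par[1]))
      best <- cand
  }
  if (is.null(best))
    stop("optimizer failed on every start; check the input curves")

  par <- as.numeric(best$par)
  params <- new("CompartmentParams", K1 = par[1], k2 = par[2],
                k3 = par[3], spill = par[4])
  flow <- if (is.null(extractionCorrection)) par[1] else
    extractionCorrection(par[1])
  new("FitResult", params = params, weightedSSE = best$sse,
      nFramesUsed = length(y), converged = anyConverged,
      mbf = flow, region = tac@region)
}

#' Septal-to-lateral MBF ratio
#'
#' @param mbfSeptal,mbfLateral mean MBF of the septal and lateral wall
#'   (ml/g/min); the lateral value must be positive.
#' @return `mbfSeptal / mbfLateral`.
#' @examples
#' mbfSLR(0.57, 0.92)
#' @export
mbfSLR <- function(mbfSeptal, mbfLateral) {
  if (any(mbfLateral <= 0))
    stop("lateral MBF must be positive to form a septal-to-lateral ratio")
  mbfSeptal / mbfLateral
}
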