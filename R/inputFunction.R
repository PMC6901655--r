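#' Default dynamic frame schedule
#'
#' The 22-frame rebinning of the 30-min dynamic 13N-ammonia list-mode
#' acquisition: 12 x 10 s, 4 x 30 s, 3 x 120 s, 1 x 180 s, 1 x 420 s and
#' 1 x 600 s (1800 s total). Kinetic fitting uses the frames ending
#' within the first 600 s (19 frames).
#'
#' @return data.frame with columns `frame_start_s`, `frame_end_s`.
#' @examples
#' sched <- defaultFrameSchedule()
#' nrow(sched)            # 22
#' sum(sched$frame_end_s <= 600)  # 19 frames inside the fit window
#' @export
defaultFrameSchedule <- function() {
  dur <- c(rep(10, 12), rep(30, 4), rep(120, 3), 180, 420, 600)
  end <- cumsum(dur)
  data.frame(frame_start_s = end - dur, frame_end_s = end)
}

#' Simulate an arterial input function
#'
#' Builds a gamma-variate bolus `A * (t - t0)^alpha * exp(-(t - t0)/beta)`
#' (zero before `t0`) as the true arterial tracer curve, and a metabolite
#' fraction that is zero during the first 2 min and then rises linearly
#' to a plateau. The stored whole-blood curve is
#' `arterial / (1 - metaboliteFraction)`, so [metaboliteCorrect()]
#' recovers the true arterial input exactly.
#'
#' @param times numeric, sample times (s), increasing from 0.
#' @param A bolus amplitude scale (kBq/ml); the default puts the peak
#'   near 100 kBq/ml.
#' @param alpha,beta gamma-variate shape (dimensionless) and time scale
#'   (s); both must be positive. The peak sits at `t0 + alpha * beta`.
#' @param t0 bolus arrival time (s).
#' @param metabOnset time (s) at which metabolites appear (default 120).
#' @param metabPlateauTime time (s) at which the metabolite fraction
#'   reaches its plateau.
#' @param metabPlateauValue plateau metabolite fraction in `[0, 1)`.
#' @return an [InputFunction-class].
#' @examples
#' aif <- makeInputFunction(seq(0, 1800, by = 0.5))
#' aif
#' @export
makeInputFunction <- function(times, A = 1.28, alpha = 2, beta = 12,
                              t0 = 10, metabOnset = 120,
                              metabPlateauTime = 600,
                              metabPlateauValue = 0.5) {
  if (alpha <= 0 || beta <= 0)
    stop("gamma-variate shape requires alpha > 0 and beta > 0")
  if (metabPlateauValue < 0 || metabPlateauValue >= 1)
    stop("metabPlateauValue must lie in [0, 1)")
  if (metabPlateauTime <= metabOnset)
    stop("metabPlateauTime must exceed metabOnset")
  arterial <- gammaVariate(times, A, alpha, beta, t0)
  mf <- metaboliteFraction(times, metabOnset, metabPlateauTime,
                           metabPlateauValue)
  new("InputFunction", times = as.numeric(times),
      wholeBlood = arterial / (1 - mf), metaboliteFraction = mf)
}

gammaVariate <- function(t, A, alpha, beta, t0) {
  out <- numeric(length(t))
  past <- t > t0
  dt <- t[past] - t0
  out[past] <- A * dt^alpha * exp(-dt / beta)
  out
}

metaboliteFraction <- function(t, onset, plateauTime, plateauValue) {
  f <- pmin(pmax((t - onset) / (plateauTime - onset), 0), 1)
  f * plateauValue
}

#' Metabolite-correct a whole-blood curve
#'
#' 13N-ammonia metabolites accumulate in blood after the first 2 min and
#' do not enter the myocardium as tracer; the corrected arterial input is
#' `wholeBlood * (1 - metaboliteFraction)`. Where the fraction is zero
#' the curve is returned unchanged.
#'
#' @param inputFn an [InputFunction-class].
#' @return data.frame with columns `time_s` and `arterial` (kBq/ml).
#' @examples
#' aif <- makeInputFunction(seq(0, 600, by = 1))
#' ca <- metaboliteCorrect(aif)
#' head(ca)
#' @export
metaboliteCorrect <- function(inputFn) {
  stopifnot(is(inputFn, "InputFunction"))
  validObject(inputFn)
  data.frame(
    time_s = inputFn@times,
    arterial = inputFn@wholeBlood * (1 - inputFn@metaboliteFraction)
  )
}
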