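## Independent oracles used across the suite. These deliberately avoid
## the package's fast paths: brute-force grids, dense-grid quadrature
## and direct O(n^2) convolution.

## Build a noiseless framed TAC from known parameters.
makeNoiselessTac <- function(K1 = 0.6, k2 = 0.25, k3 = 0.12,
                             spill = 0.3, region = "septal",
                             schedule = defaultFrameSchedule(),
                             aif = makeInputFunction(
                               seq(0, max(defaultFrameSchedule()$frame_end_s),
                                   by = 0.5))) {
  ca <- aif@wholeBlood * (1 - aif@metaboliteFraction)
  m <- modelTac(list(K1 = K1, k2 = k2, k3 = k3, spill = spill),
                aif@times, ca, wholeBlood = aif@wholeBlood,
                frameStart = schedule$frame_start_s,
                frameEnd = schedule$frame_end_s)
  list(tac = new("TimeActivityCurve",
                 frameStart = schedule$frame_start_s,
                 frameEnd = schedule$frame_end_s,
                 values = m$frames$value, region = region),
       aif = aif)
}

## Direct O(n^2) discrete convolution of the two-tissue impulse response
## with an arterial curve (trapezoid rule) -- independent of the
## recursive scheme used by the package.
directTissueConv <- function(K1, k2, k3, times, arterial) {
  dt <- times[2] - times[1]
  lam <- (k2 + k3) / 60
  h <- if (lam == 0) rep(K1, length(times)) else
    K1 * (k3 / 60 + k2 / 60 * exp(-lam * times)) / lam
  n <- length(times)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- arterial[1:i] * h[i:1]
    out[i] <- if (i == 1) 0 else dt * (sum(s) - (s[1] + s[i]) / 2)
  }
  out
}

## Brute-force weighted-least-squares oracle. The measured model is
## linear in (a, b) = ((1 - spill) * K1, spill) once (k2, k3) are
## fixed, so the brute force grids the two nonlinear axes over their
## bounds (81 points each by default) and solves the 2x2 weighted
## normal equations exactly at every grid point, then refines once
## around the coarse argmin.
gridSearchFit <- function(tac, aif, nGrid = 81, maxTime = 600, dt = 0.5) {
  keep <- tac@frameEnd <= maxTime + 1e-9
  fs <- tac@frameStart[keep]; fe <- tac@frameEnd[keep]
  y <- tac@values[keep]
  w <- fe - fs
  times <- seq(0, max(fe), by = dt)
  wb <- approx(aif@times, aif@wholeBlood, times, rule = 2)$y
  mf <- approx(aif@times, aif@metaboliteFraction, times, rule = 2)$y
  ca <- wb * (1 - mf)
  frameIdx <- lapply(seq_along(fs), function(j)
    which(times >= fs[j] - 1e-9 & times <= fe[j] + 1e-9))
  frameMean <- function(v) vapply(seq_along(fs), function(j) {
    idx <- frameIdx[[j]]
    x <- v[idx]
    (sum(x) - (x[1] + x[length(x)]) / 2) * dt / (fe[j] - fs[j])
  }, numeric(1))
  wbF <- frameMean(wb)
  evalPoint <- function(k2, k3) {
    U <- frameMean(directTissueConvFast(1, k2, k3, times, ca))
    M <- rbind(c(sum(w * U * U), sum(w * U * wbF)),
               c(sum(w * U * wbF), sum(w * wbF * wbF)))
    rhs <- c(sum(w * U * y), sum(w * wbF * y))
    ab <- tryCatch(solve(M, rhs), error = function(e) c(0, 0))
    r <- ab[1] * U + ab[2] * wbF - y
    list(a = ab[1], b = ab[2], sse = sum(w * r * r))
  }
  search <- function(lo2, hi2, lo3, hi3) {
    k2s <- seq(lo2, hi2, length.out = nGrid)
    k3s <- seq(lo3, hi3, length.out = nGrid)
    best <- NULL
    for (k2 in k2s) for (k3 in k3s) {
      e <- evalPoint(k2, k3)
      if (is.null(best) || e$sse < best$sse)
        best <- c(e, list(k2 = k2, k3 = k3))
    }
    best$step <- c(k2s[2] - k2s[1], k3s[2] - k3s[1])
    best
  }
  c1 <- search(0, 2, 0, 2)
  c2 <- search(max(0, c1$k2 - c1$step[1]), min(2, c1$k2 + c1$step[1]),
               max(0, c1$k3 - c1$step[2]), min(2, c1$k3 + c1$step[2]))
  spill <- c2$b
  K1 <- c2$a / (1 - spill)
  list(par = c(K1 = K1, k2 = c2$k2, k3 = c2$k3, spill = spill),
       sse = c2$sse, step = c2$step)
}

## same closed-form tissue model as the package but written
## independently (matrix-free loop over frames would be too slow for a
## full grid; this still avoids the package's internal helpers)
directTissueConvFast <- function(K1, k2, k3, times, arterial) {
  dt <- times[2] - times[1]
  lam <- (k2 + k3) / 60
  I <- c(0, cumsum(dt * (arterial[-1] + arterial[-length(arterial)]) / 2))
  if (lam < 1e-12) return(K1 * I)
  q <- exp(-lam * dt)
  E <- numeric(length(arterial))
  for (i in 2:length(arterial))
    E[i] <- q * E[i - 1] + dt / 2 * (arterial[i] + q * arterial[i - 1])
  K1 / lam * (k3 / 60 * I + k2 / 60 * E)
}

## dense-grid shoelace for ellipse loop areas
denseEllipseArea <- function(a, b, n = 1e5, reverse = FALSE) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  if (reverse) th <- rev(th)
  x <- a * cos(th); y <- b * sin(th)
  x <- x[-(n + 1)]; y <- y[-(n + 1)]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}
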