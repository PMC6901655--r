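#' Segmental myocardial work results
#'
#' @slot segmentWork named numeric, signed stress-strain loop area per
#'   segment (mmHg·%).
#' @slot wallWork named numeric, mean of the basal/mid/apical segment
#'   works per wall.
#' @slot regional named numeric, regional work for the septal, lateral,
#'   anterior and inferior wall groups (those present).
#' @slot wastedSeptal logical, `TRUE` when septal regional work is
#'   negative (systolic stretching, wasted work).
#'
#' @seealso [regionalWork()], [computeWork()]
#' @export
setClass("WorkResult",
  representation(segmentWork = "numeric", wallWork = "numeric",
                 regional = "numeric", wastedSeptal = "logical")
)

setMethod("show", "WorkResult", function(object) {
  cat("WorkResult (mmHg\u00b7%)\n  regional:\n")
  print(round(object@regional, 1))
  cat(sprintf("  wasted septal work: %s\n", object@wastedSeptal))
})

.checkEvents <- function(events, cycleLength) {
  need <- c("mvc", "avo", "avc", "mvo")
  if (!all(need %in% names(events)))
    stop("valve events must name mvc, avo, avc, mvo")
  ev <- events[need]
  if (!(0 <= ev[["mvc"]] && ev[["mvc"]] < ev[["avo"]] &&
        ev[["avo"]] < ev[["avc"]] && ev[["avc"]] < ev[["mvo"]] &&
        ev[["mvo"]] < cycleLength))
    stop("valve events must satisfy 0 <= mvc < avo < avc < mvo < cycle length")
  ev
}

## half-cosine interpolation between two knot values: midpoint equals
## the mean of the endpoints, slope vanishes at both knots.
.cosRamp <- function(u, u1, u2, v1, v2) {
  s <- (u - u1) / (u2 - u1)
  v1 + (v2 - v1) * (1 - cos(pi * s)) / 2
}

#' Noninvasive LV pressure estimate from a reference waveform
#'
#' A fixed normalized pressure template — diastolic plateau before
#' mitral valve closure (MVC), smooth isovolumic rise MVC to aortic
#' valve opening (AVO), a systolic dome peaking midway between AVO and
#' aortic valve closure (AVC), isovolumic fall AVC to mitral valve
#' opening (MVO), then plateau — is time-warped so its landmarks
#' coincide with the measured valve events and amplitude-scaled so its
#' maximum equals the measured systolic blood pressure. Segments between
#' landmarks are half-cosine ramps; the normalized landmark values are
#' 0.6 at AVO, 1 at the dome peak and 0.7 at AVC, and are replaceable.
#'
#' @param sbp systolic blood pressure (mmHg), the curve maximum.
#' @param events named numeric valve-event times (s): `mvc`, `avo`,
#'   `avc`, `mvo`, satisfying `0 <= mvc < avo < avc < mvo < cycleLength`.
#' @param cycleLength cardiac cycle length (s).
#' @param times optional time grid (s); default 501 uniform samples over
#'   one closed cycle.
#' @param diastolic diastolic plateau pressure (mmHg), default 5; the
#'   curve is `diastolic + (sbp - diastolic) * template`.
#' @param landmarks named numeric template values at `avo`, `peak`,
#'   `avc` (normalized to the plateau-to-peak range).
#' @return data.frame with columns `time_s`, `pressure_mmHg`.
#' @examples
#' ev <- c(mvc = 0.034, avo = 0.103, avc = 0.387, mvo = 0.447)
#' p <- estimateLVPressure(134, ev, cycleLength = 0.86)
#' max(p$pressure_mmHg)  # equals sbp
#' @export
estimateLVPressure <- function(sbp, events, cycleLength, times = NULL,
                               diastolic = 5,
                               landmarks = c(avo = 0.6, peak = 1, avc = 0.7)) {
  if (sbp <= 0) stop("sbp must be positive")
  if (diastolic < 0 || diastolic >= sbp)
    stop("diastolic plateau must be non-negative and below sbp")
  ev <- .checkEvents(events, cycleLength)
  peakT <- (ev[["avo"]] + ev[["avc"]]) / 2
  if (is.null(times))
    times <- sort(unique(c(seq(0, cycleLength, length.out = 501), peakT)))
  u <- times
  tmpl <- numeric(length(u))
  seg <- function(lo, hi, v1, v2) {
    idx <- which(u >= lo & u <= hi)
    tmpl[idx] <<- .cosRamp(u[idx], lo, hi, v1, v2)
  }
  seg(ev[["mvc"]], ev[["avo"]], 0, landmarks[["avo"]])
  seg(ev[["avo"]], peakT, landmarks[["avo"]], landmarks[["peak"]])
  seg(peakT, ev[["avc"]], landmarks[["peak"]], landmarks[["avc"]])
  seg(ev[["avc"]], ev[["mvo"]], landmarks[["avc"]], 0)
  data.frame(time_s = times,
             pressure_mmHg = diastolic + (sbp - diastolic) * tmpl)
}

#' Laplace wall stress
#'
#' Spherical Laplace stress with radius equal to the inverse mid-wall
#' curvature: `sigma = P / (2 * curvature * thickness)` (equivalently
#' `P * r / (2 h)`). A cylindrical variant (`P * r / h`) is available.
#'
#' @param pressure LV pressure (mmHg), vector.
#' @param curvature mid-wall curvature (1/mm), `> 0`.
#' @param thickness wall thickness (mm), `> 0`.
#' @param geometry `"spherical"` (default) or `"cylindrical"`.
#' @return wall stress (mmHg), same length as `pressure`.
#' @examples
#' laplaceStress(100, 0.025, 10)  # 200 mmHg
#' @export
laplaceStress <- function(pressure, curvature, thickness,
                          geometry = c("spherical", "cylindrical")) {
  geometry <- match.arg(geometry)
  if (any(curvature <= 0)) stop("curvature must be positive everywhere")
  if (any(thickness <= 0)) stop("thickness must be positive everywhere")
  denom <- curvature * thickness
  switch(geometry,
         spherical = pressure / (2 * denom),
         cylindrical = pressure / denom)
}

#' Signed area of a stress-strain loop
#'
#' Myocardial work per unit volume as the signed shoelace area of the
#' closed (strain, stress) loop over one cycle. The sign convention is
#' `work = -integral(sigma dstrain)`: shortening under high stress
#' (the physiologic loop orientation) gives positive work, systolic
#' stretching gives negative (wasted) work. The result is invariant
#' under cyclic shifts of the starting sample.
#'
#' @param stress wall stress curve (mmHg).
#' @param strain strain curve (%), same length; first and last samples
#'   must agree within `closeTol` (relative to the trace amplitude).
#' @param closeTol closure tolerance, default `1e-6`.
#' @return signed loop area (mmHg·%).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 2001)
#' loopArea(10 * sin(th), 10 * cos(th))  # ~ +100 * pi
#' @export
loopArea <- function(stress, strain, closeTol = 1e-6) {
  n <- length(strain)
  if (length(stress) != n) stop("stress and strain lengths differ")
  if (n < 4) stop("too few samples for a loop")
  sc <- function(v) max(abs(v), 1)
  if (abs(strain[1] - strain[n]) > closeTol * sc(strain) ||
      abs(stress[1] - stress[n]) > closeTol * sc(stress))
    stop("open loop: first and last samples differ beyond tolerance")
  x <- strain[-n]; y <- stress[-n]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

.parseSegments <- function(nms) {
  if (is.null(nms) || any(!grepl("_", nms)))
    stop("segment names must be '<WALL>_<level>' (e.g. 'ANTSEPT_mid')")
  data.frame(wall = sub("_[^_]*$", "", nms),
             level = sub(".*_", "", nms), name = nms)
}

#' Aggregate segment works into regional myocardial work
#'
#' Regional work per wall is the arithmetic mean of the stress-strain
#' loop areas of the wall's basal, mid and apical segments. With the
#' default 18-segment layout (6 walls x 3 levels) the septal region
#' averages the anteroseptal and inferoseptal walls and the lateral
#' region the inferolateral and anterolateral walls; a single `SEPT` /
#' `LAT` wall layout is equally accepted.
#'
#' @param segmentWorks named numeric of per-segment loop areas
#'   (mmHg·%); names `"<WALL>_<level>"` with levels basal, mid, apical.
#' @param septalWalls,lateralWalls,anteriorWalls,inferiorWalls wall
#'   names contributing to each region.
#' @return a [WorkResult-class].
#' @examples
#' w <- c(SEPT_basal = -200, SEPT_mid = -100, SEPT_apical = 150)
#' regionalWork(w)@regional  # septal -50
#' @export
regionalWork <- function(segmentWorks,
                         septalWalls = c("ANTSEPT", "INFSEPT", "SEPT"),
                         lateralWalls = c("INFLAT", "ANTLAT", "LAT"),
                         anteriorWalls = "ANT",
                         inferiorWalls = "INF") {
  seg <- .parseSegments(names(segmentWorks))
  levels <- c("basal", "mid", "apical")
  walls <- unique(seg$wall)
  wallWork <- vapply(walls, function(w) {
    lv <- seg$level[seg$wall == w]
    if (!setequal(lv, levels))
      stop("wall '", w, "' is missing a basal/mid/apical segment")
    mean(segmentWorks[seg$wall == w])
  }, numeric(1))
  groups <- list(septal = septalWalls, lateral = lateralWalls,
                 anterior = anteriorWalls, inferior = inferiorWalls)
  regional <- vapply(groups, function(g) {
    present <- intersect(g, walls)
    if (!length(present)) return(NA_real_)
    mean(wallWork[present])
  }, numeric(1))
  regional <- regional[!is.na(regional)]
  wasted <- if ("septal" %in% names(regional)) regional[["septal"]] < 0 else NA
  new("WorkResult", segmentWork = segmentWorks, wallWork = wallWork,
      regional = regional, wastedSeptal = wasted)
}

#' Myocardial work from segmental traces
#'
#' Full work chain on a [SegmentTraces-class] object: Laplace stress per
#' segment from the global pressure curve and the segment's dynamic
#' curvature and thickness, signed stress-strain loop area per segment,
#' then regional aggregation via [regionalWork()].
#'
#' @param traces a [SegmentTraces-class].
#' @param geometry Laplace geometry, see [laplaceStress()].
#' @param ... passed to [regionalWork()].
#' @return a [WorkResult-class].
#' @export
computeWork <- function(traces, geometry = "spherical", ...) {
  stopifnot(is(traces, "SegmentTraces"))
  validObject(traces)
  segs <- colnames(traces@strain)
  works <- vapply(segs, function(s) {
    sigma <- laplaceStress(traces@pressure, traces@curvature[, s],
                           traces@thickness[, s], geometry = geometry)
    loopArea(sigma, traces@strain[, s])
  }, numeric(1))
  regionalWork(works, ...)
}
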