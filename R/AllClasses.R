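#' Framed regional PET time-activity curve
#'
#' Activity concentration per reconstruction frame for one myocardial
#' region, together with the frame schedule. The default dynamic
#' 13N-ammonia schedule has 22 frames over 30 min (12 x 10 s, 4 x 30 s,
#' 3 x 120 s, 1 x 180 s, 1 x 420 s, 1 x 600 s); see
#' [defaultFrameSchedule()].
#'
#' @slot frameStart numeric, frame start times (s).
#' @slot frameEnd numeric, frame end times (s).
#' @slot values numeric, mean activity concentration per frame (kBq/ml).
#' @slot region character scalar, wall label (e.g. `"septal"`).
#'
#' @seealso [fitRegion()], [makeTacs()]
#' @export
setClass("TimeActivityCurve",
  representation(
    frameStart = "numeric",
    frameEnd = "numeric",
    values = "numeric",
    region = "character"
  )
)

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  n <- length(object@frameStart)
  if (length(object@frameEnd) != n || length(object@values) != n)
    msg <- c(msg, "frameStart, frameEnd and values must have equal length")
  if (n > 0) {
    if (any(!is.finite(object@values)))
      msg <- c(msg, "TAC values must be finite")
    if (any(object@frameEnd <= object@frameStart))
      msg <- c(msg, "each frame must end after it starts")
    if (is.unsorted(object@frameStart, strictly = TRUE))
      msg <- c(msg, "frame starts must be strictly increasing")
    if (any(abs(object@frameStart[-1] - object@frameEnd[-n]) > 1e-9))
      msg <- c(msg, "frames must be contiguous and non-overlapping")
  }
  if (length(object@region) != 1L)
    msg <- c(msg, "region must be a single label")
  if (length(msg)) msg else TRUE
})

#' Arterial input function with metabolite fraction
#'
#' Whole-blood activity concentration over time together with the
#' 13N-metabolite fraction. Metabolites of 13N-ammonia appear in blood
#' after about 2 min, so the default fraction is zero before 120 s and
#' non-decreasing afterwards; [metaboliteCorrect()] removes them.
#'
#' @slot times numeric, sample times (s), strictly increasing from 0.
#' @slot wholeBlood numeric, whole-blood activity (kBq/ml), non-negative.
#' @slot metaboliteFraction numeric in `[0, 1)`, same length as `times`.
#'
#' @seealso [makeInputFunction()], [metaboliteCorrect()]
#' @export
setClass("InputFunction",
  representation(
    times = "numeric",
    wholeBlood = "numeric",
    metaboliteFraction = "numeric"
  )
)

setValidity("InputFunction", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@wholeBlood) != n || length(object@metaboliteFraction) != n)
    msg <- c(msg, "times, wholeBlood and metaboliteFraction lengths differ")
  if (n > 0) {
    if (is.unsorted(object@times, strictly = TRUE))
      msg <- c(msg, "times must be strictly increasing")
    if (any(object@wholeBlood < 0))
      msg <- c(msg, "wholeBlood must be non-negative")
    if (any(object@metaboliteFraction < 0 | object@metaboliteFraction >= 1))
      msg <- c(msg, "metaboliteFraction must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' 17-segment polar map
#'
#' Segment values on the standard AHA 17-segment bullseye (segments 1-16
#' plus the apical cap, segment 17). Used here for static FDG SUV maps.
#'
#' @slot values numeric length 17, one value per AHA segment, `>= 0`.
#'
#' @seealso [wallMeans()], [defaultWallRegions()]
#' @export
setClass("PolarMap17", representation(values = "numeric"))

setValidity("PolarMap17", function(object) {
  msg <- character()
  if (length(object@values) != 17L)
    msg <- c(msg, "a 17-segment polar map needs exactly 17 values")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "segment values must be finite")
  if (any(object@values < 0))
    msg <- c(msg, "SUV segment values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Segmental strain/geometry traces over one cardiac cycle
#'
#' Per-segment strain, wall thickness and mid-wall curvature time series
#' on a uniform grid spanning one cycle, plus the global LV pressure
#' curve, systolic blood pressure and valve event times. Segments follow
#' an 18-segment model (6 walls x 3 levels) by default; columns are named
#' `"<WALL>_<level>"`. Traces are closed (first sample equals last) so
#' stress-strain loops are well defined.
#'
#' @slot time numeric, uniform time grid (s) over one cycle, closed.
#' @slot strain matrix (time x segment), strain in %.
#' @slot thickness matrix, wall thickness in mm, `> 0`.
#' @slot curvature matrix, mid-wall curvature in 1/mm, `> 0`.
#' @slot pressure numeric, LV pressure estimate (mmHg) on `time`.
#' @slot sbp numeric scalar, systolic blood pressure (mmHg).
#' @slot valveEvents named numeric: `mvc`, `avo`, `avc`, `mvo` (s).
#' @slot cycleLength numeric scalar, cycle length (s).
#'
#' @seealso [makeWorkTraces()], [computeWork()]
#' @export
setClass("SegmentTraces",
  representation(
    time = "numeric",
    strain = "matrix",
    thickness = "matrix",
    curvature = "matrix",
    pressure = "numeric",
    sbp = "numeric",
    valveEvents = "numeric",
    cycleLength = "numeric"
  )
)

setValidity("SegmentTraces", function(object) {
  msg <- character()
  n <- length(object@time)
  for (nm in c("strain", "thickness", "curvature")) {
    m <- slot(object, nm)
    if (nrow(m) != n)
      msg <- c(msg, sprintf("%s must have one row per time sample", nm))
    if (is.null(colnames(m)))
      msg <- c(msg, sprintf("%s needs segment column names", nm))
  }
  if (length(object@pressure) != n)
    msg <- c(msg, "pressure must be sampled on the trace time grid")
  if (any(object@thickness <= 0))
    msg <- c(msg, "thickness must be positive everywhere")
  if (any(object@curvature <= 0))
    msg <- c(msg, "curvature must be positive everywhere")
  tol <- 1e-6
  if (n > 1 && any(abs(object@strain[1, ] - object@strain[n, ]) > tol))
    msg <- c(msg, "strain traces must be closed (first sample = last)")
  ev <- object@valveEvents
  if (!all(c("mvc", "avo", "avc", "mvo") %in% names(ev))) {
    msg <- c(msg, "valveEvents must name mvc, avo, avc, mvo")
  } else if (!(0 <= ev[["mvc"]] && ev[["mvc"]] < ev[["avo"]] &&
               ev[["avo"]] < ev[["avc"]] && ev[["avc"]] < ev[["mvo"]] &&
               ev[["mvo"]] < object@cycleLength)) {
    msg <- c(msg, "valve events must satisfy 0 <= mvc < avo < avc < mvo < cycle length")
  }
  if (length(msg)) msg else TRUE
})

#' Two-tissue compartment model parameters
#'
#' Rate constants of the irreversible two-tissue model for 13N-ammonia
#' (uptake `K1`, washout `k2`, trapping `k3`) plus the blood-spill
#' fraction mixed into the measured regional signal.
#'
#' @slot K1 numeric, ml/g/min, `>= 0`.
#' @slot k2 numeric, 1/min, `>= 0`.
#' @slot k3 numeric, 1/min, `>= 0`.
#' @slot spill numeric in `[0, 1)`, blood-spill fraction.
#'
#' @seealso [modelTac()], [fitRegion()]
#' @export
setClass("CompartmentParams",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                 spill = "numeric")
)

setValidity("CompartmentParams", function(object) {
  msg <- character()
  if (any(c(object@K1, object@k2, object@k3) < 0))
    msg <- c(msg, "K1, k2 and k3 must be non-negative")
  if (object@spill < 0 || object@spill >= 1)
    msg <- c(msg, "spill must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Result of a regional compartment-model fit
#'
#' @slot params [CompartmentParams-class], the fitted rate constants.
#' @slot weightedSSE numeric, weighted residual sum of squares.
#' @slot nFramesUsed integer, frames entering the fit (default: frames
#'   ending within the first 10 min; 19 of the default 22).
#' @slot converged logical, optimizer status.
#' @slot mbf numeric, myocardial blood flow (ml/g/min); equals `K1`
#'   under the default flow convention.
#' @slot region character, wall label carried over from the TAC.
#'
#' @seealso [fitRegion()]
#' @export
setClass("FitResult",
  representation(
    params = "CompartmentParams",
    weightedSSE = "numeric",
    nFramesUsed = "integer",
    converged = "logical",
    mbf = "numeric",
    region = "character"
  )
)

#' A synthetic dyssynchrony cohort
#'
#' Container returned by [generateCohort()]: per-patient ground truth and
#' labels in `patients`, plus the simulated raw inputs every pipeline
#' stage consumes (framed TACs per wall, arterial input functions, FDG
#' polar maps, strain/geometry traces).
#'
#' @slot config list, the [cohortConfig()] that produced the cohort.
#' @slot patients data.frame, one row per patient (ground truth, labels,
#'   availability flags).
#' @slot tacs named list; per patient, a list of
#'   [TimeActivityCurve-class] objects keyed by wall.
#' @slot inputFunctions named list of [InputFunction-class].
#' @slot polarMaps named list of [PolarMap17-class].
#' @slot traces named list of [SegmentTraces-class].
#'
#' @seealso [generateCohort()], [analyzeCohort()], [writeCohort()]
#' @export
setClass("DyssyncCohort",
  representation(
    config = "list",
    patients = "data.frame",
    tacs = "list",
    inputFunctions = "list",
    polarMaps = "list",
    traces = "list"
  )
)

setValidity("DyssyncCohort", function(object) {
  msg <- character()
  ids <- object@patients$id
  if (is.null(ids)) msg <- c(msg, "patients needs an id column")
  for (nm in c("tacs", "inputFunctions", "polarMaps", "traces")) {
    x <- slot(object, nm)
    if (length(x) && !setequal(names(x), ids))
      msg <- c(msg, sprintf("%s must be keyed by patient id", nm))
  }
  if (length(msg)) msg else TRUE
})
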