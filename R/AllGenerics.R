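#' @name accessors
#' @title Accessors for dyssyncPET objects
#'
#' @description Small accessor generics: `patientData()` returns the
#' per-patient table of a cohort; `tacs()`, `inputFunction()`,
#' `polarMap()` and `segmentTraces()` return one patient's simulated raw
#' data; `mbf()` and `fitParams()` extract results from a
#' [FitResult-class].
#'
#' @param object a dyssyncPET object.
#' @param id patient identifier (character scalar).
#' @param ... unused.
#' @return See the individual methods.
NULL

#' @rdname accessors
#' @export
setGeneric("patientData", function(object, ...) standardGeneric("patientData"))

#' @rdname accessors
#' @export
setGeneric("tacs", function(object, id, ...) standardGeneric("tacs"))

#' @rdname accessors
#' @export
setGeneric("inputFunction", function(object, id, ...)
  standardGeneric("inputFunction"))

#' @rdname accessors
#' @export
setGeneric("polarMap", function(object, id, ...) standardGeneric("polarMap"))

#' @rdname accessors
#' @export
setGeneric("segmentTraces", function(object, id, ...)
  standardGeneric("segmentTraces"))

#' @rdname accessors
#' @export
setGeneric("mbf", function(object, ...) standardGeneric("mbf"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object, ...) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setMethod("patientData", "DyssyncCohort", function(object, ...) object@patients)

.checkId <- function(object, id) {
  if (!id %in% object@patients$id)
    stop("unknown patient id: ", id, call. = FALSE)
  id
}

#' @rdname accessors
#' @export
setMethod("tacs", "DyssyncCohort", function(object, id, ...)
  object@tacs[[.checkId(object, id)]])

#' @rdname accessors
#' @export
setMethod("inputFunction", "DyssyncCohort", function(object, id, ...)
  object@inputFunctions[[.checkId(object, id)]])

#' @rdname accessors
#' @export
setMethod("polarMap", "DyssyncCohort", function(object, id, ...)
  object@polarMaps[[.checkId(object, id)]])

#' @rdname accessors
#' @export
setMethod("segmentTraces", "DyssyncCohort", function(object, id, ...)
  object@traces[[.checkId(object, id)]])

#' @rdname accessors
#' @export
setMethod("mbf", "FitResult", function(object, ...) object@mbf)

#' @rdname accessors
#' @export
setMethod("fitParams", "FitResult", function(object, ...) object@params)

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve: %s, %d frames over %.0f s\n",
              object@region, length(object@values),
              if (length(object@frameEnd)) max(object@frameEnd) else 0))
})

setMethod("show", "InputFunction", function(object) {
  cat(sprintf(
    "InputFunction: %d samples over %.0f s, peak %.1f kBq/ml, metabolite fraction up to %.2f\n",
    length(object@times), max(object@times), max(object@wholeBlood),
    max(object@metaboliteFraction)))
})

setMethod("show", "PolarMap17", function(object) {
  cat("PolarMap17 (AHA 17-segment bullseye)\n")
  print(round(object@values, 3))
})

setMethod("show", "SegmentTraces", function(object) {
  cat(sprintf(
    "SegmentTraces: %d segments, %d samples over %.2f s cycle, SBP %.0f mmHg\n",
    ncol(object@strain), length(object@time), object@cycleLength,
    object@sbp))
})

setMethod("show", "CompartmentParams", function(object) {
  cat(sprintf(
    "CompartmentParams: K1 = %.4f ml/g/min, k2 = %.4f /min, k3 = %.4f /min, spill = %.3f\n",
    object@K1, object@k2, object@k3, object@spill))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult [%s]: MBF = %.4f ml/g/min (K1 = %.4f, k2 = %.4f, k3 = %.4f, spill = %.3f)\n  weighted SSE %.4g over %d frames, converged: %s\n",
    object@region, object@mbf, object@params@K1, object@params@k2,
    object@params@k3, object@params@spill, object@weightedSSE,
    object@nFramesUsed, object@converged))
})

setMethod("show", "DyssyncCohort", function(object) {
  p <- object@patients
  cat(sprintf(
    "DyssyncCohort: %d patients (%d with, %d without mechanical dyssynchrony), seed %s\n",
    nrow(p), sum(p$dyssynchrony), sum(!p$dyssynchrony),
    object@config$seed))
  cat(sprintf("  modality availability: FDG %d, NH3 %d, post-CRT echo %d\n",
              sum(p$has_fdg), sum(p$has_nh3), sum(p$has_post_echo)))
})
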