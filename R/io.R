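## Declared file interfaces of the simulate stage:
##   manifest.json                 cohort metadata + ground truth
##   tacs_<id>.csv                 frame_start_s, frame_end_s, whole_blood,
##                                 septal, lateral, anterior, inferior
##   aif_<id>.csv                  time_s, whole_blood, metabolite_fraction
##   polar_<id>.csv                segment, suv
##   traces_<id>.csv               segment, time_s, strain_pct,
##                                 thickness_mm, curvature_per_mm
##   traces_<id>.json              sbp_mmHg, cycle_length_s, valve events

#' Write a synthetic cohort to its file interface
#'
#' Persists a [DyssyncCohort-class] as plain-text files (JSON manifest
#' plus per-patient CSVs). Identical cohorts produce byte-identical
#' files, so a seed fully determines the on-disk representation.
#'
#' @param cohort a [DyssyncCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "DyssyncCohort"))
  validObject(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort@patients
  manifest <- list(
    seed = cohort@config$seed,
    config_hash = rlang::hash(cohort@config),
    n_patients = nrow(p),
    patients = p)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in p$id) {
    tl <- cohort@tacs[[id]]
    aif <- cohort@inputFunctions[[id]]
    fs <- tl[[1]]@frameStart; fe <- tl[[1]]@frameEnd
    W <- .frameAvgMatrix(aif@times, fs, fe)
    tdf <- data.frame(frame_start_s = fs, frame_end_s = fe,
                      whole_blood = as.numeric(W %*% aif@wholeBlood))
    for (w in names(tl)) tdf[[w]] <- tl[[w]]@values
    write.csv(tdf, file.path(dir, sprintf("tacs_%s.csv", id)),
              row.names = FALSE)
    write.csv(data.frame(time_s = aif@times,
                         whole_blood = aif@wholeBlood,
                         metabolite_fraction = aif@metaboliteFraction),
              file.path(dir, sprintf("aif_%s.csv", id)),
              row.names = FALSE)
    write.csv(data.frame(segment = 1:17,
                         suv = cohort@polarMaps[[id]]@values),
              file.path(dir, sprintf("polar_%s.csv", id)),
              row.names = FALSE)
    tr <- cohort@traces[[id]]
    segs <- colnames(tr@strain)
    long <- do.call(rbind, lapply(segs, function(s) {
      data.frame(segment = s, time_s = tr@time,
                 strain_pct = tr@strain[, s],
                 thickness_mm = tr@thickness[, s],
                 curvature_per_mm = tr@curvature[, s])
    }))
    write.csv(long, file.path(dir, sprintf("traces_%s.csv", id)),
              row.names = FALSE)
    ev <- tr@valveEvents
    jsonlite::write_json(
      list(sbp_mmHg = tr@sbp, cycle_length_s = tr@cycleLength,
           mvc_s = ev[["mvc"]], avo_s = ev[["avo"]],
           avc_s = ev[["avc"]], mvo_s = ev[["mvo"]]),
      file.path(dir, sprintf("traces_%s.json", id)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort back from its file interface
#'
#' Reconstructs a [DyssyncCohort-class] from the files written by
#' [writeCohort()]. The LV pressure curve of each trace set is
#' re-synthesized from the sidecar's systolic blood pressure and valve
#' events via [estimateLVPressure()].
#'
#' @param dir directory containing `manifest.json` and patient files.
#' @return a [DyssyncCohort-class] (with an empty `config` except for
#'   the recorded seed).
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  p <- as.data.frame(manifest$patients)
  tacsL <- inputL <- mapsL <- tracesL <- vector("list", nrow(p))
  names(tacsL) <- names(inputL) <- names(mapsL) <- names(tracesL) <- p$id
  for (id in p$id) {
    tdf <- read.csv(file.path(dir, sprintf("tacs_%s.csv", id)))
    walls <- setdiff(names(tdf),
                     c("frame_start_s", "frame_end_s", "whole_blood"))
    tacsL[[id]] <- lapply(walls, function(w)
      new("TimeActivityCurve", frameStart = tdf$frame_start_s,
          frameEnd = tdf$frame_end_s, values = tdf[[w]], region = w))
    names(tacsL[[id]]) <- walls
    adf <- read.csv(file.path(dir, sprintf("aif_%s.csv", id)))
    inputL[[id]] <- new("InputFunction", times = adf$time_s,
                        wholeBlood = adf$whole_blood,
                        metaboliteFraction = adf$metabolite_fraction)
    pdf <- read.csv(file.path(dir, sprintf("polar_%s.csv", id)))
    mapsL[[id]] <- new("PolarMap17", values = pdf$suv[order(pdf$segment)])
    long <- read.csv(file.path(dir, sprintf("traces_%s.csv", id)))
    side <- jsonlite::read_json(file.path(dir,
                                          sprintf("traces_%s.json", id)),
                                simplifyVector = TRUE)
    segs <- unique(long$segment)
    tm <- long$time_s[long$segment == segs[1]]
    grab <- function(col) {
      m <- vapply(segs, function(s) long[[col]][long$segment == s],
                  numeric(length(tm)))
      colnames(m) <- segs
      m
    }
    ev <- c(mvc = side$mvc_s, avo = side$avo_s, avc = side$avc_s,
            mvo = side$mvo_s)
    P <- estimateLVPressure(side$sbp_mmHg, ev, side$cycle_length_s,
                            times = tm)$pressure_mmHg
    tracesL[[id]] <- new("SegmentTraces", time = tm,
                         strain = grab("strain_pct"),
                         thickness = grab("thickness_mm"),
                         curvature = grab("curvature_per_mm"),
                         pressure = P, sbp = side$sbp_mmHg,
                         valveEvents = ev,
                         cycleLength = side$cycle_length_s)
  }
  new("DyssyncCohort", config = list(seed = manifest$seed),
      patients = p, tacs = tacsL, inputFunctions = inputL,
      polarMaps = mapsL, traces = tracesL)
}
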