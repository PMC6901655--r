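.STAGES <- c("simulate", "fit-nh3", "fdg-regional", "work", "stats")

#' Analyze a cohort in memory
#'
#' Runs the quantification chain on every patient of a
#' [DyssyncCohort-class]: compartment-model fits of the wall TACs
#' (MBF and MBF SLR), polar-map wall means and FDG SLR, stress-strain
#' loop work with regional aggregation, and ΔLV ESV.
#'
#' @param cohort a [DyssyncCohort-class].
#' @param kinetics `"fit"` (full weighted least-squares fits, default),
#'   `"true"` (copy the generator's ground-truth flows; fast path) or
#'   `"none"`.
#' @param fitWalls walls to fit; default septal and lateral (the walls
#'   entering the SLR).
#' @return data.frame, one row per patient, with measured wall metrics,
#'   SLRs, regional works, `wasted_septal`, `delta_esv` and the labels
#'   and availability flags.
#' @export
analyzeCohort <- function(cohort, kinetics = c("fit", "true", "none"),
                          fitWalls = c("septal", "lateral")) {
  stopifnot(is(cohort, "DyssyncCohort"))
  kinetics <- match.arg(kinetics)
  p <- cohort@patients
  n <- nrow(p)
  m <- data.frame(id = p$id, dyssynchrony = p$dyssynchrony,
                  has_fdg = p$has_fdg, has_nh3 = p$has_nh3,
                  has_post_echo = p$has_post_echo,
                  stringsAsFactors = FALSE)
  for (w in .WALLS4) m[[paste0("suv_", w)]] <- NA_real_
  m$fdg_slr <- NA_real_
  for (w in fitWalls) m[[paste0("mbf_", w)]] <- NA_real_
  m$mbf_slr <- NA_real_
  for (w in .WALLS4) m[[paste0("work_", w)]] <- NA_real_
  m$wasted_septal <- NA
  m$delta_esv <- NA_real_
  m$reader1 <- p$reader1
  m$reader2 <- p$reader2

  for (i in seq_len(n)) {
    id <- p$id[i]
    wm <- wallMeans(cohort@polarMaps[[id]])
    for (w in .WALLS4) m[[paste0("suv_", w)]][i] <- wm[[w]]
    m$fdg_slr[i] <- fdgSLR(wm[["septal"]], wm[["lateral"]])

    if (kinetics == "fit") {
      for (w in fitWalls) {
        fit <- fitRegion(cohort@tacs[[id]][[w]],
                         cohort@inputFunctions[[id]])
        m[[paste0("mbf_", w)]][i] <- mbf(fit)
      }
    } else if (kinetics == "true") {
      for (w in fitWalls)
        m[[paste0("mbf_", w)]][i] <- p[[paste0("mbf_", w)]][i]
    }
    if (kinetics != "none" && all(c("septal", "lateral") %in% fitWalls))
      m$mbf_slr[i] <- mbfSLR(m$mbf_septal[i], m$mbf_lateral[i])

    wr <- computeWork(cohort@traces[[id]])
    for (w in intersect(.WALLS4, names(wr@regional)))
      m[[paste0("work_", w)]][i] <- wr@regional[[w]]
    m$wasted_septal[i] <- wr@wastedSeptal
    m$delta_esv[i] <- deltaESV(p$esv_pre[i], p$esv_post[i])
  }
  m
}

.grpStat <- function(x, sel) {
  x <- x[sel & !is.na(x)]
  c(n = length(x), mean = mean(x), sd = if (length(x) > 1) sd(x) else NA)
}

#' Cohort statistics report
#'
#' Mirrors the published statistical surface on a per-patient metrics
#' table: per-group regional means ± SD for FDG SUV, MBF and myocardial
#' work (patients missing a modality are excluded per metric), paired
#' septal-vs-lateral t tests within each group with Bonferroni
#' correction over the declared family, unpaired between-group SLR and
#' ΔESV tests, Pearson correlations of the FDG and MBF SLR with ΔESV,
#' the wasted-septal-work fraction per group, and reader agreement
#' (Cohen's kappa).
#'
#' @param metrics data.frame from [analyzeCohort()].
#' @param mBonferroni Bonferroni family size for the regional paired
#'   comparisons (default 2: one septal-vs-lateral comparison per group
#'   and modality).
#' @return a list of class `DyssyncReport`.
#' @export
cohortReport <- function(metrics, mBonferroni = 2) {
  g <- metrics$dyssynchrony
  avail <- list(suv = metrics$has_fdg, mbf = metrics$has_nh3,
                work = rep(TRUE, nrow(metrics)),
                delta = metrics$has_post_echo)

  groupTable <- list()
  for (mod in c("suv", "mbf", "work")) {
    for (w in c("septal", "lateral")) {
      col <- paste0(mod, "_", w)
      if (!col %in% names(metrics)) next
      groupTable[[col]] <- list(
        dys = .grpStat(metrics[[col]], g & avail[[mod]]),
        nondys = .grpStat(metrics[[col]], !g & avail[[mod]]))
    }
  }
  slrTable <- list(
    fdg_slr = list(dys = .grpStat(metrics$fdg_slr, g & avail$suv),
                   nondys = .grpStat(metrics$fdg_slr, !g & avail$suv)),
    mbf_slr = list(dys = .grpStat(metrics$mbf_slr, g & avail$mbf),
                   nondys = .grpStat(metrics$mbf_slr, !g & avail$mbf)),
    delta_esv = list(dys = .grpStat(metrics$delta_esv, g & avail$delta),
                     nondys = .grpStat(metrics$delta_esv,
                                       !g & avail$delta)))

  pairedT <- function(mod) {
    out <- list()
    for (grpName in c("dys", "nondys")) {
      sel <- (if (grpName == "dys") g else !g) & avail[[mod]]
      a <- metrics[[paste0(mod, "_septal")]][sel]
      b <- metrics[[paste0(mod, "_lateral")]][sel]
      keep <- !is.na(a) & !is.na(b)
      out[[grpName]] <- tryCatch(
        tTestBonferroni(a[keep], b[keep], paired = TRUE,
                        mComparisons = mBonferroni),
        error = function(e) list(error = conditionMessage(e)))
    }
    out
  }
  tests <- list(suv = pairedT("suv"), mbf = pairedT("mbf"),
                work = pairedT("work"))
  for (col in c("fdg_slr", "mbf_slr", "delta_esv")) {
    sel <- switch(col, fdg_slr = avail$suv, mbf_slr = avail$mbf,
                  delta_esv = avail$delta)
    a <- metrics[[col]][g & sel]; b <- metrics[[col]][!g & sel]
    tests[[paste0(col, "_between")]] <- tryCatch(
      tTestBonferroni(a[!is.na(a)], b[!is.na(b)], paired = FALSE),
      error = function(e) list(error = conditionMessage(e)))
  }

  corSel <- function(slrCol, need) {
    sel <- need & avail$delta & !is.na(metrics[[slrCol]]) &
      !is.na(metrics$delta_esv)
    tryCatch(pearsonCorr(metrics[[slrCol]][sel],
                         metrics$delta_esv[sel]),
             error = function(e) list(error = conditionMessage(e)))
  }
  correlations <- list(
    fdg_slr_vs_delta_esv = corSel("fdg_slr", avail$suv),
    mbf_slr_vs_delta_esv = corSel("mbf_slr", avail$mbf))

  wasted <- list(
    dys = mean(metrics$wasted_septal[g], na.rm = TRUE),
    nondys = mean(metrics$wasted_septal[!g], na.rm = TRUE))
  kappa <- tryCatch(cohenKappa(metrics$reader1, metrics$reader2),
                    error = function(e) list(error = conditionMessage(e)))

  out <- list(nDys = sum(g), nNondys = sum(!g),
              groupTable = groupTable, slrTable = slrTable,
              tests = tests, correlations = correlations,
              wastedSeptalFraction = wasted, kappa = kappa)
  class(out) <- c("DyssyncReport", "list")
  out
}

#' @export
print.DyssyncReport <- function(x, ...) {
  cat(sprintf("Cohort report: %d with / %d without mechanical dyssynchrony\n",
              x$nDys, x$nNondys))
  fmt <- function(s) sprintf("%.2f \u00b1 %.2f (n=%d)",
                             s[["mean"]], s[["sd"]], s[["n"]])
  for (col in names(x$groupTable)) {
    e <- x$groupTable[[col]]
    cat(sprintf("  %-13s dys %s | non-dys %s\n", col, fmt(e$dys),
                fmt(e$nondys)))
  }
  for (col in names(x$slrTable)) {
    e <- x$slrTable[[col]]
    cat(sprintf("  %-13s dys %s | non-dys %s\n", col, fmt(e$dys),
                fmt(e$nondys)))
  }
  r <- x$correlations$fdg_slr_vs_delta_esv
  if (is.null(r$error))
    cat(sprintf("  r(FDG SLR, dESV) = %.3f (p = %.4g, n = %d)\n",
                r$r, r$p, r$n))
  cat(sprintf("  wasted septal work: %.0f%% dys, %.0f%% non-dys\n",
              100 * x$wastedSeptalFraction$dys,
              100 * x$wastedSeptalFraction$nondys))
  if (is.null(x$kappa$error))
    cat(sprintf("  reader kappa = %.3f (95%% CI %.3f-%.3f)\n",
                x$kappa$kappa, x$kappa$ci[1], x$kappa$ci[2]))
  invisible(x)
}

#' Run the full pipeline against the file interfaces
#'
#' Executes the stages `simulate`, `fit-nh3`, `fdg-regional`, `work`
#' and `stats` in order, persisting each stage's output under `outDir`
#' and reading inputs only through the declared file interfaces. A
#' stage whose outputs already exist is skipped (so a rerun on
#' persisted intermediates reproduces the same report). Identical
#' config + seed yield an identical report.
#'
#' @param config a [cohortConfig()].
#' @param outDir output directory.
#' @param stages ordered subset of the canonical stage list; must be a
#'   prefix of the canonical order.
#' @param overwrite recompute stages whose outputs already exist.
#' @param quiet suppress progress messages.
#' @return the report list (from [cohortReport()]) invisibly when the
#'   stats stage runs, otherwise `NULL` invisibly.
#' @export
runPipeline <- function(config = cohortConfig(), outDir,
                        stages = .STAGES, overwrite = FALSE,
                        quiet = FALSE) {
  if (!all(stages %in% .STAGES) ||
      !identical(stages, .STAGES[seq_along(stages)]))
    stop("stages must be a prefix of: ", paste(.STAGES, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  cohortDir <- file.path(outDir, "cohort")

  if ("simulate" %in% stages) {
    if (overwrite || !file.exists(file.path(cohortDir, "manifest.json"))) {
      say("simulate: generating cohort (seed ", config$seed, ")")
      writeCohort(generateCohort(config), cohortDir)
    } else say("simulate: cohort files present, skipping")
  }

  manifest <- function() jsonlite::read_json(
    file.path(cohortDir, "manifest.json"), simplifyVector = TRUE)

  if ("fit-nh3" %in% stages) {
    out <- file.path(outDir, "mbf.csv")
    if (overwrite || !file.exists(out)) {
      say("fit-nh3: weighted least-squares compartment fits")
      p <- as.data.frame(manifest()$patients)
      rows <- list()
      for (id in p$id) {
        res <- tryCatch({
          tdf <- read.csv(file.path(cohortDir,
                                    sprintf("tacs_%s.csv", id)))
          adf <- read.csv(file.path(cohortDir,
                                    sprintf("aif_%s.csv", id)))
          aif <- new("InputFunction", times = adf$time_s,
                     wholeBlood = adf$whole_blood,
                     metaboliteFraction = adf$metabolite_fraction)
          do.call(rbind, lapply(c("septal", "lateral"), function(w) {
            tac <- new("TimeActivityCurve",
                       frameStart = tdf$frame_start_s,
                       frameEnd = tdf$frame_end_s, values = tdf[[w]],
                       region = w)
            f <- fitRegion(tac, aif)
            data.frame(id = id, region = w, K1 = f@params@K1,
                       k2 = f@params@k2, k3 = f@params@k3,
                       spill = f@params@spill, mbf = f@mbf,
                       weighted_sse = f@weightedSSE,
                       converged = f@converged)
          }))
        }, error = function(e)
          stop("fit-nh3 failed for patient ", id, ": ",
               conditionMessage(e), call. = FALSE))
        rows[[id]] <- res
      }
      write.csv(do.call(rbind, rows), out, row.names = FALSE)
    } else say("fit-nh3: output present, skipping")
  }

  if ("fdg-regional" %in% stages) {
    out <- file.path(outDir, "fdg.csv")
    if (overwrite || !file.exists(out)) {
      say("fdg-regional: polar-map wall means")
      p <- as.data.frame(manifest()$patients)
      rows <- lapply(p$id, function(id) {
        pdf <- read.csv(file.path(cohortDir,
                                  sprintf("polar_%s.csv", id)))
        wm <- wallMeans(pdf$suv[order(pdf$segment)])
        data.frame(id = id, suv_septal = wm[["septal"]],
                   suv_lateral = wm[["lateral"]],
                   suv_anterior = wm[["anterior"]],
                   suv_inferior = wm[["inferior"]],
                   fdg_slr = fdgSLR(wm[["septal"]], wm[["lateral"]]))
      })
      write.csv(do.call(rbind, rows), out, row.names = FALSE)
    } else say("fdg-regional: output present, skipping")
  }

  if ("work" %in% stages) {
    out <- file.path(outDir, "work.csv")
    if (overwrite || !file.exists(out)) {
      say("work: stress-strain loop integration")
      p <- as.data.frame(manifest()$patients)
      coh <- readCohort(cohortDir)
      rows <- lapply(p$id, function(id) {
        wr <- computeWork(coh@traces[[id]])
        data.frame(id = id,
                   work_septal = wr@regional[["septal"]],
                   work_lateral = wr@regional[["lateral"]],
                   work_anterior = wr@regional[["anterior"]],
                   work_inferior = wr@regional[["inferior"]],
                   wasted_septal = wr@wastedSeptal)
      })
      write.csv(do.call(rbind, rows), out, row.names = FALSE)
    } else say("work: output present, skipping")
  }

  report <- NULL
  if ("stats" %in% stages) {
    say("stats: cohort report")
    p <- as.data.frame(manifest()$patients)
    fdg <- read.csv(file.path(outDir, "fdg.csv"))
    mbfT <- read.csv(file.path(outDir, "mbf.csv"))
    wrk <- read.csv(file.path(outDir, "work.csv"))
    mbfW <- data.frame(id = unique(mbfT$id))
    for (w in c("septal", "lateral"))
      mbfW[[paste0("mbf_", w)]] <-
        mbfT$mbf[mbfT$region == w][match(mbfW$id,
                                         mbfT$id[mbfT$region == w])]
    metrics <- Reduce(function(a, b) merge(a, b, by = "id"),
                      list(p[, c("id", "dyssynchrony", "has_fdg",
                                 "has_nh3", "has_post_echo", "esv_pre",
                                 "esv_post", "reader1", "reader2")],
                           fdg, mbfW, wrk))
    metrics$mbf_slr <- mbfSLR(metrics$mbf_septal, metrics$mbf_lateral)
    metrics$delta_esv <- deltaESV(metrics$esv_pre, metrics$esv_post)
    metrics <- metrics[match(p$id, metrics$id), ]
    report <- cohortReport(metrics)
    report$provenance <- list(seed = config$seed,
                              config_hash = rlang::hash(unclass(config)),
                              stages = stages)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    md <- utils::capture.output(print(report))
    writeLines(c("# Pipeline report", "", "```", md, "```"),
               file.path(outDir, "report.md"))
  }
  invisible(report)
}

#' Replicate the in-memory pipeline across seeds
#'
#' Runs cohort generation and analysis with seeds `baseSeed + 0 ...
#' baseSeed + n - 1` and collects the headline metrics per replicate:
#' dyssynchrony-group means of fitted septal/lateral MBF, septal/lateral
#' SUVmean (FDG-complete patients), FDG SLR, ΔLV ESV, septal/lateral
#' regional work and the wasted-septal-work fraction, plus the pooled
#' Pearson correlation between FDG SLR and ΔESV and the reader kappa.
#' Across-replicate means stabilize the stochastic group statistics.
#'
#' @param config a [cohortConfig()]; its seed is replaced per replicate.
#' @param nReplicates number of replicate cohorts (`>= 1`).
#' @param baseSeed first seed; defaults to `config$seed`.
#' @param kinetics passed to [analyzeCohort()]; `"fit"` runs the full
#'   compartment fits (the expensive stage).
#' @param quiet suppress progress messages.
#' @return list with `replicates` (one row per replicate), `summary`
#'   (across-replicate mean and SD per metric), `nReplicates`,
#'   `baseSeed`.
#' @export
replicateRuns <- function(config = cohortConfig(), nReplicates = 20,
                          baseSeed = config$seed,
                          kinetics = "fit", quiet = FALSE) {
  stopifnot(nReplicates >= 1)
  rows <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    cfg <- config
    cfg$seed <- baseSeed + r - 1
    if (!quiet) message("replicate ", r, "/", nReplicates,
                        " (seed ", cfg$seed, ")")
    coh <- generateCohort(cfg)
    m <- analyzeCohort(coh, kinetics = kinetics)
    g <- m$dyssynchrony
    fdgOk <- m$has_fdg
    poolSel <- fdgOk & !is.na(m$delta_esv)
    rr <- tryCatch(pearsonCorr(m$fdg_slr[poolSel],
                               m$delta_esv[poolSel])$r,
                   error = function(e) NA_real_)
    kap <- tryCatch(cohenKappa(m$reader1, m$reader2)$kappa,
                    error = function(e) NA_real_)
    rows[[r]] <- data.frame(
      replicate = r, seed = cfg$seed,
      mbf_septal_dys = mean(m$mbf_septal[g]),
      mbf_lateral_dys = mean(m$mbf_lateral[g]),
      mbf_slr_dys = mean(m$mbf_slr[g]),
      suv_septal_dys = mean(m$suv_septal[g & fdgOk]),
      suv_lateral_dys = mean(m$suv_lateral[g & fdgOk]),
      fdg_slr_dys = mean(m$fdg_slr[g & fdgOk]),
      fdg_slr_nondys = mean(m$fdg_slr[!g & fdgOk]),
      delta_esv_dys = mean(m$delta_esv[g]),
      delta_esv_nondys = mean(m$delta_esv[!g]),
      r_fdgslr_desv = rr,
      work_septal_dys = mean(m$work_septal[g]),
      work_lateral_dys = mean(m$work_lateral[g]),
      wasted_septal_frac_dys = mean(m$wasted_septal[g]),
      wasted_septal_frac_nondys = mean(m$wasted_septal[!g]),
      kappa_readers = kap)
  }
  reps <- do.call(rbind, rows)
  metricCols <- setdiff(names(reps), c("replicate", "seed"))
  summary <- data.frame(
    metric = metricCols,
    mean = vapply(metricCols, function(c) mean(reps[[c]]), numeric(1)),
    sd = vapply(metricCols, function(c)
      if (nReplicates > 1) sd(reps[[c]]) else NA_real_, numeric(1)),
    row.names = NULL)
  list(replicates = reps, summary = summary,
       nReplicates = nReplicates, baseSeed = baseSeed)
}
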