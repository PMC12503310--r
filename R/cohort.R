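#' @include AllClasses.R utils.R preprocess.R spectral.R plv.R stats.R biomarkers.R
NULL

#' Analyze one session end to end
#'
#' Runs the preprocessing chain, then per light condition the band-power
#' fraction (with baseline normalization) and the phase-locking matrix
#' (raw and baseline-normalized).
#'
#' @param recording an [EEGRecording-class] (already raw; preprocessing is
#'   applied here).
#' @param band analysis band, Hz.
#' @param artifactThreshold microvolts, passed to [rejectArtifacts()].
#' @return list with `bandPower` (tidy data frame: subject, group, day,
#'   condition, channel, rawFraction, normalized), `plv` (named list of
#'   [PLVMatrix-class] per condition), `plvNormalized` (likewise, stimulus
#'   and constant light), `segments`, `warnings`.
#' @export
analyzeSession <- function(recording, band = c(59.5, 60.5),
                           artifactThreshold = 100) {
  pp <- preprocessPipeline(recording, artifactThreshold = artifactThreshold)
  fs <- samplingRate(recording)
  md <- recordingMetadata(recording)
  day <- md$day %||% NA_real_
  fractions <- list(); plv <- list()
  for (cond in .SEGMENT_CONDITIONS) {
    seg <- segmentSamples(pp$recording, pp$segments, cond, mask = pp$mask)
    psd <- estimatePsd(seg$samples, fs, mask = seg$mask, segmentLabel = cond)
    fractions[[cond]] <- bandFraction(psd, band = band)
    nb <- narrowbandFilter(seg$samples, fs, band = band)
    ph <- instantaneousPhase(nb)
    plv[[cond]] <- computePlv(ph, mask = seg$mask, condition = cond, day = day)
  }
  base <- fractions$no_light
  bp <- do.call(rbind, lapply(.SEGMENT_CONDITIONS, function(cond) {
    data.frame(subject = md$subject %||% "unknown",
               group = md$group %||% "unknown",
               day = day,
               condition = cond,
               channel = names(fractions[[cond]]),
               rawFraction = unname(fractions[[cond]]),
               normalized = unname(normalizeToBaseline(fractions[[cond]], base)))
  }))
  plvNorm <- lapply(plv[c("constant_light", "stimulus")], normalizePlv,
                    baseline = plv$no_light)
  list(bandPower = bp, plv = plv, plvNormalized = plvNorm,
       segments = pp$segments, warnings = pp$warnings)
}

.offDiag <- function(m) m[upper.tri(m)]

#' Run the full cohort analysis
#'
#' Reads every session in the manifest, analyzes it (band power and PLV per
#' condition, baseline-normalized), and computes the group statistics:
#' active vs sham Wilcoxon rank-sum per day, and within-group
#' Kruskal-Wallis across days with Dunn-Bonferroni post hoc, separately for
#' normalized stimulus power and normalized stimulus PLV. Channel-level
#' (power) and channel-pair-level (PLV) observations are pooled across
#' subjects, as in the source analyses; `unit = "subject"` averages within
#' subject first. Optional biomarker and side-effect tables feed the
#' fold-change and tolerability summaries. A failing session is recorded
#' and skipped; the run continues.
#'
#' @param manifest data frame with columns `session_path`, `subject`,
#'   `group` ("active"/"sham"), `day`.
#' @param band analysis band, Hz.
#' @param biomarkers optional biomarker table, see [foldChangeNormalize()].
#' @param sideEffects optional side-effect log, see
#'   [weeklySideEffectCounts()].
#' @param alpha significance threshold used for the post-hoc gate.
#' @param unit `"channel"` (pool channel-level observations across subjects)
#'   or `"subject"` (per-subject means; avoids pseudo-replication).
#' @param seed integer; recorded in the bundle (the analysis itself is
#'   deterministic).
#' @return a `ResultBundle` list: `bandPower`, `plvSummary`, `plvMatrices`,
#'   `stats`, `biomarkers`, `sideEffects`, `config`, `warnings`, `failures`.
#' @export
runCohortAnalysis <- function(manifest, band = c(59.5, 60.5),
                              biomarkers = NULL, sideEffects = NULL,
                              alpha = 0.05, unit = c("channel", "subject"),
                              seed = 1L) {
  unit <- match.arg(unit)
  need <- c("session_path", "subject", "group", "day")
  .assert(all(need %in% names(manifest)),
          paste("manifest needs columns:", paste(need, collapse = ", ")))
  bandPower <- list(); plvSummary <- list(); plvMatrices <- list()
  warnings <- character(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      rec <- readRecording(manifest$session_path[i])
      rec@metadata$subject <- as.character(manifest$subject[i])
      rec@metadata$group <- as.character(manifest$group[i])
      rec@metadata$day <- manifest$day[i]
      withCallingHandlers(
        analyzeSession(rec, band = band),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        session_path = manifest$session_path[i],
        subject = manifest$subject[i], day = manifest$day[i],
        error = conditionMessage(res))
      next
    }
    bandPower[[i]] <- res$bandPower
    key <- sprintf("%s_day%s", manifest$subject[i], manifest$day[i])
    plvMatrices[[key]] <- res$plvNormalized$stimulus
    plvSummary[[i]] <- data.frame(
      subject = as.character(manifest$subject[i]),
      group = as.character(manifest$group[i]),
      day = manifest$day[i],
      condition = "stimulus",
      meanNormalizedPlv = mean(.offDiag(res$plvNormalized$stimulus@values)),
      offDiagonal = I(list(.offDiag(res$plvNormalized$stimulus@values))))
    warnings <- c(warnings, res$warnings)
  }
  bandPower <- do.call(rbind, bandPower)
  plvSummary <- do.call(rbind, plvSummary)
  .assert(!is.null(bandPower) && nrow(bandPower) > 0,
          "no session could be analyzed")

  obsPower <- bandPower[bandPower$condition == "stimulus", , drop = FALSE]
  powerObs <- function(g, d) {
    sel <- obsPower[obsPower$group == g & obsPower$day == d, , drop = FALSE]
    if (unit == "subject")
      as.numeric(tapply(sel$normalized, sel$subject, mean))
    else sel$normalized
  }
  plvObs <- function(g, d) {
    sel <- plvSummary[plvSummary$group == g & plvSummary$day == d, ,
                      drop = FALSE]
    if (unit == "subject") sel$meanNormalizedPlv
    else unlist(sel$offDiagonal)
  }
  days <- sort(unique(manifest$day))
  stats <- list()
  addStat <- function(family, measure, method, statistic, p, padj = NA_real_,
                      m = NA_integer_, detail = "") {
    stats[[length(stats) + 1L]] <<- data.frame(
      family = family, measure = measure, method = method,
      statistic = statistic, p.raw = p, p.adjusted = padj, familySize = m,
      detail = detail)
  }
  for (meas in c("power", "plv")) {
    obs <- if (meas == "power") powerObs else plvObs
    for (d in days) {
      a <- obs("active", d); s <- obs("sham", d)
      if (length(a) && length(s)) {
        t <- wilcoxonRankSum(a, s)
        addStat(sprintf("%s_day%s_active_vs_sham", meas, d), meas,
                t$method, t$statistic, t$p.value,
                detail = sprintf("n=%d/%d", length(a), length(s)))
      }
    }
    for (g in c("active", "sham")) {
      cells <- lapply(days, function(d) obs(g, d))
      names(cells) <- paste0("day", days)
      if (any(lengths(cells) == 0) || length(days) < 2) next
      kw <- kruskalWallis(cells)
      addStat(sprintf("%s_%s_across_days", meas, g), meas, kw$method,
              kw$statistic, kw$p.value,
              detail = sprintf("df=%d", kw$df))
      if (length(days) >= 3 && kw$p.value < alpha) {
        dn <- dunnPosthoc(cells)
        for (r in seq_len(nrow(dn)))
          addStat(sprintf("%s_%s_across_days", meas, g), meas,
                  sprintf("Dunn-Bonferroni %s vs %s", dn$groupA[r], dn$groupB[r]),
                  dn$z[r], dn$p.raw[r], dn$p.adjusted[r], dn$familySize[r])
      }
    }
  }
  statsTab <- do.call(rbind, stats)

  bioRes <- NULL
  if (!is.null(biomarkers)) {
    fc <- foldChangeNormalize(biomarkers)
    bioStats <- list()
    for (an in unique(fc$foldChanges$analyte)) {
      sub <- fc$foldChanges[fc$foldChanges$analyte == an, , drop = FALSE]
      if (an == "cortisol" && length(unique(sub$day)) >= 2 &&
          length(unique(sub$group)) >= 2) {
        bioStats[[an]] <- twoWayAnova(sub$foldChange, sub$group, sub$day)
      } else if (length(unique(sub$day)) >= 2) {
        kw <- kruskalWallis(split(sub$foldChange, sub$day))
        bioStats[[an]] <- data.frame(term = "day", ss = NA, df = kw$df,
                                     F = kw$statistic, p = kw$p.value)
      }
    }
    bioRes <- list(foldChanges = fc$foldChanges, excluded = fc$excluded,
                   tests = bioStats)
  }
  seRes <- NULL
  if (!is.null(sideEffects)) {
    counts <- weeklySideEffectCounts(sideEffects)
    dec <- do.call(rbind, lapply(unique(counts$group), function(g) {
      w1 <- counts$events[counts$group == g & counts$week == 1]
      w3 <- counts$events[counts$group == g & counts$week == 3]
      data.frame(group = g, week1 = w1, week3 = w3,
                 percentDecrease = if (w1 > 0) percentDecrease(w1, w3) else NA)
    }))
    seRes <- list(weeklyCounts = counts, decline = dec)
  }

  cfg <- list(band = band, alpha = alpha, unit = unit, seed = as.integer(seed),
              nSessions = nrow(manifest), days = days)
  cfg$configHash <- .configHash(cfg)
  structure(list(
    bandPower = bandPower,
    plvSummary = plvSummary[, setdiff(names(plvSummary), "offDiagonal")],
    plvObservations = plvSummary,
    plvMatrices = plvMatrices,
    stats = statsTab,
    biomarkers = bioRes,
    sideEffects = seRes,
    config = cfg,
    warnings = unique(warnings),
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(session_path = character(), subject = character(),
                 day = numeric(), error = character())
  ), class = "ResultBundle")
}

#' @export
print.ResultBundle <- function(x, ...) {
  cat(sprintf("ResultBundle: %d sessions (%d failed), %d statistics rows\n",
              x$config$nSessions, nrow(x$failures),
              if (is.null(x$stats)) 0L else nrow(x$stats)))
  cat(sprintf("  band %g-%g Hz | unit: %s | config hash %s\n",
              x$config$band[1], x$config$band[2], x$config$unit,
              x$config$configHash))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Simulate a cohort of sessions to disk
#'
#' Generates one session per subject and day and writes it (plus its
#' ground-truth sidecar) under `dir`. Active subjects carry the entrained
#' component with day-wise declining amplitude and phase-locking
#' concentration, emulating habituation over repeated stimulation; sham
#' subjects have zero entrained amplitude. The day-wise amplitude defaults
#' were chosen so that the generator's closed-form expected normalized
#' power under the default background matches the group-mean trajectory the
#' pipeline is designed to detect (about 2.8/2.4/1.5 on days 1/5/19);
#' subject- and channel-level lognormal spread adds realistic
#' inter-individual variability.
#'
#' @param dir output directory (created if needed).
#' @param nActive,nSham group sizes.
#' @param days recording days.
#' @param segmentDurations seconds per condition (protocol-true by default;
#'   scale down for desk runs).
#' @param amplitudeByDay named per-day mean entrained amplitude, microvolts.
#' @param kappaByDay named per-day von Mises jitter concentration.
#' @param subjectSdLog,channelSdLog lognormal spread (SD of log) across
#'   subjects and channels.
#' @param format `"edf"` or `"text"`.
#' @param seed master seed; per-session seeds are derived deterministically.
#' @return manifest data frame (`session_path`, `subject`, `group`, `day`).
#' @export
simulateCohort <- function(dir, nActive = 8, nSham = 6, days = c(1, 5, 19),
                           segmentDurations = c(no_light = 300,
                                                constant_light = 300,
                                                stimulus = 1200),
                           amplitudeByDay = c(`1` = 1.06, `5` = 0.93,
                                              `19` = 0.58),
                           kappaByDay = c(`1` = 8, `5` = 6, `19` = 3),
                           subjectSdLog = 0.35, channelSdLog = 0.25,
                           format = "edf", seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- c(sprintf("A%02d", seq_len(nActive)),
                sprintf("S%02d", seq_len(nSham)))
  groups <- rep(c("active", "sham"), c(nActive, nSham))
  rows <- list()
  for (si in seq_along(subjects)) {
    set.seed(seed + 7919L * si)
    subjMult <- exp(stats::rnorm(1, 0, subjectSdLog))
    chMult <- exp(stats::rnorm(8, 0, channelSdLog))
    for (di in seq_along(days)) {
      d <- days[di]
      amp <- if (groups[si] == "active")
        amplitudeByDay[[as.character(d)]] * subjMult * chMult else rep(0, 8)
      cfg <- simulationConfig(
        segmentDurations = segmentDurations,
        entrainmentAmplitudes = amp,
        jitterKappa = kappaByDay[[as.character(d)]],
        seed = seed + 7919L * si + di)
      sess <- simulateSession(cfg, subject = subjects[si], day = d,
                              group = groups[si])
      ext <- if (format == "edf") "edf" else "tsv"
      path <- file.path(dir, sprintf("%s_day%02d.%s", subjects[si], d, ext))
      writeSession(sess$recording, path, truth = sess$truth, format = format)
      rows[[length(rows) + 1L]] <- data.frame(
        session_path = path, subject = subjects[si], group = groups[si],
        day = d)
    }
  }
  do.call(rbind, rows)
}

#' Write a result bundle to disk
#'
#' Emits the bundle's tables as TSV, a single JSON summary (configuration
#' echo, warnings, failure summary, headline statistics) and a per-stage
#' log file.
#'
#' @param bundle a `ResultBundle` from [runCohortAnalysis()].
#' @param path output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
emitReport <- function(bundle, path) {
  .assert(inherits(bundle, "ResultBundle"), "'bundle' must be a ResultBundle")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- c()
  logLines <- sprintf("[%s] emitReport start", format(t0))
  wtsv <- function(tab, name) {
    f <- file.path(path, name)
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- f
    logLines <<- c(logLines,
                   sprintf("[%s] wrote %s (%d rows)", format(Sys.time()),
                           name, nrow(tab)))
  }
  wtsv(bundle$bandPower, "band_power.tsv")
  wtsv(bundle$plvSummary, "plv_summary.tsv")
  plvLong <- do.call(rbind, lapply(names(bundle$plvMatrices), function(k) {
    m <- bundle$plvMatrices[[k]]@values
    idx <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(session = k, channelA = rownames(m)[idx[, 1]],
               channelB = colnames(m)[idx[, 2]], value = m[idx])
  }))
  if (!is.null(plvLong)) wtsv(plvLong, "plv_matrices.tsv")
  if (!is.null(bundle$stats)) wtsv(bundle$stats, "stats.tsv")
  if (!is.null(bundle$biomarkers)) {
    wtsv(bundle$biomarkers$foldChanges, "biomarker_fold_changes.tsv")
    if (nrow(bundle$biomarkers$excluded))
      wtsv(bundle$biomarkers$excluded, "biomarker_exclusions.tsv")
  }
  if (!is.null(bundle$sideEffects)) {
    wtsv(bundle$sideEffects$weeklyCounts, "side_effect_counts.tsv")
    wtsv(bundle$sideEffects$decline, "side_effect_decline.tsv")
  }
  if (nrow(bundle$failures)) wtsv(bundle$failures, "session_failures.tsv")
  headline <- if (!is.null(bundle$stats))
    bundle$stats[, c("family", "method", "statistic", "p.raw", "p.adjusted")]
  else NULL
  summaryFile <- file.path(path, "summary.json")
  jsonlite::write_json(list(
    config = bundle$config,
    warnings = bundle$warnings,
    nFailures = nrow(bundle$failures),
    failures = bundle$failures,
    headlineStatistics = headline
  ), summaryFile, digits = NA, auto_unbox = TRUE, na = "null")
  files[["summary.json"]] <- summaryFile
  logLines <- c(logLines, sprintf("[%s] emitReport done (%.2f s)",
                                  format(Sys.time()),
                                  as.numeric(Sys.time() - t0, units = "secs")))
  logFile <- file.path(path, "run.log")
  writeLines(logLines, logFile)
  files[["run.log"]] <- logFile
  invisible(unlist(files))
}
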