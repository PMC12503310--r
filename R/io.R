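#' @include AllClasses.R utils.R
NULL

# ---- minimal EDF (European Data Format) support -------------------------
# Continuous EDF with 1 s data records, int16 little-endian, one signal per
# EEG channel plus a "SYNC" signal. Recordings must span whole seconds
# (sessions defined in seconds always do). Physical dimension is uV for EEG
# channels and dimensionless for SYNC.

.edfPad <- function(x, width) {
  x <- as.character(x)
  .assert(all(nchar(x) <= width),
          sprintf("EDF header field too long: '%s'", x[which(nchar(x) > width)[1]]))
  formatC(x, width = -width)                 # left-justified, space padded
}

# numeric EDF header field, at most 8 ascii characters
.edfNum <- function(x) {
  vapply(x, function(v) {
    for (d in 6:1) {
      s <- sprintf("%.*g", d, v)
      if (nchar(s) <= 8) return(s)
    }
    stop(sprintf("cannot represent %g in an 8-character EDF field", v),
         call. = FALSE)
  }, "")
}

.writeEdf <- function(recording, path) {
  fs <- recording@samplingRate
  .assert(abs(fs - round(fs)) < 1e-9, "EDF export requires an integer sampling rate")
  dat <- rbind(recording@samples,
               SYNC = if (length(recording@sync)) recording@sync
                      else rep(0, ncol(recording@samples)))
  n <- ncol(dat)
  .assert(n %% fs == 0,
          "EDF export requires a whole number of seconds; use format='text' otherwise")
  nRec <- n / fs
  ns <- nrow(dat)
  labels <- c(recording@channelLabels, "SYNC")
  physMax <- pmax(apply(abs(dat), 1, max), 1e-6)
  physMax <- as.numeric(.edfNum(physMax))    # scale with the stored precision
  digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8),
    .edfPad(recording@metadata$subject %||% "X", 80),
    .edfPad(sprintf("group=%s day=%s", recording@metadata$group %||% "NA",
                    recording@metadata$day %||% "NA"), 80),
    .edfPad("01.01.26", 8), .edfPad("00.00.00", 8),
    .edfPad(256 * (1 + ns), 8),
    .edfPad("", 44),
    .edfPad(nRec, 8),
    .edfPad("1", 8),
    .edfPad(ns, 4),
    paste(.edfPad(labels, 16), collapse = ""),
    paste(.edfPad(rep("", ns), 80), collapse = ""),
    paste(.edfPad(c(rep("uV", ns - 1), ""), 8), collapse = ""),
    paste(.edfPad(.edfNum(-physMax), 8), collapse = ""),
    paste(.edfPad(.edfNum(physMax), 8), collapse = ""),
    paste(.edfPad(rep(-digMax, ns), 8), collapse = ""),
    paste(.edfPad(rep(digMax, ns), 8), collapse = ""),
    paste(.edfPad(rep("", ns), 80), collapse = ""),
    paste(.edfPad(rep(fs, ns), 8), collapse = ""),
    paste(.edfPad(rep("", ns), 32), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- digMax / physMax
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- pmin(pmax(round(dat[, idx, drop = FALSE] * scale), -digMax), digMax)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

.readEdfField <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

.readEdf <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  .assert(length(raw) >= 256,
          sprintf("truncated EDF '%s': only %d of 256 header bytes", path, length(raw)))
  nRec <- as.integer(.readEdfField(raw, 236, 8))
  recDur <- as.numeric(.readEdfField(raw, 244, 8))
  ns <- as.integer(.readEdfField(raw, 252, 4))
  hdrBytes <- 256L * (1L + ns)
  .assert(length(raw) >= hdrBytes,
          sprintf("truncated EDF '%s': header ends at byte %d but file has %d",
                  path, hdrBytes, length(raw)))
  fieldVec <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      .readEdfField(raw, 256 + offset * ns + (i - 1) * width, width), "")
  }
  labels <- fieldVec(0, 16)
  physMin <- as.numeric(fieldVec(16 + 80 + 8, 8))
  physMax <- as.numeric(fieldVec(16 + 80 + 8 + 8, 8))
  digMin <- as.numeric(fieldVec(16 + 80 + 8 + 16, 8))
  digMax <- as.numeric(fieldVec(16 + 80 + 8 + 24, 8))
  spr <- as.integer(fieldVec(16 + 80 + 8 + 8 + 8 + 8 + 8 + 80, 8))
  need <- hdrBytes + 2 * nRec * sum(spr)
  .assert(length(raw) >= need,
          sprintf("truncated EDF '%s': expected %d bytes of samples, file ends at byte %d",
                  path, need, length(raw)))
  con <- rawConnection(raw[(hdrBytes + 1):need])
  on.exit(close(con))
  out <- lapply(seq_len(ns), function(i) numeric(nRec * spr[i]))
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      out[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        physMin[i] + (v - digMin[i]) * (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    }
  }
  syncIdx <- which(toupper(labels) == "SYNC")
  .assert(length(syncIdx) == 1L,
          sprintf("EDF '%s' has no SYNC channel (signals: %s)",
                  path, paste(labels, collapse = ", ")))
  eeg <- setdiff(seq_len(ns), syncIdx)
  patient <- .readEdfField(raw, 8, 80)
  recInfo <- .readEdfField(raw, 88, 80)
  meta <- list(subject = patient)
  m <- regmatches(recInfo, regexec("group=(\\S+) day=(\\S+)", recInfo))[[1]]
  if (length(m) == 3) {
    meta$group <- m[2]
    dayNum <- suppressWarnings(as.numeric(m[3]))
    meta$day <- if (is.na(dayNum)) m[3] else dayNum
  }
  samples <- do.call(rbind, out[eeg])
  dimnames(samples) <- list(labels[eeg], NULL)
  new("EEGRecording",
    samples = samples,
    samplingRate = spr[eeg[1]] / recDur,
    channelLabels = labels[eeg],
    sync = out[[syncIdx]],
    metadata = meta)
}

# ---- delimited text support ---------------------------------------------
# UTF-8 tab-separated: leading '# key<TAB>value' metadata block, then a
# header row of channel labels (plus SYNC), one row per sample.

.writeText <- function(recording, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  md <- recording@metadata
  writeLines(sprintf("# sampling_rate\t%.10g", recording@samplingRate), con)
  for (key in c("subject", "group", "day"))
    if (!is.null(md[[key]]))
      writeLines(sprintf("# %s\t%s", key, md[[key]]), con)
  tab <- cbind(as.data.frame(t(recording@samples)),
               SYNC = if (length(recording@sync)) recording@sync else 0)
  names(tab) <- c(recording@channelLabels, "SYNC")
  utils::write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readText <- function(path) {
  lines <- readLines(path, n = 50L, encoding = "UTF-8")
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in metaLines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "\t")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  .assert(!is.null(meta$sampling_rate),
          sprintf("'%s' lacks the required '# sampling_rate' metadata line", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  labels <- colnames(tab)
  syncIdx <- which(toupper(labels) == "SYNC")
  .assert(length(syncIdx) == 1L,
          sprintf("'%s' has no SYNC column (columns: %s)",
                  path, paste(labels, collapse = ", ")))
  eeg <- setdiff(seq_along(labels), syncIdx)
  md <- list(subject = meta$subject %||% "unknown")
  if (!is.null(meta$group)) md$group <- meta$group
  if (!is.null(meta$day)) md$day <- suppressWarnings(as.numeric(meta$day))
  new("EEGRecording",
    samples = t(as.matrix(tab[, eeg, drop = FALSE])),
    samplingRate = as.numeric(meta$sampling_rate),
    channelLabels = labels[eeg],
    sync = tab[[syncIdx]],
    metadata = md)
}

#' Write a session to disk
#'
#' Writes an [EEGRecording-class] as either a minimal EDF file (one signal
#' per channel plus a `SYNC` signal, physical dimension microvolts) or a
#' tab-separated text file with a metadata block and a header row of channel
#' labels. When `truth` is supplied, a `<name>.truth.json` sidecar with the
#' generative ground truth is written alongside.
#'
#' @param recording an [EEGRecording-class].
#' @param path output file path.
#' @param truth optional [SimTruth-class] for the JSON sidecar.
#' @param format `"edf"` or `"text"`.
#' @return the path, invisibly.
#' @seealso [readRecording()]
#' @export
writeSession <- function(recording, path, truth = NULL,
                         format = c("edf", "text")) {
  if (length(format) == 1L && !format %in% c("edf", "text"))
    stop(sprintf("unsupported session format '%s' (use 'edf' or 'text')", format),
         call. = FALSE)
  format <- match.arg(format)
  validObject(recording)
  switch(format, edf = .writeEdf(recording, path),
         text = .writeText(recording, path))
  if (!is.null(truth)) {
    validObject(truth)
    sidecar <- paste0(sub("\\.(edf|tsv|txt)$", "", path), ".truth.json")
    jsonlite::write_json(
      list(expected_band_fraction = truth@expectedBandFraction,
           expected_plv = truth@expectedPlv,
           seed = truth@seed),
      sidecar, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  }
  invisible(path)
}

#' Read a session recording
#'
#' Reads an EDF or delimited-text session written by [writeSession()] (or
#' any file following the same conventions) into an [EEGRecording-class].
#' A missing SYNC channel or a truncated file is a hard error.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"text"`.
#' @return an [EEGRecording-class].
#' @export
readRecording <- function(path, format = c("auto", "edf", "text")) {
  format <- match.arg(format)
  .assert(file.exists(path), sprintf("file '%s' does not exist", path))
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  rec <- switch(format, edf = .readEdf(path), text = .readText(path))
  validObject(rec)
  rec
}

#' Read a ground-truth sidecar
#'
#' @param path path to a `.truth.json` sidecar (or to the session file whose
#'   sidecar should be located).
#' @return a [SimTruth-class].
#' @export
readTruth <- function(path) {
  if (!grepl("\\.truth\\.json$", path))
    path <- paste0(sub("\\.(edf|tsv|txt)$", "", path), ".truth.json")
  .assert(file.exists(path), sprintf("truth sidecar '%s' does not exist", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  plv <- as.matrix(j$expected_plv)
  dimnames(plv) <- NULL
  new("SimTruth",
    expectedBandFraction = as.numeric(j$expected_band_fraction),
    expectedPlv = plv,
    seed = as.integer(j$seed))
}
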