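#' @include utils.R
NULL

#' Percent decrease, rounded to the nearest integer
#'
#' `round(100 * (1 - later / reference))` with halves rounded away from
#' zero. A 2.8 to 1.54 drop gives 45; 9 to 2 events gives 78.
#'
#' @param reference baseline value (> 0).
#' @param later later value.
#' @return integer percent decrease (negative for an increase).
#' @examples
#' percentDecrease(2.8, 1.54)
#' percentDecrease(11, 3)
#' @export
percentDecrease <- function(reference, later) {
  if (any(reference <= 0))
    stop("reference value must be > 0", call. = FALSE)
  .roundHalfAway(100 * (1 - later / reference))
}

# parse "HH:MM" clock times to minutes since midnight
.clockMinutes <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 2 || anyNA(suppressWarnings(as.numeric(p[1:2]))))
      return(NA_real_)
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, 0)
}

#' Per-subject biomarker fold changes relative to day 1
#'
#' For each subject and analyte, every concentration is divided by that
#' subject's day-1 concentration (so the day-1 fold change is 1). Subjects
#' lacking a day-1 sample are excluded with a warning; when collection clock
#' times are available, subjects with any sample collected more than
#' `maxClockDriftMin` minutes from their day-1 collection time are excluded
#' (diurnal-variation control), with the reason logged.
#'
#' @param table data frame with columns `subject`, `group`, `day`,
#'   `analyte`, `concentration` and optionally `collectionTime` ("HH:MM" or
#'   minutes).
#' @param maxClockDriftMin allowed collection-time drift vs day 1, minutes.
#' @return list with `foldChanges` (data frame with added `foldChange`
#'   column) and `excluded` (data frame: subject, analyte, reason).
#' @export
foldChangeNormalize <- function(table, maxClockDriftMin = 60) {
  need <- c("subject", "group", "day", "analyte", "concentration")
  .assert(all(need %in% names(table)),
          paste("biomarker table needs columns:", paste(need, collapse = ", ")))
  .assert(all(table$concentration >= 0), "concentrations must be >= 0")
  hasTime <- "collectionTime" %in% names(table)
  out <- list(); excluded <- list()
  for (an in unique(table$analyte)) {
    sub <- table[table$analyte == an, , drop = FALSE]
    for (s in unique(sub$subject)) {
      rows <- sub[sub$subject == s, , drop = FALSE]
      d1 <- rows[rows$day == 1, , drop = FALSE]
      if (nrow(d1) == 0 || d1$concentration[1] <= 0) {
        reason <- if (nrow(d1) == 0) "no day-1 sample"
                  else "day-1 concentration is zero"
        warning(sprintf("subject %s excluded from %s analysis: %s",
                        s, an, reason), call. = FALSE)
        excluded[[length(excluded) + 1L]] <-
          data.frame(subject = s, analyte = an, reason = reason)
        next
      }
      if (hasTime) {
        t1 <- .clockMinutes(d1$collectionTime[1])
        drift <- abs(.clockMinutes(rows$collectionTime) - t1)
        if (any(!is.na(drift) & drift > maxClockDriftMin)) {
          bad <- rows$day[which(drift > maxClockDriftMin)[1]]
          reason <- sprintf(
            "day-%s sample collected %d min from the day-1 clock time (> %d min)",
            bad, round(max(drift, na.rm = TRUE)), maxClockDriftMin)
          excluded[[length(excluded) + 1L]] <-
            data.frame(subject = s, analyte = an, reason = reason)
          next
        }
      }
      rows$foldChange <- rows$concentration / d1$concentration[1]
      out[[length(out) + 1L]] <- rows
    }
  }
  list(
    foldChanges = if (length(out)) do.call(rbind, out) else
      cbind(table[0, , drop = FALSE], foldChange = numeric(0)),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(subject = character(), analyte = character(),
                 reason = character()))
}

.WEEK_DAYS <- list(`1` = 1:5, `2` = 8:12, `3` = 15:19)

#' Weekly side-effect event counts per group
#'
#' Sessions run on weekdays; week 1 covers session days 1-5, week 2 days
#' 8-12 and week 3 days 15-19. Counts are event totals, not subject totals.
#'
#' @param log data frame with columns `subject`, `group`, `day` (session day
#'   index 1-19, weekdays only) and `event`.
#' @return data frame with `group`, `week`, `events` (all group x week
#'   combinations, zeros included).
#' @export
weeklySideEffectCounts <- function(log) {
  need <- c("subject", "group", "day", "event")
  .assert(all(need %in% names(log)),
          paste("side-effect log needs columns:", paste(need, collapse = ", ")))
  validDays <- unlist(.WEEK_DAYS)
  if (nrow(log) && !all(log$day %in% validDays))
    stop(sprintf("invalid session day(s): %s (weekday sessions are %s)",
                 paste(unique(log$day[!log$day %in% validDays]), collapse = ", "),
                 paste(range(validDays), collapse = "-")), call. = FALSE)
  groups <- sort(unique(as.character(log$group)))
  if (!length(groups)) groups <- c("active", "sham")
  out <- expand.grid(group = groups, week = 1:3, stringsAsFactors = FALSE)
  out$events <- mapply(function(g, w) {
    sum(log$group == g & log$day %in% .WEEK_DAYS[[as.character(w)]])
  }, out$group, out$week)
  out[order(out$group, out$week), ]
}
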