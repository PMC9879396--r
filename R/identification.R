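# Identification accuracy: time-period handling, confusion counts per
# stratum, and the accuracy / false-negative / false-positive rates with
# their cross-period summaries.
#
# Rates are record-level. The accuracy denominator is all image-bearing
# records; the false-negative denominator is records determined to be
# eagles; the false-positive denominator is records determined to be
# non-eagles. The two error rates therefore live on disjoint denominators
# and do not sum to one.

#' Define study time periods
#'
#' @param name Character vector of period names.
#' @param start,end Dates (or `"%Y-%m-%d"` strings), inclusive on both ends.
#' @param excluded A list, one element per period, each `NULL` or a data
#'   frame with `start`, `end` date columns of excluded ranges (inclusive);
#'   excluded ranges must lie inside their period.
#' @return A data frame of class `time_periods` with a list-column
#'   `excluded`. Periods must not overlap.
#' @export
time_periods <- function(name, start, end, excluded = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(length(name) == length(start), length(start) == length(end))
  if (any(start > end)) stop("period start after end")
  if (is.null(excluded)) excluded <- vector("list", length(name))
  stopifnot(length(excluded) == length(name))
  excluded <- lapply(excluded, function(ex) {
    if (is.null(ex) || nrow(ex) == 0L) return(NULL)
    data.frame(start = as.Date(ex$start), end = as.Date(ex$end))
  })
  for (i in seq_along(name)) {
    ex <- excluded[[i]]
    if (!is.null(ex) && (any(ex$start < start[i]) || any(ex$end > end[i]))) {
      stop("excluded range outside period ", name[i])
    }
  }
  ord <- order(start)
  if (any(utils::head(end[ord], -1) >= utils::tail(start[ord], -1))) {
    stop("periods overlap")
  }
  out <- data.frame(name = name, start = start, end = end,
                    stringsAsFactors = FALSE)
  out$excluded <- excluded
  class(out) <- c("time_periods", "data.frame")
  out
}

#' Study periods of the assessed deployment
#'
#' The five configuration periods of the year-long California deployment,
#' 21 Jun 2018 to 20 Jun 2019, with 2-19 Apr 2019 excluded from the fourth
#' period (system clock uncalibrated).
#'
#' @return A `time_periods` data frame with five rows.
#' @export
default_periods <- function() {
  time_periods(
    name = c("Original configuration", "IdentiFlight system update",
             "Equipment issue", "Equipment replacement",
             "Neural network upgrade"),
    start = c("2018-06-21", "2018-09-08", "2018-10-20", "2019-02-27",
              "2019-04-26"),
    end = c("2018-08-31", "2018-10-19", "2019-02-26", "2019-04-25",
            "2019-06-20"),
    excluded = list(NULL, NULL, NULL,
                    data.frame(start = "2019-04-02", end = "2019-04-19"),
                    NULL)
  )
}

#' Assign dates to periods
#'
#' @param dates A Date vector (timestamps are assigned by their UTC date).
#' @param periods A [time_periods()] table.
#' @return Character vector of period names; `NA` for dates falling in no
#'   period or in an excluded range (such records are dropped downstream).
#' @export
assign_period <- function(dates, periods) {
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (i in seq_len(nrow(periods))) {
    hit <- dates >= periods$start[i] & dates <= periods$end[i]
    ex <- periods$excluded[[i]]
    if (!is.null(ex)) {
      for (j in seq_len(nrow(ex))) {
        hit <- hit & !(dates >= ex$start[j] & dates <= ex$end[j])
      }
    }
    out[hit] <- periods$name[i]
  }
  out
}

#' Read / write period definitions (JSON)
#'
#' Periods are serialized as a JSON list of
#' `{name, start, end, excluded: [[start, end], ...]}`.
#'
#' @param path File path.
#' @return `read_periods()`: a [time_periods()] table.
#' @export
read_periods <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  time_periods(
    name = vapply(raw, `[[`, character(1), "name"),
    start = vapply(raw, `[[`, character(1), "start"),
    end = vapply(raw, `[[`, character(1), "end"),
    excluded = lapply(raw, function(p) {
      ex <- p$excluded
      if (is.null(ex) || length(ex) == 0L) return(NULL)
      data.frame(start = vapply(ex, `[[`, character(1), 1L),
                 end = vapply(ex, `[[`, character(1), 2L))
    })
  )
}

#' @rdname read_periods
#' @param periods A [time_periods()] table.
#' @export
write_periods <- function(periods, path) {
  lst <- lapply(seq_len(nrow(periods)), function(i) {
    ex <- periods$excluded[[i]]
    list(name = periods$name[i],
         start = as.character(periods$start[i]),
         end = as.character(periods$end[i]),
         excluded = if (is.null(ex)) list() else
           lapply(seq_len(nrow(ex)), function(j)
             list(as.character(ex$start[j]), as.character(ex$end[j]))))
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

CONFUSION_CELLS <- c("n_eagle_correct", "n_eagle_as_noneagle",
                     "n_noneagle_as_eagle", "n_noneagle_correct",
                     "n_noimage_as_eagle", "n_noimage_as_noneagle")

#' Construct a confusion-count table from raw counts
#'
#' One row per stratum. Cells are record counts: eagles identified as eagles
#' (`n_eagle_correct`), eagles identified as non-eagles (false negatives),
#' non-eagles identified as eagles (false positives), non-eagles identified
#' as non-eagles, and the two bookkeeping cells for records whose track had
#' no reviewable image.
#'
#' @param period,tower Stratum keys (tower optional, `NA` when unstratified).
#' @param n_eagle_correct,n_eagle_as_noneagle,n_noneagle_as_eagle,n_noneagle_correct,n_noimage_as_eagle,n_noimage_as_noneagle
#'   Non-negative record counts.
#' @return A data frame of class `confusion_counts`.
#' @export
confusion_counts <- function(period, n_eagle_correct, n_eagle_as_noneagle,
                             n_noneagle_as_eagle, n_noneagle_correct,
                             n_noimage_as_eagle = 0,
                             n_noimage_as_noneagle = 0, tower = NA) {
  df <- data.frame(period = period, tower = tower,
                   n_eagle_correct = n_eagle_correct,
                   n_eagle_as_noneagle = n_eagle_as_noneagle,
                   n_noneagle_as_eagle = n_noneagle_as_eagle,
                   n_noneagle_correct = n_noneagle_correct,
                   n_noimage_as_eagle = n_noimage_as_eagle,
                   n_noimage_as_noneagle = n_noimage_as_noneagle,
                   stringsAsFactors = FALSE)
  if (any(as.matrix(df[CONFUSION_CELLS]) < 0)) stop("negative counts")
  class(df) <- c("confusion_counts", "data.frame")
  df
}

#' Build confusion counts from records and determinations
#'
#' Each record increments exactly one cell of exactly one stratum, chosen by
#' the track's adjudicated determination (rows) and the system's label
#' (columns). Records dated outside all periods (gaps between periods,
#' excluded ranges) are dropped; their count is attached as attribute
#' `n_dropped`.
#'
#' @param records Record data frame (after the multi-target filter).
#' @param determinations Data frame `track_id`, `determination` as produced
#'   by [assemble_tracks()].
#' @param periods A [time_periods()] table.
#' @param by_tower Stratify by camera tower as well as period?
#' @return A `confusion_counts` data frame, one row per stratum, zero-filled.
#' @export
build_confusion <- function(records, determinations, periods,
                            by_tower = FALSE) {
  det <- determinations$determination[match(records$track_id,
                                            determinations$track_id)]
  if (anyNA(det)) {
    stop("record with no determination for track ",
         records$track_id[is.na(det)][1])
  }
  per <- assign_period(as.Date(records$timestamp, tz = "UTC"), periods)
  keep <- !is.na(per)
  n_dropped <- sum(!keep)
  recs <- records[keep, , drop = FALSE]
  det <- det[keep]; per <- per[keep]
  strata <- if (by_tower) {
    expand.grid(period = periods$name,
                tower = unique(records$tower_id),
                stringsAsFactors = FALSE)
  } else {
    data.frame(period = periods$name, tower = NA, stringsAsFactors = FALSE)
  }
  sysl <- recs$system_label
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    in_s <- per == strata$period[i]
    if (by_tower) in_s <- in_s & recs$tower_id == strata$tower[i]
    confusion_counts(
      period = strata$period[i], tower = strata$tower[i],
      n_eagle_correct = sum(in_s & det == "eagle" & sysl == "eagle"),
      n_eagle_as_noneagle = sum(in_s & det == "eagle" & sysl == "non-eagle"),
      n_noneagle_as_eagle = sum(in_s & det == "non-eagle" & sysl == "eagle"),
      n_noneagle_correct = sum(in_s & det == "non-eagle" &
                                 sysl == "non-eagle"),
      n_noimage_as_eagle = sum(in_s & det == "no-image" & sysl == "eagle"),
      n_noimage_as_noneagle = sum(in_s & det == "no-image" &
                                    sysl == "non-eagle")
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confusion_counts", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Collapse confusion strata to totals
#'
#' @param counts A `confusion_counts` data frame.
#' @return A one-row `confusion_counts` with period `"Total"`.
#' @export
total_confusion <- function(counts) {
  tot <- as.list(colSums(as.matrix(counts[CONFUSION_CELLS])))
  do.call(confusion_counts, c(list(period = "Total"), tot))
}

rate_guard <- function(num, den, what, strict = TRUE) {
  if (any(den == 0)) {
    if (strict) stop("undefined ", what, ": zero denominator")
    warning("undefined ", what, " in some strata: zero denominator")
  }
  ifelse(den == 0, NA_real_, num / den)
}

#' Identification accuracy rate
#'
#' Correct identifications over all image-bearing records analysed;
#' no-image cells never enter the denominator.
#'
#' @param counts A `confusion_counts` data frame (vectorized over rows).
#' @param strict Error on a zero denominator (`TRUE`, default) or warn and
#'   return `NA` for the affected strata.
#' @return Numeric vector of proportions.
#' @export
accuracy_rate <- function(counts, strict = TRUE) {
  rate_guard(counts$n_eagle_correct + counts$n_noneagle_correct,
             counts$n_eagle_correct + counts$n_eagle_as_noneagle +
               counts$n_noneagle_as_eagle + counts$n_noneagle_correct,
             "accuracy", strict)
}

#' False-negative rate
#'
#' Eagles identified as non-eagles, over records determined to be eagles.
#'
#' @inheritParams accuracy_rate
#' @return Numeric vector of proportions.
#' @export
false_negative_rate <- function(counts, strict = TRUE) {
  rate_guard(counts$n_eagle_as_noneagle,
             counts$n_eagle_correct + counts$n_eagle_as_noneagle,
             "false-negative rate", strict)
}

#' False-positive rate
#'
#' Non-eagles identified as eagles, over records determined to be
#' non-eagles.
#'
#' @inheritParams accuracy_rate
#' @return Numeric vector of proportions.
#' @export
false_positive_rate <- function(counts, strict = TRUE) {
  rate_guard(counts$n_noneagle_as_eagle,
             counts$n_noneagle_as_eagle + counts$n_noneagle_correct,
             "false-positive rate", strict)
}

#' Cross-period rate summary
#'
#' Unweighted mean and sample (n-1) standard deviation of period-level
#' rates. Unweighted, because periods are the comparison unit: each system
#' configuration counts once regardless of how many records it produced.
#'
#' @param rates Numeric vector of per-period rates (length >= 2); `NA`
#'   rates (undefined strata) are dropped.
#' @return A list with `mean` and `sd`.
#' @export
cross_period_summary <- function(rates) {
  if (length(rates) < 2L) stop("sd undefined for fewer than 2 periods")
  rates <- rates[!is.na(rates)]
  list(mean = mean(rates), sd = stats::sd(rates))
}

#' Published per-period confusion counts
#'
#' Loads the packaged per-period identification counts of the assessed
#' deployment (five configuration periods plus no-image bookkeeping rows)
#' as a `confusion_counts` table.
#'
#' @return A `confusion_counts` data frame with five rows.
#' @export
reference_confusion <- function() {
  path <- system.file("extdata", "reference_confusion.csv",
                      package = "curtailr", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  do.call(confusion_counts, c(list(period = df$period), df[CONFUSION_CELLS]))
}

#' Identification rate report
#'
#' Per-period accuracy, false-negative and false-positive rates plus the
#' grand-total rates and cross-period mean/sd, from a confusion table.
#'
#' @param counts A `confusion_counts` data frame with one row per period.
#' @return A list: `per_period` (data frame of rates), `total` (rates on the
#'   collapsed counts), `across_periods` (mean/sd per rate type).
#' @export
identification_report <- function(counts) {
  per <- data.frame(
    period = counts$period,
    accuracy = accuracy_rate(counts, strict = FALSE),
    false_negative_rate = false_negative_rate(counts, strict = FALSE),
    false_positive_rate = false_positive_rate(counts, strict = FALSE),
    stringsAsFactors = FALSE
  )
  tot <- total_confusion(counts)
  list(
    per_period = per,
    total = list(accuracy = accuracy_rate(tot),
                 false_negative_rate = false_negative_rate(tot),
                 false_positive_rate = false_positive_rate(tot),
                 n_records = sum(as.matrix(counts[CONFUSION_CELLS])),
                 n_system_eagle = tot$n_eagle_correct +
                   tot$n_noneagle_as_eagle + tot$n_noimage_as_eagle,
                 n_determined_eagle = tot$n_eagle_correct +
                   tot$n_eagle_as_noneagle),
    across_periods = list(
      accuracy = cross_period_summary(per$accuracy),
      false_negative_rate = cross_period_summary(per$false_negative_rate),
      false_positive_rate = cross_period_summary(per$false_positive_rate)
    )
  )
}
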