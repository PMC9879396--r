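# Curtailment-order assessment: pairing orders with adjudicated target
# identities, per-week standardization, distance-class summary tables, and
# the effectiveness proportions.

#' Pair curtailment orders with target determinations
#'
#' Orders on image-less tracks cannot be assigned a target identity; they
#' are excluded from the assessment but counted. All other orders take their
#' track's adjudicated determination as target class.
#'
#' @param orders Order data frame (see [run_orders()]).
#' @param determinations Data frame `track_id`, `determination` from
#'   [assemble_tracks()].
#' @return A list: `paired` (orders with a `target_class` column, eagle or
#'   non-eagle) and `excluded` (count of no-image orders). Conservation:
#'   `nrow(paired) + excluded == nrow(orders)`.
#' @export
pair_orders <- function(orders, determinations) {
  det <- determinations$determination[match(orders$track_id,
                                            determinations$track_id)]
  if (anyNA(det)) {
    stop("order references unknown track ", orders$track_id[is.na(det)][1])
  }
  keep <- det != "no-image"
  paired <- orders[keep, , drop = FALSE]
  paired$target_class <- det[keep]
  list(paired = paired, excluded = sum(!keep))
}

#' Effective length of a period in weeks
#'
#' Inclusive calendar day count minus excluded days, divided by 7. An
#' `effective_days` column on the period table, when present and non-`NA`,
#' overrides the calendar count (the deployment's own per-week figures imply
#' slightly shorter effective periods than the calendar).
#'
#' @param periods A [time_periods()] table.
#' @return Numeric vector of weeks, one per period.
#' @export
period_weeks <- function(periods) {
  days <- as.numeric(periods$end - periods$start) + 1
  ex_days <- vapply(periods$excluded, function(ex) {
    if (is.null(ex)) 0 else sum(as.numeric(ex$end - ex$start) + 1)
  }, numeric(1))
  days <- days - ex_days
  if (!is.null(periods$effective_days)) {
    ov <- !is.na(periods$effective_days)
    days[ov] <- periods$effective_days[ov]
  }
  if (any(days <= 0)) stop("non-positive period length")
  days / 7
}

#' Summarize curtailment orders by period, target class and distance
#'
#' One row per (period, target class, distance class) stratum, zero-filled,
#' with order counts, total duration in hours, and per-week rates. Orders
#' are assigned to periods by their start time; orders starting outside all
#' periods are dropped and counted in attribute `n_dropped`. When a
#' `coverage` map is supplied the summary is additionally split by turbine
#' coverage class.
#'
#' @param paired Paired order data frame (see [pair_orders()]).
#' @param periods A [time_periods()] table.
#' @param coverage Optional named character vector mapping turbine id to
#'   coverage class (`"full"` / `"partial"`).
#' @return A data frame of class `order_summary`.
#' @export
summarize_orders <- function(paired, periods, coverage = NULL) {
  per <- assign_period(as.Date(paired$start, tz = "UTC"), periods)
  keep <- !is.na(per)
  n_dropped <- sum(!keep)
  po <- paired[keep, , drop = FALSE]
  per <- per[keep]
  wk <- period_weeks(periods)
  names(wk) <- periods$name
  keys <- list(period = periods$name,
               target_class = c("eagle", "non-eagle"),
               distance_class = c("far", "near", "within"))
  if (!is.null(coverage)) {
    keys$coverage <- sort(unique(coverage))
    po$coverage <- unname(coverage[po$turbine_id])
  }
  grid <- do.call(expand.grid,
                  c(keys, list(stringsAsFactors = FALSE,
                               KEEP.OUT.ATTRS = FALSE)))
  key_of <- function(df, p) {
    k <- paste(p, df$target_class, df$distance_class)
    if (!is.null(coverage)) k <- paste(k, df$coverage)
    k
  }
  gkey <- key_of(grid, grid$period)
  okey <- key_of(po, per)
  cnt <- table(factor(okey, levels = gkey))
  dur <- tapply(po$duration_h, factor(okey, levels = gkey), sum)
  grid$n_orders <- as.integer(cnt)
  grid$total_duration_h <- ifelse(is.na(dur), 0, dur)
  grid$period_weeks <- unname(wk[grid$period])
  grid$rate_per_week <- grid$n_orders / grid$period_weeks
  grid$duration_per_week_h <- grid$total_duration_h / grid$period_weeks
  class(grid) <- c("order_summary", "data.frame")
  attr(grid, "n_dropped") <- n_dropped
  grid
}

#' Effectiveness proportions of a curtailment campaign
#'
#' An effective curtailment is one issued for an intended target (an eagle)
#' actually at risk. Two readings of "at risk" are reported: entry into the
#' rotor-swept zone, and coming within 100 m of it.
#'
#' @param paired Paired order data frame (see [pair_orders()]).
#' @return A list: `eagle_within_share` (eagle orders that entered the RSZ,
#'   over all paired orders), `eagle_effective_share` (eagle orders near or
#'   within the RSZ, over eagle orders), `noneagle_eagle_ratio` (non-eagle
#'   to eagle order ratio), plus the component counts.
#' @export
effectiveness_metrics <- function(paired) {
  n <- nrow(paired)
  if (n == 0L) stop("no paired orders")
  eagle <- paired$target_class == "eagle"
  n_eagle <- sum(eagle)
  n_noneagle <- n - n_eagle
  if (n_eagle == 0L) stop("no eagle orders: ratios undefined")
  n_eagle_within <- sum(eagle & paired$distance_class == "within")
  n_eagle_near_within <- sum(eagle & paired$distance_class %in%
                               c("near", "within"))
  list(
    n_orders = n, n_eagle = n_eagle, n_noneagle = n_noneagle,
    n_eagle_within = n_eagle_within,
    eagle_within_share = n_eagle_within / n,
    eagle_effective_share = n_eagle_near_within / n_eagle,
    noneagle_eagle_ratio = n_noneagle / n_eagle
  )
}

#' Published per-period curtailment-order counts
#'
#' Loads the packaged order counts of the assessed deployment (five
#' configuration periods x eagle / non-eagle x three distance classes) and
#' expands them into one pseudo-order per counted order, dated at the start
#' of its period, so the summary pipeline can be exercised against the
#' published totals. Durations reproduce the published class means (0.0631 h
#' per eagle order, 0.0554 h per non-eagle order).
#'
#' @return A paired order data frame (see [pair_orders()]).
#' @export
reference_orders <- function() {
  path <- system.file("extdata", "reference_orders.csv",
                      package = "curtailr", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  periods <- default_periods()
  rows <- df[rep(seq_len(nrow(df)), df$n_orders), , drop = FALSE]
  start <- periods$start[match(rows$period, periods$name)]
  closest <- c(far = 150, near = 50, within = -10)[rows$distance_class]
  mean_dur <- c(eagle = 53.6 / 850, `non-eagle` = 301.3 / 5439)
  dur <- unname(mean_dur[rows$target_class])
  out <- data.frame(
    order_id = sprintf("ref_%05d", seq_len(nrow(rows))),
    turbine_id = "T01",
    track_id = sprintf("ref_trk_%05d", seq_len(nrow(rows))),
    tower_id = "C1",
    start = as.POSIXct(paste(start, "12:00:00"), tz = "UTC"),
    closest_m = unname(closest),
    distance_class = rows$distance_class,
    target_class = rows$target_class,
    stringsAsFactors = FALSE
  )
  out$end <- out$start + dur * 3600
  out$duration_h <- dur
  out
}

#' Write an order summary and metrics to disk
#'
#' @param summary An `order_summary` data frame.
#' @param metrics Output of [effectiveness_metrics()].
#' @param dir Output directory.
#' @return Invisibly, the paths written (`summary.csv`, `metrics.json`).
#' @export
write_order_report <- function(summary, metrics, dir) {
  sp <- file.path(dir, "summary.csv")
  mp <- file.path(dir, "metrics.json")
  utils::write.csv(as.data.frame(summary), sp, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(metrics, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(sp, mp))
}
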