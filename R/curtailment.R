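# The curtailment prescription engine.
#
# A curtailment order is issued for a turbine while a tracked target is
# (a) identified as an eagle with confidence above the threshold, and
# (b) either inside the outer decision cylinder with a projected time to
# collision at or below the limit, or inside the inner cylinder outright.
# Orders are released a fixed hold after conditions were last met, and
# re-triggers inside the hold extend the same order.

#' Curtailment prescription configuration
#'
#' @param confidence_threshold Eagle-confidence threshold; the rule fires
#'   only strictly above it (default 0.89).
#' @param ttc_limit Time-to-collision limit, seconds (default 60).
#' @param outer_cylinder_radius Radius of the outer (far) decision cylinder,
#'   metres; defaults to the 1000 m camera detection range.
#' @param inner_cylinder_radius Radius of the inner (near) decision
#'   cylinder, metres; default 100 m, matching the 0-100 m distance bin.
#' @param cylinder_height_cap Height of both cylinders above the turbine
#'   base, metres; default 207 m (twice the blade-tip height).
#' @param release_hold Seconds an order stays open after conditions were
#'   last met (default 180).
#' @return An object of class `prescription_config`.
#' @export
prescription_config <- function(confidence_threshold = 0.89,
                                ttc_limit = 60,
                                outer_cylinder_radius = 1000,
                                inner_cylinder_radius = 100,
                                cylinder_height_cap = 207,
                                release_hold = 180) {
  stopifnot(confidence_threshold > 0, confidence_threshold <= 1,
            ttc_limit > 0, inner_cylinder_radius < outer_cylinder_radius,
            inner_cylinder_radius > 0, cylinder_height_cap > 0,
            release_hold >= 0)
  structure(
    list(confidence_threshold = confidence_threshold,
         ttc_limit = ttc_limit,
         outer_cylinder_radius = outer_cylinder_radius,
         inner_cylinder_radius = inner_cylinder_radius,
         cylinder_height_cap = cylinder_height_cap,
         release_hold = release_hold),
    class = "prescription_config"
  )
}

#' Read / write a prescription configuration (JSON)
#'
#' @param path File path.
#' @return `read_prescription()`: a [prescription_config()].
#' @export
read_prescription <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(prescription_config,
          raw[intersect(names(raw), names(formals(prescription_config)))])
}

#' @rdname read_prescription
#' @param cfg A [prescription_config()].
#' @export
write_prescription <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Estimate per-record velocities along a track
#'
#' Central finite differences over adjacent records, one-sided at the track
#' ends. A single-record track has no usable difference and returns `NA`
#' velocity, which disables the time-to-collision clause (only the inner
#' cylinder can then fire).
#'
#' @param pos n x 3 matrix of positions, metres.
#' @param times POSIXct or numeric timestamps, seconds.
#' @return n x 3 matrix of velocities, m/s.
#' @export
track_velocity <- function(pos, times) {
  n <- nrow(pos)
  t <- as.numeric(times)
  v <- matrix(NA_real_, n, 3)
  if (n < 2L) return(v)
  idx_lo <- c(1L, seq_len(n - 1L))        # backward neighbour (self at start)
  idx_hi <- c(seq_len(n - 1L) + 1L, n)    # forward neighbour (self at end)
  dt <- t[idx_hi] - t[idx_lo]
  ok <- dt > 0
  for (k in 1:3) {
    v[ok, k] <- (pos[idx_hi[ok], k] - pos[idx_lo[ok], k]) / dt[ok]
  }
  v
}

#' Per-record prescription test
#'
#' @param records Records of a single track (data frame).
#' @param velocity n x 3 velocity matrix (see [track_velocity()]).
#' @param turbine A [turbine_spec()].
#' @param cfg A [prescription_config()].
#' @return Logical vector: conditions met at each record.
#' @export
conditions_met <- function(records, velocity, turbine, cfg) {
  p <- cbind(records$x_m, records$y_m, records$z_m)
  conf_ok <- records$system_label == "eagle" &
    records$confidence > cfg$confidence_threshold
  inner <- in_cylinder(p, turbine, cfg$inner_cylinder_radius,
                       cfg$cylinder_height_cap)
  outer <- in_cylinder(p, turbine, cfg$outer_cylinder_radius,
                       cfg$cylinder_height_cap)
  ttc <- time_to_collision(p, velocity, turbine)
  ttc[is.na(ttc)] <- Inf  # undefined velocity: the approach clause is off
  conf_ok & (inner | (outer & ttc <= cfg$ttc_limit))
}

distance_class <- function(d) {
  ifelse(d <= 0, "within", ifelse(d <= 100, "near", "far"))
}

#' Closest approach of a track to a turbine
#'
#' Minimum signed RSZ distance over all of a track's records; negative means
#' the track entered the rotor-swept zone.
#'
#' @param records Records of a single track.
#' @param turbine A [turbine_spec()].
#' @return Numeric scalar, metres.
#' @export
closest_approach <- function(records, turbine) {
  p <- cbind(records$x_m, records$y_m, records$z_m)
  min(distance_to_rsz(p, turbine))
}

#' Run the order state machine over tracks
#'
#' For each track and each turbine, an order opens at the first record where
#' [conditions_met()] holds and closes `release_hold` seconds after the last
#' qualifying record; qualifying records inside an open hold extend the same
#' order, so orders for one (track, turbine) pair never overlap. The
#' closest-approach distance is computed over the whole track and attached
#' to each of its orders.
#'
#' @param records Record data frame (one or many tracks, time-ordered within
#'   track).
#' @param turbines List of [turbine_spec()] objects.
#' @param cfg A [prescription_config()].
#' @return A data frame of orders: `order_id`, `turbine_id`, `track_id`,
#'   `tower_id`, `start`, `end` (POSIXct), `duration_h`, `closest_m`,
#'   `distance_class` (`far` / `near` / `within`).
#' @export
run_orders <- function(records, turbines, cfg = prescription_config()) {
  empty <- data.frame(order_id = character(), turbine_id = character(),
                      track_id = character(), tower_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_h = numeric(), closest_m = numeric(),
                      distance_class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  out <- list(empty)
  for (tid in unique(records$track_id)) {
    tr <- records[records$track_id == tid, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    vel <- track_velocity(cbind(tr$x_m, tr$y_m, tr$z_m), tr$timestamp)
    # cheap screen: a track that never carries a qualifying label cannot fire
    if (!any(tr$system_label == "eagle" &
             tr$confidence > cfg$confidence_threshold)) next
    for (tb in turbines) {
      met <- conditions_met(tr, vel, tb, cfg)
      if (!any(met)) next
      qt <- as.numeric(tr$timestamp[met])
      # merge qualifying instants whose holds touch or overlap
      brk <- which(diff(qt) > cfg$release_hold)
      grp_start <- c(1L, brk + 1L)
      grp_end <- c(brk, length(qt))
      closest <- closest_approach(tr, tb)
      ord <- data.frame(
        order_id = sprintf("%s_%s_%02d", tid, tb$turbine_id,
                           seq_along(grp_start)),
        turbine_id = tb$turbine_id,
        track_id = tid,
        tower_id = tr$tower_id[1],
        start = as.POSIXct(qt[grp_start], origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(qt[grp_end] + cfg$release_hold,
                         origin = "1970-01-01", tz = "UTC"),
        closest_m = closest,
        distance_class = distance_class(closest),
        stringsAsFactors = FALSE
      )
      ord$duration_h <- as.numeric(ord$end - ord$start, units = "hours")
      out[[length(out) + 1L]] <- ord[names(empty)]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read curtailment orders (CSV)
#'
#' @param orders Order data frame from [run_orders()].
#' @param path File path.
#' @return `read_orders()`: the order data frame.
#' @export
write_orders <- function(orders, path) {
  out <- orders
  out$start <- format_utc(out$start)
  out$end <- format_utc(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_orders
#' @export
read_orders <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(order_id = "character",
                                       turbine_id = "character",
                                       track_id = "character",
                                       tower_id = "character"))
  df$start <- parse_utc(df$start)
  df$end <- parse_utc(df$end)
  df
}
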