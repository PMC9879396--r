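# Shared fixtures and independent oracles.
#
# The brute-force prescription oracle below deliberately re-implements the
# curtailment rule with its own arithmetic (explicit norms, its own velocity
# differencing, literal interval merging) so that run_orders() is checked
# against a second code path, not against itself.

T0 <- as.POSIXct("2018-07-01 12:00:00", tz = "UTC")

test_turbine <- function(id = "T01", x = 0, y = 0) {
  turbine_spec(id, x, y, hub_height = 65, rotor_diameter = 77)
}

# build a record data frame from a position matrix at 1 Hz
make_track <- function(track_id, pos, t0 = T0, label = "eagle",
                       confidence = 0.95, tower_id = "C1",
                       has_image = TRUE, target_index = 0L) {
  n <- nrow(pos)
  data.frame(
    track_id = track_id, tower_id = tower_id,
    timestamp = t0 + (seq_len(n) - 1),
    x_m = pos[, 1], y_m = pos[, 2], z_m = pos[, 3],
    system_label = rep(label, length.out = n),
    confidence = rep(confidence, length.out = n),
    has_image = rep(has_image, length.out = n),
    target_index = rep(as.integer(target_index), length.out = n),
    stringsAsFactors = FALSE
  )
}

# independent velocity estimate: explicit per-row loop
oracle_velocity <- function(pos, times) {
  n <- nrow(pos)
  t <- as.numeric(times)
  v <- matrix(NA_real_, n, 3)
  if (n < 2) return(v)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1)
    hi <- min(n, i + 1)
    dt <- t[hi] - t[lo]
    if (dt > 0) v[i, ] <- (pos[hi, ] - pos[lo, ]) / dt
  }
  v
}

# literal per-record re-statement of the prescription rule
oracle_conditions <- function(tr, vel, tb, cfg) {
  n <- nrow(tr)
  out <- logical(n)
  cx <- tb$x; cy <- tb$y; cz <- tb$hub_height
  r <- tb$rotor_diameter / 2
  for (i in seq_len(n)) {
    if (!(tr$system_label[i] == "eagle" &&
          tr$confidence[i] > cfg$confidence_threshold)) next
    hx <- tr$x_m[i] - cx; hy <- tr$y_m[i] - cy
    horiz <- sqrt(hx^2 + hy^2)
    in_height <- tr$z_m[i] >= 0 && tr$z_m[i] <= cfg$cylinder_height_cap
    inner <- horiz <= cfg$inner_cylinder_radius && in_height
    outer <- horiz <= cfg$outer_cylinder_radius && in_height
    ttc_ok <- FALSE
    if (outer && !anyNA(vel[i, ])) {
      dx <- cx - tr$x_m[i]; dy <- cy - tr$y_m[i]; dz <- cz - tr$z_m[i]
      dc <- sqrt(dx^2 + dy^2 + dz^2)
      signed <- dc - r
      if (signed <= 0) {
        ttc_ok <- TRUE
      } else if (dc > 0) {
        s <- (vel[i, 1] * dx + vel[i, 2] * dy + vel[i, 3] * dz) / dc
        ttc_ok <- s > 0 && signed / s <= cfg$ttc_limit
      }
    }
    out[i] <- inner || ttc_ok
  }
  out
}

# reconstruct the full order set by literal interval merging
oracle_orders <- function(records, turbines, cfg) {
  rows <- list()
  for (tid in unique(records$track_id)) {
    tr <- records[records$track_id == tid, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    vel <- oracle_velocity(cbind(tr$x_m, tr$y_m, tr$z_m), tr$timestamp)
    for (tb in turbines) {
      met <- oracle_conditions(tr, vel, tb, cfg)
      if (!any(met)) next
      qt <- as.numeric(tr$timestamp)[met]
      start <- qt[1]; last <- qt[1]
      for (q in qt[-1]) {
        if (q - last > cfg$release_hold) {
          rows[[length(rows) + 1]] <- data.frame(
            track_id = tid, turbine_id = tb$turbine_id,
            start = start, end = last + cfg$release_hold)
          start <- q
        }
        last <- q
      }
      rows[[length(rows) + 1]] <- data.frame(
        track_id = tid, turbine_id = tb$turbine_id,
        start = start, end = last + cfg$release_hold)
    }
  }
  if (!length(rows)) {
    return(data.frame(track_id = character(), turbine_id = character(),
                      start = numeric(), end = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$turbine_id, out$start), , drop = FALSE]
}

# canonical key for comparing order sets
order_key <- function(df) {
  sort(sprintf("%s|%s|%.0f|%.0f", df$track_id, df$turbine_id,
               as.numeric(df$start), as.numeric(df$end)))
}
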