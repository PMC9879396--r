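# Synthetic input bundles: correlated-random-walk flight tracks around a
# turbine layout, a confusion-model classifier with per-period error rates,
# and noisy dual reviews. Everything is deterministic under a fixed seed so
# the whole pipeline is testable without field data.

#' Simulation configuration
#'
#' Defaults state the emulated world: a target population heavily skewed
#' toward non-eagles (common ravens are over 140 times more abundant than
#' golden eagles in the study region, hence `eagle_fraction = 1/141`),
#' ~1 Hz record streams in tracks of 10-600 s, per-period misclassification
#' rates equal to those derived from the published per-period confusion
#' counts, and occasional image-less tracks and multi-target instants.
#'
#' @param seed Integer RNG seed.
#' @param n_tracks Number of tracks to generate.
#' @param eagle_fraction Probability a track's true species is an eagle.
#' @param periods A [time_periods()] table; track dates are drawn uniformly
#'   from the non-excluded days of these periods.
#' @param fn_rates,fp_rates Named numeric vectors (by period name) of
#'   record-level false-negative and false-positive probabilities. Defaults
#'   are the five per-period rates implied by [reference_confusion()].
#' @param conf_eagle,conf_noneagle Beta shape pairs for the confidence of
#'   eagle-labelled and non-eagle-labelled records. With the defaults
#'   roughly 55 percent of eagle-labelled confidences exceed 0.89.
#' @param speed_range Ground-speed range, m/s (cruising raptor flight).
#' @param turn_sd Standard deviation of the per-second heading change,
#'   radians; smaller is straighter flight.
#' @param altitude_band Flight altitude band above ground, metres.
#' @param duration_range Track duration range, seconds.
#' @param p_no_image Probability a track records no image at all.
#' @param p_multi_target Probability a track contains one multi-target
#'   instant (a second bird in the same image).
#' @param p_transit Share of tracks forced to fly a straight transit through
#'   a randomly chosen rotor-swept zone, so all distance classes occur.
#' @param reviewer_error Per-reviewer mislabel probability used when a
#'   bundle is generated.
#' @param track_level_errors Flip the classifier per track instead of per
#'   record (the published rates are record-level; track-level is offered
#'   because the real system identifies within tracks).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_tracks = 200L,
                       eagle_fraction = 1 / 141,
                       periods = default_periods(),
                       fn_rates = NULL, fp_rates = NULL,
                       conf_eagle = c(18, 2), conf_noneagle = c(2, 6),
                       speed_range = c(5, 15), turn_sd = 0.25,
                       altitude_band = c(20, 150),
                       duration_range = c(10, 600),
                       p_no_image = 0.005, p_multi_target = 0.01,
                       p_transit = 0.15, reviewer_error = 0.02,
                       track_level_errors = FALSE) {
  if (is.null(fn_rates) || is.null(fp_rates)) {
    ref <- reference_confusion()
    if (is.null(fn_rates)) {
      fn_rates <- stats::setNames(false_negative_rate(ref), ref$period)
    }
    if (is.null(fp_rates)) {
      fp_rates <- stats::setNames(false_positive_rate(ref), ref$period)
    }
  }
  stopifnot(eagle_fraction >= 0, eagle_fraction <= 1,
            all(fn_rates >= 0 & fn_rates <= 1),
            all(fp_rates >= 0 & fp_rates <= 1),
            all(speed_range > 0), turn_sd >= 0,
            p_no_image >= 0 && p_no_image <= 1,
            p_multi_target >= 0 && p_multi_target <= 1,
            p_transit >= 0 && p_transit <= 1,
            reviewer_error >= 0 && reviewer_error < 0.5,
            all(periods$name %in% names(fn_rates)),
            all(periods$name %in% names(fp_rates)))
  structure(
    list(seed = as.integer(seed), n_tracks = as.integer(n_tracks),
         eagle_fraction = eagle_fraction, periods = periods,
         fn_rates = fn_rates, fp_rates = fp_rates,
         conf_eagle = conf_eagle, conf_noneagle = conf_noneagle,
         speed_range = speed_range, turn_sd = turn_sd,
         altitude_band = altitude_band, duration_range = duration_range,
         p_no_image = p_no_image, p_multi_target = p_multi_target,
         p_transit = p_transit, reviewer_error = reviewer_error,
         track_level_errors = track_level_errors),
    class = "sim_config"
  )
}

#' A small demonstration layout
#'
#' Two camera towers and three turbines spanning all coverage classes.
#'
#' @return A list with `turbines` and `cameras`.
#' @export
default_layout <- function() {
  list(
    turbines = list(
      turbine_spec("T01", 400, 0),
      turbine_spec("T02", 900, 450),
      turbine_spec("T03", 1200, -100)
    ),
    cameras = list(
      camera_tower("C1", 0, 0),
      camera_tower("C2", 1500, 0)
    )
  )
}

# uniform draw of one day from the non-excluded days of the periods
sample_period_days <- function(periods, n) {
  days <- do.call(c, lapply(seq_len(nrow(periods)), function(i) {
    d <- seq(periods$start[i], periods$end[i], by = "day")
    ex <- periods$excluded[[i]]
    if (!is.null(ex)) {
      for (j in seq_len(nrow(ex))) {
        d <- d[d < ex$start[j] | d > ex$end[j]]
      }
    }
    d
  }))
  days[sample.int(length(days), n, replace = TRUE)]
}

#' Straight-line transit track positions
#'
#' Positions of a constant-velocity flight aimed at the centre of a
#' turbine's rotor-swept zone, sampled at 1 Hz. Useful as a kinematic test
#' bed and used internally for forced-transit tracks.
#'
#' @param turbine A [turbine_spec()].
#' @param start_dist Start distance from the RSZ centre, metres.
#' @param speed Ground speed, m/s.
#' @param n_steps Number of 1 Hz samples.
#' @param bearing Horizontal approach bearing, radians.
#' @return An n x 3 position matrix.
#' @export
straight_transit <- function(turbine, start_dist = 700, speed = 10,
                             n_steps = 2 * ceiling(start_dist / speed),
                             bearing = 0) {
  ctr <- rsz_center(turbine)
  dir3 <- c(cos(bearing), sin(bearing), 0)
  start <- ctr - start_dist * dir3
  t <- seq_len(n_steps) - 1
  cbind(start[1] + speed * t * dir3[1],
        start[2] + speed * t * dir3[2],
        rep(start[3], n_steps))
}

crw_positions <- function(n, origin, speed_range, turn_sd, altitude_band) {
  speed <- stats::runif(1, speed_range[1], speed_range[2])
  heading <- stats::runif(1, 0, 2 * pi)
  dh <- stats::rnorm(n - 1, 0, turn_sd)
  h <- heading + cumsum(c(0, dh))
  x <- origin[1] + cumsum(c(0, speed * cos(h[-n])))
  y <- origin[2] + cumsum(c(0, speed * sin(h[-n])))
  z0 <- stats::runif(1, altitude_band[1], altitude_band[2])
  dz <- stats::rnorm(n - 1, 0, 1)
  z <- pmin(pmax(z0 + cumsum(c(0, dz)), altitude_band[1]), altitude_band[2])
  cbind(x, y, z)
}

#' Simulate flight tracks
#'
#' Correlated random walks at 1 Hz spawned inside camera detection range,
#' with a configurable share of straight transits through a randomly chosen
#' rotor-swept zone. True species labels are Bernoulli draws with
#' `eagle_fraction`.
#'
#' @param cfg A [sim_config()].
#' @param layout A list with `turbines` and `cameras` (see
#'   [default_layout()]).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A list: `records` (data frame without system labels yet: columns
#'   `track_id`, `tower_id`, `timestamp`, `x_m`, `y_m`, `z_m`, `has_image`,
#'   `target_index`) and `truth` (data frame `track_id`, `species`).
#' @export
simulate_tracks <- function(cfg, layout = default_layout(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_tracks
  cams <- layout$cameras
  turbs <- layout$turbines
  species <- ifelse(stats::runif(n) < cfg$eagle_fraction,
                    "eagle", "non-eagle")
  days <- sample_period_days(cfg$periods, n)
  tod <- stats::runif(n, 6 * 3600, 18 * 3600)   # daylight operations
  no_image <- stats::runif(n) < cfg$p_no_image
  multi <- stats::runif(n) < cfg$p_multi_target
  transit <- stats::runif(n) < cfg$p_transit
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    tid <- sprintf("trk_%05d", i)
    dur <- round(stats::runif(1, cfg$duration_range[1],
                              cfg$duration_range[2]))
    cam <- cams[[sample.int(length(cams), 1)]]
    if (transit[i] && length(turbs) > 0L) {
      tb <- turbs[[sample.int(length(turbs), 1)]]
      speed <- stats::runif(1, cfg$speed_range[1], cfg$speed_range[2])
      pos <- straight_transit(tb,
                              start_dist = stats::runif(1, 500, 900),
                              speed = speed,
                              n_steps = dur,
                              bearing = stats::runif(1, 0, 2 * pi))
    } else {
      r <- cam$detection_range * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      pos <- crw_positions(dur, c(cam$x + r * cos(th), cam$y + r * sin(th)),
                           cfg$speed_range, cfg$turn_sd, cfg$altitude_band)
    }
    t0 <- as.POSIXct(days[i], tz = "UTC") + tod[i]
    df <- data.frame(
      track_id = tid, tower_id = cam$tower_id,
      timestamp = t0 + (seq_len(dur) - 1),
      x_m = pos[, 1], y_m = pos[, 2], z_m = pos[, 3],
      has_image = !no_image[i], target_index = 0L,
      stringsAsFactors = FALSE
    )
    if (multi[i] && dur > 1L) {
      j <- sample.int(dur, 1)
      extra <- df[j, , drop = FALSE]
      extra$target_index <- 1L
      df <- rbind(df[seq_len(j), ], extra,
                  if (j < dur) df[(j + 1):dur, ] else NULL)
    }
    recs[[i]] <- df
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records,
       truth = data.frame(track_id = sprintf("trk_%05d", seq_len(n)),
                          species = species, stringsAsFactors = FALSE))
}

#' Simulate the classifier's labels and confidences
#'
#' Each record of a true eagle is mislabelled non-eagle with the
#' false-negative probability of its period; each record of a true
#' non-eagle is mislabelled eagle with the period's false-positive
#' probability. Confidence is drawn from the emitted label's Beta
#' distribution. With `track_level_errors` the flip is drawn once per
#' (track, period) and applied to all its records.
#'
#' @param records Record data frame from [simulate_tracks()].
#' @param truth Truth data frame from [simulate_tracks()].
#' @param cfg A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return The records with `system_label` and `confidence` columns filled.
#' @export
simulate_classifier <- function(records, truth, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- truth$species[match(records$track_id, truth$track_id)]
  per <- assign_period(as.Date(records$timestamp, tz = "UTC"), cfg$periods)
  if (anyNA(per)) {
    stop("record outside all periods at row ", which(is.na(per))[1])
  }
  p_flip <- ifelse(species == "eagle",
                   cfg$fn_rates[per], cfg$fp_rates[per])
  if (cfg$track_level_errors) {
    key <- paste(records$track_id, per)
    u_by_key <- stats::setNames(stats::runif(length(unique(key))),
                                unique(key))
    flip <- u_by_key[key] < p_flip
  } else {
    flip <- stats::runif(nrow(records)) < p_flip
  }
  label <- ifelse(xor(species == "eagle", flip), "eagle", "non-eagle")
  conf <- numeric(nrow(records))
  is_e <- label == "eagle"
  conf[is_e] <- stats::rbeta(sum(is_e), cfg$conf_eagle[1], cfg$conf_eagle[2])
  conf[!is_e] <- stats::rbeta(sum(!is_e), cfg$conf_noneagle[1],
                              cfg$conf_noneagle[2])
  records$system_label <- label
  records$confidence <- conf
  records
}

#' Simulate dual reviewer determinations
#'
#' Two independent noisy readings of the true species; a third reviewer
#' (also noisy) is generated exactly when the first two disagree.
#'
#' @param truth Truth data frame from [simulate_tracks()].
#' @param reviewer_error Per-reviewer mislabel probability (< 0.5).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A review-set data frame (see [read_reviews()]).
#' @export
simulate_reviews <- function(truth, reviewer_error = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(reviewer_error >= 0, reviewer_error < 0.5)
  n <- nrow(truth)
  noisy <- function() {
    flip <- stats::runif(n) < reviewer_error
    ifelse(xor(truth$species == "eagle", flip), "eagle", "non-eagle")
  }
  r1 <- noisy(); r2 <- noisy(); r3 <- noisy()
  r3[r1 == r2] <- NA
  data.frame(track_id = truth$track_id, reviewer_1 = r1, reviewer_2 = r2,
             reviewer_3 = r3, stringsAsFactors = FALSE)
}

#' Generate and write a complete synthetic bundle
#'
#' Runs [simulate_tracks()], [simulate_classifier()] and
#' [simulate_reviews()] under `cfg$seed` and writes `records.csv`,
#' `reviews.csv`, `turbines.csv`, `cameras.csv`, `periods.json` and
#' `truth.csv` into `dir`. Reviews cover only tracks with at least one
#' image (image-less tracks cannot be reviewed).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param layout Site layout (see [default_layout()]).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_bundle <- function(cfg, dir, layout = default_layout()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  sim <- simulate_tracks(cfg, layout)
  records <- simulate_classifier(sim$records, sim$truth, cfg)
  reviewable <- unique(records$track_id[records$has_image])
  reviews <- simulate_reviews(sim$truth[sim$truth$track_id %in% reviewable,
                                        , drop = FALSE],
                              reviewer_error = cfg$reviewer_error)
  write_records(records, file.path(dir, "records.csv"))
  utils::write.csv(reviews, file.path(dir, "reviews.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  write_layout(layout$turbines, layout$cameras, dir)
  write_periods(cfg$periods, file.path(dir, "periods.json"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(records = records, reviews = reviews, truth = sim$truth,
                 layout = layout))
}
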