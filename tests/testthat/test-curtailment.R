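test_that("prescription_config validates thresholds", {
  cfg <- prescription_config()
  expect_equal(cfg$confidence_threshold, 0.89)
  expect_equal(cfg$ttc_limit, 60)
  expect_equal(cfg$release_hold, 180)
  expect_error(prescription_config(inner_cylinder_radius = 2000), "inner")
  expect_error(prescription_config(ttc_limit = -5))
})

test_that("prescription config round-trips through JSON", {
  cfg <- prescription_config(ttc_limit = 45, release_hold = 120)
  p <- withr::local_tempfile(fileext = ".json")
  write_prescription(cfg, p)
  expect_equal(read_prescription(p), cfg)
})

test_that("track_velocity uses central differences with one-sided ends", {
  pos <- cbind(c(0, 10, 20, 40), c(0, 0, 0, 0), c(50, 50, 50, 50))
  t <- T0 + c(0, 1, 2, 3)
  v <- track_velocity(pos, t)
  expect_equal(v[, 1], c(10, 10, 15, 20))  # fwd, central, central, bwd
  expect_true(all(is.na(track_velocity(pos[1, , drop = FALSE], t[1]))))
})

test_that("conditions_met implements the decision rule", {
  tb <- test_turbine()
  cfg <- prescription_config()
  # inside the inner cylinder, receding: fires on the position clause alone
  rec <- make_track("t", matrix(c(50, 0, 65), 1), confidence = 0.95)
  vel <- matrix(c(20, 0, 0), 1)
  expect_true(conditions_met(rec, vel, tb, cfg))
  # sub-threshold confidence never fires (strict >)
  rec$confidence <- 0.85
  expect_false(conditions_met(rec, vel, tb, cfg))
  rec$confidence <- 0.89
  expect_false(conditions_met(rec, vel, tb, cfg))
  # outer cylinder with a slow approach: TTC 90 s > 60 s, outside inner
  rec <- make_track("t", matrix(c(488.5, 0, 65), 1), confidence = 0.95)
  expect_false(conditions_met(rec, matrix(c(-5, 0, 0), 1), tb, cfg))
  # same geometry, faster: TTC = 450/10 = 45 s
  expect_true(conditions_met(rec, matrix(c(-10, 0, 0), 1), tb, cfg))
  # a non-eagle label never fires, whatever the confidence
  rec$system_label <- "non-eagle"
  expect_false(conditions_met(rec, matrix(c(-10, 0, 0), 1), tb, cfg))
})

test_that("raising the TTC limit never shrinks the qualifying set", {
  tb <- test_turbine()
  set.seed(13)
  cfg0 <- sim_config(seed = 13, n_tracks = 30, duration_range = c(5, 40),
                     eagle_fraction = 1)
  sim <- simulate_tracks(cfg0, default_layout(), seed = 13)
  recs <- simulate_classifier(sim$records, sim$truth, cfg0)
  prev <- -1L
  for (lim in c(15, 30, 60, 120, 240)) {
    cfg <- prescription_config(ttc_limit = lim)
    n_met <- 0L
    for (tid in unique(recs$track_id)) {
      tr <- recs[recs$track_id == tid, ]
      vel <- track_velocity(cbind(tr$x_m, tr$y_m, tr$z_m), tr$timestamp)
      n_met <- n_met + sum(conditions_met(tr, vel, tb, cfg))
    }
    expect_gte(n_met, prev)
    prev <- n_met
  }
})

test_that("run_orders opens, holds, merges and releases as specified", {
  tb <- test_turbine("T01", 0, 0)
  cfg <- prescription_config()
  # hovering inside the inner cylinder for 31 records (t = 0..30), then gone
  pos <- rbind(matrix(rep(c(10, 0, 65), 31), ncol = 3, byrow = TRUE),
               matrix(rep(c(5000, 5000, 65), 10), ncol = 3, byrow = TRUE))
  tr <- make_track("t1", pos)
  ords <- run_orders(tr, list(tb), cfg)
  expect_equal(nrow(ords), 1)
  expect_equal(as.numeric(ords$start - T0, units = "secs"), 0)
  expect_equal(as.numeric(ords$end - T0, units = "secs"), 30 + 180)
  expect_equal(ords$duration_h, 210 / 3600)
  expect_identical(ords$distance_class, "within")

  # re-trigger inside the hold window extends the same order
  pos2 <- rbind(matrix(rep(c(10, 0, 65), 31), ncol = 3, byrow = TRUE),
                matrix(rep(c(5000, 5000, 65), 69), ncol = 3, byrow = TRUE),
                matrix(rep(c(10, 0, 65), 11), ncol = 3, byrow = TRUE))
  tr2 <- make_track("t2", pos2)
  ords2 <- run_orders(tr2, list(tb), cfg)
  expect_equal(nrow(ords2), 1)
  expect_equal(as.numeric(ords2$end - T0, units = "secs"), 110 + 180)

  # a gap longer than the hold splits into two orders
  pos3 <- rbind(matrix(rep(c(10, 0, 65), 11), ncol = 3, byrow = TRUE),
                matrix(rep(c(5000, 5000, 65), 200), ncol = 3, byrow = TRUE),
                matrix(rep(c(10, 0, 65), 5), ncol = 3, byrow = TRUE))
  ords3 <- run_orders(make_track("t3", pos3), list(tb), cfg)
  expect_equal(nrow(ords3), 2)
  expect_true(all(ords3$duration_h >= cfg$release_hold / 3600))
  # no overlap between consecutive orders of one (track, turbine)
  expect_true(ords3$start[2] > ords3$end[1])
})

test_that("an unreachable confidence threshold emits zero orders", {
  cfg0 <- sim_config(seed = 17, n_tracks = 20, duration_range = c(5, 40),
                     eagle_fraction = 1)
  d <- withr::local_tempdir()
  b <- simulate_bundle(cfg0, d)
  cfg <- prescription_config(confidence_threshold = 1.0)
  ords <- run_orders(b$records, default_layout()$turbines, cfg)
  expect_equal(nrow(ords), 0)
})

test_that("closest_approach matches closed-form tangential geometry", {
  tb <- test_turbine()
  # fly along x at perpendicular offset such that min distance to centre is
  # 500 m (3-4-5: offset 400 horizontally, 300 vertically from hub height)
  pos <- cbind(seq(-2000, 2000, by = 10), rep(400, 401), rep(65 + 300, 401))
  tr <- make_track("tan", pos)
  expect_equal(closest_approach(tr, tb), 500 - 38.5, tolerance = 1e-9)
  # one record inside the RSZ: negative, class "within"
  inside <- make_track("in", matrix(c(10, 0, 65), 1))
  expect_lt(closest_approach(inside, tb), 0)
  ords <- run_orders(inside, list(tb), prescription_config())
  expect_identical(ords$distance_class, "within")
})

test_that("trigger instant on a straight transit matches a 0.1 s fine-step oracle", {
  tb <- test_turbine()
  cfg <- prescription_config()
  set.seed(29)
  for (rep in 1:6) {
    speed <- stats::runif(1, 6, 14)
    bearing <- stats::runif(1, 0, 2 * pi)
    start_dist <- stats::runif(1, 650, 900)
    pos <- straight_transit(tb, start_dist = start_dist, speed = speed,
                            bearing = bearing)
    tr <- make_track(sprintf("s%d", rep), pos, confidence = 0.99)
    ords <- run_orders(tr, list(tb), cfg)
    expect_equal(nrow(ords), 1)
    got <- as.numeric(ords$start - T0, units = "secs")
    # oracle: continuous-time point on the same ray, 0.1 s steps; first
    # instant where signed distance / speed <= limit (head-on closure)
    tt <- seq(0, nrow(pos) - 1, by = 0.1)
    dist_t <- (start_dist - speed * tt) - rsz_radius(tb)
    qualify <- dist_t <= cfg$ttc_limit * speed
    t_star <- tt[which(qualify)[1]]
    # the engine fires at the first 1 Hz record after t_star
    expect_lte(abs(got - ceiling(t_star)), 1)
  }
})
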