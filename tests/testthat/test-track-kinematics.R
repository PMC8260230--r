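# node registration -------------------------------------------------------

test_that("registration to a stationary node at the origin is the identity", {
  trk <- make_track(1, t = 0:5, x = 10 + 0:5, y = 2 * (0:5))
  node <- data.frame(t_min = 0:5, x_um = 0, y_um = 0)
  expect_equal(register_to_node(trk, node), trk)
})

test_that("a cell comoving with the node is stationary after registration", {
  node <- data.frame(t_min = 0:10, x_um = 0, y_um = 2 * (0:10))
  trk <- make_track(1, t = 0:10, x = rep(5, 11), y = 7 + 2 * (0:10))
  reg <- register_to_node(trk, node)
  expect_equal(reg$y_um, rep(7, 11))
  expect_equal(reg$x_um, rep(5, 11))
  expect_equal(track_velocities(reg)$v_ap, rep(0, 10))
})

test_that("registering and un-registering round-trips to 1e-9 um", {
  set.seed(31)
  trk <- do.call(rbind, lapply(1:5, function(i)
    make_track(i, t = sort(runif(8, 0, 100)),
               x = rnorm(8, 50), y = rnorm(8, 500, 100))))
  node <- data.frame(t_min = seq(0, 100, by = 5),
                     x_um = rnorm(21), y_um = cumsum(runif(21, 0, 10)))
  reg <- register_to_node(trk, node)
  unreg <- reg
  nx <- approx(node$t_min, node$x_um, reg$t_min)$y
  ny <- approx(node$t_min, node$y_um, reg$t_min)$y
  unreg$x_um <- reg$x_um + nx; unreg$y_um <- reg$y_um + ny
  expect_equal(unreg$x_um, trk$x_um, tolerance = 1e-9)
  expect_equal(unreg$y_um, trk$y_um, tolerance = 1e-9)
})

test_that("samples outside the node time span are an error", {
  trk <- make_track(1, t = c(0, 50), x = c(0, 0), y = c(0, 0))
  node <- data.frame(t_min = 0:10, x_um = 0, y_um = 0)
  expect_error(register_to_node(trk, node), "outside")
})

# velocities and angles ----------------------------------------------------

test_that("velocity sign conventions follow convergence toward the midline", {
  v1 <- track_velocities(make_track(1, t = c(0, 10), x = c(10, 0),
                                    y = c(0, 0)))
  expect_equal(v1$v_lm, 1)   # moving toward x = 0 from the right
  expect_equal(v1$v_ap, 0)
  v2 <- track_velocities(make_track(1, t = c(0, 10), x = c(-10, -20),
                                    y = c(0, 50)))
  expect_equal(v2$v_lm, -1)  # moving away from the midline on the left
  expect_equal(v2$v_ap, 5)
})

test_that("a constant-velocity track yields the programmed velocity at every step", {
  t <- seq(0, 60, by = 4)
  trk <- make_track(1, t = t, x = 200 - 0.7 * t, y = 100 + 1.2 * t)
  v <- track_velocities(trk)
  expect_equal(v$v_lm, rep(0.7, length(t) - 1), tolerance = 1e-9)
  expect_equal(v$v_ap, rep(1.2, length(t) - 1), tolerance = 1e-9)
  expect_equal(v$t, (t[-1] + t[-length(t)]) / 2)
})

test_that("non-increasing times are an error", {
  trk <- make_track(1, t = c(0, 0), x = c(0, 1), y = c(0, 1))
  expect_error(track_velocities(trk), "strictly increasing")
})

test_that("midline angle spans 0 to 90 degrees with NA at zero displacement", {
  expect_equal(midline_angle(0, 3), 0)
  expect_equal(midline_angle(2, 2), 45)
  expect_equal(midline_angle(5, 0), 90)
  expect_true(is.na(midline_angle(0, 0)))
  # reflection invariance across the midline
  set.seed(32)
  vl <- rnorm(50); va <- rnorm(50)
  expect_equal(midline_angle(vl, va), midline_angle(-vl, va))
})

test_that("angle fractions bin per-track means with 45 degrees in the upper bin", {
  # purely AP-directed motion
  trk <- rbind(make_track(1, t = 0:5, x = rep(10, 6), y = 0:5),
               make_track(2, t = 0:5, x = rep(-20, 6), y = 2 * (0:5)))
  rep1 <- angle_fraction_report(trk)
  expect_equal(rep1$frac_0_45, 1)
  # a single track at exactly 45 degrees counts as convergent
  d45 <- make_track(1, t = 0:5, x = 100 - (0:5), y = 0:5)
  rep2 <- angle_fraction_report(d45)
  expect_equal(rep2$frac_45_90, 1)
  expect_error(angle_fraction_report(trk, region = list(x = c(900, 999),
                                                        y = c(900, 999))),
               "no velocity samples")
})

test_that("convergence/drift ratios set the angle regime by region", {
  p <- track_gen_params(
    n_cells = 400, duration = 60, frame_interval = 4, node_speed = 1,
    convergence_profile = function(y) 0.001 * y,
    ap_drift_profile = function(y) pmax(0, 1 - y / 2000),
    ingression_hazard_profile = function(y) rep(0, length(y)),
    division_rate_profile = function(y) rep(0, length(y)),
    position_noise_sd = 0.5, x_range = c(200, 500), seed = 33)
  sim <- simulate_tracks(p)
  ant <- angle_fraction_report(sim$tracks,
                               region = list(x = c(-Inf, Inf), y = c(0, 500)))
  post <- angle_fraction_report(sim$tracks,
                                region = list(x = c(-Inf, Inf),
                                              y = c(1200, 2100)))
  expect_gt(ant$frac_0_45, post$frac_0_45)
  expect_gt(post$frac_45_90, 0.5)
  expect_gt(ant$frac_0_45, 0.5)
})

# speed profiles -----------------------------------------------------------

test_that("speed profile recovers a programmed linear convergence gradient", {
  p <- track_gen_params(
    n_cells = 800, duration = 60, frame_interval = 4, node_speed = 1,
    convergence_profile = function(y) 0.001 * y,
    ap_drift_profile = function(y) pmax(0, 1 - y / 2000),
    ingression_hazard_profile = function(y) rep(0, length(y)),
    division_rate_profile = function(y) rep(0, length(y)),
    position_noise_sd = 0.5, x_range = c(200, 500), seed = 34)
  sim <- simulate_tracks(p)
  sp <- speed_profile(sim$tracks, ap_bin_width = 50, time_bin_width = 120)
  sp <- sp[!sp$empty & sp$n >= 20, ]
  fit <- lm(mean_v_lm ~ ap_bin_center, data = sp, weights = sp$n)
  expect_lt(abs(coef(fit)[[2]] - 0.001) / 0.001, 0.10)
})

test_that("empty bins are flagged missing and singletons have no SD", {
  trk <- make_track(1, t = c(0, 4), x = c(100, 99), y = c(25, 25))
  trk2 <- make_track(2, t = c(0, 4), x = c(100, 99), y = c(225, 225))
  sp <- speed_profile(rbind(trk, trk2), ap_bin_width = 50,
                      time_bin_width = 30)
  expect_true(any(sp$empty))
  expect_true(all(is.na(sp$mean_v_lm[sp$empty])))
  filled <- sp[!sp$empty, ]
  expect_true(all(filled$n == 1))
  expect_true(all(is.na(filled$sd_v_lm)))
  expect_equal(filled$mean_v_lm, rep(0.25, 2))
  expect_error(speed_profile(trk, ap_bin_width = 0), "positive")
})

test_that("comoving tracks have near-zero AP speed in every bin after registration", {
  p <- det_track_params(n_cells = 50, duration = 60, frame_interval = 4,
                        convergence = 0, drift = 1.5, noise = 0, seed = 35)
  sim <- simulate_tracks(p)
  reg <- register_to_node(sim$tracks, sim$node)
  sp <- speed_profile(reg, ap_bin_width = 100, time_bin_width = 120)
  expect_true(all(abs(sp$mean_v_ap[!sp$empty]) < 1e-9))
})

# longevity ----------------------------------------------------------------

test_that("longevity ratios are exact on hand-built cohorts", {
  # 4 tracks at t0; 3 alive at 1 h; 2 at 2 h
  trk <- rbind(
    make_track(1, t = seq(0, 120, 4), x = 10, y = 10),
    make_track(2, t = seq(0, 120, 4), x = 12, y = 12),
    make_track(3, t = seq(0, 100, 4), x = 14, y = 14, status = "ingressed"),
    make_track(4, t = seq(0, 40, 4), x = 16, y = 16, status = "ingressed"))
  lg <- track_longevity(trk, list(all = NULL), t0 = 0)
  expect_equal(lg$n_t0, 4)
  expect_equal(lg$ratio_1h, 0.75)
  expect_equal(lg$ratio_2h, 0.5)
  expect_true(lg$ratio_2h <= lg$ratio_1h)
})

test_that("without censoring all ratios are 1", {
  p <- det_track_params(n_cells = 20, duration = 120, frame_interval = 4,
                        convergence = 0.1, seed = 36)
  lg <- track_longevity(simulate_tracks(p)$tracks, list(all = NULL), t0 = 0)
  expect_equal(lg$ratio_1h, 1)
  expect_equal(lg$ratio_2h, 1)
})

test_that("longevity under uniform hazard matches the binomial oracle", {
  p <- det_track_params(n_cells = 500, duration = 120, frame_interval = 4,
                        convergence = 0.2, hazard = 0.05, seed = 37)
  lg <- track_longevity(simulate_tracks(p)$tracks, list(all = NULL), t0 = 0)
  expected <- 0.95^15
  se <- sqrt(expected * (1 - expected) / 500)
  expect_lt(abs(lg$ratio_1h - expected), 3 * se)
  expect_lte(lg$ratio_2h, lg$ratio_1h)
})

test_that("divisions censor tracks only when lineage survival is off", {
  # mother divides at 30 min; both daughters persist to 120 min
  mother <- make_track(1, t = seq(0, 28, 4), x = 10, y = 10,
                       status = "divided")
  d1 <- make_track(2, t = seq(28, 120, 4), x = 10, y = 10, parent = 1L)
  d2 <- make_track(3, t = seq(28, 120, 4), x = 11, y = 11, parent = 1L)
  trk <- rbind(mother, d1, d2)
  on_ <- track_longevity(trk, list(all = NULL), t0 = 0, lineage = TRUE)
  off <- track_longevity(trk, list(all = NULL), t0 = 0, lineage = FALSE)
  expect_equal(on_$ratio_1h, 1)   # cohort is the mother; lineage survives
  expect_equal(off$ratio_1h, 0)
})

test_that("track persistence responds monotonically to the programmed hazard", {
  surv <- vapply(c(0.1, 0.05, 0.01), function(h) {
    p <- det_track_params(n_cells = 300, duration = 120, frame_interval = 4,
                          convergence = 0.2, hazard = h, seed = 38)
    track_longevity(simulate_tracks(p)$tracks, list(all = NULL),
                    t0 = 0)$ratio_1h
  }, numeric(1))
  expect_true(all(diff(surv) > 0))
})

# ingression intensity -----------------------------------------------------

test_that("a uniform image fits a zero slope and is flagged", {
  stack <- list(matrix(5, 40, 40))
  axis <- cbind(c(20, 20), c(0, 40))
  ic <- ingression_intensity(stack, axis, ap_bin_width = 10,
                             band_halfwidth = 10)
  expect_equal(ic$fits$slope, 0)
  expect_true(is.na(ic$fits$r_squared))
  expect_true(ic$fits$flagged)
})

test_that("a linear AP intensity gradient is recovered within 5%", {
  set.seed(39)
  h <- 100; w <- 40
  a <- 0.8; b <- 10
  base <- outer(seq_len(h) - 0.5, rep(1, w)) * a + b
  stack <- list(base + matrix(rnorm(h * w, 0, 1), h, w))  # SNR >> 10
  axis <- cbind(c(20, 20), c(0, 100))  # vertical axis, AP along rows
  ic <- ingression_intensity(stack, axis, ap_bin_width = 10,
                             band_halfwidth = 20)
  expect_false(ic$fits$flagged)
  expect_lt(abs(ic$fits$slope - a) / a, 0.05)
  expect_gt(ic$fits$r_squared, 0.99)
})

test_that("a steepening generator schedule yields monotone slopes over time", {
  h <- 60; w <- 30
  axis <- cbind(c(15, 15), c(0, 60))
  set.seed(42)
  stack <- lapply(1:4, function(k)
    outer(seq_len(h) - 0.5, rep(1, w)) * (0.2 * k) + 5 +
      matrix(rnorm(h * w, 0, 0.05), h, w))
  ic <- ingression_intensity(stack, axis, ap_bin_width = 10,
                             band_halfwidth = 15)
  expect_true(all(diff(ic$fits$slope) > 0))
})

# inter-division times ------------------------------------------------------

test_that("an observed birth-to-division lifetime is the frame count times the interval", {
  # born at frame 10 (60 min), divides at frame 55 (330 min), 6-min frames
  d <- make_track(2, t = 6 * (10:55), x = 0, y = 0, parent = 1L,
                  status = "divided")
  it <- interdivision_times(d)
  expect_equal(it$times, 270)
  expect_equal(it$n_censored, 0)
})

test_that("tracks without divisions are all censored", {
  p <- det_track_params(n_cells = 10, duration = 60, frame_interval = 4,
                        seed = 40)
  it <- interdivision_times(simulate_tracks(p)$tracks)
  expect_length(it$times, 0)
  expect_equal(it$n_censored, 0)  # founders have no observed birth
})

test_that("generator inter-division times match the programmed mean", {
  p <- det_track_params(n_cells = 100, duration = 1900, frame_interval = 6,
                        convergence = 0, division = 60 / 270, seed = 41)
  trk <- simulate_tracks(p)$tracks
  # restrict to daughters born early: cells born near the movie end are
  # censored before dividing, which length-biases lifetimes downward
  birth <- tapply(trk$t_min, trk$track_id, min)
  early <- as.integer(names(birth))[birth <= 300 &
                                      !is.na(tapply(trk$parent_id,
                                                    trk$track_id, `[`, 1))]
  it <- interdivision_times(trk[trk$track_id %in% early, ])
  expect_gt(length(it$times), 100)
  se <- sd(it$times) / sqrt(length(it$times))
  expect_lt(abs(mean(it$times) - 270), 3 * se)
})
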