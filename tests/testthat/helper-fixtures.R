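# shared fixtures built in code

# deterministic track params: no stochastic events unless asked for
det_track_params <- function(n_cells = 10, duration = 60, frame_interval = 1,
                             convergence = 1, drift = 0, hazard = 0,
                             division = 0, noise = 0,
                             x_range = c(100, 200), y_range = c(0, 2000),
                             seed = 1L) {
  track_gen_params(
    n_cells = n_cells, duration = duration, frame_interval = frame_interval,
    node_speed = drift,
    convergence_profile = function(y) rep(convergence, length(y)),
    ap_drift_profile = function(y) rep(drift, length(y)),
    ingression_hazard_profile = if (is.function(hazard)) hazard else
      function(y) rep(hazard, length(y)),
    division_rate_profile = function(y) rep(division, length(y)),
    position_noise_sd = noise, x_range = x_range, y_range = y_range,
    seed = seed)
}

# hand-built track: one cell id, given times and positions
make_track <- function(id, t, x, y, parent = NA_integer_, status = "live") {
  st <- rep("live", length(t))
  st[length(t)] <- status
  data.frame(track_id = id, parent_id = parent, frame = seq_along(t) - 1L,
             t_min = t, x_um = x, y_um = y, status = st,
             stringsAsFactors = FALSE)
}

# separated Gaussian blobs at fixed integer centres (row, col)
blob_image <- function(shape, centers, sigma = 3, intensity = 100) {
  img <- matrix(0, shape[1], shape[2])
  streakdyn:::render_blobs(img, centers, sigma, intensity)
}
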