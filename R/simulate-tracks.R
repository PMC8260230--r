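#' Parameters for the epiblast track simulator
#'
#' Bundles and validates the parameters of [simulate_tracks()]. The simulated
#' embryo uses a shared coordinate convention: x is mediolateral (midline at
#' x = 0), y is anteroposterior increasing posteriorly, both in micrometres;
#' Hensen's node starts at y = 0 and regresses posteriorly at `node_speed`.
#'
#' Positional profiles are functions of the AP coordinate (micrometres) and
#' must be vectorized. Defaults emulate the measured behaviour of streak-stage
#' epiblast: convergence speed toward the midline increasing posteriorly,
#' AP drift highest near the node (cells following its regression), a
#' posteriorly increasing ingression hazard, and a uniform division rate
#' corresponding to a cell cycle of roughly 4.5 h.
#'
#' @param n_cells number of starting tracks.
#' @param duration movie duration, minutes.
#' @param frame_interval minutes between frames (default 4).
#' @param node_speed posterior node regression speed, um/min.
#' @param convergence_profile function(y) -> lateral-to-medial speed, um/min.
#' @param ap_drift_profile function(y) -> posterior drift speed, um/min.
#' @param ingression_hazard_profile function(y) -> per-frame ingression
#'   probability, each value in \[0, 1\].
#' @param division_rate_profile function(y) -> division events per cell per
#'   hour.
#' @param position_noise_sd positional noise per frame, um.
#' @param x_range range of starting distances from the midline, um (sides
#'   assigned at random).
#' @param y_range range of starting AP positions, um.
#' @param midline_x x coordinate of the midline (fixed at 0).
#' @param seed integer seed.
#' @return A validated list of class `"track_gen_params"`.
#' @export
track_gen_params <- function(n_cells = 200,
                             duration = 120,
                             frame_interval = 4,
                             node_speed = 1.0,
                             convergence_profile = function(y)
                               2 * pmin(pmax(y, 0), 2000) / 2000,
                             ap_drift_profile = function(y)
                               node_speed * pmax(0, 1 - y / 2000),
                             ingression_hazard_profile = function(y)
                               0.002 + 0.018 * pmin(pmax(y / 2000, 0), 1),
                             division_rate_profile = function(y)
                               rep(0.22, length(y)),
                             position_noise_sd = 0.5,
                             x_range = c(50, 300),
                             y_range = c(0, 2000),
                             midline_x = 0,
                             seed = 1L) {
  if (duration <= 0 || frame_interval <= 0)
    stop("'duration' and 'frame_interval' must be positive")
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (midline_x != 0) stop("the midline is fixed at x = 0")
  force(node_speed)
  y_grid <- seq(y_range[1], y_range[2] + node_speed * duration, length.out = 64)
  hz <- ingression_hazard_profile(y_grid)
  if (any(hz < 0 | hz > 1))
    stop("ingression hazards must lie in [0, 1] over the simulated AP span")
  if (any(!is.finite(convergence_profile(y_grid))) ||
      any(!is.finite(ap_drift_profile(y_grid))) ||
      any(division_rate_profile(y_grid) < 0))
    stop("profiles must be finite (and division rates non-negative) over the AP span")
  structure(list(n_cells = as.integer(n_cells), duration = duration,
                 frame_interval = frame_interval, node_speed = node_speed,
                 convergence_profile = convergence_profile,
                 ap_drift_profile = ap_drift_profile,
                 ingression_hazard_profile = ingression_hazard_profile,
                 division_rate_profile = division_rate_profile,
                 position_noise_sd = position_noise_sd,
                 x_range = x_range, y_range = y_range,
                 midline_x = 0, seed = as.integer(seed)),
            class = "track_gen_params")
}

#' Simulate nuclear tracks in the regressing-streak epiblast
#'
#' Forward-simulates 2D+t nuclear tracks with AP-position-dependent
#' convergence toward the midline, AP drift, ingression (track censoring) and
#' division. Divisions end the mother track and spawn two daughter tracks at
#' the mother's position with `parent_id` recorded. Ground truth for every
#' ingression and division event and the node trajectory are returned so that
#' downstream kinematic statistics can be scored without re-deriving labels.
#'
#' Per frame and per live cell, the position advances by the local AP drift
#' plus convergence toward x = 0 (clamped so cells do not overshoot the
#' midline), with additive Gaussian noise; the cell then ingresses with its
#' local per-frame hazard or divides with probability
#' `division_rate / 60 * frame_interval`.
#'
#' @param params a [track_gen_params()] object.
#' @return A list of class `"track_sim"`:
#' \describe{
#'   \item{tracks}{data.frame with columns `track_id`, `parent_id`, `frame`,
#'     `t_min`, `x_um`, `y_um`, `status` (`live` on every row except the
#'     final row of a censored track, which carries `ingressed` or
#'     `divided`).}
#'   \item{events}{data.frame of ground-truth events: `track_id`, `type`
#'     (`ingression`/`division`), `frame`, `t_min`.}
#'   \item{node}{data.frame of the node trajectory (`frame`, `t_min`,
#'     `x_um`, `y_um`).}
#'   \item{params}{the generating parameters.}
#' }
#' @examples
#' p <- track_gen_params(n_cells = 20, duration = 40, seed = 7)
#' sim <- simulate_tracks(p)
#' head(sim$tracks)
#' @export
simulate_tracks <- function(params) {
  stopifnot(inherits(params, "track_gen_params"))
  set.seed(params$seed)
  dt <- params$frame_interval
  n_frames <- floor(params$duration / dt + 1e-9)  # samples at frames 0..n_frames

  n0 <- params$n_cells
  x <- stats::runif(n0, params$x_range[1], params$x_range[2]) *
    sample(c(-1, 1), n0, replace = TRUE)
  y <- stats::runif(n0, params$y_range[1], params$y_range[2])

  # growing per-track state
  id <- seq_len(n0)
  parent <- rep(NA_integer_, n0)
  alive <- rep(TRUE, n0)
  next_id <- n0 + 1L

  rows_id <- list(); rows_parent <- list(); rows_frame <- list()
  rows_x <- list(); rows_y <- list(); rows_status <- list()
  ev_id <- integer(); ev_type <- character(); ev_frame <- integer()
  push <- function(i, f, st) {
    k <- length(rows_id) + 1L
    rows_id[[k]] <<- id[i]; rows_parent[[k]] <<- parent[i]
    rows_frame[[k]] <<- rep(f, length(i))
    rows_x[[k]] <<- x[i]; rows_y[[k]] <<- y[i]
    rows_status[[k]] <<- st
  }
  push(which(alive), 0L, rep("live", sum(alive)))

  for (f in seq_len(n_frames)) {
    li <- which(alive)
    if (length(li) == 0L) break
    yl <- y[li]; xl <- x[li]
    conv <- params$convergence_profile(yl) * dt
    step <- pmin(conv, abs(xl))           # do not overshoot the midline
    x[li] <- xl - sign(xl) * step +
      stats::rnorm(length(li), 0, params$position_noise_sd)
    y[li] <- yl + params$ap_drift_profile(yl) * dt +
      stats::rnorm(length(li), 0, params$position_noise_sd)

    # events during this interval, resolved at frame f
    p_div <- pmin(params$division_rate_profile(y[li]) / 60 * dt, 1)
    div <- stats::runif(length(li)) < p_div
    hz <- params$ingression_hazard_profile(y[li])
    ing <- !div & (stats::runif(length(li)) < hz)

    st <- rep("live", length(li))
    st[div] <- "divided"; st[ing] <- "ingressed"
    push(li, f, st)

    if (any(ing)) {
      ii <- li[ing]
      ev_id <- c(ev_id, id[ii]); ev_type <- c(ev_type, rep("ingression", length(ii)))
      ev_frame <- c(ev_frame, rep(f, length(ii)))
      alive[ii] <- FALSE
    }
    if (any(div)) {
      di <- li[div]
      ev_id <- c(ev_id, id[di]); ev_type <- c(ev_type, rep("division", length(di)))
      ev_frame <- c(ev_frame, rep(f, length(di)))
      alive[di] <- FALSE
      nd <- 2L * length(di)
      new_ids <- seq.int(next_id, length.out = nd)
      next_id <- next_id + nd
      id <- c(id, new_ids)
      parent <- c(parent, rep(id[di], each = 2L))
      x <- c(x, rep(x[di], each = 2L))
      y <- c(y, rep(y[di], each = 2L))
      alive <- c(alive, rep(TRUE, nd))
      # daughters' first sample at the division frame
      ni <- seq.int(length(id) - nd + 1L, length(id))
      push(ni, f, rep("live", nd))
    }
  }

  tracks <- data.frame(
    track_id = unlist(rows_id), parent_id = unlist(rows_parent),
    frame = unlist(rows_frame),
    t_min = unlist(rows_frame) * dt,
    x_um = unlist(rows_x), y_um = unlist(rows_y),
    status = unlist(rows_status), stringsAsFactors = FALSE)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL

  node <- data.frame(frame = 0:n_frames, t_min = (0:n_frames) * dt,
                     x_um = 0, y_um = params$node_speed * (0:n_frames) * dt)
  events <- data.frame(track_id = ev_id, type = ev_type, frame = ev_frame,
                       t_min = ev_frame * dt, stringsAsFactors = FALSE)
  structure(list(tracks = tracks, events = events, node = node,
                 params = params),
            class = "track_sim")
}
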