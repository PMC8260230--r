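#' @importFrom stats approx lm coef var sd setNames quantile
NULL

# per-track summary: birth/end times, final status, parent
track_summary <- function(tracks) {
  sp <- split(tracks, tracks$track_id)
  out <- data.frame(
    track_id = as.integer(names(sp)),
    parent_id = vapply(sp, function(d) d$parent_id[1], integer(1)),
    t_birth = vapply(sp, function(d) min(d$t_min), numeric(1)),
    t_end = vapply(sp, function(d) max(d$t_min), numeric(1)),
    status = vapply(sp, function(d) d$status[which.max(d$t_min)],
                    character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Register tracks to the node displacement
#'
#' Subtracts the node's contemporaneous position from every track sample,
#' expressing all motion in the reference frame of the regressing Hensen's
#' node (which maps to the origin at all times). The node trajectory is
#' linearly interpolated inside its time span; track samples outside the
#' span are an error (no extrapolation).
#'
#' @param tracks data.frame with at least `track_id`, `t_min`, `x_um`,
#'   `y_um`.
#' @param node_track data.frame with `t_min`, `x_um`, `y_um` covering the
#'   track time range.
#' @return `tracks` with `x_um` and `y_um` replaced by node-relative
#'   coordinates.
#' @examples
#' trk <- data.frame(track_id = 1, t_min = 0:2, x_um = 5, y_um = 0:2 * 2)
#' node <- data.frame(t_min = 0:2, x_um = 0, y_um = 0:2 * 2)
#' register_to_node(trk, node)$y_um  # 0 0 0: comoving cell is stationary
#' @export
register_to_node <- function(tracks, node_track) {
  stopifnot(all(c("t_min", "x_um", "y_um") %in% names(tracks)),
            all(c("t_min", "x_um", "y_um") %in% names(node_track)))
  rng <- range(node_track$t_min)
  if (any(tracks$t_min < rng[1] - 1e-9) || any(tracks$t_min > rng[2] + 1e-9))
    stop("track samples fall outside the node's time span; no extrapolation")
  nx <- stats::approx(node_track$t_min, node_track$x_um,
                      xout = tracks$t_min, rule = 1)$y
  ny <- stats::approx(node_track$t_min, node_track$y_um,
                      xout = tracks$t_min, rule = 1)$y
  tracks$x_um <- tracks$x_um - nx
  tracks$y_um <- tracks$y_um - ny
  tracks
}

#' Instantaneous velocities of tracked cells
#'
#' One velocity sample per consecutive pair of track samples:
#' \eqn{v_{AP} = \Delta y / \Delta t} (positive posterior) and
#' \eqn{v_{LM} = -sign(x_{mid}) \Delta x / \Delta t} (positive toward the
#' midline at x = 0, on either side of it). Each sample is attached to the
#' midpoint time and midpoint position of its pair (central convention).
#'
#' @param tracks data.frame with `track_id`, `t_min`, `x_um`, `y_um`; times
#'   strictly increasing within each track.
#' @return data.frame with columns `track_id`, `t` (min), `v_lm`, `v_ap`
#'   (um/min), `ap_position` (midpoint y, um), `ml_position` (midpoint x,
#'   um).
#' @examples
#' trk <- data.frame(track_id = 1, t_min = c(0, 10),
#'                   x_um = c(10, 0), y_um = c(0, 0))
#' track_velocities(trk)$v_lm  # +1 um/min: pure convergence
#' @export
track_velocities <- function(tracks) {
  sp <- split(tracks[order(tracks$t_min), ], tracks$track_id[order(tracks$t_min)])
  res <- lapply(sp, function(d) {
    if (nrow(d) < 2) return(NULL)
    dt <- diff(d$t_min)
    if (any(dt <= 0)) stop("track times must be strictly increasing")
    x_mid <- (d$x_um[-1] + d$x_um[-nrow(d)]) / 2
    data.frame(track_id = d$track_id[1],
               t = (d$t_min[-1] + d$t_min[-nrow(d)]) / 2,
               v_lm = -sign(x_mid) * diff(d$x_um) / dt,
               v_ap = diff(d$y_um) / dt,
               ap_position = (d$y_um[-1] + d$y_um[-nrow(d)]) / 2,
               ml_position = x_mid)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Angle of motion with the midline
#'
#' \eqn{\theta = \arctan(|v_{LM}| / |v_{AP}|)} in degrees: 0 for motion
#' parallel to the midline, 90 for pure convergence (or divergence; the two
#' fold together since only the angle magnitude is reported).
#'
#' @param v_lm,v_ap velocity components (um/min); vectorized.
#' @return Angles in degrees in \[0, 90\]; `NA` where both components are
#'   zero (no displacement).
#' @examples
#' midline_angle(c(0, 2, 5), c(3, 2, 0))  # 0, 45, 90
#' @export
midline_angle <- function(v_lm, v_ap) {
  ang <- atan2(abs(v_lm), abs(v_ap)) * 180 / pi
  ang[v_lm == 0 & v_ap == 0] <- NA_real_
  ang
}

in_roi <- function(x, y, roi) {
  if (is.null(roi)) return(rep(TRUE, length(x)))
  x >= roi$x[1] & x <= roi$x[2] & y >= roi$y[1] & y <= roi$y[2]
}

#' Fractions of convergent vs streak-parallel tracks in a region
#'
#' Computes, for each track with velocity samples inside the region, the
#' mean angle with the midline, then reports the fraction of tracks with
#' mean angle in \[0, 45) degrees (streak-parallel motion) and in \[45, 90\]
#' degrees (convergent motion; the 45-degree boundary goes to the upper
#' bin). Averaging per track before binning avoids overweighting long
#' tracks; set `pooled = TRUE` to bin each velocity step instead.
#'
#' @param tracks data.frame of track samples.
#' @param region `list(x = c(min, max), y = c(min, max))` in um, or `NULL`
#'   for the whole field.
#' @param pooled if `TRUE`, bin pooled per-step angles rather than per-track
#'   means.
#' @return A list: `frac_0_45`, `frac_45_90` (summing to 1), `n` (tracks or
#'   steps counted) and `n_skipped` (zero-displacement samples).
#' @export
angle_fraction_report <- function(tracks, region = NULL, pooled = FALSE) {
  v <- track_velocities(tracks)
  keep <- in_roi(v$ml_position, v$ap_position, region)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0) stop("no velocity samples in the region")
  ang <- midline_angle(v$v_lm, v$v_ap)
  n_skipped <- sum(is.na(ang))
  if (pooled) {
    a <- ang[!is.na(ang)]
  } else {
    a <- tapply(ang, v$track_id, mean, na.rm = TRUE)
    a <- a[!is.na(a)]
  }
  if (length(a) == 0) stop("no valid angles in the region")
  list(frac_0_45 = mean(a < 45), frac_45_90 = mean(a >= 45),
       n = length(a), n_skipped = n_skipped)
}

#' Binned convergence and AP speed profiles
#'
#' Bins all velocity samples by AP position and time and reports mean, SD
#' and n of the lateral-to-medial and anteroposterior speed components per
#' bin. Empty bins are flagged (`n = 0`, statistics `NA`), never imputed as
#' zero; bins with a single sample report the sample with `NA` SD.
#'
#' @param tracks data.frame of track samples.
#' @param ap_bin_width AP bin width, um (default 50).
#' @param time_bin_width time bin width, minutes (default 30).
#' @return data.frame with `ap_bin_center`, `t_bin_center`, `n`,
#'   `mean_v_lm`, `sd_v_lm`, `mean_v_ap`, `sd_v_ap`, `empty`.
#' @export
speed_profile <- function(tracks, ap_bin_width = 50, time_bin_width = 30) {
  if (ap_bin_width <= 0 || time_bin_width <= 0)
    stop("bin widths must be positive")
  v <- track_velocities(tracks)
  ap_bin <- floor(v$ap_position / ap_bin_width)
  t_bin <- floor(v$t / time_bin_width)
  grid <- expand.grid(ap_bin = seq(min(ap_bin), max(ap_bin)),
                      t_bin = seq(min(t_bin), max(t_bin)))
  key <- paste(ap_bin, t_bin)
  gkey <- paste(grid$ap_bin, grid$t_bin)
  stat <- function(fun, comp) {
    agg <- tapply(v[[comp]], key, fun)
    as.numeric(agg[gkey])
  }
  n <- stat(length, "v_lm")
  n[is.na(n)] <- 0
  sd_or_na <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
  out <- data.frame(
    ap_bin_center = (grid$ap_bin + 0.5) * ap_bin_width,
    t_bin_center = (grid$t_bin + 0.5) * time_bin_width,
    n = n,
    mean_v_lm = stat(mean, "v_lm"), sd_v_lm = stat(sd_or_na, "v_lm"),
    mean_v_ap = stat(mean, "v_ap"), sd_v_ap = stat(sd_or_na, "v_ap"),
    empty = n == 0)
  out[order(out$t_bin_center, out$ap_bin_center), , drop = FALSE]
}

# is the lineage rooted at track id alive at time T?
lineage_alive_at <- function(id, T, info, children, lineage) {
  i <- match(id, info$track_id)
  if (T < info$t_birth[i]) return(FALSE)
  if (T < info$t_end[i]) return(TRUE)
  st <- info$status[i]
  if (T == info$t_end[i] && st == "live") return(TRUE)
  if (st == "divided" && lineage) {
    kids <- children[[as.character(id)]]
    for (k in kids)
      if (lineage_alive_at(k, T, info, children, lineage)) return(TRUE)
  }
  FALSE
}

#' Track longevity by region
#'
#' For each region, takes the cohort of tracks present at `t0` inside the
#' region and reports the fraction still uncensored 1 h and 2 h later.
#' With `lineage = TRUE` (default) a division does not censor: the lineage
#' survives if any descendant track is alive at the horizon; with
#' `lineage = FALSE` a division ends the track.
#'
#' @param tracks data.frame of track samples.
#' @param regions named list of ROIs (`list(x = c(min, max),
#'   y = c(min, max))` in um); `NULL` entries mean the whole field.
#' @param t0 cohort start time, minutes.
#' @param horizons survival horizons after `t0`, minutes (default 60 and
#'   120).
#' @param lineage whether lineages survive through divisions.
#' @return data.frame with one row per region: `region`, `n_t0`,
#'   `ratio_1h`, `ratio_2h` (named after the default horizons).
#' @export
track_longevity <- function(tracks, regions, t0 = 0,
                            horizons = c(60, 120), lineage = TRUE) {
  info <- track_summary(tracks)
  children <- split(info$track_id, info$parent_id)
  at_t0 <- tracks[abs(tracks$t_min - t0) < 1e-9, , drop = FALSE]
  if (nrow(at_t0) == 0) {
    # interpolate positions of tracks spanning t0
    ids <- info$track_id[info$t_birth <= t0 & info$t_end >= t0]
    at_t0 <- do.call(rbind, lapply(ids, function(id) {
      d <- tracks[tracks$track_id == id, ]
      data.frame(track_id = id,
                 x_um = stats::approx(d$t_min, d$x_um, t0)$y,
                 y_um = stats::approx(d$t_min, d$y_um, t0)$y)
    }))
  }
  res <- lapply(seq_along(regions), function(r) {
    roi <- regions[[r]]
    cohort <- at_t0$track_id[in_roi(at_t0$x_um, at_t0$y_um, roi)]
    cohort <- unique(cohort)
    if (length(cohort) == 0) stop("region ", r, " is empty at t0")
    ratios <- vapply(horizons, function(h)
      mean(vapply(cohort, lineage_alive_at, logical(1), T = t0 + h,
                  info = info, children = children, lineage = lineage)),
      numeric(1))
    c(n_t0 = length(cohort), ratios)
  })
  out <- data.frame(region = names(regions) %||% seq_along(regions),
                    do.call(rbind, res))
  names(out)[-(1:2)] <- sprintf("ratio_%gh", horizons / 60)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ingression-intensity gradient along the streak axis
#'
#' From a ventral-view image time series in which only epiblast nuclei were
#' labeled at the start, measures the mean pixel intensity in bands along
#' the streak axis at each timepoint (ingressing cells progressively light
#' up the ventral layer), then fits an ordinary-least-squares line of band
#' intensity on AP distance per timepoint. The slope sign reports the
#' direction of the AP ingression gradient.
#'
#' @param stack list of numeric matrices (one per timepoint; row = y,
#'   col = x) or a 3D array `[y, x, t]`.
#' @param ps_axis two-column matrix of polyline vertices (x, y) in um
#'   running anterior to posterior along the streak.
#' @param ap_bin_width band width along the axis, um.
#' @param pixel_size um per pixel.
#' @param band_halfwidth half-width of the measured band either side of the
#'   axis, um.
#' @return A list of class `"ingression_curve"`: `profile` (data.frame
#'   `t_index`, `ap_bin_center`, `mean_intensity`, `n_px`) and `fits`
#'   (data.frame `t_index`, `slope`, `intercept`, `r_squared`, `n_bins`,
#'   `flagged`; `flagged` marks timepoints with fewer than 3 populated bins
#'   or no intensity variation).
#' @export
ingression_intensity <- function(stack, ps_axis, ap_bin_width = 100,
                                 pixel_size = 1, band_halfwidth = 50) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  stopifnot(is.list(stack), length(stack) >= 1)
  ps_axis <- as.matrix(ps_axis)
  h <- nrow(stack[[1]]); w <- ncol(stack[[1]])
  px_x <- (col(stack[[1]]) - 0.5) * pixel_size
  px_y <- (row(stack[[1]]) - 0.5) * pixel_size

  # arclength position and distance of each pixel relative to the polyline
  best_d2 <- matrix(Inf, h, w); best_s <- matrix(NA_real_, h, w)
  s0 <- 0
  for (k in seq_len(nrow(ps_axis) - 1)) {
    a <- ps_axis[k, ]; b <- ps_axis[k + 1, ]
    ab <- b - a; len2 <- sum(ab^2)
    t_par <- ((px_x - a[1]) * ab[1] + (px_y - a[2]) * ab[2]) / len2
    t_par <- pmin(pmax(t_par, 0), 1)
    d2 <- (px_x - (a[1] + t_par * ab[1]))^2 +
          (px_y - (a[2] + t_par * ab[2]))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- s0 + (t_par * sqrt(len2))[upd]
    s0 <- s0 + sqrt(len2)
  }
  keep <- sqrt(best_d2) <= band_halfwidth
  if (!any(keep)) stop("no pixels within the band around 'ps_axis'")
  sbin <- floor(best_s[keep] / ap_bin_width)
  centers <- (sort(unique(sbin)) + 0.5) * ap_bin_width

  prof <- do.call(rbind, lapply(seq_along(stack), function(ti) {
    vals <- stack[[ti]][keep]
    mu <- tapply(vals, sbin, mean)
    data.frame(t_index = ti, ap_bin_center = centers,
               mean_intensity = as.numeric(mu),
               n_px = as.numeric(tapply(vals, sbin, length)))
  }))
  fits <- do.call(rbind, lapply(seq_along(stack), function(ti) {
    d <- prof[prof$t_index == ti & !is.na(prof$mean_intensity), ]
    if (nrow(d) < 3)
      return(data.frame(t_index = ti, slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, n_bins = nrow(d),
                        flagged = TRUE))
    if (stats::var(d$mean_intensity) == 0)
      return(data.frame(t_index = ti, slope = 0, intercept = d$mean_intensity[1],
                        r_squared = NA_real_, n_bins = nrow(d), flagged = TRUE))
    fit <- stats::lm(mean_intensity ~ ap_bin_center, data = d)
    data.frame(t_index = ti, slope = stats::coef(fit)[[2]],
               intercept = stats::coef(fit)[[1]],
               r_squared = summary(fit)$r.squared, n_bins = nrow(d),
               flagged = FALSE)
  }))
  structure(list(profile = prof, fits = fits), class = "ingression_curve")
}

#' Inter-division times from lineage-linked tracks
#'
#' For every track whose birth (a recorded parent) and division (final
#' status `divided`) are both observed, the inter-division interval is the
#' track's lifetime. Tracks with an observed birth whose division was not
#' observed are censored and only counted.
#'
#' @param tracks data.frame of track samples with `parent_id` links.
#' @return A list: `times` (minutes, possibly empty) and `n_censored`.
#' @examples
#' # a daughter born at 60 min dividing at 330 min: one 270-min interval
#' @export
interdivision_times <- function(tracks) {
  info <- track_summary(tracks)
  born <- !is.na(info$parent_id)
  complete <- born & info$status == "divided"
  list(times = info$t_end[complete] - info$t_birth[complete],
       n_censored = sum(born & info$status != "divided"))
}
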