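#' Parameters for the two-channel nuclear-image simulator
#'
#' @param shape integer length-2, image height and width in pixels.
#' @param n_cells_channel1,n_cells_channel2 nuclei per channel (including the
#'   double positives).
#' @param n_double_positive nuclei present at the same centre in both
#'   channels; must not exceed either channel count.
#' @param blob_sigma Gaussian nucleus radius, pixels.
#' @param intensity peak blob intensity, arbitrary units.
#' @param background_noise_sd additive Gaussian background noise SD.
#' @param pixel_size physical pixel size, um/px.
#' @param seed integer seed.
#' @return A validated list of class `"image_gen_params"`.
#' @export
image_gen_params <- function(shape = c(256, 256),
                             n_cells_channel1 = 30,
                             n_cells_channel2 = 30,
                             n_double_positive = 10,
                             blob_sigma = 3,
                             intensity = 100,
                             background_noise_sd = 1,
                             pixel_size = 1,
                             seed = 1L) {
  if (n_double_positive > min(n_cells_channel1, n_cells_channel2))
    stop("'n_double_positive' cannot exceed either channel count")
  if (any(shape < 8 * blob_sigma))
    stop("blobs must fit inside the frame")
  structure(list(shape = as.integer(shape),
                 n_cells_channel1 = as.integer(n_cells_channel1),
                 n_cells_channel2 = as.integer(n_cells_channel2),
                 n_double_positive = as.integer(n_double_positive),
                 blob_sigma = blob_sigma, intensity = intensity,
                 background_noise_sd = background_noise_sd,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "image_gen_params")
}

# rejection-sample n centres with pairwise separation >= min_sep inside a
# margin; errors after 10x oversampled attempts
place_centers <- function(n, shape, min_sep, margin) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 10L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " blobs at separation ", min_sep,
           " within ", max_attempts, " attempts")
    cand <- c(stats::runif(1, margin, shape[1] - margin),
              stats::runif(1, margin, shape[2] - margin))
    if (placed == 0L ||
        min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                               2, cand)^2))) >= min_sep) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  centers
}

# additively render Gaussian blobs onto img (row = y, col = x)
render_blobs <- function(img, centers, sigma, intensity) {
  if (nrow(centers) == 0) return(img)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    ys <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
    g <- outer(exp(-(ys - cy)^2 / (2 * sigma^2)),
               exp(-(xs - cx)^2 / (2 * sigma^2)))
    # truncate tails at 4 sigma so blobs separated by the placement
    # constraint never overlap and maxima stay exact
    g[outer((ys - cy)^2, (xs - cx)^2, "+") > r^2] <- 0
    img[ys, xs] <- img[ys, xs] + intensity * g
  }
  img
}

#' Simulate a co-registered two-channel nuclear image pair
#'
#' Places Gaussian nuclear blobs at random centres with a minimum pairwise
#' separation of `4 * blob_sigma`; the designated double-positive nuclei
#' share the same centre in both channels, all others are channel-specific.
#' Additive Gaussian background noise is applied per channel. Ground-truth
#' per-channel and double-positive counts (and all centres) are returned.
#'
#' @param params an [image_gen_params()] object.
#' @return A list of class `"image_sim"`: `channel1` and `channel2`
#'   (numeric matrices), `truth` (list with `n_channel1`, `n_channel2`,
#'   `n_double_positive`, and centre matrices `centers_double`,
#'   `centers_only1`, `centers_only2` in (row, col) pixels), and `params`.
#' @examples
#' sim <- simulate_two_channel_image(image_gen_params(seed = 4))
#' sim$truth$n_double_positive
#' @export
simulate_two_channel_image <- function(params) {
  stopifnot(inherits(params, "image_gen_params"))
  set.seed(params$seed)
  sep <- 4 * params$blob_sigma
  margin <- 4 * params$blob_sigma
  n_dp <- params$n_double_positive
  n1 <- params$n_cells_channel1 - n_dp
  n2 <- params$n_cells_channel2 - n_dp
  # centres snapped to pixel centres so noise-free blob maxima equal the
  # nominal intensity; rounding moves each centre by < 1 px
  all_centers <- round(place_centers(n_dp + n1 + n2, params$shape, sep + 2,
                                     margin))
  cd <- all_centers[seq_len(n_dp), , drop = FALSE]
  c1 <- all_centers[seq_len(n1) + n_dp, , drop = FALSE]
  c2 <- all_centers[seq_len(n2) + n_dp + n1, , drop = FALSE]

  img1 <- matrix(0, params$shape[1], params$shape[2])
  img2 <- matrix(0, params$shape[1], params$shape[2])
  img1 <- render_blobs(img1, rbind(cd, c1), params$blob_sigma, params$intensity)
  img2 <- render_blobs(img2, rbind(cd, c2), params$blob_sigma, params$intensity)
  if (params$background_noise_sd > 0) {
    img1 <- img1 + matrix(stats::rnorm(length(img1), 0,
                                       params$background_noise_sd),
                          nrow(img1))
    img2 <- img2 + matrix(stats::rnorm(length(img2), 0,
                                       params$background_noise_sd),
                          nrow(img2))
  }
  structure(list(channel1 = img1, channel2 = img2,
                 truth = list(n_channel1 = params$n_cells_channel1,
                              n_channel2 = params$n_cells_channel2,
                              n_double_positive = n_dp,
                              centers_double = cd, centers_only1 = c1,
                              centers_only2 = c2),
                 params = params),
            class = "image_sim")
}
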