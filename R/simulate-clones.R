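#' Parameters for the multispectral clone-color simulator
#'
#' Each clone is assigned a hue centre on the 2-simplex (fractions of the
#' three imaging channels summing to 1) and a potency class: `N` (all
#' descendants neural), `M` (all mesodermal) or `NM` (bipotent, descendants
#' in both tissues). Channel noise enters on raw intensities before
#' normalization, mimicking how acquisition noise perturbs measured color
#' codes.
#'
#' @param n_clones number of clones.
#' @param cells_per_clone integer, or integer vector of length `n_clones`.
#' @param hue_centers matrix `n_clones` x 3 of channel fractions, rows on the
#'   simplex (non-negative, summing to 1). Default: evenly spread centres.
#' @param hue_noise_sd Gaussian noise SD applied per channel (fraction units).
#' @param potency_assignment character vector in `{"N","M","NM"}`, length
#'   `n_clones`. Default: all `"NM"`.
#' @param ap_span numeric length-2, AP extent (um) over which cells are
#'   placed uniformly (image y, ascending = posterior).
#' @param intensity_scale raw-intensity multiplier (arbitrary units).
#' @param seed integer seed.
#' @return A validated list of class `"clone_gen_params"`.
#' @export
clone_gen_params <- function(n_clones = 5,
                             cells_per_clone = 60,
                             hue_centers = NULL,
                             hue_noise_sd = 0.03,
                             potency_assignment = NULL,
                             ap_span = c(0, 1000),
                             intensity_scale = 1000,
                             seed = 1L) {
  if (is.null(hue_centers)) hue_centers <- default_hue_centers(n_clones)
  hue_centers <- as.matrix(hue_centers)
  if (nrow(hue_centers) != n_clones || ncol(hue_centers) != 3)
    stop("'hue_centers' must be an n_clones x 3 matrix")
  if (any(hue_centers < 0) || any(abs(rowSums(hue_centers) - 1) > 1e-8))
    stop("hue centres must lie on the simplex (non-negative, rows summing to 1)")
  if (is.null(potency_assignment)) potency_assignment <- rep("NM", n_clones)
  if (!all(potency_assignment %in% c("N", "M", "NM")) ||
      length(potency_assignment) != n_clones)
    stop("'potency_assignment' must be in {N, M, NM}, one per clone")
  cells_per_clone <- rep_len(as.integer(cells_per_clone), n_clones)
  if (any(cells_per_clone < 1)) stop("'cells_per_clone' must be >= 1")
  structure(list(n_clones = as.integer(n_clones),
                 cells_per_clone = cells_per_clone,
                 hue_centers = hue_centers, hue_noise_sd = hue_noise_sd,
                 potency_assignment = potency_assignment,
                 ap_span = ap_span, intensity_scale = intensity_scale,
                 seed = as.integer(seed)),
            class = "clone_gen_params")
}

# well-separated default centres: channel-dominant corners then edge midpoints
default_hue_centers <- function(n) {
  base <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8),
                c(0.45, 0.45, 0.1), c(0.1, 0.45, 0.45), c(0.45, 0.1, 0.45),
                c(1/3, 1/3, 1/3))
  if (n > nrow(base))
    stop("supply 'hue_centers' explicitly for more than ", nrow(base), " clones")
  base[seq_len(n), , drop = FALSE]
}

# tissue labels consistent with a clone's potency; NM clones get both labels
assign_tissues <- function(potency, n) {
  switch(potency,
    N = rep("neural", n),
    M = rep("mesoderm", n),
    NM = {
      if (n < 2) stop("an NM clone needs at least 2 cells")
      lab <- c("neural", "mesoderm",
               sample(c("neural", "mesoderm"), n - 2, replace = TRUE))
      sample(lab)
    })
}

#' Simulate per-cell color codes for a set of clones
#'
#' Draws, for every cell, raw three-channel intensities around its clone's
#' hue centre (Gaussian noise on raw intensities, truncated at zero), a
#' tissue label consistent with the clone's potency, and a uniform AP
#' coordinate. Ground-truth clone ids are retained for scoring.
#'
#' @param params a [clone_gen_params()] object.
#' @return data.frame with columns `cell_id`, `clone_id` (ground truth),
#'   `c1`, `c2`, `c3` (raw intensities), `tissue`, `y_image` (um).
#' @examples
#' cells <- simulate_clone_colors(clone_gen_params(n_clones = 3, seed = 2))
#' table(cells$clone_id, cells$tissue)
#' @export
simulate_clone_colors <- function(params) {
  stopifnot(inherits(params, "clone_gen_params"))
  set.seed(params$seed)
  n_tot <- sum(params$cells_per_clone)
  clone <- rep(seq_len(params$n_clones), params$cells_per_clone)
  centers <- params$hue_centers[clone, , drop = FALSE]
  raw <- centers + matrix(stats::rnorm(3 * n_tot, 0, params$hue_noise_sd),
                          ncol = 3)
  raw <- pmax(raw, 0) * params$intensity_scale
  tissue <- unlist(lapply(seq_len(params$n_clones), function(k)
    assign_tissues(params$potency_assignment[k], params$cells_per_clone[k])))
  data.frame(cell_id = seq_len(n_tot), clone_id = clone,
             c1 = raw[, 1], c2 = raw[, 2], c3 = raw[, 3],
             tissue = tissue,
             y_image = stats::runif(n_tot, params$ap_span[1], params$ap_span[2]),
             stringsAsFactors = FALSE)
}

#' Simulate ambiguous (uniform-color) cells
#'
#' Draws cells whose channel fractions are uniform on the simplex
#' (Dirichlet(1,1,1)), emulating cells whose color code cannot be attributed
#' to any clone; used to exercise the silhouette quality filter.
#'
#' @param n number of cells.
#' @param ap_span numeric length-2, AP extent (um).
#' @param intensity_scale raw-intensity multiplier.
#' @param seed integer seed.
#' @return data.frame in the same layout as [simulate_clone_colors()], with
#'   `clone_id = NA` marking ambiguity.
#' @export
simulate_ambiguous_colors <- function(n, ap_span = c(0, 1000),
                                      intensity_scale = 1000, seed = 1L) {
  set.seed(seed)
  e <- matrix(stats::rexp(3 * n), ncol = 3)       # Dirichlet(1,1,1)
  frac <- e / rowSums(e)
  raw <- frac * intensity_scale
  data.frame(cell_id = seq_len(n), clone_id = NA_integer_,
             c1 = raw[, 1], c2 = raw[, 2], c3 = raw[, 3],
             tissue = sample(c("neural", "mesoderm"), n, replace = TRUE),
             y_image = stats::runif(n, ap_span[1], ap_span[2]),
             stringsAsFactors = FALSE)
}

#' Simulate a retroviral barcode table
#'
#' Draws one distinct 24-character barcode over \{A, C, G, T\} per clone
#' (redrawing on the rare collision so duplicates never cross clones) and one
#' row per cell carrying the barcode, a tissue label consistent with the
#' clone's potency, and an axial position.
#'
#' @param n_clones number of clones.
#' @param cells_per_clone integer or vector of length `n_clones`.
#' @param potency_assignment character vector in `{"N","M","NM"}` per clone;
#'   default all `"NM"`.
#' @param somite27_coordinate axial position (um) of the somite-27 landmark
#'   separating anterior from posterior contributions.
#' @param axial_span numeric length-2, range of axial positions (um).
#' @param seed integer seed.
#' @return data.frame with columns `cell_id`, `clone_id` (ground truth),
#'   `barcode`, `tissue`, `axial_pos`; attribute `somite27_coordinate`.
#' @examples
#' bc <- simulate_barcodes(7, 10, potency_assignment =
#'   c("NM", "NM", "NM", "NM", "N", "M", "N"), seed = 3)
#' length(unique(bc$barcode))  # 7
#' @export
simulate_barcodes <- function(n_clones, cells_per_clone,
                              potency_assignment = rep("NM", n_clones),
                              somite27_coordinate = 500,
                              axial_span = c(0, 1000),
                              seed = 1L) {
  if (!all(potency_assignment %in% c("N", "M", "NM")) ||
      length(potency_assignment) != n_clones)
    stop("'potency_assignment' must be in {N, M, NM}, one per clone")
  cells_per_clone <- rep_len(as.integer(cells_per_clone), n_clones)
  set.seed(seed)
  draw <- function() paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE),
                           collapse = "")
  barcodes <- character(0)
  while (length(barcodes) < n_clones) {
    b <- draw()
    if (!b %in% barcodes) barcodes <- c(barcodes, b)
  }
  clone <- rep(seq_len(n_clones), cells_per_clone)
  tissue <- unlist(lapply(seq_len(n_clones), function(k)
    assign_tissues(potency_assignment[k], cells_per_clone[k])))
  out <- data.frame(cell_id = seq_along(clone), clone_id = clone,
                    barcode = barcodes[clone], tissue = tissue,
                    axial_pos = stats::runif(length(clone), axial_span[1],
                                             axial_span[2]),
                    stringsAsFactors = FALSE)
  attr(out, "somite27_coordinate") <- somite27_coordinate
  out
}
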