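#' Normalize three-channel nuclear intensities to color fractions
#'
#' Converts raw intensities `c1, c2, c3` into percentages of their sum, the
#' color code used for clone identification. Cells whose three intensities
#' are all zero carry no color information and are excluded (recorded in the
#' `"rejected"` attribute).
#'
#' @param cells data.frame with numeric columns `c1`, `c2`, `c3` (and any
#'   other columns, carried through).
#' @return `cells` with added columns `f1`, `f2`, `f3` (percentages summing
#'   to 100); attribute `rejected` holds the excluded rows.
#' @examples
#' normalize_colors(data.frame(c1 = 10, c2 = 10, c3 = 20))[, c("f1","f2","f3")]
#' @export
normalize_colors <- function(cells) {
  stopifnot(all(c("c1", "c2", "c3") %in% names(cells)))
  raw <- as.matrix(cells[, c("c1", "c2", "c3")])
  if (any(raw < 0)) stop("intensities must be non-negative")
  tot <- rowSums(raw)
  bad <- tot == 0
  out <- cells[!bad, , drop = FALSE]
  frac <- 100 * raw[!bad, , drop = FALSE] / tot[!bad]
  out$f1 <- frac[, 1]; out$f2 <- frac[, 2]; out$f3 <- frac[, 3]
  attr(out, "rejected") <- cells[bad, , drop = FALSE]
  out
}

#' Cluster cells by color code
#'
#' K-means clustering (Euclidean, multiple restarts) of the normalized
#' channel fractions, followed by per-cell silhouette scores. With
#' `k = "auto"` the number of clusters is chosen as the k maximizing the
#' mean silhouette width over `k_range`, silhouette being the same quality
#' metric later used to filter ambiguous cells.
#'
#' @param cells data.frame with fraction columns `f1`, `f2`, `f3` (see
#'   [normalize_colors()]).
#' @param k number of clusters, or `"auto"`.
#' @param k_range candidate k values for `"auto"` (default 2:15, truncated
#'   to n - 1).
#' @param nstart k-means restarts (best inertia kept).
#' @param seed integer seed, for reproducible restarts.
#' @return `cells` with added `cluster_id` and `silhouette` columns;
#'   attributes `k` (chosen k), `centers` (cluster centres) and `degenerate`
#'   (`TRUE` when all colors are identical, in which case a single cluster
#'   is returned with `NA` silhouettes).
#' @export
cluster_colors <- function(cells, k = "auto", k_range = 2:15, nstart = 25,
                           seed = 1L) {
  stopifnot(all(c("f1", "f2", "f3") %in% names(cells)))
  X <- as.matrix(cells[, c("f1", "f2", "f3")])
  n <- nrow(X)
  if (is.numeric(k) && k > n) stop("k cannot exceed the number of cells")
  if (nrow(unique(X)) == 1L) {
    cells$cluster_id <- 1L
    cells$silhouette <- NA_real_
    attr(cells, "k") <- 1L
    attr(cells, "degenerate") <- TRUE
    return(cells)
  }
  d <- stats::dist(X)
  run_k <- function(kk) {
    set.seed(seed)
    km <- stats::kmeans(X, centers = kk, nstart = nstart, iter.max = 100)
    sil <- cluster::silhouette(km$cluster, d)
    list(km = km, sil_widths = sil[, "sil_width"],
         mean_sil = mean(sil[, "sil_width"]))
  }
  if (identical(k, "auto")) {
    k_range <- k_range[k_range >= 2 & k_range <= n - 1]
    if (length(k_range) == 0) stop("no admissible k in 'k_range'")
    fits <- lapply(k_range, run_k)
    best <- which.max(vapply(fits, `[[`, numeric(1), "mean_sil"))
    fit <- fits[[best]]
    k <- k_range[best]
  } else {
    if (k > n) stop("k cannot exceed the number of cells")
    if (k < 2) stop("k must be >= 2 (or 'auto')")
    fit <- run_k(k)
  }
  cells$cluster_id <- as.integer(fit$km$cluster)
  cells$silhouette <- fit$sil_widths
  attr(cells, "k") <- as.integer(k)
  attr(cells, "centers") <- fit$km$centers
  attr(cells, "degenerate") <- FALSE
  cells
}

#' Filter cells by silhouette quality
#'
#' Keeps only cells whose silhouette score strictly exceeds the threshold
#' (default 0.4), discarding cells whose color code sits ambiguously between
#' clusters. Cluster assignments are never altered, only membership of the
#' kept set.
#'
#' @param cells data.frame with a `silhouette` column.
#' @param threshold silhouette cutoff (strict inequality).
#' @return A list with data.frames `kept` and `discarded` (an exact
#'   partition of the input rows).
#' @examples
#' x <- data.frame(silhouette = c(0.5, 0.39, 0.41))
#' nrow(silhouette_filter(x)$kept)  # 2
#' @export
silhouette_filter <- function(cells, threshold = 0.4) {
  stopifnot("silhouette" %in% names(cells))
  keep <- !is.na(cells$silhouette) & cells$silhouette > threshold
  list(kept = cells[keep, , drop = FALSE],
       discarded = cells[!keep, , drop = FALSE])
}

#' Ternary-plot coordinates of color fractions
#'
#' Maps fraction triples onto the plane of an equilateral triangle with unit
#' side: pure channel 1 at the origin, pure channel 2 at (1, 0), pure
#' channel 3 at (0.5, sqrt(3)/2); equal fractions map to the centroid.
#'
#' @param f1,f2,f3 channel percentages (summing to 100), vectorized.
#' @return data.frame with columns `u` and `v`.
#' @examples
#' triplot_coordinates(100, 0, 0)  # the first vertex, (0, 0)
#' @export
triplot_coordinates <- function(f1, f2, f3) {
  tot <- f1 + f2 + f3
  b <- f2 / tot; c <- f3 / tot
  data.frame(u = b + c / 2, v = c * sqrt(3) / 2)
}

#' Invert ternary-plot coordinates back to fractions
#'
#' @param u,v planar coordinates from [triplot_coordinates()].
#' @return data.frame with columns `f1`, `f2`, `f3` (percentages).
#' @export
triplot_fractions <- function(u, v) {
  c_ <- v / (sqrt(3) / 2)
  b <- u - c_ / 2
  data.frame(f1 = 100 * (1 - b - c_), f2 = 100 * b, f3 = 100 * c_)
}

potency_from_counts <- function(n_neural, n_mesoderm) {
  ifelse(n_neural > 0 & n_mesoderm > 0, "NM",
         ifelse(n_neural > 0, "N", "M"))
}

#' Classify clones by potency and axial distribution
#'
#' Aggregates cells sharing a clone label (a `cluster_id` from color
#' clustering, or a barcode group) into clone calls: potency `N` (neural
#' only), `M` (mesoderm only) or `NM` (bipotent) from the member tissue
#' labels, plus anterior/posterior composition relative to `ap_boundary`
#' (axial coordinate ascending = posterior; the somite-27 landmark in real
#' data).
#'
#' @param cells data.frame with columns `tissue` (`"neural"`/`"mesoderm"`),
#'   an axial coordinate column, and a clone label column.
#' @param ap_boundary axial position separating anterior (<) from posterior
#'   (>=).
#' @param clone_col name of the clone label column (default
#'   `"cluster_id"`).
#' @param axial_col name of the axial coordinate column (default
#'   `"y_image"`).
#' @return data.frame of clone calls: `clone_id`, `n_cells`, `n_neural`,
#'   `n_mesoderm`, `potency`, `n_anterior`, `n_posterior`; attribute
#'   `potency_table` tabulates potency frequencies.
#' @export
classify_clones <- function(cells, ap_boundary, clone_col = "cluster_id",
                            axial_col = "y_image") {
  stopifnot(all(c("tissue", clone_col, axial_col) %in% names(cells)))
  if (!all(cells$tissue %in% c("neural", "mesoderm")))
    stop("'tissue' must be 'neural' or 'mesoderm'")
  sp <- split(cells, cells[[clone_col]])
  sp <- sp[vapply(sp, nrow, integer(1)) > 0]
  out <- do.call(rbind, lapply(names(sp), function(id) {
    d <- sp[[id]]
    nn <- sum(d$tissue == "neural"); nm <- sum(d$tissue == "mesoderm")
    data.frame(clone_id = id, n_cells = nrow(d), n_neural = nn,
               n_mesoderm = nm, potency = potency_from_counts(nn, nm),
               n_anterior = sum(d[[axial_col]] < ap_boundary),
               n_posterior = sum(d[[axial_col]] >= ap_boundary),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "potency_table") <- table(factor(out$potency,
                                             levels = c("N", "M", "NM")))
  out
}

#' Group cells into clones by exact barcode match
#'
#' Cells sharing an identical barcode string form a clone; rows whose
#' barcode contains characters outside \{A, C, G, T\} (ambiguous sequencing
#' calls) are excluded and recorded. Downstream potency and axial
#' classification is identical to [classify_clones()].
#'
#' @param table data.frame with columns `barcode`, `tissue`, `axial_pos`.
#' @param ap_boundary axial position separating anterior from posterior
#'   (defaults to the table's `somite27_coordinate` attribute, else the
#'   median axial position).
#' @return Clone calls as in [classify_clones()]; attribute `excluded`
#'   holds rows dropped for ambiguous barcodes.
#' @export
group_barcodes <- function(table, ap_boundary = NULL) {
  stopifnot(all(c("barcode", "tissue", "axial_pos") %in% names(table)))
  if (is.null(ap_boundary))
    ap_boundary <- attr(table, "somite27_coordinate") %||%
      stats::median(table$axial_pos)
  ok <- grepl("^[ACGT]+$", table$barcode)
  calls <- classify_clones(table[ok, , drop = FALSE], ap_boundary,
                           clone_col = "barcode", axial_col = "axial_pos")
  attr(calls, "excluded") <- table[!ok, , drop = FALSE]
  calls
}

#' Adjusted Rand index between called and ground-truth clones
#'
#' Thin scoring wrapper (adjusted Rand index via the mclust implementation)
#' for comparing cluster assignments with generator clone labels.
#'
#' @param called,truth label vectors of equal length.
#' @return The adjusted Rand index (1 for perfect agreement).
#' @export
score_clone_calls <- function(called, truth) {
  stopifnot(length(called) == length(truth))
  mclust::adjustedRandIndex(called, truth)
}
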