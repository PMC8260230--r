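#' Locate the extreme sliding windows of an ordered expression vector
#'
#' Scans all contiguous windows of `w` cells (stride 1) along the supplied
#' ordering and returns the start indices (1-based) of the windows with the
#' highest and the lowest mean expression. Ties resolve to the earliest
#' start.
#'
#' @param values numeric vector of expression values in pseudotime order.
#' @param w window size in cells (default 100).
#' @return A list: `max_start`, `min_start` (1-based), `max_mean`,
#'   `min_mean`, and `degenerate` (`TRUE` for a constant vector, where both
#'   windows sit at the start by the tie rule).
#' @examples
#' extreme_windows(1:300, w = 100)[c("min_start", "max_start")]  # 1, 201
#' @export
extreme_windows <- function(values, w = 100) {
  n <- length(values)
  if (n < w) stop("need at least 'w' values")
  cs <- c(0, cumsum(values))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  list(max_start = which.max(means), min_start = which.min(means),
       max_mean = max(means), min_mean = min(means),
       degenerate = max(means) == min(means))
}

#' Detect dynamically variable genes along a pseudotime ordering
#'
#' For each gene, finds the sliding windows of `w` cells with maximal and
#' minimal mean expression along the ordering, then tests the two sets of
#' `w` expression measurements against each other with a two-sample t-test
#' (Welch by default). P-values are Benjamini-Hochberg adjusted across
#' genes and genes with adjusted p below `alpha` are called significant.
#'
#' Note that the windows are selected as extremes of the same data that is
#' then tested, so the raw p-values are anti-conservative even for genes
#' with no true trend; the procedure reports this selection-inflated test
#' as such rather than correcting it, and its realized false-positive rate
#' should be judged empirically (see the package vignette).
#'
#' @param mat numeric matrix, cells x genes, rows in pseudotime order.
#' @param w window size (default 100).
#' @param alpha FDR level (default 0.01).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame with one row per gene: `gene`, `window_max_start`,
#'   `window_min_start`, `t_statistic`, `p_value`, `fdr_adjusted_p`,
#'   `significant`, `flagged` (zero variance in both windows, p forced to
#'   1).
#' @export
dynamic_gene_test <- function(mat, w = 100, alpha = 0.01,
                              var_equal = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 3 * w)
  if (anyNA(mat)) stop("expression matrix must have no missing values")
  genes <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  res <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    ew <- extreme_windows(x, w)
    hi <- x[ew$max_start:(ew$max_start + w - 1)]
    lo <- x[ew$min_start:(ew$min_start + w - 1)]
    if (stats::var(hi) == 0 && stats::var(lo) == 0)
      return(data.frame(gene = genes[j], window_max_start = ew$max_start,
                        window_min_start = ew$min_start,
                        t_statistic = NA_real_, p_value = 1,
                        flagged = TRUE, stringsAsFactors = FALSE))
    tt <- stats::t.test(hi, lo, var.equal = var_equal)
    data.frame(gene = genes[j], window_max_start = ew$max_start,
               window_min_start = ew$min_start,
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr_adjusted_p < alpha
  out[, c("gene", "window_max_start", "window_min_start", "t_statistic",
          "p_value", "fdr_adjusted_p", "significant", "flagged")]
}

# centered moving average with shrinking windows at the edges (no padding)
moving_average <- function(x, w) {
  n <- length(x)
  half_lo <- floor((w - 1) / 2); half_hi <- ceiling((w - 1) / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth significant genes and rank by peak position
#'
#' Z-scales each significant gene's expression along the ordering, smooths
#' it with a centered moving average of width `w` (windows shrink at the
#' edges; no padding), records the argmax of the smoothed profile as the
#' gene's peak position, and returns the smoothed matrix with genes ordered
#' by ascending peak, ready for heat-map display.
#'
#' @param mat numeric matrix, cells x genes, rows in pseudotime order.
#' @param results output of [dynamic_gene_test()] on the same matrix.
#' @param w smoothing window (default 100).
#' @return Matrix genes x cells (significant genes only, rows ordered by
#'   peak position) with attribute `peaks` (named vector of peak cell
#'   indices). Zero significant genes yield a 0-row matrix.
#' @export
smooth_and_rank <- function(mat, results, w = 100) {
  sig <- results$gene[results$significant & !results$flagged]
  sig <- intersect(sig, colnames(mat) %||% as.character(seq_len(ncol(mat))))
  if (length(sig) == 0) {
    out <- matrix(numeric(0), nrow = 0, ncol = nrow(mat))
    attr(out, "peaks") <- setNames(numeric(0), character(0))
    return(out)
  }
  sm <- vapply(sig, function(g) {
    x <- mat[, g]
    s <- stats::sd(x)
    if (s == 0) return(rep(NA_real_, length(x)))  # defensive; cannot be significant
    moving_average((x - mean(x)) / s, w)
  }, numeric(nrow(mat)))
  keep <- colSums(is.na(sm)) == 0
  sm <- sm[, keep, drop = FALSE]
  peaks <- apply(sm, 2, which.max)
  ord <- order(peaks)
  out <- t(sm[, ord, drop = FALSE])
  attr(out, "peaks") <- peaks[ord]
  out
}
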