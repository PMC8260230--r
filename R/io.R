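#' Write and read the tracks CSV dialect
#'
#' Tracks travel as plain CSV with columns `track_id`, `parent_id`,
#' `frame`, `t_min`, `x_um`, `y_um`, `status`.
#'
#' @param tracks data.frame of track samples.
#' @param path file path.
#' @return `read_tracks` returns the tracks data.frame; `write_tracks`
#'   returns `path` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("track_id", "parent_id", "frame", "t_min", "x_um", "y_um",
            "status")
  stopifnot(all(cols %in% names(tracks)))
  utils::write.csv(tracks[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("track_id", "t_min", "x_um", "y_um") %in% names(tr)))
    stop("not a tracks CSV: required columns missing")
  tr
}

#' Write a simulated two-channel image pair to TIFF with a ground-truth
#' sidecar
#'
#' Writes the two channels as a multi-page TIFF (one page per channel,
#' 32-bit float) and the ground-truth counts as a JSON sidecar next to it.
#' Requires the `tiff` package.
#'
#' @param sim an `"image_sim"` from [simulate_two_channel_image()].
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image_pair <- function(sim, path) {
  stopifnot(inherits(sim, "image_sim"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF")
  scale <- max(sim$channel1, sim$channel2, 1)
  tiff::writeTIFF(list(sim$channel1 / scale, sim$channel2 / scale), path,
                  bits.per.sample = 32L)
  truth <- sim$truth
  truth$intensity_scale <- scale
  truth$centers_double <- unname(apply(truth$centers_double, 1, identity,
                                       simplify = FALSE))
  truth$centers_only1 <- unname(apply(truth$centers_only1, 1, identity,
                                      simplify = FALSE))
  truth$centers_only2 <- unname(apply(truth$centers_only2, 1, identity,
                                      simplify = FALSE))
  jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a two-channel TIFF image pair
#'
#' @param path TIFF path written by [write_image_pair()] (or any two-page
#'   TIFF).
#' @return A list with `channel1`, `channel2` matrices and, when present,
#'   the parsed JSON `truth` sidecar.
#' @export
read_image_pair <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a two-page TIFF")
  out <- list(channel1 = pages[[1]], channel2 = pages[[2]])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    out$truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(out$truth$intensity_scale)) {
      out$channel1 <- out$channel1 * out$truth$intensity_scale
      out$channel2 <- out$channel2 * out$truth$intensity_scale
    }
  }
  out
}

#' Write and read cell color / barcode tables and expression matrices
#'
#' Plain-CSV round trips for the remaining interchange tables: per-cell
#' color intensities (with any annotation columns), barcode tables, and a
#' cells-by-genes expression matrix (cells as rows, first column
#' `cell_id`).
#'
#' @param x data.frame (tables) or numeric matrix (expression).
#' @param path file path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
write_cell_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_cell_table
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x))
  df <- data.frame(cell_id = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
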