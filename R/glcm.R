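# Lattice ROI segmentation and symmetric probability-normalized GLCMs.

#' GLCM displacement vector for a canonical angle
#'
#' Displacements in (row, col) with rows increasing downward:
#' 0 degrees is `(0, +d)`, 45 is `(-d, +d)`, 90 is `(-d, 0)` and
#' 135 is `(-d, -d)`. Opposite directions (+180 degrees) give the GLCM
#' transpose and are covered by symmetrization.
#'
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param d Positive integer pixel offset.
#' @return Integer vector `c(drow, dcol)`.
#' @export
glcm_displacement <- function(angle, d) {
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be a positive integer offset.", call. = FALSE)
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("`angle` must be one of 0, 45, 90, 135.", call. = FALSE)
  )
}

#' Segment a quantized image into a non-overlapping ROI lattice
#'
#' Tiles the image from the top-left corner in steps of `roi_size`.
#' Incomplete boundary tiles are discarded, and tiles whose in-mask pixel
#' fraction falls below `min_mask_fraction` are discarded and recorded in
#' the coverage policy.
#'
#' @param image A `quantized_image` from [quantize()].
#' @param roi_size Square ROI side length in pixels; study defaults are
#'   10, 25, 50, 100.
#' @param min_mask_fraction Minimum in-mask fraction for a window to be
#'   retained (default 0.5).
#' @return An object of class `roi_lattice`: `roi_size`, a tibble
#'   `windows` (`roi_id`, `row`, `col`, `mask_fraction`, 1-based upper-left
#'   corners), and `coverage_policy` listing the dropped windows and the
#'   thresholds applied.
#' @export
segment_rois <- function(image, roi_size, min_mask_fraction = 0.5) {
  stopifnot(inherits(image, "quantized_image"))
  roi_size <- as.integer(roi_size)
  h <- nrow(image$levels)
  w <- ncol(image$levels)
  if (roi_size > min(h, w)) {
    stop("`roi_size` (", roi_size, ") exceeds the image dimensions (",
         h, "x", w, ").", call. = FALSE)
  }
  rows <- seq(1L, h - roi_size + 1L, by = roi_size)
  cols <- seq(1L, w - roi_size + 1L, by = roi_size)
  grid <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  frac <- vapply(seq_len(nrow(grid)), function(k) {
    r <- grid$row[k]; c0 <- grid$col[k]
    mean(image$mask[r:(r + roi_size - 1L), c0:(c0 + roi_size - 1L)])
  }, numeric(1))
  keep <- frac >= min_mask_fraction
  windows <- tibble::tibble(
    roi_id = seq_len(sum(keep)),
    row = grid$row[keep], col = grid$col[keep],
    mask_fraction = frac[keep]
  )
  dropped <- tibble::tibble(row = grid$row[!keep], col = grid$col[!keep],
                            mask_fraction = frac[!keep])
  structure(
    list(roi_size = roi_size, windows = windows,
         coverage_policy = list(min_mask_fraction = min_mask_fraction,
                                boundary = "discard incomplete tiles",
                                dropped = dropped)),
    class = "roi_lattice"
  )
}

#' @export
print.roi_lattice <- function(x, ...) {
  cat("<roi_lattice> ", nrow(x$windows), " windows of ",
      x$roi_size, "x", x$roi_size, " (",
      nrow(x$coverage_policy$dropped), " dropped)\n", sep = "")
  invisible(x)
}

#' Compute a symmetric, probability-normalized co-occurrence matrix
#'
#' Counts ordered pixel pairs `(i, j)` at the displacement given by
#' `angle` and offset `d` inside one square window, adds the transpose
#' (so opposite directions are covered), and divides by the total count.
#' Pairs with either endpoint outside the mask are excluded.
#'
#' @param image A `quantized_image`.
#' @param window Integer `c(row, col)` upper-left corner (1-based) of the
#'   window, e.g. one row of `segment_rois()$windows`.
#' @param size Window side length in pixels.
#' @param angle One of 0, 45, 90, 135.
#' @param d Positive integer offset; must satisfy `d < size`.
#' @param roi_id Optional identifier carried through to the result.
#' @return An object of class `co_occurrence`: `P` (Q x Q probability
#'   matrix summing to 1, symmetric), `Q`, `angle`, `d`, `roi_id`, and
#'   `pair_count` (raw total including transposed pairs).
#' @export
compute_glcm <- function(image, window, size, angle, d, roi_id = NA_integer_) {
  stopifnot(inherits(image, "quantized_image"))
  size <- as.integer(size)
  d <- as.integer(d)
  if (d >= size) {
    stop("Offset d = ", d, " must be smaller than the window size ", size,
         ".", call. = FALSE)
  }
  row <- as.integer(window[1])
  col <- as.integer(window[2])
  h <- nrow(image$levels)
  w <- ncol(image$levels)
  if (row < 1L || col < 1L || row + size - 1L > h || col + size - 1L > w) {
    stop("Window does not lie fully inside the image.", call. = FALSE)
  }
  Q <- image$Q
  C <- glcm_pair_counts(image$levels, image$mask, row, col, size, angle, d, Q)
  if (is.null(C)) {
    stop("No valid in-mask pixel pairs at this displacement.", call. = FALSE)
  }
  C <- C + t(C)
  total <- sum(C)
  structure(
    list(P = C / total, Q = Q, angle = angle, d = d, roi_id = roi_id,
         pair_count = total),
    class = "co_occurrence"
  )
}

# Directed (un-symmetrized) pair counts as a Q x Q matrix, or NULL if no
# valid pairs. Level value v occupies row/column v + 1.
glcm_pair_counts <- function(levels, mask, row, col, size, angle, d, Q) {
  disp <- glcm_displacement(angle, d)
  W <- levels[row:(row + size - 1L), col:(col + size - 1L), drop = FALSE]
  M <- mask[row:(row + size - 1L), col:(col + size - 1L), drop = FALSE]
  src_r <- seq_len(size)
  src_r <- src_r[src_r + disp[1] >= 1L & src_r + disp[1] <= size]
  src_c <- seq_len(size)
  src_c <- src_c[src_c + disp[2] >= 1L & src_c + disp[2] <= size]
  if (length(src_r) == 0L || length(src_c) == 0L) return(NULL)
  i <- W[src_r, src_c, drop = FALSE]
  j <- W[src_r + disp[1], src_c + disp[2], drop = FALSE]
  ok <- M[src_r, src_c, drop = FALSE] &
        M[src_r + disp[1], src_c + disp[2], drop = FALSE]
  ok <- ok & !is.na(i) & !is.na(j)
  if (!any(ok)) return(NULL)
  counts <- tabulate(i[ok] * Q + j[ok] + 1L, nbins = Q * Q)
  matrix(counts, Q, Q, byrow = TRUE)
}

#' Export an ROI lattice as a CSV of window corners
#'
#' Writes `row`, `col` (1-based upper-left corners) and `size` for audit.
#'
#' @param lattice An `roi_lattice`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_lattice <- function(lattice, path) {
  stopifnot(inherits(lattice, "roi_lattice"))
  df <- data.frame(row = lattice$windows$row, col = lattice$windows$col,
                   size = lattice$roi_size)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
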