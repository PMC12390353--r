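# Pre-processing: adaptive Wiener denoising and gray-level quantization.

# Sliding box sum with edge truncation (summed-column trick along each
# dimension); windows near the border use only in-image pixels.
box_sum <- function(x, r) {
  one_dim <- function(m, r) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(seq_len(n) + r, n) + 1L
    lo <- pmax(seq_len(n) - r, 1L)
    cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  t(one_dim(t(one_dim(x, r)), r))
}

#' Adaptive Wiener filter
#'
#' Local minimum-mean-square-error denoiser driven by per-window
#' statistics. For each pixel, with local mean `m` and local variance `v`
#' over a `window x window` neighborhood (truncated at image borders) and
#' the noise-variance estimate `vbar` (the mean of local variances over
#' the mask), the output is
#' `m + max(0, v - vbar) / max(v, vbar) * (pixel - m)`.
#' Smooth regions (`v <= vbar`) collapse to the local mean; structured
#' regions (`v >> vbar`) pass through nearly unchanged.
#'
#' @param slab An [image_slab()].
#' @param window Odd window side length, >= 3 (default 5).
#' @return A denoised [image_slab()] flagged `filtered = TRUE`.
#' @export
wiener_filter <- function(slab, window = 5L) {
  stopifnot(inherits(slab, "image_slab"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3.", call. = FALSE)
  }
  x <- slab$pixels
  if (window > nrow(x) || window > ncol(x)) {
    stop("`window` exceeds an image dimension.", call. = FALSE)
  }
  r <- (window - 1L) %/% 2L
  n <- box_sum(matrix(1, nrow(x), ncol(x)), r)
  m <- box_sum(x, r) / n
  v <- pmax(box_sum(x^2, r) / n - m^2, 0)
  vbar <- mean(v[slab$mask])
  denom <- pmax(v, vbar)
  gain <- ifelse(denom > 0, pmax(v - vbar, 0) / denom, 0)
  out <- m + gain * (x - m)
  image_slab(out, slab$mask,
             density_label = slab$density_label,
             filtered = TRUE, seed = slab$seed)
}

#' Quantize a slab to Q gray levels by min-max normalization
#'
#' Pixels inside the mask are scaled to `[0, 1]` by the masked minimum
#' and maximum, multiplied by `Q - 1`, and rounded to the nearest integer
#' (halves away from zero), giving levels `0 .. Q-1` and hence a `Q x Q`
#' co-occurrence matrix downstream. Scaling by `Q - 1` (rather than `Q`)
#' keeps the level count at exactly `Q`; see the methods vignette for the
#' bin-count discussion. Pixels outside the mask become `NA`.
#'
#' @param slab An [image_slab()] with at least two distinct masked values.
#' @param Q Integer number of gray levels, >= 2. Study defaults are
#'   8, 32, 64 and 128.
#' @return An object of class `quantized_image` with fields `levels`
#'   (integer matrix), `Q`, `source_min`, `source_max`, `mask`, plus the
#'   slab provenance (`density_label`, `filtered`, `seed`).
#' @export
quantize <- function(slab, Q) {
  stopifnot(inherits(slab, "image_slab"))
  Q <- as.integer(Q)
  if (is.na(Q) || Q < 2L) stop("`Q` must be an integer >= 2.", call. = FALSE)
  vals <- slab$pixels[slab$mask]
  mn <- min(vals)
  mx <- max(vals)
  if (mx == mn) {
    stop("Degenerate normalization: the masked image is constant ",
         "(I_Max = I_Min).", call. = FALSE)
  }
  norm <- (slab$pixels - mn) / (mx - mn)
  # round half away from zero; arguments are >= 0 within the mask
  lev <- matrix(as.integer(floor(norm * (Q - 1L) + 0.5)),
                nrow(norm), ncol(norm))
  lev[!slab$mask] <- NA_integer_
  structure(
    list(levels = lev, Q = Q, source_min = mn, source_max = mx,
         mask = slab$mask,
         density_label = slab$density_label,
         filtered = slab$filtered, seed = slab$seed),
    class = "quantized_image"
  )
}

#' @export
print.quantized_image <- function(x, ...) {
  cat("<quantized_image> ", nrow(x$levels), "x", ncol(x$levels),
      ", Q = ", x$Q,
      ", source range [", format(x$source_min, digits = 5), ", ",
      format(x$source_max, digits = 5), "]\n", sep = "")
  invisible(x)
}
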