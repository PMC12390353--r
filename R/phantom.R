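# Synthetic two-tissue slab phantoms with correlated structure and
# count-domain acquisition noise.

#' Specify a synthetic two-tissue phantom slab
#'
#' A phantom spec describes a 2D grayscale slab composed of two tissue
#' classes (adipose and fibroglandular) at a target dense-tissue area
#' fraction, with isotropic spatial correlation and a count-domain noise
#' model (scaled Poisson quantum noise plus additive Gaussian electronic
#' noise). Intensities are detector-count-like, so the denser,
#' more-attenuating fibroglandular class has the *lower* mean intensity.
#'
#' @param height,width Slab dimensions in pixels. Defaults match a
#'   reconstructed tomosynthesis slab of 760 x 240.
#' @param density_fraction Target area fraction of the dense
#'   (fibroglandular) class, strictly between 0 and 1.
#' @param correlation_length Isotropic correlation scale in pixels; the
#'   standard deviation of the Gaussian kernel used to smooth the latent
#'   field before thresholding.
#' @param tissue_values Length-2 numeric, mean intensities of the
#'   (adipose, fibroglandular) classes in arbitrary count-like units.
#' @param quantum_gain Scale of the Poisson (quantum) noise stage;
#'   `0` disables it. The noisy pixel is `rpois(gain * value) / gain`,
#'   so larger gain means relatively less quantum noise.
#' @param electronic_sigma Standard deviation of the additive Gaussian
#'   (electronic) noise stage, in intensity units; `0` disables it.
#' @param seed Integer seed; all randomness in phantom generation is
#'   reproducible from it.
#'
#' @return An object of class `phantom_spec` (a validated list).
#' @seealso [generate_tissue_field()], [add_acquisition_noise()]
#' @export
#' @examples
#' spec <- phantom_spec(height = 120, width = 120, density_fraction = 0.25,
#'                      seed = 1)
#' slab <- generate_tissue_field(spec)
#' mean(slab$pixels == min(slab$pixels))  # close to 0.25
phantom_spec <- function(height = 760L,
                         width = 240L,
                         density_fraction = 0.25,
                         correlation_length = 4,
                         tissue_values = c(adipose = 1200, fibroglandular = 900),
                         quantum_gain = 1,
                         electronic_sigma = 15,
                         seed = 1L) {
  if (!is.numeric(height) || !is.numeric(width) ||
      height < 2 || width < 2) {
    stop("`height` and `width` must be >= 2 pixels.", call. = FALSE)
  }
  if (!is.numeric(density_fraction) || length(density_fraction) != 1 ||
      density_fraction <= 0 || density_fraction >= 1) {
    stop("`density_fraction` must lie strictly between 0 and 1.",
         call. = FALSE)
  }
  if (!is.numeric(correlation_length) || correlation_length <= 0) {
    stop("`correlation_length` must be a positive number of pixels.",
         call. = FALSE)
  }
  if (length(tissue_values) != 2 || any(tissue_values < 0)) {
    stop("`tissue_values` must be two non-negative intensities ",
         "(adipose, fibroglandular).", call. = FALSE)
  }
  if (quantum_gain < 0 || electronic_sigma < 0) {
    stop("`quantum_gain` and `electronic_sigma` must be >= 0.",
         call. = FALSE)
  }
  structure(
    list(
      height = as.integer(height),
      width = as.integer(width),
      density_fraction = density_fraction,
      correlation_length = correlation_length,
      tissue_values = stats::setNames(as.numeric(tissue_values),
                                      c("adipose", "fibroglandular")),
      quantum_gain = quantum_gain,
      electronic_sigma = electronic_sigma,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$height, "x", x$width,
      ", dense fraction ", x$density_fraction,
      ", correlation ", x$correlation_length, " px",
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Construct an image slab
#'
#' Container for a 2D grayscale slab with its analysis mask and
#' provenance. Users normally obtain slabs from
#' [generate_tissue_field()] or [read_slab()] rather than calling this
#' directly.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param mask Logical matrix of the same shape; `TRUE` marks tissue
#'   pixels that participate in quantization and texture estimation.
#' @param density_label Optional dense-tissue fraction used to generate
#'   the slab (`NA` for user-supplied images).
#' @param filtered Logical flag; `TRUE` once a denoising filter has been
#'   applied.
#' @param seed Integer seed used in generation, or `NA`.
#'
#' @return An object of class `image_slab`.
#' @export
image_slab <- function(pixels, mask = NULL, density_label = NA_real_,
                       filtered = FALSE, seed = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix.", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("All pixel values must be finite.", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(pixels))) {
    stop("`mask` must be a logical matrix with the same shape as `pixels`.",
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, mask = mask,
         density_label = density_label,
         filtered = isTRUE(filtered),
         seed = seed),
    class = "image_slab"
  )
}

#' @export
print.image_slab <- function(x, ...) {
  cat("<image_slab> ", nrow(x$pixels), "x", ncol(x$pixels),
      ", density ", format(x$density_label),
      ", filtered ", x$filtered,
      ", intensity range [", format(min(x$pixels), digits = 5), ", ",
      format(max(x$pixels), digits = 5), "]\n", sep = "")
  invisible(x)
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Half-ellipse breast outline: chest wall on column 1, apex at the last
# column; TRUE inside the outline.
breast_outline_mask <- function(height, width) {
  r <- matrix(seq_len(height), height, width)
  c0 <- matrix(rep(seq_len(width), each = height), height, width)
  ((r - (height + 1) / 2) / (height / 2))^2 + ((c0 - 1) / (width - 1))^2 <= 1
}

#' Generate a noiseless two-tissue slab
#'
#' Draws a Gaussian random field (white noise smoothed with an isotropic
#' Gaussian kernel of standard deviation `correlation_length`), thresholds
#' it at the `1 - density_fraction` quantile, and maps the two classes to
#' the tissue mean intensities. By construction the realized dense-class
#' fraction matches the target up to the pixel-count resolution, and the
#' output is bit-identical for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param breast_outline If `TRUE`, restrict the mask to a half-ellipse
#'   breast outline (chest wall on the first column); pixels outside the
#'   outline are set to zero and excluded from the mask. Default `FALSE`
#'   (full rectangular tissue field).
#'
#' @return An [image_slab()] with `filtered = FALSE` and the spec's
#'   density label and seed.
#' @export
generate_tissue_field <- function(spec, breast_outline = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height
  w <- spec$width
  z <- with_local_seed(spec$seed, matrix(stats::rnorm(h * w), h, w))
  # Kernel radius clamped so small slabs remain smoothable.
  radius <- 2L * as.integer(ceiling(3 * spec$correlation_length)) + 1L
  max_r <- min(h, w)
  if (radius > max_r) radius <- max_r - (1L - max_r %% 2L)
  field <- EBImage::imageData(
    EBImage::gblur(z, sigma = spec$correlation_length, radius = radius)
  )
  mask <- if (breast_outline) breast_outline_mask(h, w)
          else matrix(TRUE, h, w)
  thr <- stats::quantile(field[mask], probs = 1 - spec$density_fraction,
                         names = FALSE)
  dense <- field > thr
  pixels <- matrix(spec$tissue_values[["adipose"]], h, w)
  pixels[dense] <- spec$tissue_values[["fibroglandular"]]
  pixels[!mask] <- 0
  image_slab(pixels, mask,
             density_label = spec$density_fraction,
             filtered = FALSE, seed = spec$seed)
}

#' Add scaled-Poisson and Gaussian acquisition noise
#'
#' Emulates detector noise as a scaled Poisson (quantum) process followed
#' by additive Gaussian (electronic) noise:
#' `out = Poisson(gain * pixel) / gain + N(0, electronic_sigma)`,
#' elementwise. With `quantum_gain = 0` the Poisson stage is skipped; with
#' both parameters zero the slab is returned unchanged. Stages compose,
#' so the operation may be applied to an already-noisy slab.
#'
#' @param slab An [image_slab()] with non-negative pixels.
#' @param spec A [phantom_spec()] supplying `quantum_gain` and
#'   `electronic_sigma`.
#' @param seed Integer seed for the noise draw. Defaults to
#'   `spec$seed + 1L` so the noise stream is distinct from, but still
#'   determined by, the phantom seed.
#' @param mask_only If `TRUE`, noise is applied only where the slab mask
#'   is `TRUE`; background pixels pass through unchanged.
#'
#' @return A new [image_slab()]; provenance flags are preserved.
#' @export
add_acquisition_noise <- function(slab, spec, seed = spec$seed + 1L,
                                  mask_only = FALSE) {
  stopifnot(inherits(slab, "image_slab"), inherits(spec, "phantom_spec"))
  px <- slab$pixels
  if (any(px < 0)) {
    stop("Poisson noise is undefined for negative pixel values.",
         call. = FALSE)
  }
  gain <- spec$quantum_gain
  sigma <- spec$electronic_sigma
  if (gain == 0 && sigma == 0) return(slab)
  idx <- if (mask_only) which(slab$mask) else seq_along(px)
  v <- px[idx]
  v <- with_local_seed(seed, {
    if (gain > 0) v <- stats::rpois(length(v), gain * v) / gain
    if (sigma > 0) v <- v + stats::rnorm(length(v), 0, sigma)
    v
  })
  px[idx] <- v
  image_slab(px, slab$mask,
             density_label = slab$density_label,
             filtered = slab$filtered, seed = slab$seed)
}
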