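# Haralick features of a co-occurrence matrix and their aggregation into
# long-form texture surfaces.

#' Names of the ten GLCM texture features
#'
#' Order features (energy, entropy), contrast/structure features
#' (homogeneity, contrast), descriptive statistics of the GLCM itself
#' (mean, variance, correlation), and cluster features (tendency, shade,
#' prominence -- the 2nd, 3rd and 4th central co-moments about the
#' marginal means).
#'
#' @export
glcm_feature_names <- c(
  "energy", "entropy", "homogeneity", "contrast",
  "glcm_mean", "glcm_variance", "correlation",
  "cluster_tendency", "cluster_shade", "cluster_prominence"
)

# Feature sums over the nonzero GLCM cells. `P` is a Q x Q probability
# matrix; levels are 0-based indices. Returns a named numeric vector with
# marginal statistics as attributes.
features_from_matrix <- function(P, Q) {
  nz <- which(P > 0)
  p <- P[nz]
  i <- (nz - 1L) %% Q          # 0-based row level
  j <- (nz - 1L) %/% Q         # 0-based column level
  mu_x <- sum(i * p)
  mu_y <- sum(j * p)
  sig_x <- sqrt(sum(p * (i - mu_x)^2))
  sig_y <- sqrt(sum(p * (j - mu_y)^2))
  degenerate <- sig_x * sig_y == 0
  corr <- if (degenerate) 0 else (sum(i * j * p) - mu_x * mu_y) / (sig_x * sig_y)
  s <- i + j - mu_x - mu_y
  out <- c(
    energy = sum(p^2),
    entropy = -sum(p * log(p)),          # 0 * log(0) never arises: p > 0
    homogeneity = sum(p / (1 + abs(i - j))),
    contrast = sum(p * (i - j)^2),
    glcm_mean = mu_x,
    glcm_variance = sig_x,
    correlation = corr,
    cluster_tendency = sum(s^2 * p),
    cluster_shade = sum(s^3 * p),
    cluster_prominence = sum(s^4 * p)
  )
  attr(out, "mu_y") <- mu_y
  attr(out, "sigma_y") <- sig_y
  attr(out, "degenerate") <- degenerate
  out
}

#' Compute the ten Haralick features of a GLCM
#'
#' Given a symmetric probability-normalized co-occurrence matrix `G`,
#' computes energy `sum G^2`, entropy `-sum G ln G` (natural log, with
#' `0 ln 0 := 0`), homogeneity `sum G / (1 + |i - j|)`, contrast
#' `sum G (i - j)^2`, the GLCM mean `mu_x = sum i G`, the GLCM variance
#' reported as `sigma_x = sqrt(sum G (i - mu_x)^2)`, the correlation
#' `(sum i j G - mu_x mu_y) / (sigma_x sigma_y)`, and the cluster
#' tendency / shade / prominence `sum (i + j - mu_x - mu_y)^k G` for
#' k = 2, 3, 4. Levels `i, j` are the 0-based gray levels.
#'
#' If the GLCM is concentrated on a single level (`sigma_x sigma_y = 0`)
#' the correlation is set to 0 and the `degenerate` attribute is `TRUE`,
#' so aggregation over ROIs stays finite.
#'
#' @param glcm A `co_occurrence` object from [compute_glcm()], or a plain
#'   square probability matrix.
#' @return Named numeric vector of the ten features (see
#'   [glcm_feature_names]) with attributes `mu_y`, `sigma_y` and
#'   `degenerate`.
#' @export
compute_features <- function(glcm) {
  if (inherits(glcm, "co_occurrence")) {
    P <- glcm$P
    Q <- glcm$Q
  } else if (is.matrix(glcm) && nrow(glcm) == ncol(glcm)) {
    P <- glcm
    Q <- nrow(glcm)
    if (abs(sum(P) - 1) > 1e-8 || any(P < 0)) {
      stop("`glcm` must be a probability matrix (non-negative, sum 1).",
           call. = FALSE)
    }
  } else {
    stop("`glcm` must be a co_occurrence object or a square matrix.",
         call. = FALSE)
  }
  features_from_matrix(P, Q)
}

#' Average per-angle feature values into a texture surface record
#'
#' Implements the study's aggregation rule: feature magnitudes are first
#' averaged over the four GLCM angles within each (ROI, offset), then
#' averaged (unweighted) over all retained ROIs.
#'
#' @param tbl A tibble with columns `roi_id`, `angle`, `feature`, `value`
#'   (long form), plus any grouping columns to carry through (e.g.
#'   `roi_size`, `offset`, `quantization`).
#' @return A tibble with one row per feature per carried-through group:
#'   `value` (mean over angles then ROIs) and `n_rois`.
#' @export
aggregate_features <- function(tbl) {
  stopifnot(all(c("roi_id", "angle", "feature", "value") %in% names(tbl)))
  carry <- setdiff(names(tbl), c("roi_id", "angle", "value"))
  per_roi <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(carry, "roi_id")))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  per_roi |>
    dplyr::group_by(dplyr::across(dplyr::all_of(carry))) |>
    dplyr::summarise(value = mean(.data$value),
                     n_rois = dplyr::n(), .groups = "drop")
}

# Per-ROI angle-averaged feature table for one quantized image and one
# ROI size. Returns a list(per_roi = tibble, skipped = tibble).
roi_feature_table <- function(image, roi_size, offsets,
                              angles = c(0, 45, 90, 135),
                              min_mask_fraction = 0.5) {
  lattice <- segment_rois(image, roi_size, min_mask_fraction)
  wins <- lattice$windows
  valid_d <- offsets[offsets < roi_size]
  skipped <- tibble::tibble(roi_size = roi_size,
                            offset = setdiff(offsets, valid_d),
                            reason = "offset >= roi_size")
  if (nrow(wins) == 0L || length(valid_d) == 0L) {
    return(list(per_roi = NULL, skipped = skipped))
  }
  nf <- length(glcm_feature_names)
  rows <- vector("list", nrow(wins) * length(valid_d))
  k <- 0L
  for (w in seq_len(nrow(wins))) {
    for (d in valid_d) {
      acc <- numeric(nf)
      n_ok <- 0L
      for (a in angles) {
        C <- glcm_pair_counts(image$levels, image$mask,
                              wins$row[w], wins$col[w], roi_size, a, d,
                              image$Q)
        if (is.null(C)) next
        C <- C + t(C)
        acc <- acc + features_from_matrix(C / sum(C), image$Q)
        n_ok <- n_ok + 1L
      }
      if (n_ok == 0L) next
      k <- k + 1L
      rows[[k]] <- c(roi_id = wins$roi_id[w], offset = d,
                     acc / n_ok)
    }
  }
  if (k == 0L) return(list(per_roi = NULL, skipped = skipped))
  m <- do.call(rbind, rows[seq_len(k)])
  per_roi <- tibble::as_tibble(as.data.frame(m))
  list(per_roi = per_roi, skipped = skipped)
}

#' Texture surface of a single slab
#'
#' Quantizes the slab at each requested gray-level count, tiles it into
#' non-overlapping square ROIs at each ROI size, computes the
#' angle-averaged Haralick features per (ROI, offset), and averages over
#' ROIs. Offsets with `d >= roi_size` are skipped and recorded in the
#' `skipped` attribute rather than raising an error.
#'
#' @param slab An [image_slab()].
#' @param quantizations Integer vector of gray-level counts
#'   (default `c(8, 32, 64, 128)`).
#' @param roi_sizes Integer vector of square ROI side lengths
#'   (default `c(10, 25, 50, 100)`).
#' @param offsets Integer vector of pixel offsets
#'   (default `c(1, 5, 7, 10, 15, 20)`).
#' @param angles GLCM angles in degrees (default all four canonical).
#' @param min_mask_fraction Minimum in-mask fraction to retain a window.
#' @return A long tibble with columns `feature`, `roi_size`, `offset`,
#'   `quantization`, `density`, `filtered`, `value`, `n_rois`; the skipped
#'   (roi_size, offset) combinations are attached as attribute `skipped`.
#' @export
slab_texture_surface <- function(slab,
                                 quantizations = c(8L, 32L, 64L, 128L),
                                 roi_sizes = c(10L, 25L, 50L, 100L),
                                 offsets = c(1L, 5L, 7L, 10L, 15L, 20L),
                                 angles = c(0, 45, 90, 135),
                                 min_mask_fraction = 0.5) {
  stopifnot(inherits(slab, "image_slab"))
  out <- list()
  skipped <- list()
  for (Q in quantizations) {
    qimg <- quantize(slab, Q)
    for (s in roi_sizes) {
      rt <- roi_feature_table(qimg, s, offsets, angles, min_mask_fraction)
      skipped[[length(skipped) + 1L]] <- rt$skipped
      if (is.null(rt$per_roi)) next
      long <- rt$per_roi |>
        tidyr::pivot_longer(dplyr::all_of(glcm_feature_names),
                            names_to = "feature", values_to = "value") |>
        dplyr::mutate(roi_size = s, quantization = Q)
      # per-ROI values are already angle means; average over ROIs
      agg <- long |>
        dplyr::group_by(.data$feature, .data$roi_size, .data$offset,
                        .data$quantization) |>
        dplyr::summarise(value = mean(.data$value),
                         n_rois = dplyr::n(), .groups = "drop") |>
        dplyr::mutate(density = slab$density_label,
                      filtered = slab$filtered)
      out[[length(out) + 1L]] <- agg
    }
  }
  surface <- dplyr::bind_rows(out) |>
    dplyr::select(dplyr::all_of(c("feature", "roi_size", "offset",
                                  "quantization", "density", "filtered",
                                  "value", "n_rois")))
  attr(surface, "skipped") <- unique(dplyr::bind_rows(skipped))
  surface
}
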