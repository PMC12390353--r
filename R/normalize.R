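# Multi-resolution min-max normalization and robustness summary tables.

# Grouping keys of a surface other than the value columns and the axis
# being normalized or differenced over.
series_keys <- function(surface, axis) {
  setdiff(names(surface),
          c(axis, "value", "n_rois", "n_images", "value_raw"))
}

#' Multi-resolution min-max normalization of a texture surface
#'
#' Rescales each feature's magnitudes to `[0, 1]` within a series: in
#' `fixed_roi` mode the series runs across the pixel offsets of one ROI
#' size (`value' = (value - min) / (max - min)` with the extremes taken
#' over all offsets of that ROI size); in `fixed_offset` mode it runs
#' across ROI sizes at a fixed offset. Each quantization level -- and any
#' other condition column present (density, filter arm, image id) -- is
#' normalized independently. Because the map is invariant to positive
#' affine rescaling of the raw feature, quantization-induced magnitude
#' disparities collapse while trends across the series are preserved.
#'
#' @param surface A long texture surface (e.g. from
#'   [slab_texture_surface()]) with at least `feature`, `roi_size`,
#'   `offset`, `quantization`, `value`.
#' @param mode `"fixed_roi"` (normalize across offsets; default) or
#'   `"fixed_offset"` (normalize across ROI sizes).
#' @return The surface with `value` replaced by the normalized value,
#'   plus columns `mode` and `degenerate` (`TRUE` for constant series,
#'   which are mapped to 0).
#' @export
multires_normalize <- function(surface, mode = c("fixed_roi", "fixed_offset")) {
  mode <- match.arg(mode)
  axis <- if (mode == "fixed_roi") "offset" else "roi_size"
  keys <- series_keys(surface, axis)
  out <- surface |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      .n_axis = dplyr::n_distinct(.data[[axis]]),
      .min = min(.data$value),
      .max = max(.data$value),
      degenerate = .data$.max == .data$.min,
      value = dplyr::if_else(.data$.max > .data$.min,
                             (.data$value - .data$.min) /
                               (.data$.max - .data$.min),
                             0)
    ) |>
    dplyr::ungroup()
  if (any(out$.n_axis < 2L)) {
    warning("Some series have fewer than 2 ", axis,
            " values; their normalization is degenerate.", call. = FALSE)
  }
  out |>
    dplyr::select(-dplyr::all_of(c(".min", ".max", ".n_axis"))) |>
    dplyr::mutate(mode = mode)
}

#' Average change over consecutive pixel-offset pairs
#'
#' For each (feature, ROI size, condition) series, takes the offsets at or
#' above `min_offset` that are present, forms the consecutive pairs (with
#' the default grid: 7-5, 10-7, 15-10, 20-15), and reports the mean raw
#' change and the mean percentage change `100 (v2 - v1) / v1` (denominator
#' at the smaller offset). An ROI size of 10 with the default grid only
#' has the (7-5) pair, since larger offsets do not fit. Pairs whose
#' denominator is zero are omitted from the percentage mean and flagged.
#'
#' @param surface A long texture surface.
#' @param min_offset Smallest offset entering the pairs (default 5; offset
#'   1 is deliberately excluded as the short-offset region is the least
#'   robust).
#' @return A tibble per series with `avg_change`, `avg_pct_change`,
#'   `n_pairs`, `n_pct_pairs`, and `pct_flagged` when zero-denominator
#'   pairs were dropped.
#' @export
consecutive_offset_deltas <- function(surface, min_offset = 5) {
  keys <- series_keys(surface, "offset")
  surface |>
    dplyr::filter(.data$offset >= min_offset) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$offset, .by_group = TRUE) |>
    dplyr::summarise(
      n_pairs = dplyr::n() - 1L,
      avg_change = if (dplyr::n() >= 2L) mean(diff(.data$value)) else NA_real_,
      avg_pct_change = {
        v <- .data$value
        if (length(v) >= 2L) {
          dv <- diff(v)
          v1 <- v[-length(v)]
          ok <- v1 != 0
          if (any(ok)) mean(100 * dv[ok] / v1[ok]) else NA_real_
        } else NA_real_
      },
      n_pct_pairs = {
        v <- .data$value
        if (length(v) >= 2L) sum(v[-length(v)] != 0) else 0L
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_pairs >= 1L) |>
    dplyr::mutate(pct_flagged = .data$n_pct_pairs < .data$n_pairs)
}

#' Min-max feature ranges across images at two quantization levels
#'
#' For each (feature, ROI size, quantization) the minimum and maximum of
#' the per-image mean feature values (means over ROIs and angles) are
#' taken across all images and offsets, pairing a low and a high
#' quantization to expose the magnitude disparity between them.
#'
#' @param per_image_surface A long surface with one row per image and
#'   parameter combination (must contain an `image` identifier column or
#'   at least per-image rows; extremes are taken over all non-key rows).
#' @param Q_low,Q_high The two quantization levels to compare
#'   (defaults 8 and 128).
#' @return A tibble with `feature`, `roi_size`, `quantization`, `min`,
#'   `max`, and `n` (number of values the extremes are taken over).
#' @export
quantization_range_table <- function(per_image_surface, Q_low = 8L,
                                     Q_high = 128L) {
  have <- unique(per_image_surface$quantization)
  use <- intersect(c(Q_low, Q_high), have)
  if (length(use) < 2L) {
    warning("Fewer than two of the requested quantization levels are ",
            "present; the range table compares ", length(use), " level(s).",
            call. = FALSE)
  }
  per_image_surface |>
    dplyr::filter(.data$quantization %in% c(Q_low, Q_high)) |>
    dplyr::group_by(.data$feature, .data$roi_size, .data$quantization) |>
    dplyr::summarise(min = min(.data$value), max = max(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Paired contrasts of a surface across a two-level condition
#'
#' Pairs surface rows that differ only in `condition` (e.g. `filtered`
#' or `density`) and reports the difference and percentage difference of
#' `value` between the two levels, per parameter combination.
#'
#' @param surface A long texture surface containing the condition column
#'   with exactly two distinct values.
#' @param condition Name of the condition column.
#' @return A tibble with the key columns, values at both levels
#'   (`value_lo`, `value_hi` ordered by the condition levels), `diff`
#'   (`hi - lo`) and `pct_diff` (100 * diff / lo, `NA` when `lo` is 0).
#' @export
condition_contrast <- function(surface, condition) {
  lv <- sort(unique(surface[[condition]]))
  if (length(lv) != 2L) {
    stop("`", condition, "` must take exactly two values; found ",
         length(lv), ".", call. = FALSE)
  }
  keys <- series_keys(surface, condition)
  wide <- surface |>
    dplyr::select(dplyr::all_of(c(keys, condition, "value"))) |>
    dplyr::mutate(.lvl = dplyr::if_else(.data[[condition]] == lv[1],
                                        "value_lo", "value_hi")) |>
    dplyr::select(-dplyr::all_of(condition)) |>
    tidyr::pivot_wider(names_from = ".lvl", values_from = "value")
  wide |>
    dplyr::mutate(
      diff = .data$value_hi - .data$value_lo,
      pct_diff = dplyr::if_else(.data$value_lo != 0,
                                100 * .data$diff / .data$value_lo,
                                NA_real_)
    )
}
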