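# Configuration-driven orchestration of the full experiment grid:
# phantoms -> noise -> filter arms -> quantization -> GLCM features ->
# normalization, robustness tables and ANOVA.

#' Build an experiment configuration
#'
#' Collects every knob of the synthetic texture-robustness experiment.
#' The defaults reproduce the study grid: two tissue densities, both
#' filter arms, quantizations 8/32/64/128, ROI sizes 10/25/50/100,
#' offsets 1/5/7/10/15/20 and the four canonical GLCM angles.
#'
#' @param densities Dense-tissue fractions of the phantom arms.
#' @param n_images Phantom realizations (seeds) per density arm.
#' @param height,width Slab dimensions in pixels.
#' @param correlation_length,tissue_values,quantum_gain,electronic_sigma
#'   Passed to [phantom_spec()].
#' @param filter_arms Logical vector: which Wiener-filter arms to run
#'   (default both unfiltered and filtered).
#' @param wiener_window Wiener filter window (odd, default 5).
#' @param quantizations,roi_sizes,offsets,angles Estimation grids.
#' @param normalization_mode `"fixed_roi"` or `"fixed_offset"`.
#' @param base_seed Integer; per-image seeds are derived from it as
#'   `base_seed + image index`.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(densities = c(0.25, 0.5),
                              n_images = 2L,
                              height = 240L, width = 240L,
                              correlation_length = 4,
                              tissue_values = c(adipose = 1200,
                                                fibroglandular = 900),
                              quantum_gain = 1,
                              electronic_sigma = 15,
                              filter_arms = c(FALSE, TRUE),
                              wiener_window = 5L,
                              quantizations = c(8L, 32L, 64L, 128L),
                              roi_sizes = c(10L, 25L, 50L, 100L),
                              offsets = c(1L, 5L, 7L, 10L, 15L, 20L),
                              angles = c(0, 45, 90, 135),
                              normalization_mode = "fixed_roi",
                              base_seed = 1L) {
  cfg <- list(
    densities = as.numeric(densities), n_images = as.integer(n_images),
    height = as.integer(height), width = as.integer(width),
    correlation_length = correlation_length,
    tissue_values = tissue_values,
    quantum_gain = quantum_gain, electronic_sigma = electronic_sigma,
    filter_arms = as.logical(filter_arms),
    wiener_window = as.integer(wiener_window),
    quantizations = as.integer(quantizations),
    roi_sizes = as.integer(roi_sizes),
    offsets = as.integer(offsets),
    angles = as.numeric(angles),
    normalization_mode = match.arg(normalization_mode,
                                   c("fixed_roi", "fixed_offset")),
    base_seed = as.integer(base_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  if (!length(cfg$densities) || any(cfg$densities <= 0 | cfg$densities >= 1))
    stop("`densities` must lie strictly in (0, 1).", call. = FALSE)
  if (cfg$n_images < 1L) stop("`n_images` must be >= 1.", call. = FALSE)
  if (any(cfg$quantizations < 2L))
    stop("`quantizations` must all be >= 2.", call. = FALSE)
  if (any(cfg$roi_sizes > min(cfg$height, cfg$width)))
    stop("Every `roi_size` must fit inside the slab.", call. = FALSE)
  if (any(cfg$offsets < 1L)) stop("`offsets` must be >= 1.", call. = FALSE)
  if (!all(cfg$angles %in% c(0, 45, 90, 135)))
    stop("`angles` must be drawn from 0, 45, 90, 135.", call. = FALSE)
  invisible(cfg)
}

#' Read an experiment configuration from YAML
#'
#' Any field of [experiment_config()] may appear in the file; omitted
#' fields take the defaults. Unknown fields raise an error so typos are
#' caught before compute starts.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("Unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$tissue_values)) raw$tissue_values <- unlist(raw$tissue_values)
  do.call(experiment_config, raw)
}

#' Generate the phantom ensemble of an experiment
#'
#' One noisy slab per (density, image index), plus its Wiener-filtered
#' counterpart when the filtered arm is on. Per-image seeds are
#' `base_seed + sequential index`, so the ensemble is fully reproducible.
#'
#' @param config An [experiment_config()].
#' @return A tibble with columns `density`, `image`, `filtered`, `seed`
#'   and a list-column `slab`.
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  idx <- 0L
  for (dens in config$densities) {
    for (img in seq_len(config$n_images)) {
      idx <- idx + 1L
      seed <- config$base_seed + idx
      spec <- phantom_spec(
        height = config$height, width = config$width,
        density_fraction = dens,
        correlation_length = config$correlation_length,
        tissue_values = config$tissue_values,
        quantum_gain = config$quantum_gain,
        electronic_sigma = config$electronic_sigma,
        seed = seed
      )
      noisy <- add_acquisition_noise(generate_tissue_field(spec), spec)
      if (FALSE %in% config$filter_arms) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          density = dens, image = img, filtered = FALSE, seed = seed,
          slab = list(noisy))
      }
      if (TRUE %in% config$filter_arms) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          density = dens, image = img, filtered = TRUE, seed = seed,
          slab = list(wiener_filter(noisy, config$wiener_window)))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full texture-robustness experiment
#'
#' Executes the whole grid: generates the phantom ensemble, computes the
#' per-image texture surfaces, the ensemble-mean surface, the
#' multi-resolution normalized surface, the consecutive-offset delta
#' tables (per filter arm and per density arm), the cross-quantization
#' range table, and -- when at least two images per cell are available --
#' the correlation-filtered ANOVA effect tables. All outputs are returned
#' in memory; when `out_dir` is given they are also written as tidy CSVs
#' with a JSON manifest, and advisory figures (offset curves and the
#' normalized feature-by-parameter heatmap) are saved when a PNG device
#' is available.
#'
#' @param config An [experiment_config()] (or path to a YAML file).
#' @param out_dir Optional output directory.
#' @param figures Write advisory figures (default `TRUE` when `out_dir`
#'   is given).
#' @return A list: `per_image_surface`, `surface` (ensemble mean),
#'   `normalized`, `delta_filter`, `delta_density`, `range_table`,
#'   `effects` (or `NULL`), `skipped`, `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL,
                           figures = !is.null(out_dir)) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  ensemble <- generate_ensemble(config)

  per_image <- lapply(seq_len(nrow(ensemble)), function(k) {
    surf <- slab_texture_surface(
      ensemble$slab[[k]],
      quantizations = config$quantizations,
      roi_sizes = config$roi_sizes,
      offsets = config$offsets,
      angles = config$angles
    )
    dplyr::mutate(surf, image = ensemble$image[k], seed = ensemble$seed[k])
  })
  skipped <- unique(dplyr::bind_rows(lapply(per_image, attr, "skipped")))
  per_image_surface <- dplyr::bind_rows(per_image)

  surface <- per_image_surface |>
    dplyr::group_by(.data$feature, .data$roi_size, .data$offset,
                    .data$quantization, .data$density, .data$filtered) |>
    dplyr::summarise(value = mean(.data$value),
                     n_rois = sum(.data$n_rois),
                     n_images = dplyr::n(), .groups = "drop")

  normalized <- multires_normalize(surface, config$normalization_mode)

  delta_filter <- if (length(unique(surface$filtered)) > 0)
    consecutive_offset_deltas(surface) else NULL
  delta_density <- if (length(unique(surface$density)) == 2L)
    condition_contrast(surface, "density") else NULL

  range_table <- if (length(config$quantizations) >= 2L) {
    quantization_range_table(per_image_surface,
                             Q_low = min(config$quantizations),
                             Q_high = max(config$quantizations))
  } else {
    warning("Only one quantization level configured; ",
            "no cross-quantization range table.", call. = FALSE)
    NULL
  }

  effects <- NULL
  retained <- NULL
  n_cells <- nrow(ensemble)
  if (config$n_images >= 2L && length(config$quantizations) >= 2L &&
      length(config$roi_sizes) >= 2L) {
    wide <- per_image_surface |>
      tidyr::pivot_wider(names_from = "feature", values_from = "value")
    cf <- correlation_filter(
      wide, features = intersect(glcm_feature_names, names(wide)),
      strata = intersect(c("density", "filtered"), names(wide)))
    retained <- cf$retained
    effects <- effect_table(per_image_surface, features = retained)
    effects$correlation_filter <- cf
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("glcmrobust")),
    r_version = as.character(getRversion()),
    config = unclass(config),
    image_seeds = unique(ensemble$seed),
    skipped_combinations = as.data.frame(skipped),
    retained_features = retained
  )

  result <- list(per_image_surface = per_image_surface,
                 surface = surface, normalized = normalized,
                 delta_filter = delta_filter,
                 delta_density = delta_density,
                 range_table = range_table, effects = effects,
                 skipped = skipped, manifest = manifest)

  if (!is.null(out_dir)) {
    write_experiment(result, out_dir, figures = figures)
  }
  result
}

# Write all tables, the manifest, and (optionally) advisory figures.
write_experiment <- function(result, out_dir, figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                       row.names = FALSE)
    }
  }
  wcsv(result$per_image_surface, "per_image_surface.csv")
  wcsv(result$surface, "texture_surface.csv")
  wcsv(result$normalized, "normalized_surface.csv")
  wcsv(result$delta_filter, "delta_offsets.csv")
  wcsv(result$delta_density, "density_contrast.csv")
  wcsv(result$range_table, "quantization_ranges.csv")
  if (!is.null(result$effects)) {
    wcsv(result$effects$r2, "anova_r2.csv")
    wcsv(result$effects$effects, "anova_effects.csv")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  if (figures && capabilities("png")) {
    try(write_experiment_figures(result, out_dir), silent = TRUE)
  }
  invisible(out_dir)
}

# Offset-curve and heatmap figures (advisory; tables are the tested surface).
write_experiment_figures <- function(result, out_dir) {
  figdir <- file.path(out_dir, "figures")
  dir.create(figdir, showWarnings = FALSE)
  surf <- result$surface
  for (feat in intersect(c("contrast", "cluster_shade"),
                         unique(surf$feature))) {
    d <- surf[surf$feature == feat & surf$offset > 1, ]
    p <- ggplot2::ggplot(
      d, ggplot2::aes(x = .data$offset, y = .data$value,
                      colour = factor(.data$roi_size),
                      linetype = .data$filtered)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::facet_grid(quantization ~ density, scales = "free_y",
                          labeller = ggplot2::label_both) +
      ggplot2::labs(x = "pixel offset d", y = feat,
                    colour = "ROI size", linetype = "filtered") +
      ggplot2::theme_minimal(base_size = 9)
    ggplot2::ggsave(file.path(figdir, paste0("offset_curves_", feat, ".png")),
                    p, width = 7, height = 5, dpi = 150)
  }
  # Fig.-12-style heatmap: features x (offset, ROI) combinations at one Q,
  # each row min-max normalized.
  qs <- sort(unique(surf$quantization))
  q0 <- if (32 %in% qs) 32L else qs[[1]]
  hm <- surf |>
    dplyr::filter(.data$quantization == q0, .data$offset > 1) |>
    dplyr::group_by(.data$feature, .data$roi_size, .data$offset) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(value = if (max(.data$value) > min(.data$value))
      (.data$value - min(.data$value)) / (max(.data$value) - min(.data$value))
      else 0) |>
    dplyr::ungroup() |>
    dplyr::mutate(combo = paste0("D", .data$offset, ".ROI", .data$roi_size))
  p <- ggplot2::ggplot(hm, ggplot2::aes(x = .data$combo, y = .data$feature,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "row-normalized\nmagnitude") +
    ggplot2::labs(x = "offset x ROI combination", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  ggplot2::ggsave(file.path(figdir, "normalized_heatmap.png"), p,
                  width = 7, height = 4, dpi = 150)
  invisible(figdir)
}
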