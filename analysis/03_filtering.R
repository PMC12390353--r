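#!/usr/bin/env Rscript
# How does adaptive Wiener filtering move texture magnitudes?
# Consecutive-offset delta tables (offsets >= 5) per filter arm for
# contrast and cluster shade, plus the paired filtered-vs-unfiltered
# contrast. Requires results/experiment/ from 02_features.R.

suppressMessages({
  library(glcmrobust)
  library(dplyr)
})

surface <- read.csv("results/experiment/texture_surface.csv")

deltas <- surface |>
  filter(feature %in% c("contrast", "cluster_shade"), quantization == 32) |>
  consecutive_offset_deltas() |>
  arrange(feature, filtered, roi_size, density)
write.csv(deltas, "results/delta_by_filter_arm.csv", row.names = FALSE)

cat("Average change over consecutive offsets >= 5 (Q = 32):\n")
deltas |>
  group_by(feature, filtered, roi_size) |>
  summarise(avg_change = mean(avg_change),
            avg_pct_change = mean(avg_pct_change), .groups = "drop") |>
  as.data.frame() |>
  print(row.names = FALSE, digits = 3)

paired <- surface |>
  filter(feature == "contrast") |>
  condition_contrast("filtered")
write.csv(paired, "results/contrast_filter_contrast.csv", row.names = FALSE)

cat("\nPaired filtered-vs-unfiltered contrast (mean % change",
    "by quantization):\n")
paired |>
  group_by(quantization) |>
  summarise(mean_pct_change = mean(pct_diff), .groups = "drop") |>
  as.data.frame() |>
  print(row.names = FALSE, digits = 3)
cat("\nNote: under per-slab min-max quantization of these two-valued",
    "phantoms,\ndenoising shrinks the global intensity range and RAISES",
    "quantized contrast\nat offsets >= 5; only at d = 1, where noise",
    "dominates pixel differences,\ndoes filtering lower contrast.",
    "See the methods vignette.\n")
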