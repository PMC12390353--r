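surface_row <- function(offsets, values, feature = "contrast",
                        roi_size = 25L, quantization = 32L, ...) {
  tibble::tibble(feature = feature, roi_size = roi_size, offset = offsets,
                 quantization = quantization, value = values, ...)
}

test_that("multi-resolution normalization is an exact min-max affine map", {
  s <- surface_row(1:5, c(2, 4, 6, 8, 10))
  n <- multires_normalize(s, "fixed_roi")
  expect_equal(n$value, c(0, 0.25, 0.5, 0.75, 1))
  expect_false(any(n$degenerate))

  set.seed(6)
  v <- rnorm(6)
  n2 <- multires_normalize(surface_row(c(1, 5, 7, 10, 15, 20), v))
  expect_equal(n2$value[which.min(v)], 0)
  expect_equal(n2$value[which.max(v)], 1)
  expect_true(all(n2$value >= 0 & n2$value <= 1))
})

test_that("normalization is invariant to positive affine rescaling and idempotent", {
  set.seed(8)
  v <- rnorm(6)
  s1 <- surface_row(c(1, 5, 7, 10, 15, 20), v, quantization = 8L)
  s2 <- surface_row(c(1, 5, 7, 10, 15, 20), 3.7 * v + 11, quantization = 128L)
  n <- multires_normalize(dplyr::bind_rows(s1, s2))
  expect_equal(n$value[n$quantization == 8], n$value[n$quantization == 128],
               tolerance = 1e-12)

  again <- multires_normalize(n)
  expect_equal(again$value, n$value, tolerance = 1e-12)
})

test_that("constant series are flagged degenerate and mapped to zero", {
  s <- surface_row(c(1, 5, 7), c(4, 4, 4))
  expect_warning(n <- multires_normalize(s), NA)
  expect_true(all(n$degenerate))
  expect_equal(n$value, c(0, 0, 0))
})

test_that("fixed-offset mode normalizes across ROI sizes", {
  s <- tibble::tibble(feature = "entropy", roi_size = c(10L, 25L, 50L, 100L),
                      offset = 5L, quantization = 32L, value = c(1, 2, 3, 5))
  n <- multires_normalize(s, "fixed_offset")
  expect_equal(n$value, c(0, 0.25, 0.5, 1))
  expect_equal(unique(n$mode), "fixed_offset")
})

test_that("normalization preserves the ranks of monotone offset series", {
  s <- surface_row(c(1, 5, 7, 10, 15, 20), c(1, 3, 4, 8, 9, 12))
  n <- multires_normalize(s)
  expect_equal(cor(s$value, n$value, method = "spearman"), 1)
})

test_that("consecutive-offset deltas follow the pairwise definition", {
  s <- surface_row(c(5, 7, 10, 15, 20), c(10, 12, 13, 14, 15))
  d <- consecutive_offset_deltas(s)
  expect_equal(d$avg_change, 1.25)
  expect_equal(d$avg_pct_change,
               mean(100 * c(2 / 10, 1 / 12, 1 / 13, 1 / 14)))
  expect_equal(d$n_pairs, 4L)
  expect_false(d$pct_flagged)

  # offset 1 is excluded from the pairs
  s1 <- surface_row(c(1, 5, 7), c(100, 10, 12))
  d1 <- consecutive_offset_deltas(s1)
  expect_equal(d1$n_pairs, 1L)
  expect_equal(d1$avg_change, 2)

  # an ROI of 10 has offsets 5 and 7 only: exactly one pair
  s10 <- surface_row(c(1, 5, 7), c(5, 10, 12), roi_size = 10L)
  expect_equal(consecutive_offset_deltas(s10)$n_pairs, 1L)
})

test_that("zero denominators drop out of the percentage mean with a flag", {
  s <- surface_row(c(5, 7, 10), c(0, 2, 3))
  d <- consecutive_offset_deltas(s)
  expect_equal(d$n_pairs, 2L)
  expect_equal(d$n_pct_pairs, 1L)
  expect_true(d$pct_flagged)
  expect_equal(d$avg_pct_change, 50)
})

test_that("quantization range tables take extremes over images and offsets", {
  s <- dplyr::bind_rows(
    surface_row(c(5, 7), c(0.5, 0.8), quantization = 8L, image = 1L),
    surface_row(c(5, 7), c(1.5, 1.0), quantization = 8L, image = 2L),
    surface_row(c(5, 7), c(40, 50), quantization = 128L, image = 1L),
    surface_row(c(5, 7), c(60, 45), quantization = 128L, image = 2L)
  )
  r <- quantization_range_table(s, 8L, 128L)
  expect_equal(r$min[r$quantization == 8], 0.5)
  expect_equal(r$max[r$quantization == 8], 1.5)
  expect_equal(r$min[r$quantization == 128], 40)
  expect_equal(r$max[r$quantization == 128], 60)
  expect_warning(quantization_range_table(s[s$quantization == 8, ], 8L, 128L),
                 "Fewer than two")
})

test_that("condition contrasts pair the two arms of a condition", {
  s <- dplyr::bind_rows(
    surface_row(c(5, 7), c(10, 20), density = 0.25),
    surface_row(c(5, 7), c(15, 22), density = 0.5)
  )
  cc <- condition_contrast(s, "density")
  expect_equal(cc$diff, c(5, 2))
  expect_equal(cc$pct_diff, c(50, 10))
  expect_error(condition_contrast(s[s$density == 0.25, ], "density"),
               "exactly two")
})
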