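test_that("tissue field hits its target density and is reproducible", {
  fracs <- vapply(1:20, function(s) {
    spec <- phantom_spec(height = 120, width = 120, density_fraction = 0.25,
                         seed = s)
    slab <- generate_tissue_field(spec)
    mean(slab$pixels == spec$tissue_values[["fibroglandular"]])
  }, numeric(1))
  expect_true(all(abs(fracs - 0.25) <= 0.02))
  expect_lt(abs(mean(fracs) - 0.25), 0.01)

  spec <- phantom_spec(height = 100, width = 80, density_fraction = 0.5,
                       seed = 42)
  a <- generate_tissue_field(spec)
  b <- generate_tissue_field(spec)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
})

test_that("correlation length controls dense-class run lengths", {
  base <- list(height = 150, width = 150, density_fraction = 0.5, seed = 7)
  slab_for <- function(cl) {
    spec <- do.call(phantom_spec, c(base, list(correlation_length = cl)))
    generate_tissue_field(spec)
  }
  dense_value <- phantom_spec()$tissue_values[["fibroglandular"]]
  rl8 <- mean_run_length(slab_for(8)$pixels == dense_value)
  rl2 <- mean_run_length(slab_for(2)$pixels == dense_value)
  expect_gt(rl8, rl2)
})

test_that("acquisition noise follows the scaled-Poisson plus Gaussian model", {
  spec0 <- phantom_spec(height = 320, width = 320, seed = 5)
  const <- image_slab(matrix(100, 320, 320))

  pois_spec <- phantom_spec(height = 320, width = 320, quantum_gain = 1,
                            electronic_sigma = 0, seed = 5)
  noisy <- add_acquisition_noise(const, pois_spec)
  expect_lt(abs(var(as.vector(noisy$pixels)) - 100) / 100, 0.05)

  gauss_spec <- phantom_spec(height = 320, width = 320, quantum_gain = 0,
                             electronic_sigma = 2, seed = 5)
  noisy <- add_acquisition_noise(const, gauss_spec)
  expect_lt(abs(sd(as.vector(noisy$pixels)) - 2) / 2, 0.05)

  none_spec <- phantom_spec(height = 320, width = 320, quantum_gain = 0,
                            electronic_sigma = 0, seed = 5)
  expect_identical(add_acquisition_noise(const, none_spec)$pixels,
                   const$pixels)

  neg <- image_slab(matrix(c(-1, rep(1, 15)), 4, 4))
  expect_error(add_acquisition_noise(neg, pois_spec), "negative")

  # determinism of the noise stream
  n1 <- add_acquisition_noise(const, pois_spec)
  n2 <- add_acquisition_noise(const, pois_spec)
  expect_identical(n1$pixels, n2$pixels)
})

test_that("noise honors the mask option", {
  mask <- matrix(FALSE, 50, 50)
  mask[, 1:25] <- TRUE
  slab <- image_slab(matrix(100, 50, 50), mask)
  spec <- phantom_spec(height = 50, width = 50, quantum_gain = 1,
                       electronic_sigma = 3, seed = 9)
  noisy <- add_acquisition_noise(slab, spec, mask_only = TRUE)
  expect_identical(noisy$pixels[!mask], slab$pixels[!mask])
  expect_gt(var(noisy$pixels[mask]), 0)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(density_fraction = 0), "between 0 and 1")
  expect_error(phantom_spec(density_fraction = 1.2), "between 0 and 1")
  expect_error(phantom_spec(height = 0), ">= 2")
  expect_error(phantom_spec(correlation_length = -1), "positive")
  expect_error(phantom_spec(electronic_sigma = -5), ">= 0")
})

test_that("breast outline mask restricts the tissue field", {
  spec <- phantom_spec(height = 80, width = 60, density_fraction = 0.4,
                       seed = 3)
  slab <- generate_tissue_field(spec, breast_outline = TRUE)
  expect_false(all(slab$mask))
  expect_true(all(slab$pixels[!slab$mask] == 0))
  dense <- slab$pixels == spec$tissue_values[["fibroglandular"]]
  expect_lt(abs(mean(dense[slab$mask]) - 0.4), 0.02)
})

test_that("slabs round-trip through image files with provenance", {
  spec <- phantom_spec(height = 40, width = 30, density_fraction = 0.3,
                       seed = 8)
  slab <- add_acquisition_noise(generate_tissue_field(spec), spec)
  for (ext in c("png", "tiff")) {
    path <- file.path(withr::local_tempdir(), paste0("slab.", ext))
    write_slab(slab, path)
    back <- read_slab(path)
    bits <- if (ext == "png") 255 else 65535
    tol <- diff(range(slab$pixels)) / bits
    expect_lt(max(abs(back$pixels - slab$pixels)), tol)
    expect_equal(back$density_label, 0.3)
    expect_false(back$filtered)
    expect_equal(back$seed, 8L)
  }
})
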