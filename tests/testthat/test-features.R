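test_that("a single-entry GLCM gives the delta-distribution closed forms", {
  P <- matrix(0, 4, 4)
  P[3, 3] <- 1
  f <- compute_features(P)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["cluster_tendency"]], 0)
  expect_equal(f[["cluster_shade"]], 0)
  expect_equal(f[["correlation"]], 0)  # degenerate, flagged
  expect_true(attr(f, "degenerate"))
})

test_that("the two-level checkerboard GLCM matches hand evaluation", {
  P <- matrix(0, 2, 2)
  P[1, 2] <- 0.5
  P[2, 1] <- 0.5
  f <- compute_features(P)
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["energy"]], 0.5)
  expect_equal(f[["entropy"]], log(2))
  expect_equal(f[["homogeneity"]], 0.5)
  expect_equal(f[["glcm_mean"]], 0.5)
  expect_equal(attr(f, "mu_y"), 0.5)
  expect_equal(f[["cluster_tendency"]], 0)
  expect_equal(f[["cluster_shade"]], 0)
})

test_that("the uniform Q=4 GLCM matches brute-force sums", {
  P <- matrix(1 / 16, 4, 4)
  f <- compute_features(P)
  expect_equal(f[["energy"]], 1 / 16)
  expect_equal(f[["entropy"]], log(16))
  expect_equal(f[["contrast"]], 2.5)
})

test_that("all ten features match a literal double-loop implementation", {
  set.seed(31)
  for (Q in c(3L, 5L, 8L)) {
    for (rep in 1:15) {
      P <- random_glcm(Q)
      got <- compute_features(P)
      ref <- naive_features(P)
      expect_equal(as.numeric(got[glcm_feature_names]),
                   as.numeric(ref[glcm_feature_names]),
                   tolerance = 1e-10)
    }
  }
})

test_that("gray-level reflection preserves contrast and negates cluster shade", {
  set.seed(13)
  for (rep in 1:10) {
    Q <- 6L
    P <- random_glcm(Q)
    refl <- P[Q:1, Q:1]  # i -> Q-1-i on both axes
    f <- compute_features(P)
    g <- compute_features(refl)
    expect_equal(g[["contrast"]], f[["contrast"]], tolerance = 1e-12)
    expect_equal(g[["cluster_shade"]], -f[["cluster_shade"]],
                 tolerance = 1e-12)
  }
})

test_that("entropy peaks at the uniform GLCM and correlation stays bounded", {
  set.seed(41)
  Q <- 5L
  max_ent <- compute_features(matrix(1 / Q^2, Q, Q))[["entropy"]]
  for (rep in 1:20) {
    f <- compute_features(random_glcm(Q))
    expect_lte(f[["entropy"]], max_ent + 1e-12)
    expect_gte(f[["correlation"]], -1 - 1e-12)
    expect_lte(f[["correlation"]], 1 + 1e-12)
  }
})

test_that("symmetric GLCMs have equal marginal moments", {
  set.seed(53)
  P <- random_glcm(7L)
  f <- compute_features(P)
  expect_equal(f[["glcm_mean"]], attr(f, "mu_y"), tolerance = 1e-12)
  expect_equal(f[["glcm_variance"]], attr(f, "sigma_y"), tolerance = 1e-12)
})

test_that("aggregation averages over angles first, then over ROIs", {
  base <- tidyr::expand_grid(roi_id = 1:2, angle = c(0, 45, 90, 135),
                             feature = "contrast")
  # identical values across angles: aggregate reproduces them
  t1 <- dplyr::mutate(base, value = 7)
  a1 <- aggregate_features(t1)
  expect_equal(a1$value, 7)
  expect_equal(a1$n_rois, 2L)

  # angle values 1..4 average to 2.5
  t2 <- dplyr::mutate(base[base$roi_id == 1, ], value = c(1, 2, 3, 4))
  expect_equal(aggregate_features(t2)$value, 2.5)

  # ROI angle-means 10 and 20 average to 15
  t3 <- dplyr::mutate(base, value = ifelse(roi_id == 1, 10, 20))
  a3 <- aggregate_features(t3)
  expect_equal(a3$value, 15)
  expect_equal(a3$n_rois, 2L)
})

test_that("slab surfaces cover exactly the valid parameter grid", {
  spec <- phantom_spec(height = 60, width = 60, density_fraction = 0.4,
                       seed = 14)
  slab <- add_acquisition_noise(generate_tissue_field(spec), spec)
  surf <- slab_texture_surface(slab, quantizations = c(8L, 32L),
                               roi_sizes = c(10L, 25L),
                               offsets = c(1L, 5L, 7L, 10L, 15L, 20L))
  # roi 10 admits offsets {1,5,7}; roi 25 admits all six -> 9 combos
  expect_equal(nrow(surf), 2L * 9L * 10L)
  expect_true(all(surf$value[surf$feature == "energy"] > 0))
  expect_true(all(is.finite(surf$value)))
  skipped <- attr(surf, "skipped")
  expect_setequal(skipped$offset[skipped$roi_size == 10], c(10L, 15L, 20L))
  # n_rois: 60/10 -> 36 windows, 60/25 -> 4 windows
  expect_setequal(unique(surf$n_rois[surf$roi_size == 10]), 36L)
  expect_setequal(unique(surf$n_rois[surf$roi_size == 25]), 4L)
})
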