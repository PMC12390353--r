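test_that("the ROI lattice tiles exactly and discards boundary remainders", {
  q <- make_qimg(matrix(0L, 100, 100), 4)
  expect_equal(nrow(segment_rois(q, 25)$windows), 16L)

  q2 <- make_qimg(matrix(0L, 760, 240), 4)
  expect_equal(nrow(segment_rois(q2, 100)$windows), 14L)  # 7 x 2 tiles

  q3 <- make_qimg(matrix(0L, 9, 9), 4)
  expect_error(segment_rois(q3, 10), "exceeds")
})

test_that("windows dominated by background are dropped and recorded", {
  mask <- matrix(TRUE, 20, 20)
  mask[1:10, 1:10] <- FALSE  # first tile fully background
  mask[1:10, 11:14] <- FALSE # second tile 40% background -> kept
  q <- make_qimg(matrix(0L, 20, 20), 4, mask)
  lat <- segment_rois(q, 10)
  expect_equal(nrow(lat$windows), 3L)
  expect_equal(nrow(lat$coverage_policy$dropped), 1L)
  expect_equal(lat$coverage_policy$dropped$mask_fraction, 0)
})

test_that("GLCMs match hand-enumerated pair counts", {
  # constant 2x2 window: only identical pairs
  q <- make_qimg(matrix(3L, 2, 2), 4)
  g <- compute_glcm(q, c(1, 1), 2, angle = 0, d = 1)
  expect_equal(g$P[4, 4], 1)
  expect_equal(sum(g$P), 1)

  # the row 0,0,1,1 (via a mask restricted to one row of a 4x4 image)
  lev <- matrix(0L, 4, 4)
  lev[1, ] <- c(0L, 0L, 1L, 1L)
  mask <- matrix(FALSE, 4, 4); mask[1, ] <- TRUE
  q <- make_qimg(lev, 2, mask)
  g <- compute_glcm(q, c(1, 1), 4, angle = 0, d = 1)
  expect_equal(g$P, matrix(c(2, 1, 1, 2) / 6, 2, 2))
  expect_equal(g$pair_count, 6)

  # vertical pairs at d = size - 1: one pair per column, doubled
  set.seed(2)
  s <- 6L
  q <- make_qimg(matrix(sample(0:3, s * s, TRUE), s, s), 4)
  g <- compute_glcm(q, c(1, 1), s, angle = 90, d = s - 1L)
  expect_equal(g$pair_count, 2L * s)
})

test_that("offsets not smaller than the window size are rejected", {
  q <- make_qimg(matrix(0L, 10, 10), 2)
  expect_error(compute_glcm(q, c(1, 1), 5, angle = 0, d = 5), "smaller")
})

test_that("GLCMs equal the naive double-loop counter exactly", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(8:32, 1)
    Q <- sample(c(4L, 8L), 1)
    lev <- matrix(sample(0:(Q - 1), n * n, TRUE), n, n)
    q <- make_qimg(lev, Q)
    for (a in c(0, 45, 90, 135)) {
      for (d in 1:3) {
        got <- compute_glcm(q, c(1, 1), n, angle = a, d = d)
        ref <- naive_glcm(lev, Q, a, d)
        expect_identical(got$P, ref$P)
        expect_equal(got$pair_count, ref$pair_count,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("opposite directions are transposes, so symmetrization is direction-free", {
  set.seed(5)
  lev <- matrix(sample(0:3, 144, TRUE), 12, 12)
  # count at theta and at theta + 180 (explicit reversed displacement),
  # symmetrize both: identical matrices
  reversed <- function(angle, d) {
    disp <- glcm_displacement(angle, d)
    h <- nrow(lev); w <- ncol(lev)
    C <- matrix(0, 4, 4)
    for (r in seq_len(h)) for (c0 in seq_len(w)) {
      r2 <- r - disp[1]; c2 <- c0 - disp[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        C[lev[r, c0] + 1, lev[r2, c2] + 1] <-
          C[lev[r, c0] + 1, lev[r2, c2] + 1] + 1
      }
    }
    C <- C + t(C)
    C / sum(C)
  }
  q <- make_qimg(lev, 4)
  for (a in c(0, 45, 90, 135)) {
    fwd <- compute_glcm(q, c(1, 1), 12, angle = a, d = 2)
    expect_equal(fwd$P, reversed(a, 2), tolerance = 1e-15)
  }
})

test_that("GLCM invariants hold on random inputs", {
  set.seed(17)
  for (rep in 1:10) {
    lev <- matrix(sample(0:7, 100, TRUE), 10, 10)
    q <- make_qimg(lev, 8)
    g <- compute_glcm(q, c(1, 1), 10, angle = sample(c(0, 45, 90, 135), 1),
                      d = sample(1:3, 1))
    expect_lt(abs(sum(g$P) - 1), 1e-12)
    expect_identical(g$P, t(g$P))
    expect_true(all(g$P >= 0))
  }
})

test_that("masked pixels are excluded from pair counts", {
  lev <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  q <- make_qimg(lev, 2, mask)
  g <- compute_glcm(q, c(1, 1), 2, angle = 0, d = 1)
  # only the top-row pair (0,0) survives
  expect_identical(g$P, naive_glcm(lev, 2, 0, 1, mask)$P)
  expect_equal(g$pair_count, 2)
})

test_that("ROI lattices export as plain CSV", {
  q <- make_qimg(matrix(0L, 50, 50), 4)
  lat <- segment_rois(q, 25)
  path <- file.path(withr::local_tempdir(), "lattice.csv")
  write_roi_lattice(lat, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 4L)
  expect_equal(unique(back$size), 25L)
})
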