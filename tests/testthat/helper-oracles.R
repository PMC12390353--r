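# Independent brute-force references used as oracles: a naive double-loop
# GLCM counter and literal (unvectorized) Haralick feature sums.

# Wrap a 0-based integer level matrix as a quantized_image.
make_qimg <- function(levels, Q, mask = NULL) {
  levels <- matrix(as.integer(levels), nrow(levels), ncol(levels))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(levels), ncol(levels))
  structure(
    list(levels = levels, Q = as.integer(Q),
         source_min = 0, source_max = Q - 1, mask = mask,
         density_label = NA_real_, filtered = FALSE, seed = NA_integer_),
    class = "quantized_image"
  )
}

# Naive symmetric GLCM: explicit double loop over every pixel of the
# window, counting ordered pairs at the displacement, then adding the
# transpose and normalizing.
naive_glcm <- function(levels, Q, angle, d, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(levels), ncol(levels))
  disp <- switch(as.character(angle),
                 "0" = c(0, d), "45" = c(-d, d),
                 "90" = c(-d, 0), "135" = c(-d, -d))
  h <- nrow(levels); w <- ncol(levels)
  C <- matrix(0, Q, Q)
  for (r in seq_len(h)) {
    for (c0 in seq_len(w)) {
      r2 <- r + disp[1]; c2 <- c0 + disp[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
          mask[r, c0] && mask[r2, c2] &&
          !is.na(levels[r, c0]) && !is.na(levels[r2, c2])) {
        C[levels[r, c0] + 1, levels[r2, c2] + 1] <-
          C[levels[r, c0] + 1, levels[r2, c2] + 1] + 1
      }
    }
  }
  C <- C + t(C)
  list(P = C / sum(C), pair_count = sum(C))
}

# Literal Table-style feature sums, double loop, no vectorization.
naive_features <- function(P) {
  Q <- nrow(P)
  mu_x <- 0; mu_y <- 0
  for (i in 0:(Q - 1)) for (j in 0:(Q - 1)) {
    mu_x <- mu_x + i * P[i + 1, j + 1]
    mu_y <- mu_y + j * P[i + 1, j + 1]
  }
  sx2 <- 0; sy2 <- 0
  for (i in 0:(Q - 1)) for (j in 0:(Q - 1)) {
    sx2 <- sx2 + P[i + 1, j + 1] * (i - mu_x)^2
    sy2 <- sy2 + P[i + 1, j + 1] * (j - mu_y)^2
  }
  sig_x <- sqrt(sx2); sig_y <- sqrt(sy2)
  energy <- 0; entropy <- 0; homog <- 0; contrast <- 0
  sij <- 0; t2 <- 0; t3 <- 0; t4 <- 0
  for (i in 0:(Q - 1)) for (j in 0:(Q - 1)) {
    p <- P[i + 1, j + 1]
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log(p)
    homog <- homog + p / (1 + abs(i - j))
    contrast <- contrast + p * (i - j)^2
    sij <- sij + i * j * p
    s <- i + j - mu_x - mu_y
    t2 <- t2 + s^2 * p
    t3 <- t3 + s^3 * p
    t4 <- t4 + s^4 * p
  }
  corr <- if (sig_x * sig_y > 0) (sij - mu_x * mu_y) / (sig_x * sig_y) else 0
  c(energy = energy, entropy = entropy, homogeneity = homog,
    contrast = contrast, glcm_mean = mu_x, glcm_variance = sig_x,
    correlation = corr, cluster_tendency = t2, cluster_shade = t3,
    cluster_prominence = t4)
}

# Random symmetric probability GLCM for property tests.
random_glcm <- function(Q) {
  C <- matrix(rpois(Q * Q, 3), Q, Q)
  C <- C + t(C)
  if (sum(C) == 0) C[1, 1] <- 1
  C / sum(C)
}

# Naive local-MMSE Wiener estimate: explicit per-pixel window loops with
# edge truncation, population local variance, vbar = mean local variance.
naive_wiener <- function(x, window) {
  r <- (window - 1) / 2
  h <- nrow(x); w <- ncol(x)
  m <- matrix(0, h, w); v <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- max(1, i - r):min(h, i + r)
      ci <- max(1, j - r):min(w, j + r)
      win <- x[ri, ci]
      m[i, j] <- mean(win)
      v[i, j] <- mean(win^2) - mean(win)^2
    }
  }
  vbar <- mean(v)
  gain <- ifelse(pmax(v, vbar) > 0, pmax(v - vbar, 0) / pmax(v, vbar), 0)
  m + gain * (x - m)
}

# Mean run length of TRUE values along matrix rows.
mean_run_length <- function(b) {
  runs <- unlist(lapply(seq_len(nrow(b)), function(r) {
    x <- rle(b[r, ])
    x$lengths[x$values]
  }))
  mean(runs)
}
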