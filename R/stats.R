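# Correlation-based feature filtering and factorial ANOVA / MANOVA of
# parameter effects on feature magnitudes.

#' Drop highly inter-correlated features
#'
#' Computes pairwise absolute Pearson correlations between feature
#' columns -- within each scenario stratum when `strata` is given, then
#' averaged across strata -- and greedily removes one member of every
#' pair whose mean absolute correlation exceeds the threshold. At each
#' step the pair with the largest mean `|r|` is resolved by dropping the
#' member with the larger mean absolute correlation to all remaining
#' features (ties broken by column order), so the result is
#' deterministic. Constant columns carry no information and are dropped
#' first, with a flag.
#'
#' @param feature_table Data frame with one column per feature plus any
#'   scenario columns; rows are observations.
#' @param features Character vector of feature column names (default: all
#'   numeric columns not named in `strata`).
#' @param strata Optional character vector of scenario columns to
#'   stratify the correlation estimates by.
#' @param threshold Mean absolute correlation above which a pair is
#'   considered redundant (default 0.85).
#' @return A list with `retained`, `dropped` (tibble of feature, reason),
#'   and `mean_abs_cor` (the averaged correlation matrix).
#' @export
correlation_filter <- function(feature_table, features = NULL,
                               strata = NULL, threshold = 0.85) {
  df <- as.data.frame(feature_table)
  if (is.null(features)) {
    features <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                        strata)
  }
  if (length(features) < 2L) {
    stop("Need at least two feature columns.", call. = FALSE)
  }
  if (nrow(df) < 3L) stop("Need at least three observations.", call. = FALSE)

  dropped <- tibble::tibble(feature = character(), reason = character())
  constant <- features[vapply(features, function(f) {
    stats::var(df[[f]]) == 0 || !is.finite(stats::var(df[[f]]))
  }, logical(1))]
  if (length(constant)) {
    dropped <- dplyr::bind_rows(
      dropped, tibble::tibble(feature = constant, reason = "constant"))
    features <- setdiff(features, constant)
  }

  strata_id <- if (is.null(strata)) rep(1L, nrow(df))
               else interaction(df[strata], drop = TRUE)
  mats <- lapply(split(seq_len(nrow(df)), strata_id), function(idx) {
    if (length(idx) < 3L) return(NULL)
    sub <- df[idx, features, drop = FALSE]
    ok <- vapply(sub, function(v) stats::var(v) > 0, logical(1))
    m <- matrix(NA_real_, length(features), length(features),
                dimnames = list(features, features))
    if (sum(ok) >= 2L) {
      m[ok, ok] <- abs(stats::cor(sub[, ok, drop = FALSE]))
    }
    m
  })
  mats <- Filter(Negate(is.null), mats)
  if (!length(mats)) stop("No stratum has enough observations.", call. = FALSE)
  mean_cor <- apply(simplify2array(mats), c(1, 2), mean, na.rm = TRUE)
  diag(mean_cor) <- NA_real_

  retained <- features
  repeat {
    sub <- mean_cor[retained, retained, drop = FALSE]
    if (all(is.na(sub)) || max(sub, na.rm = TRUE) <= threshold) break
    top <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    cand <- retained[top]
    mean_to_others <- vapply(cand, function(f) {
      mean(sub[f, setdiff(retained, f)], na.rm = TRUE)
    }, numeric(1))
    drop_f <- cand[which.max(mean_to_others)]
    dropped <- dplyr::bind_rows(
      dropped,
      tibble::tibble(feature = drop_f,
                     reason = sprintf("mean |r| = %.3f with %s",
                                      max(sub, na.rm = TRUE),
                                      setdiff(cand, drop_f))))
    retained <- setdiff(retained, drop_f)
    if (length(retained) < 2L) break
  }
  list(retained = retained, dropped = dropped, mean_abs_cor = mean_cor)
}

#' Factorial ANOVA of parameter effects on a texture feature
#'
#' Fits fixed-effects linear models of a feature magnitude on the
#' texture-estimation factors (ROI size, pixel offset, quantization --
#' all treated as categorical) with main effects only, all two-way
#' interactions, and the full three-way model, and reports the model
#' R-squared ladder together with per-term F tests. Type II sums of
#' squares are used, which stay well defined for the necessarily
#' unbalanced design (offset levels at or above an ROI size have no
#' cells); empty cells are simply absent rows.
#'
#' @param data Data frame of observations (e.g. a per-image texture
#'   surface filtered to one feature).
#' @param response Name of the response column (default `"value"`).
#' @param factors Character vector of factor column names (default
#'   `c("roi_size", "offset", "quantization")`).
#' @param max_order Highest interaction order to fit: 1, 2 or 3.
#' @param alpha Significance level for the significance flags
#'   (default 0.01).
#' @return A list with `r2` (tibble: order, r_squared) and `effects`
#'   (tibble: order, term, df, f_value, p_value, significant).
#' @export
factorial_anova <- function(data, response = "value",
                            factors = c("roi_size", "offset", "quantization"),
                            max_order = 3L, alpha = 0.01) {
  stopifnot(max_order %in% 1:3, length(factors) >= 2L)
  df <- as.data.frame(data)
  for (f in factors) df[[f]] <- factor(df[[f]])
  df$.y <- df[[response]]
  r2 <- list()
  eff <- list()
  for (ord in seq_len(max_order)) {
    rhs <- if (ord == 1L) paste(factors, collapse = " + ")
           else sprintf("(%s)^%d", paste(factors, collapse = " + "), ord)
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
    r2[[ord]] <- tibble::tibble(order = ord,
                                r_squared = summary(fit)$r.squared)
    at <- suppressMessages(car::Anova(fit, type = 2, singular.ok = TRUE))
    terms_tbl <- tibble::tibble(
      order = ord,
      term = rownames(at),
      df = at$Df,
      f_value = at$`F value`,
      p_value = at$`Pr(>F)`
    ) |>
      dplyr::filter(.data$term != "Residuals") |>
      dplyr::mutate(significant = .data$p_value < alpha)
    eff[[ord]] <- terms_tbl
  }
  list(r2 = dplyr::bind_rows(r2), effects = dplyr::bind_rows(eff))
}

#' Per-feature effect table across a texture surface
#'
#' Runs [factorial_anova()] for each feature of a long surface and
#' collects the R-squared ladder and per-term tests, mirroring the usual
#' presentation (one row per feature with main-effect, 2-way and 3-way
#' model R-squared and significance stars).
#'
#' @param surface Long texture surface with a `feature` column.
#' @param features Features to analyze (default: all present).
#' @inheritParams factorial_anova
#' @return A list with `r2` (feature x order) and `effects` (per feature,
#'   order, term).
#' @export
effect_table <- function(surface, features = NULL, response = "value",
                         factors = c("roi_size", "offset", "quantization"),
                         max_order = 3L, alpha = 0.01) {
  if (is.null(features)) features <- unique(surface$feature)
  res <- lapply(features, function(f) {
    d <- surface[surface$feature == f, , drop = FALSE]
    a <- factorial_anova(d, response, factors, max_order, alpha)
    list(r2 = dplyr::mutate(a$r2, feature = f, .before = 1),
         effects = dplyr::mutate(a$effects, feature = f, .before = 1))
  })
  list(r2 = dplyr::bind_rows(lapply(res, `[[`, "r2")),
       effects = dplyr::bind_rows(lapply(res, `[[`, "effects")))
}

#' MANOVA of parameter effects on several features at once
#'
#' Stacks the given feature columns as a multivariate response and tests
#' each factor's multivariate main effect, reporting the Pillai trace by
#' default (the most robust of the classical statistics to covariance
#' heterogeneity; Wilks, Hotelling-Lawley and Roy are available).
#'
#' @param data Data frame with one column per feature (wide form).
#' @param features Character vector of feature column names.
#' @param factors Factor column names (treated as categorical).
#' @param test Multivariate test statistic (default `"Pillai"`).
#' @param alpha Significance level for flags.
#' @return Tibble with one row per factor: statistic, approximate F,
#'   degrees of freedom, p value, significance flag.
#' @export
manova_effects <- function(data,
                           features,
                           factors = c("roi_size", "offset", "quantization"),
                           test = c("Pillai", "Wilks", "Hotelling-Lawley",
                                    "Roy"),
                           alpha = 0.01) {
  test <- match.arg(test)
  df <- as.data.frame(data)
  for (f in factors) df[[f]] <- factor(df[[f]])
  Y <- as.matrix(df[, features, drop = FALSE])
  fit <- stats::manova(
    stats::as.formula(paste("Y ~", paste(factors, collapse = " + "))),
    data = df)
  st <- summary(fit, test = test)$stats
  keep <- rownames(st) != "Residuals"
  tibble::tibble(
    term = trimws(rownames(st)[keep]),
    statistic = st[keep, 2],  # column 2 holds the requested statistic
    approx_f = st[keep, "approx F"],
    num_df = st[keep, "num Df"],
    den_df = st[keep, "den Df"],
    p_value = st[keep, "Pr(>F)"],
    significant = st[keep, "Pr(>F)"] < alpha
  )
}
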