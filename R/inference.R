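#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic referred to the chi-squared upper tail on
#' `g - 1` degrees of freedom (base R's `kruskal.test` behind this surface).
#'
#' @param values Numeric response.
#' @param groups Group label per value (>= 2 groups).
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (length(values) < 3) abort("need at least 3 observations")
  if (length(unique(values)) == 1) {
    return(tibble::tibble(test = "kruskal-wallis", statistic = 0,
                          df = nlevels(groups) - 1L, p_value = 1,
                          n = length(values)))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(test = "kruskal-wallis", statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value,
                 n = length(values))
}

#' Two-sided Mann-Whitney U test
#'
#' Reports `U = min(U1, U2)`. The P value is exact (enumeration) when
#' `n1 * n2 <= 400` and the data are tie-free, and otherwise uses the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return A one-row tibble: `test`, `statistic` (U), `p_value`, `n`, `exact`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n1 * n2 <= 400 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  u1 <- unname(wt$statistic)
  tibble::tibble(test = "mann-whitney", statistic = min(u1, n1 * n2 - u1),
                 p_value = min(1, wt$p.value), n = n1 + n2, exact = exact)
}

#' All pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' @param values Numeric response.
#' @param groups Group label per value.
#' @return A tibble with one row per group pair: `comparison`, `test`,
#'   `statistic`, `p_value`, `p_adjusted` (`min(1, P * n_pairs)`).
#' @export
pairwise_mann_whitney <- function(values, groups) {
  groups <- as.factor(groups)
  pairs <- combn(levels(groups), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    r <- mann_whitney_u(values[groups == pr[1]], values[groups == pr[2]])
    dplyr::mutate(r, comparison = paste(pr, collapse = " vs "), .before = 1)
  })
  dplyr::mutate(out, p_adjusted = bonferroni(.data$p_value))
}

#' Classical one-way ANOVA
#'
#' `F = MS_between / MS_within` on `(g - 1, n - g)` degrees of freedom.
#' When the within-group variance is exactly zero with unequal means the
#' statistic is infinite and P = 0, flagged by `degenerate = TRUE`.
#'
#' @param values Numeric response.
#' @param groups Group label per value (>= 2 groups, each >= 2 values).
#' @return A one-row tibble: `test`, `statistic`, `df1`, `df2`, `p_value`,
#'   `n`, `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("every group needs at least 2 values")
  n <- length(values); g <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  ssb <- sum(table(groups) * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- g - 1L; df2 <- n - g
  if (ssw == 0) {
    degenerate <- ssb > 0
    f <- if (degenerate) Inf else 0
    return(tibble::tibble(test = "anova", statistic = f, df1 = df1, df2 = df2,
                          p_value = if (degenerate) 0 else 1, n = n,
                          degenerate = degenerate))
  }
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(test = "anova", statistic = f, df1 = df1, df2 = df2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE), n = n,
                 degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p P values.
#' @param m Number of comparisons (default `length(p)`).
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p P values in `[0, 1]`.
#' @return Adjusted P values in the original order (base R's
#'   `p.adjust(..., "BH")`).
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
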