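#' Per-group taxon distribution and mean abundance
#'
#' For every taxon observed in a group, computes its distribution `d` (percent
#' of the group's samples in which it occurs with count > 0) and its mean
#' percent relative abundance across those positive samples only. These two
#' quantities define the distribution-abundance relationship on which the
#' core/satellite split rests.
#'
#' @param counts A count tibble.
#' @param metadata Metadata tibble with `sample_id` and `group`.
#' @param groups Group label(s) to summarise; default all groups in the
#'   metadata. Unknown labels are an error.
#' @return A tibble with columns `group`, `taxon_id`, `distribution` (percent),
#'   `mean_abundance` (percent), `n_present`, `n_samples`.
#' @export
summarize_taxa <- function(counts, metadata, groups = NULL) {
  check_counts(counts)
  grp <- sample_groups(counts, metadata)
  if (is.null(groups)) groups <- unique(grp)
  unknown <- setdiff(groups, grp)
  if (length(unknown) > 0) {
    abort(paste0("unknown group label(s): ", paste(unknown, collapse = ", ")))
  }
  rel <- counts_matrix(to_relative_abundance(counts))
  purrr::map_dfr(groups, function(g) {
    cols <- names(grp)[grp == g]
    if (length(cols) < 2) abort(paste0("group '", g, "' has fewer than 2 samples"))
    sub <- rel[, cols, drop = FALSE]
    present <- sub > 0
    n_present <- rowSums(present)
    keep <- n_present > 0
    mean_ab <- rowSums(sub) / pmax(n_present, 1)  # mean over positive samples
    tibble::tibble(
      group = g,
      taxon_id = rownames(sub)[keep],
      distribution = unname(100 * n_present[keep] / length(cols)),
      mean_abundance = unname(mean_ab[keep]),
      n_present = unname(as.integer(n_present[keep])),
      n_samples = length(cols)
    )
  })
}

#' Fit the distribution-abundance regression
#'
#' Ordinary least squares of log10 mean percent abundance on distribution
#' (percent occupancy), the regression whose significance justifies the
#' core/satellite partition. Reports the coefficient of determination, the
#' F statistic on (1, n - 2) degrees of freedom and its upper-tail P value.
#'
#' @param taxon_summary One group's rows from [summarize_taxa()] (at least 3
#'   taxa, non-constant distribution).
#' @param log_abundance Regress log10(abundance) (default) or raw abundance.
#' @return A `da_fit` object; see [tidy.da_fit()] and [glance.da_fit()].
#' @export
fit_distribution_abundance <- function(taxon_summary, log_abundance = TRUE) {
  if (length(unique(taxon_summary$group)) > 1) {
    abort("fit one group at a time (filter the summary first)")
  }
  x <- taxon_summary$distribution
  y <- if (log_abundance) log10(taxon_summary$mean_abundance) else
    taxon_summary$mean_abundance
  n <- length(x)
  if (n < 3) abort("need at least 3 taxa to fit the regression")
  if (var(x) == 0) abort("distribution has zero variance; slope undefined")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - intercept - slope * x)^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  f <- if (r2 >= 1) Inf else (r2 / 1) / ((1 - r2) / (n - 2))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  structure(list(
    slope = slope, intercept = intercept, r_squared = r2,
    fstatistic = f, df = c(1L, n - 2L), p_value = p, n = n,
    log_abundance = log_abundance, group = taxon_summary$group[1],
    data = taxon_summary
  ), class = "da_fit")
}

#' @export
print.da_fit <- function(x, ...) {
  cat("Distribution-abundance regression (group ", x$group, ")\n", sep = "")
  cat(sprintf("  slope = %.4g, intercept = %.4g (%s abundance)\n",
              x$slope, x$intercept, if (x$log_abundance) "log10" else "raw"))
  cat(sprintf("  R^2 = %.3f, F(%d,%d) = %.2f, P = %.3g, n = %d\n",
              x$r_squared, x$df[1], x$df[2], x$fstatistic, x$p_value, x$n))
  invisible(x)
}

#' Tidy a distribution-abundance fit
#'
#' @param x A `da_fit`.
#' @param ... Unused.
#' @return One row per coefficient with `term` and `estimate`.
#' @method tidy da_fit
#' @export
tidy.da_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "distribution"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of a distribution-abundance fit
#'
#' @param x A `da_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `statistic`, `df`, `df.residual`,
#'   `p.value`, `nobs`.
#' @method glance da_fit
#' @export
glance.da_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, statistic = x$fstatistic,
                 df = x$df[1], df.residual = x$df[2], p.value = x$p_value,
                 nobs = x$n)
}

#' Partition taxa into core and satellite by prevalence
#'
#' Labels a taxon `core` in a group when its distribution is at or above the
#' prevalence threshold (default 75 percent, the inclusive ">=" rule), and
#' `satellite` otherwise. The fit of the core taxa's mean abundances to the
#' log-normal distribution is attached as supporting evidence for the
#' threshold choice (see [lognormal_gof()]).
#'
#' @param taxon_summary A [summarize_taxa()] tibble (one or several groups).
#' @param threshold Prevalence threshold in percent, in (0, 100].
#' @return The summary tibble with a `label` column, carrying attributes
#'   `threshold` and `gof` (per-group log-normal goodness-of-fit tibble).
#' @export
partition_taxa <- function(taxon_summary, threshold = 75) {
  if (threshold <= 0 || threshold > 100) abort("threshold must lie in (0, 100]")
  out <- dplyr::mutate(
    taxon_summary,
    label = ifelse(.data$distribution >= threshold, "core", "satellite")
  )
  gof <- out |>
    dplyr::filter(.data$label == "core") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(res = list(lognormal_gof(.data$mean_abundance)),
                     .groups = "drop") |>
    tidyr::unnest_wider("res")
  attr(out, "threshold") <- threshold
  attr(out, "gof") <- gof
  out
}

#' Chi-squared goodness-of-fit of abundances to the log-normal
#'
#' Tests whether a set of mean abundances follows a log-normal distribution:
#' abundances are log10-transformed, the normal is fit by sample mean and SD,
#' the data are binned into `k = max(4, ceiling(sqrt(n)))` equal-probability
#' bins under the fitted normal (adjacent bins merged until every expected
#' count is at least 1), and the Pearson chi-squared statistic is referred to
#' the upper tail on `bins - 3` degrees of freedom (two estimated parameters;
#' floored at 1).
#'
#' @param abundances Positive abundances (core taxa mean abundances).
#' @return A list: `statistic`, `df`, `p_value`, `n`, and `reliable` (FALSE
#'   when fewer than 8 values were supplied).
#' @export
lognormal_gof <- function(abundances) {
  x <- abundances[!is.na(abundances)]
  if (any(x <= 0)) abort("abundances must be positive for a log-normal fit")
  n <- length(x)
  reliable <- n >= 8
  if (n < 4 || sd(log10(x)) == 0) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                n = n, reliable = FALSE))
  }
  z <- log10(x)
  mu <- mean(z); s <- sd(z)
  k <- max(4L, ceiling(sqrt(n)))
  breaks <- qnorm(seq(0, 1, length.out = k + 1), mu, s)
  breaks[1] <- -Inf; breaks[k + 1] <- Inf
  obs <- as.vector(table(cut(z, breaks, include.lowest = TRUE)))
  expd <- rep(n / k, k)
  while (length(expd) > 1 && any(expd < 1)) {   # merge smallest into neighbour
    i <- which.min(expd)
    j <- if (i == 1) 2L else i - 1L
    expd[j] <- expd[j] + expd[i]; obs[j] <- obs[j] + obs[i]
    expd <- expd[-i]; obs <- obs[-i]
  }
  stat <- sum((obs - expd)^2 / expd)
  df <- max(1L, length(expd) - 3L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), n = n,
       reliable = reliable)
}

#' Share of total abundance held by core vs satellite taxa
#'
#' For each sample of a group, the percent of reads belonging to taxa labelled
#' core (resp. satellite) in that group's partition. The two shares sum to 100
#' per sample.
#'
#' @param counts A count tibble.
#' @param partition A [partition_taxa()] result covering the group(s).
#' @param metadata Metadata tibble.
#' @param groups Groups to report; default every group in the partition.
#' @return A tibble with `sample_id`, `group`, `core_pct`, `satellite_pct`.
#' @export
partition_abundance_share <- function(counts, partition, metadata, groups = NULL) {
  grp <- sample_groups(counts, metadata)
  if (is.null(groups)) groups <- unique(partition$group)
  rel <- counts_matrix(to_relative_abundance(counts))
  purrr::map_dfr(groups, function(g) {
    core_taxa <- partition$taxon_id[partition$group == g & partition$label == "core"]
    cols <- names(grp)[grp == g]
    core_pct <- colSums(rel[rownames(rel) %in% core_taxa, cols, drop = FALSE])
    tibble::tibble(sample_id = cols, group = g,
                   core_pct = unname(core_pct),
                   satellite_pct = 100 - unname(core_pct))
  })
}

#' Plot the distribution-abundance relationship
#'
#' Scatter of mean percent abundance (log10 axis) against distribution, with
#' the fitted regression line and the core/satellite prevalence threshold.
#'
#' @param object A `da_fit`.
#' @param threshold Vertical threshold line in percent (default 75).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot da_fit
#' @export
autoplot.da_fit <- function(object, threshold = 75, ...) {
  df <- dplyr::mutate(object$data,
                      label = ifelse(.data$distribution >= threshold,
                                     "core", "satellite"))
  ggplot2::ggplot(df, ggplot2::aes(.data$distribution, .data$mean_abundance)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::scale_colour_manual(values = c(core = "#E69F00", satellite = "grey55")) +
    ggplot2::labs(x = "Distribution (% of samples)",
                  y = "Mean % abundance (positive samples)",
                  colour = NULL,
                  title = paste0("Group ", object$group,
                                 sprintf(": R² = %.2f, F(%d,%d) = %.1f",
                                         object$r_squared, object$df[1],
                                         object$df[2], object$fstatistic))) +
    ggplot2::theme_minimal()
}
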