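#' Fisher's log-series alpha
#'
#' Solves the log-series relation `S = alpha * ln(1 + N/alpha)` for `alpha`
#' given `S` observed taxa among `N` reads, by bracketed root search on
#' `(1e-10, 1e10)`; the returned value satisfies the defining equation to a
#' residual below 1e-8.
#'
#' @param S Observed taxon count (0 < S < N).
#' @param N Total reads.
#' @return The alpha diversity parameter (scalar).
#' @export
fishers_alpha <- function(S, N) {
  if (length(S) != 1 || length(N) != 1) abort("S and N must be scalars")
  if (S <= 0) abort("S must be positive")
  if (S >= N) abort("Fisher's alpha requires S < N (log-series undefined)")
  f <- function(a) a * log1p(N / a) - S
  root <- uniroot(f, interval = c(1e-10, 1e10), tol = .Machine$double.eps^0.75)$root
  # one Newton polish: f'(a) = log1p(N/a) - N/(a+N)
  root - f(root) / (log1p(N / root) - N / (root + N))
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (vegan's `rrarefy`), so rarefied column sums equal `depth` and no rarefied
#' count exceeds the original. Deterministic for a fixed seed.
#'
#' @param counts A count tibble.
#' @param depth Target reads per sample; defaults to the minimum sample total.
#' @param seed Integer seed.
#' @return A rarefied count tibble.
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = 1L) {
  check_counts(counts)
  m <- counts_matrix(counts)
  tot <- colSums(m)
  if (is.null(depth)) depth <- min(tot)
  short <- tot < depth
  if (any(short)) {
    abort(paste0("depth ", depth, " exceeds total reads of sample(s): ",
                 paste(colnames(m)[short], collapse = ", ")))
  }
  # depth is validated above, so rrarefy's advisory warnings are redundant here
  r <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(t(m), depth)))
  counts_tbl(t(r))
}

#' Shannon diversity of an abundance vector
#'
#' `H' = -sum(p_i * ln(p_i))` over positive entries, natural-log units.
#'
#' @param x Non-negative abundances, not all zero.
#' @return Shannon index H'.
#' @export
shannon <- function(x) {
  if (any(x < 0)) abort("abundances must be non-negative")
  if (sum(x) == 0) abort("all-zero abundance vector")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Per-sample alpha diversity across microbiota partitions, with group tests
#'
#' Computes Fisher's alpha (on unrarefied counts) or Shannon diversity (on
#' counts rarefied to `depth`) per sample, on the whole community and — when a
#' partition is supplied — on the core-only and satellite-only submatrices
#' (each sample restricted to the taxa its own group labels core/satellite).
#' Groups are compared per stratum by Kruskal-Wallis, with pairwise
#' Mann-Whitney U tests under Bonferroni correction.
#'
#' @param counts A count tibble.
#' @param metadata Metadata tibble.
#' @param partition Optional [partition_taxa()] result; adds the core and
#'   satellite strata.
#' @param metric `"fisher"` or `"shannon"`.
#' @param depth Rarefaction depth for the Shannon metric (default: minimum
#'   sample total).
#' @param seed Seed for rarefaction.
#' @return A list of class `diversity_result`: `samples` (tibble: `sample_id`,
#'   `group`, `stratum`, `S`, `N`, `value`) and `tests` (tibble of omnibus and
#'   pairwise results). Samples with no reads in a stratum, or where the
#'   metric is undefined, carry `NA` and are excluded from that stratum's
#'   tests (a warning reports them).
#' @export
diversity_by_group <- function(counts, metadata, partition = NULL,
                               metric = c("fisher", "shannon"),
                               depth = NULL, seed = 1L) {
  metric <- match.arg(metric)
  check_counts(counts)
  grp <- sample_groups(counts, metadata)
  base <- if (metric == "shannon") rarefy_counts(counts, depth, seed) else counts
  m <- counts_matrix(base)

  strata <- "whole"
  if (!is.null(partition)) strata <- c(strata, "core", "satellite")

  samples <- purrr::map_dfr(strata, function(st) {
    purrr::map_dfr(colnames(m), function(s) {
      x <- m[, s]
      if (st != "whole") {
        keep <- partition$taxon_id[partition$group == grp[[s]] &
                                     partition$label == st]
        x <- x[rownames(m) %in% keep]
      }
      S <- sum(x > 0); N <- sum(x)
      val <- if (N == 0) NA_real_
      else if (metric == "shannon") shannon(x)
      else if (S > 0 && S < N) fishers_alpha(S, N)
      else NA_real_
      tibble::tibble(sample_id = s, group = grp[[s]], stratum = st,
                     S = as.integer(S), N = as.integer(N), value = val)
    })
  })
  dropped <- samples$sample_id[is.na(samples$value)]
  if (length(dropped) > 0) {
    warn(paste0("excluded from tests (metric undefined/empty stratum): ",
                paste(unique(dropped), collapse = ", ")))
  }

  tests <- purrr::map_dfr(strata, function(st) {
    d <- samples[samples$stratum == st & !is.na(samples$value), ]
    if (length(unique(d$group)) < 2) return(NULL)
    kw <- kruskal_wallis(d$value, d$group)
    pw <- pairwise_mann_whitney(d$value, d$group)
    dplyr::bind_rows(
      dplyr::mutate(kw, stratum = st, comparison = "overall", .before = 1),
      dplyr::mutate(pw, stratum = st, .before = 1)
    )
  })
  structure(list(samples = samples, tests = tests, metric = metric),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("Alpha diversity (", x$metric, ") — ",
      length(unique(x$samples$sample_id)), " samples, strata: ",
      paste(unique(x$samples$stratum), collapse = ", "), "\n", sep = "")
  print(x$tests)
  invisible(x)
}

#' Plot per-sample diversity by group and partition
#'
#' @param object A `diversity_result`.
#' @param ... Unused.
#' @return A ggplot object (boxplots with jittered points, one facet per
#'   stratum).
#' @method autoplot diversity_result
#' @export
autoplot.diversity_result <- function(object, ...) {
  df <- object$samples[!is.na(object$samples$value), ]
  ylab <- if (object$metric == "fisher") "Fisher's alpha" else "Shannon H'"
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(ggplot2::aes(fill = .data$stratum),
                          outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(whole = "grey20", core = "#E69F00",
                                          satellite = "grey70")) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
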