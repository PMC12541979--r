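#' Aggregate KO contributions to level-3 pathways
#'
#' Sums per-sample KO abundances into their pathways (a KO mapped to several
#' pathways contributes its full abundance to each, the standard hierarchy
#' convention), then rescales every sample to percent of its total pathway
#' abundance. Unmapped KOs are excluded; their count is attached and reported.
#'
#' @param contrib Contribution tibble (`sample_id`, `taxon_id`, `function_id`,
#'   `abundance`). An unstratified KO table can be passed after pivoting to
#'   this long layout.
#' @param mapping Tibble with `function_id`, `pathway_id` (and optionally
#'   `pathway_name`).
#' @return A pathway table: tibble `pathway_id` + one percent-abundance column
#'   per sample, attributes `stratum` (`"whole"`) and `unmapped_kos`.
#' @export
aggregate_to_pathways <- function(contrib, mapping) {
  check_contributions(contrib)
  if (nrow(mapping) == 0) abort("empty KO-to-pathway mapping")
  unmapped <- setdiff(unique(contrib$function_id), mapping$function_id)
  if (length(unmapped) > 0) {
    warn(paste0(length(unmapped), " function id(s) absent from the mapping were excluded"))
  }
  long <- contrib |>
    dplyr::inner_join(mapping[c("function_id", "pathway_id")], by = "function_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$pathway_id, .data$sample_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "abundance", values_fill = 0)
  wide <- dplyr::arrange(wide, .data$pathway_id)
  out <- to_relative_abundance(wide)
  attr(out, "stratum") <- "whole"
  attr(out, "unmapped_kos") <- length(unmapped)
  out
}

#' Pathway table restricted to one microbiota partition
#'
#' Keeps only the contributions of taxa labelled `stratum` (core or satellite)
#' in the contributing sample's own group, then aggregates and renormalises
#' within the stratum. Samples with no functional abundance left in the
#' stratum are flagged with a warning and dropped from the table (and hence
#' from that stratum's tests).
#'
#' @param contrib Contribution tibble.
#' @param partition A [partition_taxa()] result.
#' @param metadata Metadata tibble (maps each sample to the group whose
#'   partition labels apply).
#' @param stratum `"core"` or `"satellite"`.
#' @param mapping KO-to-pathway mapping tibble.
#' @return A pathway table (percent within stratum), attribute `stratum` set.
#' @export
stratify_by_partition <- function(contrib, partition, metadata, stratum,
                                  mapping) {
  stratum <- match.arg(stratum, c("core", "satellite"))
  check_metadata(metadata)
  grp <- setNames(as.character(metadata$group), metadata$sample_id)
  keep_key <- paste(partition$group[partition$label == stratum],
                    partition$taxon_id[partition$label == stratum])
  sel <- contrib[paste(grp[contrib$sample_id], contrib$taxon_id) %in% keep_key, ]
  empty <- setdiff(unique(contrib$sample_id), unique(sel$sample_id))
  if (length(empty) > 0) {
    warn(paste0("sample(s) with zero ", stratum, "-stratum abundance dropped: ",
                paste(empty, collapse = ", ")))
  }
  out <- aggregate_to_pathways(sel, mapping)
  attr(out, "stratum") <- stratum
  out
}

#' Filter to pathways above a share of total functionality
#'
#' Keeps pathways whose share of the table's grand total abundance strictly
#' exceeds `threshold` percent (the "> 1 % of total predicted functionality"
#' rule by default).
#'
#' @param pathway_table A pathway table.
#' @param threshold Percent share; strict inequality.
#' @return The filtered pathway table (attributes preserved).
#' @export
abundant_pathways <- function(pathway_table, threshold = 1) {
  m <- as.matrix(pathway_table[-1])
  share <- 100 * rowSums(m) / sum(m)
  out <- pathway_table[share > threshold, , drop = FALSE]
  attr(out, "stratum") <- attr(pathway_table, "stratum")
  out
}

#' Pathways exclusive to the satellite taxa
#'
#' Identifies pathways carried only by the satellite subcommunity: positive
#' abundance in at least one sample of the satellite stratum, zero (or absent)
#' in every sample of the core stratum.
#'
#' @param core,satellite Pathway tables for the two strata, built from the
#'   same contributions.
#' @return Character vector of pathway ids.
#' @export
satellite_exclusive_pathways <- function(core, satellite) {
  sat_pos <- satellite$pathway_id[rowSums(as.matrix(satellite[-1])) > 0]
  core_pos <- core$pathway_id[rowSums(as.matrix(core[-1])) > 0]
  sort(setdiff(sat_pos, core_pos))
}

#' Centred log-ratio transform of a pathway table
#'
#' Zeros are replaced by a multiplicative pseudocount equal to half the
#' smallest positive value in the table: within each sample the zero cells
#' receive the pseudocount and the positive cells are shrunk proportionally so
#' the sample total is preserved. Each sample is then mapped to
#' `clr(x)_i = ln(x_i) - mean(ln(x))`, so its CLR values sum to zero.
#'
#' @param pathway_table A pathway table (non-negative; no all-zero sample).
#' @return A tibble of the same layout holding CLR values.
#' @export
clr_transform <- function(pathway_table) {
  m <- as.matrix(pathway_table[-1])
  if (any(m < 0)) abort("pathway table must be non-negative")
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0("all-zero sample(s): ",
                 paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  pos <- m[m > 0]
  delta <- min(pos) / 2
  for (j in seq_len(ncol(m))) {
    z <- m[, j] == 0
    if (any(z)) {
      m[z, j] <- delta
      m[!z, j] <- m[!z, j] * (tot[j] - sum(z) * delta) / tot[j]
    }
  }
  lm_ <- log(m)
  clr <- sweep(lm_, 2L, colMeans(lm_), "-")
  out <- pathway_table
  out[-1] <- clr
  attr(out, "stratum") <- attr(pathway_table, "stratum")
  out
}

#' Per-pathway group comparisons
#'
#' Omnibus test per pathway (Kruskal-Wallis by default, or classical ANOVA —
#' the route used for CLR heatmap comparisons) with Benjamini-Hochberg
#' adjustment across pathways, plus pairwise Mann-Whitney U tests under
#' Bonferroni correction. Pathways constant across all samples are skipped
#' and reported.
#'
#' @param values A pathway table or CLR tibble (`pathway_id` + sample columns).
#' @param metadata Metadata tibble.
#' @param test `"kw"` or `"anova"`.
#' @return A list of class `pathway_tests`: `omnibus` (tibble sorted by
#'   adjusted P: `pathway_id`, `statistic`, `p_value`, `p_adjusted`) and
#'   `pairwise` (tibble: `pathway_id`, `comparison`, `statistic`, `p_value`,
#'   `p_adjusted`), plus `skipped` (constant pathway ids).
#' @export
compare_pathways <- function(values, metadata, test = c("kw", "anova")) {
  test <- match.arg(test)
  m <- as.matrix(values[-1])
  rownames(m) <- values[[1]]
  check_metadata(metadata)
  idx <- match(colnames(m), metadata$sample_id)
  if (anyNA(idx)) abort("samples absent from metadata")
  grp <- as.character(metadata$group[idx])
  if (length(unique(grp)) < 2) abort("need at least 2 groups")

  constant <- apply(m, 1L, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    warn(paste0(sum(constant), " constant pathway(s) skipped"))
  }
  keep <- rownames(m)[!constant]
  omnibus <- purrr::map_dfr(keep, function(pw) {
    r <- if (test == "kw") kruskal_wallis(m[pw, ], grp)
    else one_way_anova(m[pw, ], grp)
    tibble::tibble(pathway_id = pw, statistic = r$statistic, p_value = r$p_value)
  })
  omnibus <- omnibus |>
    dplyr::mutate(p_adjusted = benjamini_hochberg(.data$p_value)) |>
    dplyr::arrange(.data$p_adjusted, .data$p_value)
  pairwise <- purrr::map_dfr(keep, function(pw) {
    dplyr::mutate(pairwise_mann_whitney(m[pw, ], grp), pathway_id = pw,
                  .before = 1)
  })
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 skipped = rownames(m)[constant], test = test),
            class = "pathway_tests")
}

#' @export
print.pathway_tests <- function(x, ...) {
  cat("Per-pathway ", if (x$test == "kw") "Kruskal-Wallis" else "ANOVA",
      " comparisons (BH-adjusted), top rows:\n", sep = "")
  print(head(x$omnibus, 10))
  invisible(x)
}

#' Ordination of predicted-function profiles
#'
#' Composes [bray_curtis()] and [pcoa()] on pathway relative abundances, and —
#' when metadata is supplied — runs [anosim()] and [pairwise_anosim()] on the
#' same distance matrix.
#'
#' @param pathway_table A pathway table.
#' @param metadata Optional metadata tibble.
#' @param n_perm,seed Passed to the ANOSIM runs.
#' @return A list: `distance`, `pcoa` (a `pcoa_result`), and (with metadata)
#'   `anosim`, `pairwise_anosim`.
#' @export
pathway_pcoa <- function(pathway_table, metadata = NULL, n_perm = 9999,
                         seed = 1L) {
  d <- bray_curtis(pathway_table)
  out <- list(distance = d, pcoa = pcoa(d))
  if (!is.null(metadata)) {
    out$anosim <- anosim(d, metadata, n_perm = n_perm, seed = seed)
    out$pairwise_anosim <- pairwise_anosim(d, metadata, n_perm = n_perm,
                                           seed = seed)
  }
  out
}

#' Heatmap of CLR-transformed pathway abundances
#'
#' @param clr A [clr_transform()] tibble.
#' @param metadata Metadata tibble (orders samples by group).
#' @return A ggplot tile plot.
#' @export
plot_pathway_heatmap <- function(clr, metadata) {
  long <- tidyr::pivot_longer(clr, -1, names_to = "sample_id",
                              values_to = "clr")
  long$group <- metadata$group[match(long$sample_id, metadata$sample_id)]
  long$sample_id <- factor(long$sample_id,
                           levels = metadata$sample_id[order(metadata$group)])
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$pathway_id,
                                     fill = .data$clr)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "CLR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
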