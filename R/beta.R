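#' Bray-Curtis dissimilarity matrix
#'
#' `d(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` over taxa, between all
#' sample pairs. The complement `1 - d` is the similarity scale used in the
#' within/between-group summaries.
#'
#' @param abundance A count or abundance tibble (`taxon_id` + sample columns),
#'   every sample with positive total. Relative and raw abundances give the
#'   same matrix only when sample totals are equal; pass the scale you want
#'   compared (percent relative abundance throughout this package's pipeline).
#' @return A symmetric sample-by-sample numeric matrix with zero diagonal.
#' @export
bray_curtis <- function(abundance) {
  m <- counts_matrix(abundance)
  if (ncol(m) < 2) abort("need at least 2 samples")
  tot <- colSums(m)
  if (any(tot <= 0)) {
    abort(paste0("all-zero sample(s): ", paste(colnames(m)[tot <= 0], collapse = ", ")))
  }
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      d[j, k] <- d[k, j] <- sum(abs(m[, j] - m[, k])) / (tot[j] + tot[k])
    }
  }
  d
}

#' Within- and between-group similarity summaries
#'
#' Mean and SD of Bray-Curtis similarity (`1 - d`) over all within-group
#' sample pairs (per group) and all between-group pairs (per group pair).
#'
#' @param d A dissimilarity matrix from [bray_curtis()].
#' @param metadata Metadata tibble covering the matrix's samples.
#' @return A tibble: `type` (`intra`/`inter`), `comparison`, `mean_similarity`,
#'   `sd_similarity`, `n_pairs`.
#' @export
group_similarity_summary <- function(d, metadata) {
  grp <- matrix_groups(d, metadata)
  lv <- unique(grp)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  sim <- 1 - d[pairs]
  g1 <- grp[pairs[, 1]]; g2 <- grp[pairs[, 2]]
  intra <- purrr::map_dfr(lv, function(g) {
    s <- sim[g1 == g & g2 == g]
    tibble::tibble(type = "intra", comparison = g, mean_similarity = mean(s),
                   sd_similarity = if (length(s) > 1) sd(s) else 0,
                   n_pairs = length(s))
  })
  inter <- purrr::map_dfr(combn(lv, 2, simplify = FALSE), function(pr) {
    s <- sim[(g1 == pr[1] & g2 == pr[2]) | (g1 == pr[2] & g2 == pr[1])]
    tibble::tibble(type = "inter", comparison = paste(pr, collapse = " vs "),
                   mean_similarity = mean(s),
                   sd_similarity = if (length(s) > 1) sd(s) else 0,
                   n_pairs = length(s))
  })
  dplyr::bind_rows(intra, inter)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix:
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' with mid-ranks for ties, and a permutation P value
#' `(1 + #{permuted R >= observed}) / (1 + n_perm)` under random relabelling
#' of samples. With `exact = TRUE` all distinct label assignments are
#' enumerated instead and P is the exact fraction (the observed assignment
#' included).
#'
#' @param d Dissimilarity matrix.
#' @param metadata Metadata tibble (or a character/factor vector of group
#'   labels in sample order).
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Integer seed.
#' @param exact Enumerate all label assignments (feasible for small n only;
#'   capped at 200000 assignments).
#' @return An `anosim_result`: `statistic` (R), `p_value`, `n_perm`, `exact`,
#'   `n`, `groups`.
#' @export
anosim <- function(d, metadata, n_perm = 9999, seed = 1L, exact = FALSE) {
  grp <- matrix_groups(d, metadata)
  sizes <- table(grp)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(paste0("group(s) of size 1: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  n <- length(grp)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  rk <- rank(d[pairs])                       # mid-ranks for ties
  denom <- n * (n - 1) / 4
  r_stat <- function(labels) {
    within <- labels[pairs[, 1]] == labels[pairs[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  obs <- r_stat(grp)
  if (exact) {
    perms <- multiset_permutations(grp, cap = 200000L)
    stats <- apply(perms, 1L, r_stat)
    p <- mean(stats >= obs)
    n_perm <- nrow(perms)
  } else {
    stats <- withr::with_seed(seed,
      vapply(seq_len(n_perm), function(i) r_stat(sample(grp)), numeric(1)))
    p <- (1 + sum(stats >= obs)) / (1 + n_perm)
  }
  structure(list(statistic = obs, p_value = p, n_perm = n_perm, exact = exact,
                 n = n, groups = names(sizes)),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, P = %.4g (%s, n = %d, groups: %s)\n",
              x$statistic, x$p_value,
              if (x$exact) paste0(x$n_perm, " exact assignments")
              else paste0(x$n_perm, " permutations"),
              x$n, paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Tidy an ANOSIM result
#'
#' @param x An `anosim_result`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p.value`, `n.perm`, `exact`, `n`.
#' @method tidy anosim_result
#' @export
tidy.anosim_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n.perm = x$n_perm, exact = x$exact, n = x$n)
}

#' Pairwise ANOSIM with Bonferroni correction
#'
#' Runs [anosim()] on every group pair's submatrix and multiplies each raw P
#' by the number of pairs (capped at 1).
#'
#' @inheritParams anosim
#' @return A tibble: `comparison`, `statistic`, `p_value`, `p_adjusted`,
#'   `n_perm`.
#' @export
pairwise_anosim <- function(d, metadata, n_perm = 9999, seed = 1L) {
  grp <- matrix_groups(d, metadata)
  lv <- unique(grp)
  pairs <- combn(lv, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    keep <- grp %in% pr
    a <- anosim(d[keep, keep, drop = FALSE], grp[keep], n_perm = n_perm,
                seed = seed)
    tibble::tibble(comparison = paste(pr, collapse = " vs "),
                   statistic = a$statistic, p_value = a$p_value,
                   n_perm = a$n_perm)
  })
  dplyr::mutate(out, p_adjusted = bonferroni(.data$p_value, m = length(pairs)))
}

#' SIMPER decomposition of between-group dissimilarity
#'
#' For every between-group sample pair (j, k) the Bray-Curtis dissimilarity is
#' split into per-taxon terms `delta_i = |x_ij - x_ik| / sum_l (x_lj + x_lk)`;
#' each taxon's mean over all pairs is its contribution. Contributions sum
#' exactly to the mean between-group dissimilarity.
#'
#' @param abundance Abundance tibble on the scale used for [bray_curtis()]
#'   (percent relative abundance in this package's pipeline).
#' @param metadata Metadata tibble.
#' @param group_a,group_b The two groups to contrast.
#' @return A tibble sorted by contribution: `taxon_id`, `average` (mean
#'   per-pair contribution), `pct_contribution`, `cumulative_pct`,
#'   `mean_abundance_a`, `mean_abundance_b`; attribute `overall` holds the
#'   mean between-group dissimilarity.
#' @export
simper <- function(abundance, metadata, group_a, group_b) {
  m <- counts_matrix(abundance)
  grp <- sample_groups(abundance, metadata)
  a_cols <- names(grp)[grp == group_a]
  b_cols <- names(grp)[grp == group_b]
  if (length(a_cols) < 1 || length(b_cols) < 1) abort("both groups need samples")
  contrib <- matrix(0, nrow(m), length(a_cols) * length(b_cols))
  idx <- 0L
  for (j in a_cols) {
    for (k in b_cols) {
      idx <- idx + 1L
      contrib[, idx] <- abs(m[, j] - m[, k]) / sum(m[, j] + m[, k])
    }
  }
  avg <- rowMeans(contrib)
  overall <- sum(avg)
  out <- tibble::tibble(
    taxon_id = rownames(m), average = avg,
    pct_contribution = if (overall > 0) 100 * avg / overall else 0,
    mean_abundance_a = rowMeans(m[, a_cols, drop = FALSE]),
    mean_abundance_b = rowMeans(m[, b_cols, drop = FALSE])
  ) |>
    dplyr::arrange(dplyr::desc(.data$average)) |>
    dplyr::mutate(cumulative_pct = cumsum(.data$pct_contribution),
                  .after = "pct_contribution")
  attr(out, "overall") <- overall
  attr(out, "groups") <- c(group_a, group_b)
  out
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: the squared dissimilarities are double-centered
#' (`-1/2 * J D^2 J`), eigendecomposed, and coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Axes with
#' negative eigenvalues are dropped and reported; percent variance is taken
#' relative to the sum of positive eigenvalues.
#'
#' @param d Dissimilarity matrix.
#' @return A `pcoa_result`: `coordinates` (tibble: `sample_id`, `Axis1`, ...),
#'   `eigenvalues` (all, sorted), `pct_variance` (positive axes), and
#'   `negative` (count and total magnitude of negative eigenvalues).
#' @export
pcoa <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-12)) abort("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  g <- -0.5 * scale(t(scale(t(d^2), center = TRUE, scale = FALSE)),
                    center = TRUE, scale = FALSE)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  lam <- e$values[pos]
  coords <- if (any(pos)) {
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), sum(pos))
  } else {
    matrix(numeric(0), n, 0)   # degenerate: all samples at the origin
  }
  if (ncol(coords) > 0) colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  neg <- e$values[e$values < -tol]
  structure(list(
    coordinates = dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(d)),
      tibble::as_tibble(coords, .name_repair = "minimal")),
    eigenvalues = e$values,
    pct_variance = 100 * lam / sum(lam),
    negative = list(count = length(neg), total_magnitude = sum(abs(neg)))
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes (%.1f%% + %.1f%% on the first two)\n",
              nrow(x$coordinates), length(x$pct_variance),
              x$pct_variance[1],
              if (length(x$pct_variance) > 1) x$pct_variance[2] else 0))
  if (x$negative$count > 0) {
    cat(sprintf("  %d negative eigenvalues dropped (total magnitude %.4g)\n",
                x$negative$count, x$negative$total_magnitude))
  }
  invisible(x)
}

#' Tidy PCoA coordinates
#'
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return The coordinate tibble.
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' One-row PCoA summary
#'
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return A tibble: axes retained, % variance of the first two, negative
#'   eigenvalue report.
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(n_axes = length(x$pct_variance),
                 pct_axis1 = x$pct_variance[1],
                 pct_axis2 = if (length(x$pct_variance) > 1) x$pct_variance[2] else NA_real_,
                 n_negative = x$negative$count,
                 negative_magnitude = x$negative$total_magnitude)
}

#' Group confidence ellipse on 2-D ordination coordinates
#'
#' Normal-theory ellipse: centered on the group mean, axes along the
#' eigenvectors of the group covariance, semi-axis lengths
#' `sqrt(lambda_i * qchisq(level, 2))`. A degenerate (line/point) covariance
#' is flagged rather than an error.
#'
#' @param coords Coordinate tibble (`sample_id`, two axis columns) as from
#'   [pcoa()].
#' @param metadata Metadata tibble.
#' @param level Coverage level (default 0.95).
#' @return A tibble per group: `group`, `center_x`, `center_y`, `semi_major`,
#'   `semi_minor`, `angle` (radians, major axis vs x), `n`, `degenerate`.
#' @export
confidence_ellipse <- function(coords, metadata, level = 0.95) {
  check_metadata(metadata)
  grp <- metadata$group[match(coords$sample_id, metadata$sample_id)]
  xy <- as.matrix(coords[, setdiff(names(coords), "sample_id")[1:2]])
  r2 <- qchisq(level, df = 2)
  purrr::map_dfr(unique(grp), function(g) {
    pts <- xy[grp == g, , drop = FALSE]
    if (nrow(pts) < 3) abort(paste0("group '", g, "' has fewer than 3 samples"))
    ctr <- colMeans(pts)
    ev <- eigen(cov(pts), symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    degenerate <- lam[2] <= max(lam[1], .Machine$double.eps) * 1e-12
    tibble::tibble(group = g, center_x = ctr[1], center_y = ctr[2],
                   semi_major = sqrt(lam[1] * r2), semi_minor = sqrt(lam[2] * r2),
                   angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
                   n = nrow(pts), degenerate = degenerate)
  })
}

#' Plot a PCoA ordination with group confidence ellipses
#'
#' @param object A `pcoa_result`.
#' @param metadata Metadata tibble (enables colouring and ellipses).
#' @param level Ellipse coverage level (default 0.95); `NULL` suppresses
#'   ellipses.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, metadata = NULL, level = 0.95, ...) {
  df <- object$coordinates
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i, object$pct_variance[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
  if (is.null(metadata)) return(p + ggplot2::geom_point())
  df$group <- metadata$group[match(df$sample_id, metadata$sample_id)]
  p <- p + ggplot2::geom_point(data = df, ggplot2::aes(colour = .data$group))
  if (!is.null(level)) {
    ell <- confidence_ellipse(object$coordinates, metadata, level)
    theta <- seq(0, 2 * pi, length.out = 120)
    ring <- purrr::map_dfr(seq_len(nrow(ell)), function(i) {
      e <- ell[i, ]
      x0 <- e$semi_major * cos(theta); y0 <- e$semi_minor * sin(theta)
      tibble::tibble(
        group = e$group,
        Axis1 = e$center_x + x0 * cos(e$angle) - y0 * sin(e$angle),
        Axis2 = e$center_y + x0 * sin(e$angle) + y0 * cos(e$angle))
    })
    p <- p + ggplot2::geom_path(data = ring,
                                ggplot2::aes(colour = .data$group, group = .data$group))
  }
  p
}

#' Plot within/between-group similarity means
#'
#' Bar chart of the [group_similarity_summary()] output with SD error bars.
#'
#' @param summary_tbl Output of [group_similarity_summary()].
#' @return A ggplot object.
#' @export
plot_group_similarity <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(.data$comparison, .data$mean_similarity,
                               fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_similarity - .data$sd_similarity,
      ymax = .data$mean_similarity + .data$sd_similarity), width = 0.25) +
    ggplot2::labs(x = NULL, y = "Bray-Curtis similarity", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

# ---- internal ----------------------------------------------------------------

# group labels aligned with a square matrix's sample order
matrix_groups <- function(d, metadata) {
  ids <- rownames(d)
  if (is.data.frame(metadata)) {
    check_metadata(metadata)
    idx <- match(ids, metadata$sample_id)
    if (anyNA(idx)) {
      abort(paste0("samples absent from metadata: ",
                   paste(ids[is.na(idx)], collapse = ", ")))
    }
    setNames(as.character(metadata$group[idx]), ids)
  } else {
    if (length(metadata) != nrow(d)) abort("group vector length mismatch")
    setNames(as.character(metadata), ids)
  }
}

# all distinct permutations of a label multiset (rows of the returned matrix)
multiset_permutations <- function(labels, cap = 200000L) {
  lv <- unique(labels)
  counts <- table(factor(labels, levels = lv))
  total <- factorial(length(labels)) / prod(factorial(counts))
  if (total > cap) abort(paste0("exact enumeration needs ", total, " assignments"))
  n <- length(labels)
  out <- matrix(NA_character_, total, n)
  row <- 0L
  rec <- function(pos, remaining, current) {
    if (pos > n) {
      row <<- row + 1L
      out[row, ] <<- current
      return(invisible(NULL))
    }
    for (l in lv) {
      if (remaining[[l]] > 0L) {
        remaining[[l]] <- remaining[[l]] - 1L
        current[pos] <- l
        rec(pos + 1L, remaining, current)
        remaining[[l]] <- remaining[[l]] + 1L
      }
    }
  }
  rec(1L, as.list(counts), character(n))
  out
}
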