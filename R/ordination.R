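#' Hellinger transform of an abundance table
#'
#' Square root of per-sample proportions — the standard response
#' transformation that makes species abundance data suitable for linear
#' (RDA-style) ordination.
#'
#' @param abundance A count or abundance tibble (`taxon_id` + sample columns).
#' @return A tibble of the same layout with Hellinger-transformed values.
#' @export
hellinger_transform <- function(abundance) {
  m <- as.matrix(abundance[-1])
  tot <- colSums(m)
  if (any(tot <= 0)) abort("all-zero sample in abundance table")
  out <- abundance
  out[-1] <- sqrt(sweep(m, 2L, tot, "/"))
  out
}

#' Redundancy analysis (RDA)
#'
#' Regresses the (column-centered) response matrix on the covariates and
#' eigendecomposes the fitted part. The explained fraction is the constrained
#' inertia (variance of fitted values) over the total inertia, identical to
#' `1 - RSS/TSS` of the multivariate least-squares fit. Collinear covariate
#' columns are dropped (and reported) and the fit proceeds on the reduced
#' rank.
#'
#' @param response Response tibble: id column plus one column per sample
#'   (taxa/pathways in rows). Hellinger-transform species data first
#'   ([hellinger_transform()]).
#' @param metadata Metadata tibble holding the covariates.
#' @param covariates Character vector of metadata column names. Categorical
#'   columns are dummy-coded with a first-level reference.
#' @return An `ordination_fit`: `method`, `total_inertia`,
#'   `constrained_inertia`, `explained_fraction`, constrained `eigenvalues`,
#'   `site_scores` tibble, `rank`, `dropped` (aliased columns).
#' @export
rda <- function(response, metadata, covariates) {
  prep <- ord_prepare(response, metadata, covariates, method = "rda")
  ord_core_fit(prep)
}

#' Canonical correspondence analysis (CCA)
#'
#' Chi-square-standardises the non-negative response matrix (contingency
#' residuals under row/column independence), regresses it on the covariates
#' with sample (row) weights, and eigendecomposes the constrained part.
#' Inertia is in chi-square units; the total equals the table's chi-square
#' statistic divided by its grand total.
#'
#' @inheritParams rda
#' @return An `ordination_fit` (see [rda()]).
#' @export
cca <- function(response, metadata, covariates) {
  prep <- ord_prepare(response, metadata, covariates, method = "cca")
  ord_core_fit(prep)
}

#' @export
print.ordination_fit <- function(x, ...) {
  cat(sprintf("%s fit: constrained %.4g of %.4g total inertia (%.1f%%), rank %d\n",
              toupper(x$method), x$constrained_inertia, x$total_inertia,
              100 * x$explained_fraction, x$rank))
  if (length(x$dropped) > 0) {
    cat("  dropped collinear columns:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-row ordination fit summary
#'
#' @param x An `ordination_fit`.
#' @param ... Unused.
#' @return A tibble: method, inertias, explained fraction, rank.
#' @method glance ordination_fit
#' @export
glance.ordination_fit <- function(x, ...) {
  tibble::tibble(method = x$method, total_inertia = x$total_inertia,
                 constrained_inertia = x$constrained_inertia,
                 explained_fraction = x$explained_fraction, rank = x$rank)
}

#' Monte-Carlo pseudo-F test for one candidate covariate
#'
#' Tests the inertia added by `candidate` on top of the already-selected
#' covariates: `pseudo-F = (added inertia / df_added) / (residual inertia /
#' df_residual)`. The null distribution comes from permuting the rows of the
#' reduced-model residuals (response minus its fit on the selected
#' covariates), the convention of constrained-ordination software;
#' `P = (1 + #\{permuted F >= observed\}) / (1 + n_perm)`, deterministic per
#' seed.
#'
#' @inheritParams rda
#' @param selected Character vector of already-selected covariates (may be
#'   empty).
#' @param candidate The covariate to test (not among `selected`).
#' @param method `"rda"` or `"cca"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A one-row tibble: `candidate`, `added_inertia`, `df_added`,
#'   `pseudo_f`, `p_value`.
#' @export
permutation_pseudo_F <- function(response, metadata, selected, candidate,
                                 method = c("rda", "cca"), n_perm = 999,
                                 seed = 1L) {
  method <- match.arg(method)
  if (candidate %in% selected) abort("candidate already selected")
  prep <- ord_prepare(response, metadata, unique(c(selected, candidate)), method)
  withr::with_seed(seed, ord_test_candidate(prep, selected, candidate, n_perm))
}

#' Forward selection of covariates for constrained ordination
#'
#' Starting from the empty model, repeatedly ranks the remaining candidates by
#' the inertia each would add, permutation-tests them in that order, and adds
#' the first (largest-gain) candidate whose P value is at or below `alpha`.
#' Stops when no candidate qualifies. An empty selection is a valid outcome.
#'
#' @inheritParams permutation_pseudo_F
#' @param candidates Character vector of candidate covariate names.
#' @param alpha Inclusion threshold on the permutation P value.
#' @return An `ordination_selection`: `selected` tibble (selection order,
#'   added inertia, pseudo-F, P, cumulative explained fraction), `trail`
#'   (every candidate tested at every step), `total_inertia`, `method`.
#' @export
forward_select <- function(response, metadata, candidates,
                           method = c("rda", "cca"), alpha = 0.05,
                           n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  if (length(candidates) < 1) abort("need at least one candidate")
  prep <- ord_prepare(response, metadata, candidates, method)
  selected <- character(0)
  remaining <- candidates
  rows <- list(); trail <- list(); step <- 0L
  withr::with_seed(seed, {
    repeat {
      if (length(remaining) == 0) break
      step <- step + 1L
      gains <- vapply(remaining, function(cand) {
        ord_added_inertia(prep, selected, cand)
      }, numeric(1))
      order_try <- remaining[order(gains, decreasing = TRUE)]
      added <- NULL
      for (cand in order_try) {
        res <- ord_test_candidate(prep, selected, cand, n_perm)
        trail[[length(trail) + 1L]] <- dplyr::mutate(res, step = step, .before = 1)
        if (!is.na(res$p_value) && res$p_value <= alpha) {
          added <- res
          break
        }
      }
      if (is.null(added)) break
      selected <- c(selected, added$candidate)
      rows[[length(rows) + 1L]] <- added
      remaining <- setdiff(remaining, added$candidate)
    }
  })
  sel <- dplyr::bind_rows(rows)
  if (nrow(sel) > 0) {
    cum <- vapply(seq_len(nrow(sel)), function(i) {
      ord_inertia(prep, sel$candidate[seq_len(i)]) / prep$total
    }, numeric(1))
    sel <- dplyr::mutate(sel, order = dplyr::row_number(),
                         cumulative_fraction = cum)
  }
  structure(list(selected = sel, trail = dplyr::bind_rows(trail),
                 total_inertia = prep$total, method = method,
                 alpha = alpha, n_perm = n_perm),
            class = "ordination_selection")
}

#' @export
print.ordination_selection <- function(x, ...) {
  cat(sprintf("Forward selection (%s, alpha = %g, %d permutations)\n",
              toupper(x$method), x$alpha, x$n_perm))
  if (nrow(x$selected) == 0) cat("  no covariate selected\n")
  else print(x$selected)
  invisible(x)
}

#' Tidy a forward-selection result
#'
#' @param x An `ordination_selection`.
#' @param ... Unused.
#' @return The `selected` tibble (one row per selected covariate).
#' @method tidy ordination_selection
#' @export
tidy.ordination_selection <- function(x, ...) x$selected

# ---- internal engine ---------------------------------------------------------

# Builds the common linear-algebra state: Y in the method's metric (rows =
# samples), and one centered (weighted, for CCA) design block per covariate.
ord_prepare <- function(response, metadata, covariates, method) {
  m <- as.matrix(response[-1])
  rownames(m) <- response[[1]]
  ids <- colnames(m)
  check_metadata(metadata)
  idx <- match(ids, metadata$sample_id)
  if (anyNA(idx)) abort("samples absent from metadata")
  md <- metadata[idx, , drop = FALSE]
  missing <- setdiff(covariates, names(md))
  if (length(missing) > 0) {
    abort(paste0("covariate(s) not in metadata: ", paste(missing, collapse = ", ")))
  }
  Y <- t(m)                      # samples x responses
  n <- nrow(Y)

  if (method == "rda") {
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    w <- rep(1, n)
    center <- function(block) scale(block, center = TRUE, scale = FALSE)
  } else {
    if (any(Y < 0)) abort("CCA requires non-negative responses")
    r <- rowSums(Y); cc <- colSums(Y)
    if (any(r == 0)) abort("sample(s) with zero total in response")
    if (any(cc == 0)) abort("response column(s) with zero total")
    tot <- sum(Y)
    P <- Y / tot; rp <- r / tot; cp <- cc / tot
    Yc <- (P - outer(rp, cp)) / sqrt(outer(rp, cp))
    w <- rp
    # weighted centering then sqrt-weight rows so unweighted projections apply
    center <- function(block) {
      ctr <- colSums(block * w) / sum(w)
      sqrt(w) * sweep(block, 2L, ctr, "-")
    }
  }

  blocks <- lapply(covariates, function(v) {
    col <- md[[v]]
    if (anyNA(col)) abort(paste0("covariate '", v, "' has missing values"))
    block <- if (is.numeric(col)) matrix(col, ncol = 1,
                                         dimnames = list(NULL, v))
    else {
      f <- factor(col)
      if (nlevels(f) < 2) matrix(0, n, 1, dimnames = list(NULL, v))
      else stats::model.matrix(~f)[, -1, drop = FALSE]
    }
    center(block)
  })
  names(blocks) <- covariates
  list(Y = Yc, blocks = blocks, total = sum(Yc^2), n = n, method = method)
}

ord_design <- function(prep, covariates) {
  if (length(covariates) == 0) {
    return(matrix(0, prep$n, 0))
  }
  do.call(cbind, prep$blocks[covariates])
}

# projection of Y onto span(X): returns fitted matrix and rank
ord_project <- function(X, Y) {
  if (ncol(X) == 0) return(list(fitted = Y * 0, rank = 0L, dropped = character(0)))
  qx <- qr(X)
  if (qx$rank == 0L) {
    return(list(fitted = Y * 0, rank = 0L, dropped = colnames(X)))
  }
  dropped <- if (qx$rank < ncol(X)) colnames(X)[qx$pivot[-seq_len(qx$rank)]]
  else character(0)
  list(fitted = qr.fitted(qx, Y), rank = qx$rank, dropped = dropped)
}

ord_inertia <- function(prep, covariates, Y = prep$Y) {
  sum(ord_project(ord_design(prep, covariates), Y)$fitted^2)
}

ord_added_inertia <- function(prep, selected, candidate) {
  ord_inertia(prep, c(selected, candidate)) - ord_inertia(prep, selected)
}

# pseudo-F with reduced-model residual permutation; assumes RNG state is set
ord_test_candidate <- function(prep, selected, candidate, n_perm) {
  Xs <- ord_design(prep, selected)
  Xf <- ord_design(prep, c(selected, candidate))
  qs <- if (ncol(Xs) > 0) qr(Xs) else NULL
  qf <- if (ncol(Xf) > 0) qr(Xf) else NULL
  rank_s <- if (is.null(qs)) 0L else qs$rank
  rank_f <- if (is.null(qf)) 0L else qf$rank
  df_added <- max(rank_f - rank_s, 0L)
  df_res <- prep$n - 1L - rank_f
  if (df_res <= 0) abort("no residual degrees of freedom")
  fit_s <- function(Y) if (is.null(qs)) Y * 0 else qr.fitted(qs, Y)
  fit_f <- function(Y) if (is.null(qf)) Y * 0 else qr.fitted(qf, Y)
  f_stat <- function(Y) {
    i_full <- sum(fit_f(Y)^2)
    added <- i_full - sum(fit_s(Y)^2)
    resid <- sum(Y^2) - i_full
    f <- if (df_added == 0) 0
    else if (resid <= 0) Inf
    else (added / df_added) / (resid / df_res)
    list(added = added, f = f)
  }
  obs <- f_stat(prep$Y)
  fitted_s <- fit_s(prep$Y)
  E <- prep$Y - fitted_s
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    Yp <- fitted_s + E[sample.int(prep$n), , drop = FALSE]
    if (f_stat(Yp)$f >= obs$f) exceed <- exceed + 1L
  }
  tibble::tibble(candidate = candidate, added_inertia = obs$added,
                 df_added = df_added, pseudo_f = obs$f,
                 p_value = (1 + exceed) / (1 + n_perm))
}

ord_core_fit <- function(prep) {
  X <- ord_design(prep, names(prep$blocks))
  pr <- ord_project(X, prep$Y)
  constrained <- sum(pr$fitted^2)
  sv <- svd(pr$fitted)
  keep <- sv$d^2 > max(sv$d^2, .Machine$double.eps) * 1e-12
  eig <- sv$d[keep]^2
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  if (ncol(scores) > 0) colnames(scores) <- paste0("CAxis", seq_len(ncol(scores)))
  structure(list(
    method = prep$method,
    total_inertia = prep$total,
    constrained_inertia = constrained,
    explained_fraction = if (prep$total > 0) constrained / prep$total else 0,
    eigenvalues = eig,
    site_scores = dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(prep$Y)),
      tibble::as_tibble(scores, .name_repair = "minimal")),
    rank = pr$rank,
    dropped = pr$dropped
  ), class = "ordination_fit")
}
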