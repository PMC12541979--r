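ord_fixture <- function(seed = 1, n = 20, p = 5) {
  withr::with_seed(seed, {
    y <- matrix(rexp(n * p, 1), p, n)
    md <- tibble::tibble(sample_id = paste0("s", seq_len(n)),
                         group = rep(c("A", "B"), length.out = n),
                         x1 = rnorm(n), x2 = rnorm(n))
  })
  resp <- tibble::tibble(id = paste0("r", seq_len(p))) |>
    dplyr::bind_cols(tibble::as_tibble(y, .name_repair = ~ md$sample_id))
  list(resp = resp, md = md)
}

test_that("rda explained fraction equals 1 - RSS/TSS from independent least squares", {
  fx <- ord_fixture(seed = 2)
  fit <- rda(fx$resp, fx$md, c("x1", "group"))
  Y <- scale(t(as.matrix(fx$resp[-1])), center = TRUE, scale = FALSE)
  X <- cbind(fx$md$x1, as.integer(fx$md$group == "B"))
  rss <- sum(stats::lm.fit(cbind(1, X), Y)$residuals^2)
  tss <- sum(Y^2)
  expect_equal(fit$explained_fraction, 1 - rss / tss, tolerance = 1e-8)
})

test_that("rda agrees with vegan and handles perfect and saturated fits", {
  fx <- ord_fixture(seed = 3)
  fit <- rda(fx$resp, fx$md, c("x1", "x2"))
  ref <- vegan::rda(t(as.matrix(fx$resp[-1])) ~ x1 + x2, data = fx$md)
  expect_equal(fit$explained_fraction,
               ref$CCA$tot.chi / ref$tot.chi, tolerance = 1e-8)

  # single response exactly linear in a single covariate
  lin <- tibble::tibble(id = "y",
                        !!!setNames(as.list(2 * fx$md$x1 + 1), fx$md$sample_id))
  expect_equal(rda(lin, fx$md, "x1")$explained_fraction, 1, tolerance = 1e-10)

  # saturated model: full dummy coding of sample identity
  md_id <- dplyr::mutate(fx$md, ident = sample_id)
  expect_equal(rda(fx$resp, md_id, "ident")$explained_fraction, 1,
               tolerance = 1e-10)
})

test_that("rda is invariant to invertible reparameterisation and reports aliasing", {
  fx <- ord_fixture(seed = 4)
  base <- rda(fx$resp, fx$md, c("x1", "x2"))
  md2 <- dplyr::mutate(fx$md, x1 = 3 * x1 - 7, x2 = x2 + 0.5 * x1)
  expect_equal(rda(fx$resp, md2, c("x1", "x2"))$explained_fraction,
               base$explained_fraction, tolerance = 1e-8)

  md3 <- dplyr::mutate(fx$md, x3 = 2 * x1)
  col <- rda(fx$resp, md3, c("x1", "x3"))
  expect_equal(col$rank, 1L)
  expect_length(col$dropped, 1)
  expect_equal(col$explained_fraction, rda(fx$resp, fx$md, "x1")$explained_fraction,
               tolerance = 1e-10)
})

test_that("cca total inertia equals the chi-square identity and matches vegan", {
  fx <- ord_fixture(seed = 5)
  fit <- cca(fx$resp, fx$md, c("x1", "group"))
  Y <- t(as.matrix(fx$resp[-1]))
  chi <- suppressWarnings(stats::chisq.test(Y)$statistic)
  expect_equal(fit$total_inertia, unname(chi) / sum(Y), tolerance = 1e-8)

  ref <- vegan::cca(Y ~ x1 + group, data = fx$md)
  expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-8)
  expect_equal(fit$constrained_inertia, ref$CCA$tot.chi, tolerance = 1e-8)

  # constant covariate explains nothing
  mdc <- dplyr::mutate(fx$md, flat = 1)
  expect_equal(cca(fx$resp, mdc, "flat")$constrained_inertia, 0, tolerance = 1e-12)
})

test_that("cca axis one separates a planted two-block structure", {
  withr::with_seed(6, {
    blockA <- rbind(matrix(rpois(5 * 6, 20), 5, 6), matrix(rpois(5 * 6, 1), 5, 6))
    blockB <- rbind(matrix(rpois(5 * 6, 1), 5, 6), matrix(rpois(5 * 6, 20), 5, 6))
  })
  resp <- tibble::tibble(id = paste0("r", 1:10)) |>
    dplyr::bind_cols(tibble::as_tibble(cbind(blockA, blockB),
                                       .name_repair = ~ paste0("s", 1:12)))
  md <- two_group_metadata(paste0("s", 1:12), per_group = 6)
  fit <- cca(resp, md, "group")
  ax1 <- fit$site_scores$CAxis1
  expect_true(all(sign(ax1[1:6]) == sign(ax1[1])))
  expect_true(all(sign(ax1[7:12]) == -sign(ax1[1])))
})

test_that("pseudo-F is zero for a redundant candidate and saturates for a strong one", {
  fx <- ord_fixture(seed = 7)
  md2 <- dplyr::mutate(fx$md, copy = x1)
  red <- permutation_pseudo_F(fx$resp, md2, "x1", "copy", "rda",
                              n_perm = 19, seed = 1)
  expect_equal(red$added_inertia, 0, tolerance = 1e-10)
  expect_equal(red$pseudo_f, 0)

  withr::with_seed(8, {
    strong_md <- tibble::tibble(sample_id = paste0("s", 1:24),
                                group = "G", x = rnorm(24))
    y <- outer(1:4, strong_md$x) + matrix(rnorm(4 * 24, sd = 0.01), 4, 24)
  })
  resp <- tibble::tibble(id = paste0("r", 1:4)) |>
    dplyr::bind_cols(tibble::as_tibble(y, .name_repair = ~ strong_md$sample_id))
  hit <- permutation_pseudo_F(resp, strong_md, character(0), "x", "rda",
                              n_perm = 199, seed = 2)
  expect_equal(hit$p_value, 1 / 200)
})

test_that("forward selection keeps a lone candidate at alpha one and finds a planted effect", {
  fx <- ord_fixture(seed = 9)
  sel <- forward_select(fx$resp, fx$md, "x1", method = "rda", alpha = 1,
                        n_perm = 19, seed = 1)
  expect_equal(sel$selected$candidate, "x1")
  expect_equal(nrow(sel$selected), 1)

  hits <- vapply(1:5, function(sd) {
    withr::with_seed(sd, {
      md <- tibble::tibble(sample_id = paste0("s", 1:24),
                           group = "G", signal = rnorm(24),
                           noise1 = rnorm(24), noise2 = rnorm(24))
      y <- outer(rep(1, 6), md$signal) + matrix(rnorm(6 * 24, sd = 0.3), 6, 24)
    })
    resp <- tibble::tibble(id = paste0("r", 1:6)) |>
      dplyr::bind_cols(tibble::as_tibble(y, .name_repair = ~ md$sample_id))
    s <- forward_select(resp, md, c("noise1", "signal", "noise2"),
                        method = "rda", n_perm = 99, seed = sd)
    nrow(s$selected) >= 1 && s$selected$candidate[1] == "signal"
  }, logical(1))
  expect_true(all(hits))
})

test_that("forward selection on pure noise rarely selects anything", {
  n_sel <- vapply(1:10, function(sd) {
    fx <- ord_fixture(seed = 100 + sd)
    s <- forward_select(fx$resp, fx$md, c("x1", "x2"), method = "rda",
                        n_perm = 99, seed = sd)
    nrow(s$selected)
  }, numeric(1))
  expect_lte(sum(n_sel > 0), 4)   # ~2 false inclusions expected at alpha 0.05
})
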