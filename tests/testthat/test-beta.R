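test_that("bray-curtis matches hand values and vegan", {
  tbl <- tibble::tibble(taxon_id = c("a", "b", "c"),
                        s1 = c(1, 2, 3), s2 = c(3, 2, 1), s3 = c(1, 2, 3))
  d <- bray_curtis(tbl)
  expect_equal(d["s1", "s2"], 4 / 12, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))

  disjoint <- tibble::tibble(taxon_id = c("a", "b"), s1 = c(5, 0), s2 = c(0, 9))
  expect_equal(bray_curtis(disjoint)["s1", "s2"], 1)

  rnd <- random_counts(n_taxa = 20, n_samples = 8, seed = 6)
  ours <- bray_curtis(rnd)
  ref <- as.matrix(vegan::vegdist(t(as.matrix(rnd[-1])), method = "bray"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("similarity summaries match brute-force pair enumeration", {
  rnd <- random_counts(n_taxa = 15, n_samples = 8, seed = 13)
  md <- two_group_metadata(names(rnd)[-1], per_group = 4)
  d <- bray_curtis(rnd)
  s <- group_similarity_summary(d, md)

  # oracle: enumerate pairs explicitly
  sims <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    sims <- rbind(sims, c(i, j, 1 - d[i, j]))
  }
  grp <- md$group
  intra_a <- sims[grp[sims[, 1]] == "A" & grp[sims[, 2]] == "A", 3]
  inter <- sims[grp[sims[, 1]] != grp[sims[, 2]], 3]
  expect_equal(s$mean_similarity[s$comparison == "A"], mean(intra_a), tolerance = 1e-12)
  expect_equal(s$sd_similarity[s$comparison == "A"], sd(intra_a), tolerance = 1e-12)
  expect_equal(s$mean_similarity[s$type == "inter"], mean(inter), tolerance = 1e-12)

  ident <- tibble::tibble(taxon_id = c("a", "b"),
                          s1 = c(1, 2), s2 = c(1, 2), s3 = c(1, 2), s4 = c(1, 2))
  si <- group_similarity_summary(bray_curtis(ident),
                                 two_group_metadata(paste0("s", 1:4)))
  expect_true(all(abs(si$mean_similarity - 1) < 1e-12))
  expect_true(all(si$sd_similarity < 1e-12))
})

test_that("anosim attains R = 1 under complete separation and matches vegan", {
  blocks <- tibble::tibble(taxon_id = paste0("t", 1:4),
                           s1 = c(9, 9, 0, 0), s2 = c(8, 9, 0, 0),
                           s3 = c(9, 8, 0, 0), s4 = c(0, 0, 9, 9),
                           s5 = c(0, 0, 8, 9), s6 = c(0, 0, 9, 8))
  md <- two_group_metadata(paste0("s", 1:6), per_group = 3)
  d <- bray_curtis(blocks)
  a <- anosim(d, md, n_perm = 199, seed = 1)
  expect_equal(a$statistic, 1)
  # only the observed split and its mirror reach R = 1 among the 20 assignments
  expect_lte(a$p_value, 0.15)

  rnd <- random_counts(n_taxa = 12, n_samples = 10, seed = 17)
  md10 <- two_group_metadata(names(rnd)[-1], per_group = 5)
  d10 <- bray_curtis(rnd)
  ours <- anosim(d10, md10, n_perm = 99, seed = 1)
  ref <- withr::with_seed(1, vegan::anosim(stats::as.dist(d10),
                                           grouping = md10$group,
                                           permutations = 99))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("anosim R is invariant under monotone transforms of the dissimilarities", {
  rnd <- random_counts(n_taxa = 10, n_samples = 8, seed = 19)
  md <- two_group_metadata(names(rnd)[-1], per_group = 4)
  d <- bray_curtis(rnd)
  r1 <- anosim(d, md, n_perm = 9, seed = 1)$statistic
  r2 <- anosim(d^3, md, n_perm = 9, seed = 1)$statistic   # order-preserving
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("exact anosim enumerates every label assignment", {
  rnd <- random_counts(n_taxa = 8, n_samples = 6, seed = 23)
  md <- two_group_metadata(names(rnd)[-1], per_group = 3)
  d <- bray_curtis(rnd)
  ex <- anosim(d, md, exact = TRUE)
  expect_equal(ex$n_perm, choose(6, 3))

  # brute-force oracle over combn label assignments
  rk <- rank(d[upper.tri(d)])
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  r_of <- function(lab) {
    within <- lab[pairs[, 1]] == lab[pairs[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (6 * 5 / 4)
  }
  obs <- r_of(md$group)
  all_r <- apply(combn(6, 3), 2, function(ix) {
    lab <- rep("B", 6); lab[ix] <- "A"; r_of(lab)
  })
  expect_equal(ex$statistic, obs, tolerance = 1e-12)
  expect_equal(ex$p_value, mean(all_r >= obs - 1e-12), tolerance = 1e-12)
})

test_that("pairwise anosim is consistent with standalone runs and bonferroni-adjusted", {
  sim <- small_sim(seed = 41)
  d <- bray_curtis(to_relative_abundance(sim$counts))
  pw <- pairwise_anosim(d, sim$metadata, n_perm = 99, seed = 2)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_value * 3))
  expect_true(all(pw$p_adjusted >= pw$p_value))

  keep <- sim$metadata$group %in% c("HC", "D1")
  ids <- sim$metadata$sample_id[keep]
  solo <- anosim(d[ids, ids], sim$metadata[keep, ], n_perm = 99, seed = 2)
  row <- pw[pw$comparison %in% c("HC vs D1", "D1 vs HC"), ]
  expect_equal(row$statistic, solo$statistic, tolerance = 1e-12)
})

test_that("simper contributions sum to the mean between-group dissimilarity", {
  for (seed in 1:5) {
    rnd <- to_relative_abundance(random_counts(n_taxa = 15, n_samples = 8,
                                               seed = seed))
    md <- two_group_metadata(names(rnd)[-1], per_group = 4)
    st <- simper(rnd, md, "A", "B")
    d <- bray_curtis(rnd)
    between <- d[md$sample_id[md$group == "A"], md$sample_id[md$group == "B"]]
    expect_equal(sum(st$average), mean(between), tolerance = 1e-10)
    expect_equal(sum(st$pct_contribution), 100, tolerance = 1e-9)
  }
})

test_that("simper isolates a single driving taxon and agrees with vegan", {
  tbl <- tibble::tibble(taxon_id = c("driver", "same"),
                        s1 = c(10, 50), s2 = c(10, 50),
                        s3 = c(30, 50), s4 = c(30, 50))
  md <- two_group_metadata(paste0("s", 1:4))
  st <- simper(tbl, md, "A", "B")
  expect_equal(st$pct_contribution[st$taxon_id == "driver"], 100)

  ident <- simper(tbl, md, "A", "A")
  expect_equal(attr(ident, "overall"), 0)

  rnd <- to_relative_abundance(random_counts(n_taxa = 10, n_samples = 6, seed = 3))
  md6 <- two_group_metadata(names(rnd)[-1], per_group = 3)
  ours <- simper(rnd, md6, "A", "B")
  comm <- t(as.matrix(rnd[-1]))
  colnames(comm) <- rnd$taxon_id
  ref <- summary(vegan::simper(comm, md6$group, permutations = 0))[["A_B"]]
  expect_equal(ours$average[match(rownames(ref), ours$taxon_id)],
               unname(ref$average), tolerance = 1e-10)
})

test_that("pcoa embeds euclidean configurations exactly", {
  pts <- withr::with_seed(10, matrix(rnorm(10), 5, 2))
  d <- as.matrix(stats::dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:5)
  res <- pcoa(d)
  xy <- as.matrix(res$coordinates[-1])
  expect_equal(unname(as.matrix(stats::dist(xy))), unname(d), tolerance = 1e-8)

  # trace identity on the euclidean case
  g <- -0.5 * scale(t(scale(t(d^2), center = TRUE, scale = FALSE)),
                    center = TRUE, scale = FALSE)
  expect_equal(sum(res$eigenvalues[res$eigenvalues > 0]), sum(diag(g)),
               tolerance = 1e-8)

  # cross-check against classical scaling
  ref <- stats::cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(xy[, 1:2]), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)

  two <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
  cc <- pcoa(two)$coordinates
  expect_equal(sort(cc$Axis1), c(-0.3, 0.3), tolerance = 1e-12)
})

test_that("pcoa reports dropped negative eigenvalues for non-euclidean input", {
  rnd <- random_counts(n_taxa = 10, n_samples = 8, seed = 29)
  res <- pcoa(bray_curtis(to_relative_abundance(rnd)))
  expect_gte(res$negative$count, 0)
  expect_equal(sum(res$pct_variance), 100, tolerance = 1e-9)
})

test_that("confidence ellipses recover scale and orientation of a planted gaussian", {
  withr::with_seed(77, {
    iso <- matrix(rnorm(4000), 2000, 2)
  })
  coords <- tibble::tibble(sample_id = paste0("s", 1:2000),
                           Axis1 = iso[, 1], Axis2 = iso[, 2])
  md <- tibble::tibble(sample_id = coords$sample_id, group = "G")
  e <- confidence_ellipse(coords, md)
  expect_equal(e$semi_major, sqrt(qchisq(0.95, 2)), tolerance = 0.06)
  expect_equal(e$semi_minor, sqrt(qchisq(0.95, 2)), tolerance = 0.06)
  expect_false(e$degenerate)

  withr::with_seed(78, {
    z <- cbind(rnorm(500, sd = 3), rnorm(500, sd = 0.5))
    rot <- matrix(c(cos(pi / 6), sin(pi / 6), -sin(pi / 6), cos(pi / 6)), 2, 2)
    xy <- z %*% t(rot)
  })
  coords2 <- tibble::tibble(sample_id = paste0("s", 1:500),
                            Axis1 = xy[, 1], Axis2 = xy[, 2])
  md2 <- tibble::tibble(sample_id = coords2$sample_id, group = "G")
  e2 <- confidence_ellipse(coords2, md2)
  ang <- (e2$angle * 180 / pi) %% 180
  expect_lt(min(abs(ang - 30), abs(ang - 210 %% 180)), 5)

  flat <- tibble::tibble(sample_id = paste0("s", 1:4),
                         Axis1 = c(1, 1, 1, 1), Axis2 = c(2, 2, 2, 2))
  mdf <- tibble::tibble(sample_id = flat$sample_id, group = "G")
  ef <- confidence_ellipse(flat, mdf)
  expect_true(ef$degenerate)
})
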