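ko_fixture <- function() {
  contrib <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    taxon_id = rep(c("t1", "t1", "t2"), 2),
    function_id = rep(c("K1", "K2", "K3"), 2),
    abundance = c(3, 7, 10, 1, 1, 2)
  )
  mapping <- tibble::tibble(function_id = c("K1", "K2", "K3"),
                            pathway_id = c("pA", "pA", "pB"),
                            pathway_name = c("A", "A", "B"))
  list(contrib = contrib, mapping = mapping)
}

test_that("pathway aggregation sums member KOs and normalises to percent", {
  fx <- ko_fixture()
  pt <- aggregate_to_pathways(fx$contrib, fx$mapping)
  expect_equal(pt$s1[pt$pathway_id == "pA"], 100 * 10 / 20)  # 3 + 7 vs 10
  expect_true(all(abs(colSums(as.matrix(pt[-1])) - 100) < 1e-9))

  # a KO on two pathways contributes fully to both
  map2 <- dplyr::bind_rows(fx$mapping,
                           tibble::tibble(function_id = "K1", pathway_id = "pB",
                                          pathway_name = "B"))
  raw <- fx$contrib |>
    dplyr::inner_join(map2[1:2], by = "function_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$sample_id == "s1") |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(x = sum(.data$abundance))
  pt2 <- aggregate_to_pathways(fx$contrib, map2)
  expect_equal(pt2$s1, 100 * raw$x / sum(raw$x))

  # unmapped KOs excluded with a warning and counted
  expect_warning(pt3 <- aggregate_to_pathways(fx$contrib, fx$mapping[-3, ]),
                 "excluded")
  expect_equal(attr(pt3, "unmapped_kos"), 1)
  expect_false("pB" %in% pt3$pathway_id)
  expect_error(aggregate_to_pathways(fx$contrib, fx$mapping[0, ]), "empty")
})

test_that("stratified aggregation equals aggregation of the filtered contributions", {
  sim <- small_sim(seed = 51)
  pw <- simulate_pathway_assignments(sim, n_pathways = 10, n_exclusive = 2)
  part <- truth_as_partition(sim$truth, unique(sim$metadata$group))

  core_pt <- stratify_by_partition(pw$contributions, part, sim$metadata,
                                   "core", pw$mapping)
  core_taxa <- sim$truth$taxon_id[sim$truth$type == "core"]
  manual <- aggregate_to_pathways(
    pw$contributions[pw$contributions$taxon_id %in% core_taxa, ], pw$mapping)
  expect_equal(core_pt, manual, ignore_attr = TRUE)

  # additivity before normalisation: core + satellite raw sums = whole raw sums
  raw_sum <- function(contrib) {
    contrib |>
      dplyr::inner_join(pw$mapping[1:2], by = "function_id") |>
      dplyr::group_by(.data$pathway_id, .data$sample_id) |>
      dplyr::summarise(x = sum(.data$abundance), .groups = "drop")
  }
  whole <- dplyr::rename(raw_sum(pw$contributions), total = "x")
  core_raw <- raw_sum(pw$contributions[pw$contributions$taxon_id %in% core_taxa, ])
  sat_raw <- raw_sum(pw$contributions[!pw$contributions$taxon_id %in% core_taxa, ])
  rejoined <- dplyr::full_join(core_raw, sat_raw,
                               by = c("pathway_id", "sample_id")) |>
    dplyr::transmute(.data$pathway_id, .data$sample_id,
                     combined = dplyr::coalesce(.data$x.x, 0) +
                       dplyr::coalesce(.data$x.y, 0))
  merged <- dplyr::inner_join(whole, rejoined, by = c("pathway_id", "sample_id"))
  expect_equal(nrow(merged), nrow(whole))
  expect_equal(merged$total, merged$combined, tolerance = 1e-9)
})

test_that("the >1 % filter is strict and matches a brute-force share oracle", {
  pt <- tibble::tibble(pathway_id = c("p1", "p2", "p3"),
                       s1 = c(1, 49, 50), s2 = c(1, 49, 50))
  kept <- abundant_pathways(pt, threshold = 1)
  expect_false("p1" %in% kept$pathway_id)      # exactly 1.0 % -> excluded
  expect_equal(kept$pathway_id, c("p2", "p3"))

  single <- tibble::tibble(pathway_id = "only", s1 = 3, s2 = 5)
  expect_equal(abundant_pathways(single)$pathway_id, "only")

  rnd <- withr::with_seed(31, tibble::tibble(
    pathway_id = sprintf("p%02d", 1:20)) |>
      dplyr::bind_cols(tibble::as_tibble(matrix(rexp(100), 20, 5),
                                         .name_repair = ~ paste0("s", 1:5))))
  share <- 100 * rowSums(as.matrix(rnd[-1])) / sum(as.matrix(rnd[-1]))
  expect_equal(abundant_pathways(rnd, 4)$pathway_id, rnd$pathway_id[share > 4])
  expect_equal(abundant_pathways(rnd, 0)$pathway_id, rnd$pathway_id)
})

test_that("satellite-exclusive detection equals the brute-force set comparison", {
  core <- tibble::tibble(pathway_id = c("p1", "p2", "p3"),
                         s1 = c(5, 0, 0), s2 = c(1, 0, 0))
  sat <- tibble::tibble(pathway_id = c("p1", "p2", "p4"),
                        s1 = c(2, 3, 0), s2 = c(0, 1, 6))
  got <- satellite_exclusive_pathways(core, sat)
  expect_equal(got, c("p2", "p4"))   # p1 shared, p3 core-only, zero-rows ignored
})

test_that("clr transform centres every sample and matches the hand example", {
  pt <- tibble::tibble(pathway_id = c("p1", "p2", "p3"),
                       s1 = c(1, 1, 4), s2 = c(2, 2, 2))
  clr <- clr_transform(pt)
  g <- 4^(1 / 3)
  expect_equal(clr$s1, log(c(1, 1, 4) / g), tolerance = 1e-9)
  expect_equal(clr$s2, c(0, 0, 0))

  withzero <- tibble::tibble(pathway_id = c("p1", "p2", "p3"),
                             s1 = c(0, 30, 70), s2 = c(10, 40, 50))
  cz <- clr_transform(withzero)
  expect_true(all(is.finite(as.matrix(cz[-1]))))
  expect_true(all(abs(colSums(as.matrix(cz[-1]))) < 1e-9))

  rnd <- withr::with_seed(41, tibble::tibble(pathway_id = paste0("p", 1:12)) |>
    dplyr::bind_cols(tibble::as_tibble(matrix(rexp(60), 12, 5),
                                       .name_repair = ~ paste0("s", 1:5))))
  cr <- clr_transform(rnd)
  expect_true(all(abs(colSums(as.matrix(cr[-1]))) < 1e-9))
  expect_error(clr_transform(dplyr::mutate(rnd, s1 = 0)), "s1")
})

test_that("a planted pathway shift ranks first and nulls stay unflagged", {
  withr::with_seed(61, {
    m <- matrix(rexp(30 * 18, 1), 30, 18)
    m[7, 13:18] <- m[7, 13:18] * 8          # shift pathway 7 in group C
  })
  pt <- tibble::tibble(pathway_id = sprintf("p%02d", 1:30)) |>
    dplyr::bind_cols(tibble::as_tibble(m, .name_repair = ~ paste0("s", 1:18)))
  md <- tibble::tibble(sample_id = paste0("s", 1:18),
                       group = rep(c("A", "B", "C"), each = 6))
  res <- compare_pathways(clr_transform(to_relative_abundance(pt)), md,
                          test = "kw")
  expect_equal(res$omnibus$pathway_id[1], "p07")
  expect_equal(res$pairwise$p_adjusted, pmin(1, res$pairwise$p_value * 3))

  # fully null tables: BH keeps discoveries near zero
  hits <- vapply(1:10, function(sd) {
    null_m <- withr::with_seed(100 + sd, matrix(rexp(30 * 18, 1), 30, 18))
    npt <- tibble::tibble(pathway_id = sprintf("p%02d", 1:30)) |>
      dplyr::bind_cols(tibble::as_tibble(null_m, .name_repair = ~ paste0("s", 1:18)))
    r <- compare_pathways(npt, md, test = "kw")
    sum(r$omnibus$p_adjusted <= 0.05)
  }, numeric(1))
  expect_lte(mean(hits), 0.5)
})

test_that("constant pathways are skipped with a warning", {
  pt <- tibble::tibble(pathway_id = c("flat", "varies"),
                       s1 = c(2, 1), s2 = c(2, 5), s3 = c(2, 3), s4 = c(2, 9))
  md <- two_group_metadata(paste0("s", 1:4))
  expect_warning(res <- compare_pathways(pt, md), "constant")
  expect_equal(res$skipped, "flat")
  expect_equal(res$omnibus$pathway_id, "varies")
})

test_that("pathway ordination composes bray-curtis and pcoa and separates planted clusters", {
  withr::with_seed(71, {
    a <- matrix(rexp(20 * 6, 1), 20, 6)
    b <- rbind(matrix(rexp(10 * 6, 1 / 5), 10, 6), matrix(rexp(10 * 6, 5), 10, 6))
  })
  pt <- tibble::tibble(pathway_id = sprintf("p%02d", 1:20)) |>
    dplyr::bind_cols(tibble::as_tibble(cbind(a, b), .name_repair = ~ paste0("s", 1:12)))
  pt <- to_relative_abundance(pt)
  md <- two_group_metadata(paste0("s", 1:12), per_group = 6)
  res <- pathway_pcoa(pt, md, n_perm = 99, seed = 5)
  expect_gt(res$anosim$statistic, 0.5)

  manual <- pcoa(bray_curtis(pt))
  expect_equal(res$pcoa$coordinates, manual$coordinates, tolerance = 1e-12)

  ident <- tibble::tibble(pathway_id = c("p1", "p2"),
                          s1 = c(30, 70), s2 = c(30, 70), s3 = c(30, 70))
  same <- pathway_pcoa(ident)
  expect_equal(length(same$pcoa$pct_variance), 0)  # no positive axis: all at origin
})
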