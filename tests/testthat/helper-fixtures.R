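# in-code fixtures shared across the suite

tiny_counts <- function() {
  tibble::tibble(
    taxon_id = c("tA", "tB", "tC"),
    s1 = c(5, 0, 10),
    s2 = c(3, 2, 0)
  )
}

random_counts <- function(n_taxa = 12, n_samples = 6, seed = 1, lambda = 8) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples)
    m[1, colSums(m) == 0] <- 1   # keep every sample non-empty
    tibble::tibble(taxon_id = sprintf("t%02d", seq_len(n_taxa))) |>
      dplyr::bind_cols(tibble::as_tibble(m, .name_repair = ~ sprintf("s%02d", seq_len(n_samples))))
  })
}

two_group_metadata <- function(samples, per_group = length(samples) / 2) {
  tibble::tibble(
    sample_id = samples,
    group = rep(c("A", "B"), c(per_group, length(samples) - per_group))
  )
}

# small cohort for integration-style tests (fast but structured)
small_sim <- function(seed = 11) {
  simulate_counts(sim_config(seed = seed, samples_per_group = 6,
                             n_core = 20, n_satellite = 60, depth = 4000))
}

# summary tibble built directly (bypasses counts) for partition edge cases
manual_summary <- function(d, a, group = "G") {
  tibble::tibble(group = group,
                 taxon_id = sprintf("t%02d", seq_along(d)),
                 distribution = d, mean_abundance = a,
                 n_present = pmax(1L, round(d / 10)), n_samples = 10L)
}
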