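#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set for [simulate_counts()]. The defaults describe a
#' three-group faecal cohort (one healthy control group plus two disease
#' subtypes) with a planted core/satellite community structure: high-prevalence
#' core taxa whose mean percent abundances are log-normal, low-prevalence
#' low-abundance satellite taxa, a positive coupling between a taxon's
#' occupancy and its log abundance, and a group-specific expansion of the
#' satellite fraction in the disease groups.
#'
#' @param n_groups Number of study groups; group 1 is the control.
#' @param samples_per_group Samples per group.
#' @param n_core,n_satellite Number of planted core and satellite taxa.
#' @param core_logmean,core_logsd Mean and SD of taxon mean abundance on the
#'   log10 percent scale.
#' @param core_prevalence Baseline presence probability of core taxa, in
#'   `[0.75, 1]`.
#' @param satellite_prevalence Baseline presence probability of satellite taxa,
#'   in `(0, 0.75)`.
#' @param satellite_abundance_scale Multiplier (< 1) shrinking satellite mean
#'   abundances relative to the core log-normal.
#' @param disease_satellite_expansion Multiplier (>= 1) applied to satellite
#'   abundances in disease groups. A scalar applies to every non-control
#'   group; a vector of length `n_groups` sets per-group multipliers (the
#'   control entry must be 1).
#' @param depth Reads per sample (multinomial total).
#' @param da_slope Slope (per log10 abundance unit, on the logit scale)
#'   coupling presence probability to a taxon's latent log abundance.
#' @param sample_logsd Per-sample log10 noise around each taxon's mean
#'   abundance.
#' @param overdispersion Optional Dirichlet overdispersion of per-sample
#'   relative abundances before read sampling; 0 (default) draws plain
#'   multinomial reads.
#' @param seed Integer seed; a fixed seed makes every draw reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_groups = 3, samples_per_group = 12,
                       n_core = 40, n_satellite = 160,
                       core_logmean = -0.5, core_logsd = 0.5,
                       core_prevalence = 0.95, satellite_prevalence = 0.3,
                       satellite_abundance_scale = 0.15,
                       disease_satellite_expansion = 2,
                       depth = 5e4, da_slope = 1.5,
                       sample_logsd = 0.25, overdispersion = 0, seed = 1L) {
  if (n_core + n_satellite < 2) abort("need at least two taxa")
  if (depth < 10) abort("depth must be at least 10 reads")
  if (core_prevalence < 0.75 || core_prevalence > 1) {
    abort("core_prevalence must lie in [0.75, 1]")
  }
  if (satellite_prevalence <= 0 || satellite_prevalence >= 0.75) {
    abort("satellite_prevalence must lie in (0, 0.75)")
  }
  if (satellite_abundance_scale <= 0) abort("satellite_abundance_scale must be positive")
  expansion <- disease_satellite_expansion
  if (length(expansion) == 1) expansion <- c(1, rep(expansion, n_groups - 1))
  if (length(expansion) != n_groups || any(expansion < 1) || expansion[1] != 1) {
    abort("disease_satellite_expansion must be >= 1 per group with control fixed at 1")
  }
  structure(list(
    n_groups = as.integer(n_groups), samples_per_group = as.integer(samples_per_group),
    n_core = as.integer(n_core), n_satellite = as.integer(n_satellite),
    core_logmean = core_logmean, core_logsd = core_logsd,
    core_prevalence = core_prevalence, satellite_prevalence = satellite_prevalence,
    satellite_abundance_scale = satellite_abundance_scale,
    disease_satellite_expansion = expansion,
    depth = as.integer(depth), da_slope = da_slope,
    sample_logsd = sample_logsd, overdispersion = overdispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a cohort with planted core/satellite structure
#'
#' Draws, for each taxon, a latent mean percent abundance (log-normal on the
#' log10 scale; satellites additionally shrunk by
#' `satellite_abundance_scale`), then couples each taxon's presence
#' probability to its latent log abundance on the logit scale around the
#' class baseline prevalence (`da_slope`). Per sample, presence is Bernoulli,
#' present-taxon abundances get multiplicative log-normal noise, satellite
#' abundances in disease groups are multiplied by that group's expansion
#' factor, the vector is renormalised, and reads are drawn multinomially at
#' the configured depth (optionally with Dirichlet overdispersion). Column
#' sums therefore equal `depth` exactly and the whole draw is deterministic
#' for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `coresat_sim` with elements `counts` (count
#'   tibble), `metadata` (tibble: `sample_id`, `group`, plus a numeric
#'   covariate `age` drawn independently of the community), `truth` (tibble:
#'   `taxon_id`, planted `type`), and `config`.
#' @export
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort("cfg must come from sim_config()")
  withr::with_seed(cfg$seed, {
    n_taxa <- cfg$n_core + cfg$n_satellite
    type <- rep(c("core", "satellite"), c(cfg$n_core, cfg$n_satellite))
    taxon_id <- sprintf("t%03d", seq_len(n_taxa))

    log_m <- rnorm(n_taxa, cfg$core_logmean, cfg$core_logsd)
    log_m[type == "satellite"] <- log_m[type == "satellite"] +
      log10(cfg$satellite_abundance_scale)
    m <- 10^log_m

    base_prev <- ifelse(type == "core", cfg$core_prevalence, cfg$satellite_prevalence)
    centred <- stats::ave(log_m, type, FUN = function(z) z - mean(z))
    p_present <- stats::plogis(stats::qlogis(base_prev) + cfg$da_slope * centred)
    p_present <- pmin(pmax(p_present, 0.01), 0.999)

    groups <- if (cfg$n_groups == 3) c("HC", "D1", "D2") else
      paste0("G", seq_len(cfg$n_groups))
    n_samples <- cfg$n_groups * cfg$samples_per_group
    group_of <- rep(groups, each = cfg$samples_per_group)
    sample_id <- sprintf("s%03d", seq_len(n_samples))

    counts <- matrix(0L, n_taxa, n_samples, dimnames = list(taxon_id, sample_id))
    for (j in seq_len(n_samples)) {
      g <- match(group_of[j], groups)
      present <- rbinom(n_taxa, 1L, p_present) == 1L
      if (!any(present)) present[which.max(p_present)] <- TRUE
      abun <- m * 10^rnorm(n_taxa, 0, cfg$sample_logsd)
      abun[type == "satellite"] <- abun[type == "satellite"] *
        cfg$disease_satellite_expansion[g]
      abun[!present] <- 0
      prob <- abun / sum(abun)
      if (cfg$overdispersion > 0) {
        pos <- prob > 0
        gam <- stats::rgamma(sum(pos), shape = prob[pos] / cfg$overdispersion)
        prob[pos] <- gam / sum(gam)
      }
      counts[, j] <- rmultinom(1L, cfg$depth, prob)[, 1L]
    }

    metadata <- tibble::tibble(
      sample_id = sample_id, group = group_of,
      age = round(rnorm(n_samples, mean = 50, sd = 12), 1)
    )
    structure(list(
      counts = counts_tbl(counts[rowSums(counts) > 0, , drop = FALSE]),
      metadata = metadata,
      truth = tibble::tibble(taxon_id = taxon_id, type = type),
      config = cfg
    ), class = "coresat_sim")
  })
}

#' Plant a taxon-to-pathway incidence structure and per-sample contributions
#'
#' Assigns KEGG-style orthologs (KOs) to level-3 pathways (a fixed number of
#' KOs per pathway) and pathways to taxa by Bernoulli incidence, reserving a
#' configurable number of pathways for satellite taxa only. Per-sample
#' contributions are proportional to the taxon's read count: every (sample,
#' taxon, KO) record carries the taxon's count in that sample, so pathway
#' totals are exact sums of contributing taxon counts.
#'
#' @param sim A `coresat_sim` from [simulate_counts()].
#' @param n_pathways Total number of pathways.
#' @param n_exclusive Number of pathways assigned only to satellite taxa.
#' @param kos_per_pathway KOs per pathway.
#' @param incidence_prob Probability a given (eligible) taxon carries a given
#'   pathway.
#' @param seed Seed for the incidence and contribution draw; defaults to the
#'   cohort seed offset by 1000 so counts and pathways are independently
#'   reproducible.
#' @return A list with `contributions` (tibble: `sample_id`, `taxon_id`,
#'   `function_id`, `abundance`), `mapping` (tibble: `function_id`,
#'   `pathway_id`, `pathway_name`), `incidence` (taxon-by-pathway 0/1 matrix),
#'   and `exclusive_pathways` (character).
#' @export
simulate_pathway_assignments <- function(sim, n_pathways = 40, n_exclusive = 5,
                                         kos_per_pathway = 3, incidence_prob = 0.2,
                                         seed = sim$config$seed + 1000L) {
  if (!inherits(sim, "coresat_sim")) abort("sim must come from simulate_counts()")
  if (n_exclusive > n_pathways) abort("n_exclusive cannot exceed n_pathways")
  withr::with_seed(seed, {
    truth <- sim$truth
    n_taxa <- nrow(truth)
    pathway_id <- sprintf("path%03d", seq_len(n_pathways))
    exclusive <- pathway_id[seq_len(n_exclusive)]
    is_sat <- truth$type == "satellite"

    incidence <- matrix(rbinom(n_taxa * n_pathways, 1L, incidence_prob),
                        n_taxa, n_pathways,
                        dimnames = list(truth$taxon_id, pathway_id))
    incidence[!is_sat, pathway_id %in% exclusive] <- 0L
    for (k in seq_len(n_pathways)) {      # every pathway needs >= 1 carrier
      if (sum(incidence[, k]) == 0L) {
        eligible <- if (pathway_id[k] %in% exclusive) which(is_sat) else seq_len(n_taxa)
        incidence[sample(eligible, 1L), k] <- 1L
      }
    }

    # ground truth: every pathway with no core carrier is satellite-exclusive,
    # whether reserved by design or core-free by chance of the incidence draw
    exclusive <- pathway_id[colSums(incidence[!is_sat, , drop = FALSE]) == 0L]

    mapping <- tibble::tibble(
      pathway_id = rep(pathway_id, each = kos_per_pathway),
      function_id = sprintf("K%05d", seq_len(n_pathways * kos_per_pathway))
    )
    mapping$pathway_name <- paste0("pathway ", mapping$pathway_id)
    mapping <- mapping[c("function_id", "pathway_id", "pathway_name")]

    m <- counts_matrix(sim$counts)
    pairs <- which(incidence == 1L, arr.ind = TRUE)
    contrib <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
      tx <- rownames(incidence)[pairs[r, 1L]]
      if (!tx %in% rownames(m)) return(NULL)   # taxon never observed
      kos <- mapping$function_id[mapping$pathway_id == pathway_id[pairs[r, 2L]]]
      cts <- m[tx, ]
      keep <- cts > 0
      if (!any(keep)) return(NULL)
      tidyr::expand_grid(sample_id = colnames(m)[keep], function_id = kos) |>
        dplyr::mutate(taxon_id = tx,
                      abundance = rep(unname(cts[keep]), each = length(kos)))
    })
    contrib <- dplyr::select(contrib, "sample_id", "taxon_id", "function_id",
                             "abundance")
    list(contributions = contrib, mapping = mapping, incidence = incidence,
         exclusive_pathways = exclusive)
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the on-disk artefacts consumed by the readers in this package: the
#' count table (TSV), sample metadata (CSV), stratified contributions (TSV),
#' KO-to-pathway mapping (TSV), and the ground truth (JSON).
#'
#' @param sim A `coresat_sim`.
#' @param dir Output directory (created if needed).
#' @param pathways Optional result of [simulate_pathway_assignments()].
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir, pathways = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  readr::write_csv(sim$metadata, file.path(dir, "metadata.csv"), progress = FALSE)
  truth <- list(taxa = sim$truth, config = unclass(sim$config))
  if (!is.null(pathways)) {
    readr::write_tsv(pathways$contributions, file.path(dir, "contributions.tsv"),
                     progress = FALSE)
    readr::write_tsv(pathways$mapping, file.path(dir, "pathway_mapping.tsv"),
                     progress = FALSE)
    truth$exclusive_pathways <- pathways$exclusive_pathways
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Estimate the satellite expansion factor from a cohort
#'
#' Recovers the multiplicative satellite expansion planted (or present) in
#' disease groups. Because relative abundances are renormalised within each
#' sample, the naive disease/control ratio of mean satellite share
#' under-estimates the multiplier; the satellite odds `s / (100 - s)` (s the
#' percent satellite share of a sample) respond multiplicatively, so the
#' ratio of group geometric-mean odds estimates the planted factor without
#' that bias.
#'
#' @param counts A count tibble.
#' @param metadata Metadata tibble; the first group in metadata order is the
#'   reference unless `reference` says otherwise.
#' @param labels Tibble mapping `taxon_id` to core/satellite: either a
#'   ground-truth tibble (`type` column) or one group's [partition_taxa()]
#'   rows (`label` column).
#' @param reference Reference (control) group label.
#' @return A tibble per group: `group`, `satellite_share` (mean percent),
#'   `expansion_estimate` (reference = 1).
#' @export
estimate_satellite_expansion <- function(counts, metadata, labels,
                                         reference = metadata$group[1]) {
  grp <- sample_groups(counts, metadata)
  lab_col <- if ("type" %in% names(labels)) labels$type else labels$label
  sat_taxa <- labels$taxon_id[lab_col == "satellite"]
  rel <- counts_matrix(to_relative_abundance(counts))
  share <- colSums(rel[rownames(rel) %in% sat_taxa, , drop = FALSE])
  share <- pmin(pmax(share, 1e-6), 100 - 1e-6)
  odds <- share / (100 - share)
  by_grp <- tibble::tibble(group = unname(grp), share = unname(share),
                           log_odds = log(unname(odds))) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(satellite_share = mean(.data$share),
                     mean_log_odds = mean(.data$log_odds), .groups = "drop")
  ref <- by_grp$mean_log_odds[by_grp$group == reference]
  if (length(ref) != 1) abort("reference group not found")
  by_grp |>
    dplyr::mutate(expansion_estimate = exp(.data$mean_log_odds - ref)) |>
    dplyr::select("group", "satellite_share", "expansion_estimate")
}

#' Ground-truth labels in partition layout
#'
#' Expands a simulation's planted taxon types into the per-(group, taxon)
#' layout of [partition_taxa()], so downstream stratification can run against
#' the planted truth instead of a measured partition.
#'
#' @param truth Truth tibble (`taxon_id`, `type`).
#' @param groups Character vector of group labels to replicate over.
#' @return A tibble with `group`, `taxon_id`, `label`.
#' @export
truth_as_partition <- function(truth, groups) {
  tidyr::expand_grid(group = groups, taxon_id = truth$taxon_id) |>
    dplyr::mutate(label = truth$type[match(.data$taxon_id, truth$taxon_id)])
}
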