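#' Percent abundance table restricted to one partition stratum
#'
#' Zeroes out, per sample, every taxon not labelled `stratum` in that sample's
#' own group, drops taxa left with no reads anywhere, and renormalises each
#' remaining sample to 100 percent. Samples with no reads in the stratum are
#' dropped with a warning.
#'
#' @param counts A count tibble.
#' @param partition A [partition_taxa()] result.
#' @param metadata Metadata tibble.
#' @param stratum `"core"` or `"satellite"`.
#' @return A percent relative-abundance tibble for the stratum.
#' @export
stratum_abundance <- function(counts, partition, metadata, stratum) {
  stratum <- match.arg(stratum, c("core", "satellite"))
  grp <- sample_groups(counts, metadata)
  m <- counts_matrix(counts)
  keep_key <- paste(partition$group[partition$label == stratum],
                    partition$taxon_id[partition$label == stratum])
  for (s in colnames(m)) {
    drop <- !(paste(grp[[s]], rownames(m)) %in% keep_key)
    m[drop, s] <- 0
  }
  empty <- colSums(m) == 0
  if (any(empty)) {
    warn(paste0("sample(s) with no ", stratum, " reads dropped: ",
                paste(colnames(m)[empty], collapse = ", ")))
    m <- m[, !empty, drop = FALSE]
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  to_relative_abundance(counts_tbl(m))
}

#' Run the full core/satellite analysis pipeline
#'
#' Executes the stages in order — input (or simulation), preprocessing
#' (singleton removal, optional species-level ASV collapsing), per-group
#' distribution-abundance partitioning, alpha diversity with group tests,
#' Bray-Curtis community structure (within/between-group similarity, ANOSIM
#' with Bonferroni pairwise tests, SIMPER), predicted-function profiling
#' (pathway aggregation, partition strata, >1 % filter, CLR, group tests,
#' pathway ordination, satellite-exclusive pathways), and forward-selection
#' constrained ordination — writing every artefact under `out_dir` together
#' with a manifest of file hashes and the parameter values used. Reruns with
#' the same configuration and seed are bit-identical.
#'
#' @param config A configuration list or path to a YAML file. Either
#'   `simulation` (arguments for [sim_config()]) or `input` (paths: `counts`,
#'   `metadata`, optionally `taxonomy`, `contributions`, `mapping`) must be
#'   present — exactly one of the two. Optional entries: `threshold` (default
#'   75), `rarefaction_depth` (default: minimum sample total), `n_perm`
#'   (default 999), `alpha` (forward-selection threshold, default 0.05),
#'   `covariates` (candidate covariate columns; default `group` plus any
#'   numeric metadata columns), `seed` (default 1).
#' @param out_dir Output directory.
#' @return Invisibly, a list with every stage's in-memory results and the
#'   `manifest` tibble.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    abort("config must hold exactly one of 'simulation' or 'input'")
  }
  threshold <- config$threshold %||% 75
  n_perm <- config$n_perm %||% 999
  alpha <- config$alpha %||% 0.05
  seed <- as.integer(config$seed %||% 1L)
  stage_seed <- function(k) seed + k   # per-stage expansion of the global seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  # -- stage 1: inputs ---------------------------------------------------------
  contributions <- NULL; mapping <- NULL
  if (has_sim) {
    cfg <- do.call(sim_config, c(config$simulation,
                                 if (is.null(config$simulation$seed))
                                   list(seed = stage_seed(1)) else NULL))
    sim <- simulate_counts(cfg)
    pw <- simulate_pathway_assignments(sim)
    counts <- sim$counts
    metadata <- sim$metadata
    contributions <- pw$contributions
    mapping <- pw$mapping
    res$simulation <- list(truth = sim$truth,
                           exclusive_pathways = pw$exclusive_pathways)
    write_simulation(sim, file.path(out_dir, "input"), pathways = pw)
  } else {
    counts <- read_count_table(config$input$counts,
                               orientation = config$input$orientation %||% "taxon")
    metadata <- read_metadata(config$input$metadata)
    if (!is.null(config$input$taxonomy)) {
      taxonomy <- read_taxonomy(config$input$taxonomy)
      counts <- collapse_to_species_otus(counts, taxonomy)
    }
    if (!is.null(config$input$contributions)) {
      contributions <- read_contributions(config$input$contributions)
      mapping <- readr::read_tsv(config$input$mapping, show_col_types = FALSE,
                                 progress = FALSE)
    }
  }
  counts <- remove_singleton_taxa(counts)
  counts <- counts[rowSums(as.matrix(counts[-1])) > 0, , drop = FALSE]
  check_counts(counts)
  sample_groups(counts, metadata)  # validates coverage early
  res$counts <- counts; res$metadata <- metadata

  # -- stage 2: partitioning ---------------------------------------------------
  summary_tbl <- summarize_taxa(counts, metadata)
  fits <- purrr::map(split(summary_tbl, summary_tbl$group),
                     fit_distribution_abundance)
  partition <- partition_taxa(summary_tbl, threshold = threshold)
  shares <- partition_abundance_share(counts, partition, metadata)
  res$partition <- list(summary = summary_tbl, fits = fits,
                        partition = partition, shares = shares,
                        gof = attr(partition, "gof"))
  readr::write_tsv(summary_tbl, file.path(out_dir, "taxon_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::select(partition, "group", "taxon_id", "label"),
                   file.path(out_dir, "partition.tsv"), progress = FALSE)
  readr::write_tsv(shares, file.path(out_dir, "abundance_shares.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    purrr::map(fits, ~ as.list(glance(.x))),
    file.path(out_dir, "regression.json"), auto_unbox = TRUE, digits = NA)

  # -- stage 3: diversity ------------------------------------------------------
  fisher <- diversity_by_group(counts, metadata, partition, metric = "fisher")
  shn <- diversity_by_group(counts, metadata, partition, metric = "shannon",
                            depth = config$rarefaction_depth,
                            seed = stage_seed(3))
  res$diversity <- list(fisher = fisher, shannon = shn)
  readr::write_tsv(dplyr::bind_rows(fisher = fisher$samples,
                                    shannon = shn$samples, .id = "metric"),
                   file.path(out_dir, "diversity.tsv"), progress = FALSE)
  jsonlite::write_json(list(fisher = fisher$tests, shannon = shn$tests),
                       file.path(out_dir, "diversity_tests.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- stage 4: community structure -------------------------------------------
  rel <- to_relative_abundance(counts)
  strata_tbl <- list(whole = rel)
  strata_tbl$core <- stratum_abundance(counts, partition, metadata, "core")
  strata_tbl$satellite <- stratum_abundance(counts, partition, metadata, "satellite")
  beta <- purrr::imap(strata_tbl, function(tbl, st) {
    d <- bray_curtis(tbl)
    list(similarity = group_similarity_summary(d, metadata),
         anosim = anosim(d, metadata, n_perm = n_perm, seed = stage_seed(4)),
         pairwise = pairwise_anosim(d, metadata, n_perm = n_perm,
                                    seed = stage_seed(4)),
         pcoa = pcoa(d))
  })
  groups <- unique(metadata$group)
  simper_tbl <- purrr::map_dfr(combn(groups, 2, simplify = FALSE), function(pr) {
    s <- simper(rel, metadata, pr[1], pr[2])
    dplyr::mutate(s, comparison = paste(pr, collapse = " vs "), .before = 1)
  })
  res$beta <- beta; res$simper <- simper_tbl
  readr::write_tsv(simper_tbl, file.path(out_dir, "simper.tsv"), progress = FALSE)
  jsonlite::write_json(
    purrr::map(beta, ~ list(anosim = as.list(tidy(.x$anosim)),
                            pairwise = .x$pairwise,
                            similarity = .x$similarity)),
    file.path(out_dir, "anosim.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(beta$whole$pcoa$coordinates,
                   file.path(out_dir, "pcoa_structure.tsv"), progress = FALSE)

  # -- stage 5: predicted function --------------------------------------------
  if (!is.null(contributions)) {
    whole_pt <- aggregate_to_pathways(contributions, mapping)
    core_pt <- stratify_by_partition(contributions, partition, metadata,
                                     "core", mapping)
    sat_pt <- stratify_by_partition(contributions, partition, metadata,
                                    "satellite", mapping)
    exclusive <- satellite_exclusive_pathways(core_pt, sat_pt)
    fun <- purrr::imap(list(whole = whole_pt, core = core_pt, satellite = sat_pt),
                       function(pt, st) {
      top <- abundant_pathways(pt, threshold = 1)
      clr <- clr_transform(top)
      md <- metadata[metadata$sample_id %in% names(pt)[-1], ]
      list(pathways = pt, abundant = top, clr = clr,
           tests = compare_pathways(clr, md, test = "anova"),
           tests_kw = compare_pathways(pt, md, test = "kw"))
    })
    ford <- pathway_pcoa(whole_pt, metadata, n_perm = n_perm,
                         seed = stage_seed(5))
    res$functions <- c(fun, list(exclusive = exclusive, ordination = ford))
    readr::write_tsv(whole_pt, file.path(out_dir, "pathways_whole.tsv"),
                     progress = FALSE)
    readr::write_tsv(fun$core$clr, file.path(out_dir, "pathways_core_clr.tsv"),
                     progress = FALSE)
    readr::write_tsv(fun$satellite$clr,
                     file.path(out_dir, "pathways_satellite_clr.tsv"),
                     progress = FALSE)
    readr::write_tsv(ford$pcoa$coordinates,
                     file.path(out_dir, "pcoa_function.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(exclusive_pathways = exclusive,
           anosim = as.list(tidy(ford$anosim)),
           tests = purrr::map(fun, ~ .x$tests$omnibus)),
      file.path(out_dir, "function_tests.json"), auto_unbox = TRUE, digits = NA)
  }

  # -- stage 6: constrained ordination ----------------------------------------
  covars <- config$covariates %||% {
    extra <- setdiff(names(metadata)[vapply(metadata, is.numeric, logical(1))],
                     "sample_id")
    c("group", extra)
  }
  hel <- hellinger_transform(counts)
  ords <- list(
    rda = forward_select(hel, metadata, covars, method = "rda", alpha = alpha,
                         n_perm = n_perm, seed = stage_seed(6)),
    cca = forward_select(rel, metadata, covars, method = "cca", alpha = alpha,
                         n_perm = n_perm, seed = stage_seed(6))
  )
  res$ordination <- ords
  jsonlite::write_json(
    purrr::map(ords, ~ list(selected = .x$selected, trail = .x$trail,
                            total_inertia = .x$total_inertia)),
    file.path(out_dir, "ordination.json"), auto_unbox = TRUE, digits = NA)

  # -- manifest ----------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    parameters = list(
      threshold = threshold, n_perm = n_perm, alpha = alpha, seed = seed,
      rarefaction_depth = config$rarefaction_depth %||% "minimum sample total",
      log_abundance_regression = TRUE,
      simper_scale = "percent relative abundance",
      clr_pseudocount = "multiplicative half-minimum",
      anosim_p_estimator = "(1 + exceedances) / (1 + n_perm)",
      rda_response = "hellinger", cca_response = "relative abundance",
      covariates = covars
    ),
    files = tibble::tibble(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files)))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
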