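#' Read a taxon-by-sample count table
#'
#' Reads a tab-separated count table into the tidy layout used throughout the
#' package: a tibble whose first column, `taxon_id`, holds unique taxon
#' identifiers and whose remaining columns are integer counts, one column per
#' sample. Files may be stored taxon-major (rows are taxa, the usual amplicon
#' convention) or sample-major (rows are samples); `orientation` declares which,
#' and sample-major files are transposed on read so downstream code always sees
#' taxa in rows.
#'
#' @param path Path to a UTF-8 TSV file. The first header cell names the row
#'   axis; the remaining header cells name the other axis.
#' @param orientation `"taxon"` (default) if rows are taxa, `"sample"` if rows
#'   are samples.
#' @return A count tibble: `taxon_id` plus one integer column per sample.
#' @seealso [write_count_table()], [read_count_biom()]
#' @export
read_count_table <- function(path, orientation = c("taxon", "sample")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  names(raw)[1] <- "id"
  if (anyDuplicated(raw$id)) {
    dup <- unique(raw$id[duplicated(raw$id)])
    abort(paste0("duplicate row identifiers in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  vals <- as.matrix(raw[-1])
  bad <- which(!is.finite(vals) | vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-integer or negative count at row '", raw$id[bad[1, 1]],
                 "', column '", colnames(vals)[bad[1, 2]], "' in ", path))
  }
  rownames(vals) <- raw$id
  if (orientation == "sample") vals <- t(vals)
  if (anyDuplicated(colnames(vals))) {
    dup <- unique(colnames(vals)[duplicated(colnames(vals))])
    abort(paste0("duplicate column identifiers in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  counts_tbl(vals)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: integer tables round-trip bit-identically.
#'
#' @param counts A count tibble (`taxon_id` + sample columns).
#' @param path Output path.
#' @return `counts`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  check_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(counts)
}

#' Read a count table from a BIOM 2.1 file
#'
#' Same contract as [read_count_table()] for BIOM-format feature tables
#' (requires the `biomformat` package).
#'
#' @param path Path to a BIOM file.
#' @return A count tibble.
#' @export
read_count_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("BIOM ingestion requires the 'biomformat' package")
  }
  m <- as(biomformat::biom_data(biomformat::read_biom(path)), "matrix")
  if (any(m < 0) || any(m != round(m))) abort("BIOM table holds non-integer counts")
  counts_tbl(m)
}

#' Read per-sample metadata
#'
#' @param path CSV file with mandatory columns `sample_id` and `group`;
#'   any further columns are carried as clinical covariates.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_metadata(md)
  md
}

#' Read a taxonomy assignment table
#'
#' @param path TSV file with a `taxon_id` column followed by the seven ranks
#'   `domain`, `phylum`, `class`, `order`, `family`, `genus`, `species`
#'   (lower ranks may be empty/NA where unassigned).
#' @return A tibble with `taxon_id` and the seven rank columns.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(c("taxon_id", tax_ranks()), names(tax))
  if (length(missing) > 0) {
    abort(paste0("taxonomy table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  tax
}

#' Read a stratified function contribution table
#'
#' Long-form per-taxon functional contributions as emitted by metagenome
#' prediction tools: one row per (sample, taxon, function) with a non-negative
#' abundance.
#'
#' @param path TSV with columns `sample_id`, `taxon_id`, `function_id`,
#'   `abundance`.
#' @return A contribution tibble.
#' @export
read_contributions <- function(path) {
  ct <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), taxon_id = readr::col_character(),
    function_id = readr::col_character(), abundance = readr::col_double()
  ), progress = FALSE)
  check_contributions(ct)
  ct
}

#' Read an unstratified function-by-sample table
#'
#' @param path TSV whose first column is `function_id` and whose remaining
#'   columns are per-sample abundances (non-negative reals).
#' @return A tibble with `function_id` plus one numeric column per sample.
#' @export
read_function_table <- function(path) {
  ft <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  names(ft)[1] <- "function_id"
  if (anyDuplicated(ft$function_id)) abort("duplicate function_id entries")
  if (any(as.matrix(ft[-1]) < 0)) abort("negative abundances in function table")
  ft
}

#' Drop taxa observed as a single read
#'
#' Removes taxa whose total count across the whole dataset equals one — the
#' usual post-denoising filter for sequencing artefacts. Taxa seen twice
#' (even once in each of two samples) are retained; the sample set is
#' unchanged; the operation is idempotent.
#'
#' @param counts A count tibble.
#' @return The filtered count tibble.
#' @export
remove_singleton_taxa <- function(counts) {
  check_counts(counts)
  total <- rowSums(as.matrix(counts[-1]))
  counts[total != 1, , drop = FALSE]
}

#' Collapse ASVs sharing a species-level assignment into one OTU
#'
#' Rows whose full seven-rank lineage is identical down to species level are
#' summed into a single operational taxonomic unit keyed by that lineage.
#' Rows without a species-level assignment pass through unmerged under their
#' original identifiers. Lineage equality is case-sensitive on all seven ranks,
#' so homonymous species in different genera are never merged. Per-sample
#' totals are conserved exactly (integer arithmetic).
#'
#' @param counts A count tibble.
#' @param taxonomy A taxonomy tibble covering every `taxon_id` in `counts`.
#' @return A count tibble of collapsed OTUs.
#' @export
collapse_to_species_otus <- function(counts, taxonomy) {
  check_counts(counts)
  missing <- setdiff(counts$taxon_id, taxonomy$taxon_id)
  if (length(missing) > 0) {
    abort(paste0("taxonomy missing for taxa: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  tax <- taxonomy[match(counts$taxon_id, taxonomy$taxon_id), tax_ranks()]
  has_species <- !is.na(tax$species) & tax$species != ""
  lineage <- apply(as.matrix(tax), 1L, paste, collapse = ";")
  key <- ifelse(has_species, lineage, paste0(".asv:", counts$taxon_id))
  out_id <- ifelse(has_species, lineage, counts$taxon_id)
  m <- as.matrix(counts[-1])
  collapsed <- rowsum(m, group = key, reorder = FALSE)
  rownames(collapsed) <- out_id[!duplicated(key)]
  counts_tbl(collapsed)
}

#' Convert counts to percent relative abundance
#'
#' Each sample column is rescaled to sum to 100.
#'
#' @param counts A count tibble (or any non-negative abundance tibble in the
#'   same layout).
#' @return A tibble of the same shape on the percent scale.
#' @export
to_relative_abundance <- function(counts) {
  m <- as.matrix(counts[-1])
  tot <- colSums(m)
  if (any(tot <= 0)) {
    abort(paste0("sample(s) with zero total: ",
                 paste(colnames(m)[tot <= 0], collapse = ", ")))
  }
  out <- counts
  out[-1] <- sweep(m, 2L, tot, "/") * 100
  out
}

# ---- internal helpers -------------------------------------------------------

tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

# matrix (taxa in rows, named dims) -> count tibble
counts_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# count tibble -> base matrix with taxon_id rownames
counts_matrix <- function(counts) {
  m <- as.matrix(counts[-1])
  storage.mode(m) <- "double"
  rownames(m) <- counts[[1]]
  m
}

check_counts <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2 ||
      !is.character(counts[[1]])) {
    abort("expected a count tibble: character `taxon_id` plus sample columns")
  }
  if (anyDuplicated(counts[[1]])) abort("duplicate taxon_id values")
  if (anyDuplicated(names(counts)[-1])) abort("duplicate sample columns")
  m <- as.matrix(counts[-1])
  if (any(m < 0)) abort("negative counts")
  invisible(counts)
}

check_metadata <- function(metadata) {
  missing <- setdiff(c("sample_id", "group"), names(metadata))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) abort("duplicate sample_id in metadata")
  if (any(is.na(metadata$group))) abort("missing group labels in metadata")
  invisible(metadata)
}

check_contributions <- function(contrib) {
  need <- c("sample_id", "taxon_id", "function_id", "abundance")
  missing <- setdiff(need, names(contrib))
  if (length(missing) > 0) {
    abort(paste0("contribution table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(contrib$abundance < 0)) abort("negative contribution abundances")
  if (anyDuplicated(contrib[c("sample_id", "taxon_id", "function_id")])) {
    abort("duplicate (sample, taxon, function) records")
  }
  invisible(contrib)
}

# groups for a set of sample columns, in column order
sample_groups <- function(counts, metadata) {
  check_metadata(metadata)
  samples <- names(counts)[-1]
  idx <- match(samples, metadata$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples absent from metadata: ",
                 paste(samples[is.na(idx)], collapse = ", ")))
  }
  setNames(as.character(metadata$group[idx]), samples)
}
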