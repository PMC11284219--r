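# Reading, writing, pooling and normalising taxon count tables.
#
# A count table is a tibble with a `sample_id` column followed by one numeric
# column per taxon (samples x taxa). The on-disk default dialect is
# taxa-as-rows with a `taxon_id` first column, which is how classifier outputs
# are usually shipped; `dialect = "samples_rows"` reads the transpose.

#' Read a taxon count table
#'
#' Reads a tab-separated count table and returns it oriented samples x taxa as
#' a tibble with a `sample_id` column. The default on-disk dialect is taxa as
#' rows with a `taxon_id` first column; `samples_rows` expects samples as rows
#' with a `sample_id` first column.
#'
#' @param path Path to a UTF-8 tab-separated file with one header row and one
#'   label column; the body must be numeric integer counts.
#' @param dialect `"taxa_rows"` (default) or `"samples_rows"`.
#' @return A tibble with `sample_id` plus one integer-valued column per taxon.
#' @export
read_count_table <- function(path, dialect = c("taxa_rows", "samples_rows")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("count table needs a label column and at least one data column")
  labels <- as.character(raw[[1]])
  label_col <- names(raw)[1]
  if (anyDuplicated(labels)) {
    abort(paste0("duplicate ", label_col, " labels in ", path, ": ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort(paste0("duplicate column labels in ", path))
  }
  body <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                  labels[bad[1]], colnames(body)[bad[2]], path))
  }
  rownames(num) <- labels
  if (dialect == "taxa_rows") num <- t(num)
  out <- ct_tibble(num)
  validate_count_table(out)
  out
}

#' Write a taxon count table
#'
#' Inverse of [read_count_table()]; writing then reading with the same dialect
#' reproduces the table exactly.
#'
#' @param table Count table tibble (samples x taxa).
#' @param path Output path.
#' @param dialect On-disk orientation, as in [read_count_table()].
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, dialect = c("taxa_rows", "samples_rows")) {
  dialect <- match.arg(dialect)
  m <- ct_matrix(table)
  if (dialect == "taxa_rows") {
    out <- dplyr::bind_cols(tibble(taxon_id = colnames(m)),
                            as_tibble(t(m), .name_repair = "minimal"))
  } else {
    out <- ct_tibble(m)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a taxonomy lineage table
#'
#' @param path TSV with columns `taxon_id`, `genus`, `class`, `phylum`.
#' @return A tibble with those columns.
#' @export
read_lineage <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  need <- c("taxon_id", "genus", "class", "phylum")
  if (!all(need %in% names(x))) {
    abort(paste0("lineage table must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(x$taxon_id)) abort("lineage has duplicated taxon_id entries")
  as_tibble(x[need])
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `run`, `library`, `site`, `plot`,
#'   `replicate`, `sample_type`.
#' @return A tibble with those columns.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  need <- c("sample_id", "run", "library", "site", "plot", "replicate", "sample_type")
  if (!all(need %in% names(x))) {
    abort(paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  }
  bad_type <- setdiff(unique(x$sample_type),
                      c("soil", "mock", "ext_control", "pcr_control"))
  if (length(bad_type)) abort(paste0("unknown sample_type: ", paste(bad_type, collapse = ", ")))
  bad_lib <- setdiff(unique(x$library), lib_levels())
  if (length(bad_lib)) abort(paste0("unknown library level: ", paste(bad_lib, collapse = ", ")))
  as_tibble(x[need])
}

#' Read per-run QC funnels
#'
#' @param path TSV with columns `run`, `raw_reads`, `demux_reads`,
#'   `qualfilt_reads`, `lenfilt_reads`.
#' @return A tibble with those columns (counts as numeric).
#' @export
read_funnels <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    run = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  need <- c("run", "raw_reads", "demux_reads", "qualfilt_reads", "lenfilt_reads")
  if (!all(need %in% names(x))) {
    abort(paste0("funnel table must have columns: ", paste(need, collapse = ", ")))
  }
  as_tibble(x[need])
}

#' Read an EMU-style merged relative-abundance table as pseudo-counts
#'
#' Classifier outputs are often shipped as per-sample relative abundances. This
#' reader converts them to pseudo-counts by multiplying each sample's column by
#' a supplied per-sample read count and rounding. The conversion is lossy:
#' rounding discards sub-read mass, so row sums may differ slightly from the
#' supplied totals.
#'
#' @param path TSV, taxa as rows (`taxon_id` first column), one column of
#'   relative abundances per sample.
#' @param read_counts Named numeric vector of per-sample read totals covering
#'   every sample column.
#' @return A count table tibble (samples x taxa, integer counts).
#' @export
read_emu_table <- function(path, read_counts) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  taxa <- as.character(raw[[1]])
  body <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  if (anyNA(num)) abort("non-numeric relative abundance cell")
  samples <- colnames(num)
  missing <- setdiff(samples, names(read_counts))
  if (length(missing)) {
    abort(paste0("read_counts missing for samples: ", paste(missing, collapse = ", ")))
  }
  counts <- round(sweep(num, 2, read_counts[samples], `*`))
  rownames(counts) <- taxa
  out <- ct_tibble(t(counts))
  validate_count_table(out)
  out
}

#' Pool several count tables over the union of their taxa
#'
#' Taxa absent from a table are zero-filled; sample ids must be disjoint.
#'
#' @param tables List of count table tibbles.
#' @return A single pooled count table.
#' @export
pool_count_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  mats <- lapply(tables, ct_matrix)
  taxa <- Reduce(union, lapply(mats, colnames))
  ids <- unlist(lapply(mats, rownames))
  if (anyDuplicated(ids)) abort("sample ids overlap between pooled tables")
  pooled <- matrix(0, nrow = length(ids), ncol = length(taxa),
                   dimnames = list(ids, taxa))
  for (m in mats) pooled[rownames(m), colnames(m)] <- m
  out <- ct_tibble(pooled)
  validate_count_table(out)
  out
}

#' Aggregate a count table to a higher taxonomic rank
#'
#' Counts are summed over taxa sharing the target-rank label; per-sample totals
#' are preserved exactly (integer arithmetic).
#'
#' @param table Count table at species (or finer-than-target) rank.
#' @param lineage Lineage tibble with columns `taxon_id`, `genus`, `class`,
#'   `phylum` covering every taxon in `table`.
#' @param rank Target rank: `"genus"`, `"class"` or `"phylum"`.
#' @return A count table whose taxon columns are the target-rank labels.
#' @export
aggregate_to_rank <- function(table, lineage, rank = c("genus", "class", "phylum")) {
  rank <- match.arg(rank)
  m <- ct_matrix(table)
  orphans <- setdiff(colnames(m), lineage$taxon_id)
  if (length(orphans)) {
    abort(paste0("taxa missing from lineage: ", paste(orphans, collapse = ", ")))
  }
  parent <- lineage[[rank]][match(colnames(m), lineage$taxon_id)]
  agg <- t(rowsum(t(m), group = parent))
  out <- ct_tibble(agg)
  validate_count_table(out, integer = FALSE)
  out
}

#' Convert counts to per-sample relative abundances
#'
#' Rows are divided by their row sums; all-zero rows are returned as zeros with
#' a warning naming the samples.
#'
#' @param table Count (or abundance) table.
#' @return An abundance table; non-degenerate rows sum to 1.
#' @export
to_relative_abundance <- function(table) {
  m <- ct_matrix(table)
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    warn(paste0("zero-sum samples left as zeros: ",
                paste(rownames(m)[zero], collapse = ", ")))
    rs[zero] <- 1
  }
  ct_tibble(m / rs)
}

#' Normalise counts to counts per million reads (CPM)
#'
#' @param table Count table; every sample must have a positive total.
#' @return An abundance table whose rows sum to 1e6.
#' @export
cpm_normalize <- function(table) {
  m <- ct_matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(paste0("zero-sum samples cannot be CPM-normalised: ",
                 paste(rownames(m)[rs == 0], collapse = ", ")))
  }
  ct_tibble(m / rs * 1e6)
}
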