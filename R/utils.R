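# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
NULL

# Library autonomy levels, least to most autonomous.
lib_levels <- function() c("Seq", "PCR/Seq", "Ext/PCR/Seq")

# Workflow stages covered by each library's autonomy level. A bias entering at
# stage s propagates into every library whose preparation includes s.
lib_stages <- function(library) {
  switch(library,
    "Seq"         = "sequencing",
    "PCR/Seq"     = c("pcr", "sequencing"),
    "Ext/PCR/Seq" = c("extraction", "pcr", "sequencing"),
    abort(paste0("unknown library level: '", library, "'"))
  )
}

# Extract the numeric samples x taxa matrix from a count/abundance tibble whose
# first column is `sample_id`.
ct_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"sample_id" %in% names(x)) {
    abort("count table must have a 'sample_id' column")
  }
  ids <- as.character(x$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  if (!is.numeric(m)) abort("count table body must be numeric")
  rownames(m) <- ids
  m
}

# Rebuild a samples x taxa tibble from a matrix with sample ids as rownames.
ct_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
}

# Validate the TaxonCountTable invariants: non-negative integer counts, unique
# sample and taxon labels.
validate_count_table <- function(x, integer = TRUE) {
  m <- ct_matrix(x)
  taxa <- colnames(m)
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon ids: ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  if (anyNA(m)) abort("count table contains missing values")
  if (any(m < 0)) abort("counts must be non-negative")
  if (integer && any(abs(m - round(m)) > 1e-8)) {
    abort("counts must be integers")
  }
  invisible(x)
}

# Per-sample library sizes (row sums).
library_sizes <- function(x) {
  m <- ct_matrix(x)
  tibble(sample_id = rownames(m), library_size = unname(rowSums(m)))
}

# Deterministic substream seed derivation; keeps results < 2^31 so they are
# valid R integer seeds.
mix_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 48271 + as.double(k) * 104729) %% 2147483629 + 1)
}

# Benjamini-Hochberg adjustment, NA-safe.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
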