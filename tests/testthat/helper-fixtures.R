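# Shared fixture builders. Everything is generated in code; no data files.

# A tiny hand-checkable count table (samples x taxa).
tiny_table <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    t1 = c(1L, 0L, 5L),
    t2 = c(1L, 10L, 0L),
    t3 = c(2L, 0L, 5L)
  )
}

tiny_lineage <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    genus = c("g1", "g1", "g2"),
    class = c("c1", "c1", "c1"),
    phylum = c("p1", "p1", "p1")
  )
}

# Random small count table for property tests.
random_table <- function(n_samples, n_taxa, lambda = 5, min_total = 2) {
  m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("t", seq_len(n_taxa))))
  # ensure classical-Morisita preconditions
  low <- rowSums(m) < min_total
  m[low, 1] <- m[low, 1] + min_total
  tibble::as_tibble(cbind(tibble::tibble(sample_id = rownames(m)),
                          tibble::as_tibble(m, .name_repair = "minimal")))
}

# A fast reduced study configuration for structural unit tests.
small_config <- function(seed = 1, ...) {
  runs <- tibble::tibble(
    run = paste0("Run", 1:4),
    mean_depth = c(4000, 3000, 5000, 3500),
    demux_removed = 0.42, quality_removed = 0.03, length_removed = 0.005,
    aberrant = c(FALSE, TRUE, FALSE, FALSE),
    reference = c(TRUE, FALSE, FALSE, TRUE)
  )
  synthetic_config(n_phyla = 4, n_classes_per_phylum = 2,
                   n_genera_per_class = 3, n_species_per_genus = 2,
                   runs = runs, n_plots = 2, n_replicates = 2,
                   aberrant_bias = list(phyla = c("P01", "P02"), log2_sd = 1.5,
                                        stage = "pcr", within_sd = 0.4),
                   seed = seed, ...)
}

# Cache one default-configuration study per test session.
default_study <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) cache <<- simulate_study(synthetic_config(seed = seed))
    cache
  }
})

# Study configuration whose only pathology is the PCR-stage bias: comparable
# depths, no extreme low-depth run.
biased_run_config <- function(seed, aberrant = TRUE) {
  runs <- tibble::tibble(
    run = paste0("Run", 1:6),
    mean_depth = c(45000, 30000, 60000, 40000, 20000, 25000),
    demux_removed = 0.42, quality_removed = 0.03, length_removed = 0.005,
    aberrant = c(FALSE, aberrant, FALSE, FALSE, FALSE, FALSE),
    reference = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  synthetic_config(runs = runs, seed = seed)
}

# Brute-force oracles written against the formulas, independent of the
# package's implementation paths.
brute_bray_curtis <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  d
}

brute_hellinger <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- sqrt(m[i, ] / sum(m[i, ]))
  out
}

brute_morisita <- function(m) {
  lam <- function(x) sum(x * (x - 1)) / (sum(x) * (sum(x) - 1))
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    C <- 2 * sum(m[i, ] * m[j, ]) /
      ((lam(m[i, ]) + lam(m[j, ])) * sum(m[i, ]) * sum(m[j, ]))
    d[i, j] <- 1 - C
  }
  d
}
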