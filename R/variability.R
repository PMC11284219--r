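# Between-run abundance variability: RLE normalisation, log2 fold-changes
# against a primary-lab baseline and between sites, the range-of-Log2FC
# statistic, and repeated-measures ANOVA across library autonomy levels.
#
# The range (max - min) of a taxon's log2 fold-changes across sequence runs is
# the study's between-run variability statistic: if runs agreed perfectly every
# taxon's range would be 0, and workflow autonomy (extraction, PCR) adds to it.

#' Relative log expression (median-of-ratios) size factors
#'
#' For each sample, the median over taxa of `count / geometric mean across
#' samples`, computed on taxa with all-positive counts, then rescaled so the
#' factors have geometric mean 1.
#'
#' @param table Count table (samples x taxa).
#' @return Tibble `sample_id`, `size_factor`.
#' @export
rle_size_factors <- function(table) {
  m <- ct_matrix(table)
  pos <- colSums(m > 0) == nrow(m)
  if (!any(pos)) {
    abort(paste0("no taxon has positive counts in every sample; ",
                 "consider adding a pseudocount before RLE normalisation"))
  }
  lm_ <- log(m[, pos, drop = FALSE])
  ref <- colMeans(lm_)            # log geometric mean per taxon
  sf <- exp(apply(sweep(lm_, 2, ref), 1, stats::median))
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = rownames(m), size_factor = unname(sf))
}

#' Log2 fold-changes against the primary-lab baseline
#'
#' CPM-normalises the soil samples at the requested rank and computes, per
#' (run, library, taxon), `log2((mean CPM of the run-library's soil samples +
#' pc) / (mean CPM of the reference runs' soil samples + pc))`. The baseline
#' pools all soil samples of the reference runs.
#'
#' @param table Count table (species rank if `lineage` is supplied).
#' @param metadata Sample metadata; only soil samples are used.
#' @param reference_runs Labels of the primary-lab runs forming the baseline.
#' @param lineage Optional lineage for aggregation to `rank`.
#' @param rank Taxonomic rank (default `"genus"`).
#' @param pseudocount Pseudocount in CPM units (default 0.5) keeping all values
#'   finite.
#' @return Tibble `run`, `library`, `taxon`, `log2fc`, with `baseline` and
#'   `pseudocount` attributes.
#' @export
log2fc_vs_reference <- function(table, metadata, reference_runs,
                                lineage = NULL, rank = "genus",
                                pseudocount = 0.5) {
  if (!all(reference_runs %in% metadata$run)) {
    abort("reference_runs must be present in the metadata")
  }
  soil <- metadata %>% filter(.data$sample_type == "soil")
  tab <- at_rank(table, lineage, rank)
  m <- ct_matrix(tab)
  soil <- soil %>% filter(.data$sample_id %in% rownames(m))
  cpm <- ct_matrix(cpm_normalize(ct_tibble(m[soil$sample_id, , drop = FALSE])))
  ref_ids <- soil$sample_id[soil$run %in% reference_runs]
  if (!length(ref_ids)) abort("reference runs contain no soil samples")
  baseline <- colMeans(cpm[ref_ids, , drop = FALSE])
  out <- soil %>%
    distinct(.data$run, .data$library) %>%
    arrange(.data$run, .data$library)
  rows <- purrr::pmap(out, function(run, library) {
    ids <- soil$sample_id[soil$run == run & soil$library == library]
    mu <- colMeans(cpm[ids, , drop = FALSE])
    tibble(run = run, library = library, taxon = names(mu),
           log2fc = unname(log2((mu + pseudocount) /
                                  (baseline + pseudocount))))
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "baseline") <- paste0("mean CPM over soil samples of runs: ",
                                  paste(reference_runs, collapse = ", "))
  attr(res, "pseudocount") <- pseudocount
  res
}

#' Site-contrast log2 fold-changes with permutation significance
#'
#' Within each (run, library): counts at the requested rank are RLE-normalised,
#' and each taxon's `log2((mean site2 + pc) / (mean site1 + pc))` (sites in
#' sorted label order) is tested by a two-sided permutation test on the site
#' labels, Benjamini-Hochberg adjusted across taxa. Contexts missing a site are
#' skipped with a warning.
#'
#' @inheritParams log2fc_vs_reference
#' @param rank Taxonomic rank (default `"phylum"`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return Tibble `run`, `library`, `taxon`, `log2fc`, `p.value`, `p_adj`.
#' @export
log2fc_site_contrast <- function(table, metadata, lineage = NULL,
                                 rank = "phylum", n_perm = 1000, seed = 1L,
                                 pseudocount = 0.5) {
  soil <- metadata %>% filter(.data$sample_type == "soil")
  tab <- at_rank(table, lineage, rank)
  m <- ct_matrix(tab)
  soil <- soil %>% filter(.data$sample_id %in% rownames(m))
  sites <- sort(unique(soil$site))
  if (length(sites) != 2) abort("site contrast needs exactly 2 sites")
  contexts <- soil %>% distinct(.data$run, .data$library) %>%
    arrange(.data$run, .data$library)
  skipped <- character()
  rows <- vector("list", nrow(contexts))
  for (i in seq_len(nrow(contexts))) {
    cx <- contexts[i, ]
    sub <- soil %>% filter(.data$run == cx$run, .data$library == cx$library)
    if (!all(sites %in% sub$site)) {
      skipped <- c(skipped, paste0(cx$run, "/", cx$library))
      next
    }
    counts <- m[sub$sample_id, , drop = FALSE]
    # Size factors need at least one all-positive taxon; fall back to a +1
    # pseudocount for factor estimation only.
    sf <- if (any(colSums(counts > 0) == nrow(counts))) {
      rle_size_factors(ct_tibble(counts))
    } else {
      rle_size_factors(ct_tibble(counts + 1))
    }
    norm <- counts / sf$size_factor
    is2 <- sub$site == sites[2]
    stat <- function(flag2) {
      log2((colMeans(norm[flag2, , drop = FALSE]) + pseudocount) /
             (colMeans(norm[!flag2, , drop = FALSE]) + pseudocount))
    }
    obs <- stat(is2)
    n2 <- sum(is2)
    exceed <- rep(0L, ncol(norm))
    withr::with_seed(mix_seed(seed, i), {
      for (b in seq_len(n_perm)) {
        perm <- rep(FALSE, nrow(norm))
        perm[sample.int(nrow(norm), n2)] <- TRUE
        exceed <- exceed + (abs(stat(perm)) >= abs(obs) - 1e-12)
      }
    })
    p <- (1 + exceed) / (1 + n_perm)
    rows[[i]] <- tibble(run = cx$run, library = cx$library,
                        taxon = colnames(norm), log2fc = unname(obs),
                        p.value = unname(p), p_adj = bh_adjust(unname(p)))
  }
  if (length(skipped)) {
    warn(paste0("contexts missing a site skipped: ",
                paste(skipped, collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) abort("no context contains both sites")
  out
}

#' Per-taxon range of log2 fold-changes across runs
#'
#' `max - min` of each taxon's log2fc across sequence runs, within each
#' library. Adding a run can only increase a taxon's range.
#'
#' @param log2fc Tibble with columns `library`, `taxon`, `run`, `log2fc` (e.g.
#'   from [log2fc_vs_reference()]).
#' @return Tibble `library`, `taxon`, `range`, `n_runs`.
#' @export
log2fc_range <- function(log2fc) {
  out <- log2fc %>%
    group_by(.data$library, .data$taxon) %>%
    summarise(range = max(.data$log2fc) - min(.data$log2fc),
              n_runs = dplyr::n_distinct(.data$run), .groups = "drop")
  if (any(out$n_runs < 2)) {
    abort("log2fc_range needs values from at least 2 runs per taxon")
  }
  out
}

# Greenhouse-Geisser epsilon from the condition covariance matrix.
gg_epsilon <- function(y) {
  k <- ncol(y)
  S <- stats::cov(y)
  C <- diag(k) - matrix(1 / k, k, k)
  M <- C %*% S %*% C
  tr <- sum(diag(M))
  if (tr <= 0) return(1)
  max(1 / (k - 1), min(1, tr^2 / ((k - 1) * sum(M * M))))
}

#' Repeated-measures ANOVA on log2FC ranges across libraries
#'
#' One-way within-subject ANOVA with taxon as the subject and library as the
#' (within) main effect. Greenhouse-Geisser sphericity correction is applied to
#' the default p-value (`p.value`), with the uncorrected `p_raw` also reported.
#' Pairwise library contrasts are paired t-tests with Benjamini-Hochberg
#' adjustment; per-library means carry t-based 95% confidence intervals. Taxa
#' missing any library level are listwise-dropped (count reported).
#'
#' @param ranges Tibble `library`, `taxon`, `range` from [log2fc_range()].
#' @return A list of class `rm_anova_variability`: `anova` (tibble `statistic`,
#'   `df1`, `df2`, `gg_epsilon`, `p.value`, `p_raw`), `means` (per-library mean
#'   range with `se`, `ci_low`, `ci_high`, `n`), `pairwise` (paired contrasts
#'   with `p.value`, `p_adj`), `n_subjects`, `n_dropped`.
#' @export
rm_anova_variability <- function(ranges) {
  wide <- ranges %>%
    select("taxon", "library", "range") %>%
    tidyr::pivot_wider(names_from = "library", values_from = "range")
  libs <- intersect(lib_levels(), names(wide))
  if (length(libs) < 2) libs <- setdiff(names(wide), "taxon")
  y <- as.matrix(wide[libs])
  complete <- stats::complete.cases(y)
  n_dropped <- sum(!complete)
  y <- y[complete, , drop = FALSE]
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) abort("need >= 2 complete taxa and >= 2 libraries")
  grand <- mean(y)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err <= .Machine$double.eps) {
    if (ms_cond <= .Machine$double.eps) 0 else Inf
  } else {
    ms_cond / ms_err
  }
  eps <- gg_epsilon(y)
  p_raw <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  p_gg <- if (is.infinite(f)) 0 else
    stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  means <- tibble(
    library = libs,
    mean = colMeans(y),
    se = apply(y, 2, stats::sd) / sqrt(n),
    n = n
  ) %>%
    mutate(ci_low = .data$mean - stats::qt(0.975, n - 1) * .data$se,
           ci_high = .data$mean + stats::qt(0.975, n - 1) * .data$se)
  combs <- utils::combn(libs, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(combs, function(pr) {
    dif <- y[, pr[1]] - y[, pr[2]]
    tt <- if (stats::sd(dif) == 0) {
      list(statistic = 0, p.value = 1)
    } else {
      stats::t.test(dif)
    }
    tibble(library_a = pr[1], library_b = pr[2],
           estimate = mean(dif), statistic = unname(tt$statistic),
           p.value = tt$p.value)
  }) %>%
    mutate(p_adj = bh_adjust(.data$p.value))
  structure(list(
    anova = tibble(statistic = f, df1 = df1, df2 = df2, gg_epsilon = eps,
                   p.value = p_gg, p_raw = p_raw),
    means = means, pairwise = pairwise,
    n_subjects = n, n_dropped = n_dropped
  ), class = "rm_anova_variability")
}

#' @export
print.rm_anova_variability <- function(x, ...) {
  cat("Repeated-measures ANOVA on log2FC ranges (", x$n_subjects,
      " taxa, ", x$n_dropped, " dropped)\n", sep = "")
  print(x$anova, ...)
  print(x$means, ...)
  invisible(x)
}
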