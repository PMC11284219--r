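# The headline run-level diagnostics: within-run replicate similarity,
# between-run reference-soil similarity, IQR-based flag rules, and
# mock-community evaluation.
#
# The underlying idea: a successful sequence run reproduces the community
# profile of the same physical soil seen by other (reference) runs. Replicate
# subsamples bound the within-run noise floor; comparing every sample to the
# matching sample of a well-characterised reference run turns "this run looks
# odd" into a one-sided IQR rule on pooled similarities.

#' Boxplot statistics
#'
#' Quartiles by linear interpolation between order statistics (type-7, the
#' plotting convention), IQR, whiskers at the most extreme points within
#' 1.5 x IQR of the quartiles, and the points beyond them as outliers.
#'
#' @param values Numeric vector (>= 1 value).
#' @return List with `n`, `q1`, `median`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) abort("boxplot_stats needs at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(n = length(values), q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}

# Vectorised pair similarities over row-index vectors of a samples x taxa
# matrix.
similarity_pairs <- function(m, ia, ib, metric) {
  if (metric == "bc_hellinger") {
    rs <- rowSums(m)
    h <- sqrt(m / ifelse(rs == 0, 1, rs))
    num <- rowSums(abs(h[ia, , drop = FALSE] - h[ib, , drop = FALSE]))
    den <- rowSums(h[ia, , drop = FALSE] + h[ib, , drop = FALSE])
    unname(ifelse(den == 0, 1, 1 - num / den))
  } else if (metric == "morisita") {
    if (any(abs(m - round(m)) > 1e-8)) {
      abort("morisita similarity requires integer counts")
    }
    tot <- rowSums(m)
    if (any(tot < 2)) abort("morisita similarity requires sample totals >= 2")
    lam <- rowSums(m * (m - 1)) / (tot * (tot - 1))
    cross <- rowSums(m[ia, , drop = FALSE] * m[ib, , drop = FALSE])
    C <- 2 * cross / ((lam[ia] + lam[ib]) * tot[ia] * tot[ib])
    unname(pmin(pmax(C, 0), 1))
  } else {
    abort(paste0("unknown metric: ", metric))
  }
}

# Aggregate to comparison rank if a lineage is supplied.
at_rank <- function(table, lineage, rank) {
  if (is.null(lineage)) table else aggregate_to_rank(table, lineage, rank)
}

summarise_similarity <- function(values) {
  values %>%
    group_by(.data$run, .data$library) %>%
    summarise({
      b <- boxplot_stats(.data$similarity)
      tibble(n_pairs = b$n, q1 = b$q1, median = b$median, q3 = b$q3,
             iqr = b$iqr, whisker_low = b$whisker_low,
             whisker_high = b$whisker_high)
    }, .groups = "drop")
}

new_similarity_summary <- function(values, metric, type) {
  structure(list(values = values, summaries = summarise_similarity(values),
                 metric = metric, type = type),
            class = "similarity_summary")
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat("Similarity diagnostic (", x$type, ", ", x$metric, ")\n", sep = "")
  print(x$summaries, ...)
  invisible(x)
}

#' Within-run replicate similarity
#'
#' For every (run, library, site, plot), the similarity between each pair of
#' replicate subsamples, pooled into per-(run, library) boxplot summaries.
#' Comparison is at genus rank by default (supply `lineage`), using either
#' Bray-Curtis similarity of Hellinger-transformed abundances or the classical
#' Morisita similarity of raw counts.
#'
#' @param table Count table (species rank if `lineage` is supplied).
#' @param metadata Sample metadata; only soil samples are used.
#' @param lineage Optional lineage for aggregation to `rank`.
#' @param metric `"bc_hellinger"` (default) or `"morisita"`.
#' @param rank Comparison rank when `lineage` is given (default `"genus"`).
#' @return A `similarity_summary`: `values` (one row per replicate pair) and
#'   `summaries` (per run x library).
#' @export
within_run_similarity <- function(table, metadata, lineage = NULL,
                                  metric = c("bc_hellinger", "morisita"),
                                  rank = "genus") {
  metric <- match.arg(metric)
  soil <- metadata %>% filter(.data$sample_type == "soil")
  tab <- at_rank(table, lineage, rank)
  m <- ct_matrix(tab)
  soil <- soil %>% filter(.data$sample_id %in% rownames(m))
  grouped <- soil %>%
    group_by(.data$run, .data$library, .data$site, .data$plot) %>%
    filter(n() >= 2)
  if (!nrow(grouped)) abort("no replicate pairs found")
  pairs <- grouped %>%
    summarise(pair = {
      ids <- sort(.data$sample_id)
      if (length(ids) < 2) {
        tibble(id_a = character(), id_b = character())
      } else {
        cmb <- utils::combn(ids, 2)
        tibble(id_a = cmb[1, ], id_b = cmb[2, ])
      }
    }, .groups = "drop") %>%
    tidyr::unnest(cols = "pair")
  if (!nrow(pairs)) abort("no replicate pairs found")
  pairs$similarity <- similarity_pairs(m, match(pairs$id_a, rownames(m)),
                                       match(pairs$id_b, rownames(m)), metric)
  new_similarity_summary(pairs, metric, "within_run")
}

#' Reference-soil similarity between runs
#'
#' Each evaluated soil sample is compared to the matching sample of each
#' reference run -- same (site, plot, replicate) and same library where
#' available, falling back to any replicate of the same (site, plot, library).
#' Samples of a reference run are compared only to the other reference run(s).
#' Unmatched samples are skipped with a warning. One similarity per (sample,
#' reference run) is recorded and pooled into per-(run, library) summaries.
#'
#' @inheritParams within_run_similarity
#' @param reference_runs Labels of the reference (primary-lab) runs.
#' @return A `similarity_summary` with `values` columns `run`, `library`,
#'   `site`, `plot`, `replicate`, `sample_id`, `reference_run`,
#'   `reference_sample`, `similarity`.
#' @export
reference_similarity <- function(table, metadata, reference_runs,
                                 lineage = NULL,
                                 metric = c("bc_hellinger", "morisita"),
                                 rank = "genus") {
  metric <- match.arg(metric)
  if (!length(reference_runs) || !all(reference_runs %in% metadata$run)) {
    abort("reference_runs must be run labels present in the metadata")
  }
  soil <- metadata %>% filter(.data$sample_type == "soil")
  tab <- at_rank(table, lineage, rank)
  m <- ct_matrix(tab)
  soil <- soil %>% filter(.data$sample_id %in% rownames(m))
  refs <- soil %>% filter(.data$run %in% reference_runs)
  ref_exact <- refs %>%
    select(reference_run = "run", "site", "plot", "replicate", "library",
           exact_sample = "sample_id")
  ref_any <- refs %>%
    group_by(.data$run, .data$site, .data$plot, .data$library) %>%
    arrange(.data$replicate, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(reference_run = "run", "site", "plot", "library",
           fallback_sample = "sample_id")
  values <- tidyr::crossing(soil, reference_run = reference_runs) %>%
    filter(.data$run != .data$reference_run) %>%
    left_join(ref_exact,
              by = c("site", "plot", "replicate", "library", "reference_run")) %>%
    left_join(ref_any, by = c("site", "plot", "library", "reference_run")) %>%
    mutate(reference_sample = dplyr::coalesce(.data$exact_sample,
                                              .data$fallback_sample))
  unmatched <- unique(values$sample_id[is.na(values$reference_sample)])
  if (length(unmatched)) {
    warn(paste0("no matching reference sample for: ",
                paste(unmatched, collapse = ", ")))
    values <- values %>% filter(!is.na(.data$reference_sample))
  }
  if (!nrow(values)) abort("no sample could be matched to a reference run")
  values <- values %>%
    mutate(similarity = similarity_pairs(
      m, match(.data$sample_id, rownames(m)),
      match(.data$reference_sample, rownames(m)), metric)) %>%
    select("run", "library", "site", "plot", "replicate", "sample_id",
           "reference_run", "reference_sample", "similarity") %>%
    arrange(.data$run, .data$library, .data$site, .data$plot,
            .data$replicate, .data$reference_run)
  new_similarity_summary(values, metric, "reference")
}

#' Flag runs whose similarity falls below the reference pool band
#'
#' The pool band is the median and IQR of the pooled similarity values of the
#' pool runs; a (run, library) is flagged iff its median similarity falls below
#' `pool median - band_multiplier * pool IQR`. Low similarity is the failure
#' mode, so flagging is one-sided. By default the band is computed per library
#' (each run-library is judged against the pool runs' values of the same
#' library, since variability grows with library autonomy); `per_library =
#' FALSE` uses one band pooled over all libraries.
#'
#' @param x A `similarity_summary` from [within_run_similarity()] or
#'   [reference_similarity()].
#' @param pool_runs Labels of the runs forming the reference pool (>= 2).
#' @param band_multiplier Width of the band in pool IQRs (default 1; use 0.5
#'   for a median +/- IQR/2 reading).
#' @param per_library Compute the band within each library level (default
#'   `TRUE`).
#' @return Tibble of run flags: `run`, `library`, `rule`, `statistic` (the
#'   run's median), `threshold`, `pool_median`, `pool_iqr`, `flag`.
#' @export
flag_outlier_runs <- function(x, pool_runs, band_multiplier = 1,
                              per_library = TRUE) {
  stopifnot(inherits(x, "similarity_summary"))
  pool_vals <- x$values %>% filter(.data$run %in% pool_runs)
  if (length(unique(pool_vals$run)) < 2) {
    abort("pool must contain at least 2 runs with similarity values")
  }
  bands <- if (per_library) {
    pool_vals %>%
      group_by(.data$library) %>%
      summarise({
        b <- boxplot_stats(.data$similarity)
        tibble(pool_median = b$median, pool_iqr = b$iqr)
      }, .groups = "drop")
  } else {
    b <- boxplot_stats(pool_vals$similarity)
    x$summaries %>% distinct(.data$library) %>%
      mutate(pool_median = b$median, pool_iqr = b$iqr)
  }
  x$summaries %>%
    inner_join(bands, by = "library") %>%
    transmute(.data$run, .data$library,
              rule = paste0(x$type, "_similarity_low"),
              statistic = .data$median,
              threshold = .data$pool_median - band_multiplier * .data$pool_iqr,
              .data$pool_median, .data$pool_iqr,
              flag = .data$statistic < .data$threshold)
}

#' Evaluate a mock-community sample against its expected profile
#'
#' Bray-Curtis similarity of relative abundances on the union of observed and
#' expected taxa, the contaminant fraction (observed mass on taxa outside the
#' expected profile), and a pass/fail verdict at the similarity threshold.
#'
#' @param observed Named numeric vector of counts (or a one-row count table) at
#'   the rank of `expected` (genus by default).
#' @param expected Expected profile tibble (`taxon_id`, `percent`), default the
#'   8-genus community standard.
#' @param thresholds A [diagnostic_thresholds()].
#' @return Tibble `similarity`, `contaminant_fraction`, `pass`.
#' @export
mock_evaluation <- function(observed,
                            expected = mock_expected_profile("genus"),
                            thresholds = diagnostic_thresholds()) {
  if (is.data.frame(observed)) {
    m <- ct_matrix(observed)
    if (nrow(m) != 1) abort("observed must be a single mock sample")
    observed <- m[1, ]
  }
  if (sum(observed) == 0) abort("mock sample has zero counts")
  obs <- observed / sum(observed)
  exp_p <- stats::setNames(expected$percent / 100, expected$taxon_id)
  exp_p <- exp_p / sum(exp_p)
  taxa <- union(names(obs), names(exp_p))
  o <- stats::setNames(numeric(length(taxa)), taxa); o[names(obs)] <- obs
  e <- stats::setNames(numeric(length(taxa)), taxa); e[names(exp_p)] <- exp_p
  sim <- 1 - sum(abs(o - e)) / sum(o + e)
  contam <- sum(o[setdiff(taxa, names(exp_p))])
  tibble(similarity = sim, contaminant_fraction = contam,
         pass = sim >= thresholds$mock_similarity_min)
}

#' Evaluate every mock sample of a study
#'
#' @param table Count table (species rank if `lineage` is supplied).
#' @param metadata Sample metadata; mock samples have `sample_type == "mock"`.
#' @param lineage Optional lineage for aggregation to genus rank.
#' @param thresholds A [diagnostic_thresholds()].
#' @return Tibble `sample_id`, `run`, `library`, `similarity`,
#'   `contaminant_fraction`, `pass`.
#' @export
evaluate_mocks <- function(table, metadata, lineage = NULL,
                           thresholds = diagnostic_thresholds()) {
  mocks <- metadata %>% filter(.data$sample_type == "mock")
  if (!nrow(mocks)) abort("no mock samples in metadata")
  tab <- at_rank(table, lineage, "genus")
  m <- ct_matrix(tab)
  rows <- purrr::pmap(mocks[, c("sample_id", "run", "library")],
    function(sample_id, run, library) {
      ev <- mock_evaluation(m[sample_id, ], thresholds = thresholds)
      dplyr::bind_cols(tibble(sample_id = sample_id, run = run,
                              library = library), ev)
    })
  dplyr::bind_rows(rows)
}
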