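test_that("boxplot_stats follows the type-7 / 1.5 IQR convention", {
  b <- boxplot_stats(1:5)
  expect_equal(b$median, 3)
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)
  expect_equal(b$iqr, 2)
  expect_length(b$outliers, 0)
  const <- boxplot_stats(rep(4, 6))
  expect_equal(const$iqr, 0)
  expect_length(const$outliers, 0)
  out <- boxplot_stats(c(1, 1, 1, 1, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 1)
  expect_error(boxplot_stats(numeric()), "at least one")
})

# A four-sample two-run study where every sample is identical.
identical_study <- function() {
  meta <- tidyr::expand_grid(run = c("R1", "R2"), library = "Seq",
                             site = "A", plot = "1", replicate = c("A", "B")) %>%
    dplyr::mutate(sample_id = paste(run, replicate, sep = "_"),
                  sample_type = "soil")
  counts <- tibble::tibble(sample_id = meta$sample_id,
                           t1 = 40L, t2 = 30L, t3 = 30L)
  list(meta = meta, counts = counts)
}

test_that("within-run similarity is 1 for identical replicates and bookkeeps", {
  st <- identical_study()
  w <- within_run_similarity(st$counts, st$meta)
  expect_equal(w$values$similarity, rep(1, 2))
  # summaries recompute exactly from the stored pair values
  redo <- w$values %>%
    dplyr::group_by(run, library) %>%
    dplyr::summarise(median = median(similarity), .groups = "drop")
  expect_equal(w$summaries$median, redo$median)
  expect_error(within_run_similarity(st$counts, st$meta[c(1, 3), ]),
               "no replicate pairs")
})

test_that("similarity diagnostics are invariant to sample order and taxon labels", {
  study <- simulate_study(small_config(seed = 14))
  w1 <- within_run_similarity(study$counts, study$metadata, study$lineage)
  perm <- sample(nrow(study$counts))
  counts2 <- study$counts[perm, ]
  w2 <- within_run_similarity(counts2, study$metadata, study$lineage)
  expect_equal(w1$summaries, w2$summaries)
  # relabel taxa (same lineage structure, new names)
  counts3 <- study$counts
  lin3 <- study$lineage
  names(counts3)[-1] <- paste0("x", seq_len(ncol(counts3) - 1))
  lin3$taxon_id <- paste0("x", match(lin3$taxon_id, names(study$counts)[-1]))
  w3 <- within_run_similarity(counts3, study$metadata, lin3)
  expect_equal(w1$summaries$median, w3$summaries$median)
})

test_that("reference similarity is 1 against an identical reference", {
  st <- identical_study()
  r <- reference_similarity(st$counts, st$meta, reference_runs = "R1")
  expect_equal(r$values$similarity, rep(1, 2))   # R2's two samples vs R1
  expect_setequal(r$values$run, "R2")
  # unmatched plots are skipped with a warning
  meta2 <- st$meta
  meta2$plot[meta2$run == "R2"] <- "9"
  expect_warning(expect_error(
    reference_similarity(st$counts, meta2, reference_runs = "R1"),
    "no sample could be matched"), "no matching reference")
})

test_that("flag rule arithmetic and monotonicity", {
  # pool of 5 values whose type-7 quartiles are exact: median 0.89, IQR 0.04
  values <- tibble::tibble(
    run = c("P1", "P1", "P1", "P2", "P2", rep("bad", 3), rep("good", 3)),
    library = "Seq",
    similarity = c(0.85, 0.89, 0.93, 0.87, 0.91, rep(0.60, 3), rep(0.88, 3))
  )
  x <- structure(list(values = values,
                      summaries = values %>%
                        dplyr::group_by(run, library) %>%
                        dplyr::summarise({
                          b <- boxplot_stats(similarity)
                          tibble::tibble(n_pairs = b$n, q1 = b$q1,
                                         median = b$median, q3 = b$q3,
                                         iqr = b$iqr,
                                         whisker_low = b$whisker_low,
                                         whisker_high = b$whisker_high)
                        }, .groups = "drop"),
                      metric = "bc_hellinger", type = "reference"),
                 class = "similarity_summary")
  fl <- flag_outlier_runs(x, pool_runs = c("P1", "P2"))
  expect_true(fl$flag[fl$run == "bad"])
  expect_false(fl$flag[fl$run == "good"])
  expect_equal(fl$pool_median[1], 0.89)
  expect_equal(fl$pool_iqr[1], 0.04, tolerance = 1e-9)
  # lowering a run's values never removes its flag
  x2 <- x
  x2$values$similarity[x2$values$run == "bad"] <- 0.3
  x2$summaries$median[x2$summaries$run == "bad"] <- 0.3
  fl2 <- flag_outlier_runs(x2, pool_runs = c("P1", "P2"))
  expect_true(fl2$flag[fl2$run == "bad"])
  expect_error(flag_outlier_runs(x, pool_runs = "P1"), "at least 2")
})

test_that("mock evaluation computes similarity and contaminant fraction", {
  expected <- mock_expected_profile("genus")
  obs <- stats::setNames(expected$percent * 100, expected$taxon_id)
  ev <- mock_evaluation(obs)
  expect_equal(ev$similarity, 1)
  expect_equal(ev$contaminant_fraction, 0)
  expect_true(ev$pass)
  # move 5% of the mass onto a contaminant genus
  obs2 <- c(obs * 0.95, Contam = sum(obs) * 0.05)
  ev2 <- mock_evaluation(obs2)
  expect_equal(ev2$contaminant_fraction, 0.05)
  expect_equal(ev2$similarity, 0.95)
  # default threshold
  expect_equal(diagnostic_thresholds()$mock_similarity_min, 0.860)
  expect_error(mock_evaluation(c(a = 0, b = 0)), "zero counts")
})

test_that("the aberrant and low-depth runs show their library signatures", {
  study <- default_study()
  refs <- study$truth$reference_runs
  r <- suppressWarnings(
    reference_similarity(study$counts, study$metadata, refs, study$lineage))
  clean <- setdiff(unique(study$metadata$run), study$truth$aberrant_run)
  fl <- flag_outlier_runs(r, pool_runs = clean)
  f2 <- fl %>% dplyr::filter(run == study$truth$aberrant_run)
  # PCR-stage bias: flags in PCR/Seq and Ext/PCR/Seq, not in Seq
  expect_true(all(f2$flag[f2$library != "Seq"]))
  expect_false(any(f2$flag[f2$library == "Seq"]))
  # the low-depth run is depressed under Bray-Curtis in every library ...
  med_by_run <- r$summaries %>%
    dplyr::group_by(run) %>% dplyr::summarise(m = median(median))
  others <- med_by_run$m[!med_by_run$run %in% c("Run5", study$truth$aberrant_run)]
  run5 <- r$summaries %>% dplyr::filter(run == "Run5")
  expect_true(all(run5$median < min(others)))
  # ... but not flagged under Morisita
  rm_ <- suppressWarnings(
    reference_similarity(study$counts, study$metadata, refs, study$lineage,
                         metric = "morisita"))
  flm <- flag_outlier_runs(rm_, pool_runs = clean)
  expect_false(any(flm$flag[flm$run == "Run5"]))
  # while Morisita still points at the aberrant run (in at least one of the
  # two autonomous libraries) and never at its Seq library
  fm2 <- flm %>% dplyr::filter(run == study$truth$aberrant_run)
  expect_true(any(fm2$flag[fm2$library != "Seq"]))
  expect_false(any(fm2$flag[fm2$library == "Seq"]))
})

test_that("every mock sample of the default study passes its evaluation", {
  study <- default_study()
  ev <- evaluate_mocks(study$counts, study$metadata, study$lineage)
  expect_equal(nrow(ev), sum(study$metadata$sample_type == "mock"))
  expect_true(all(ev$pass))
  expect_true(all(ev$similarity > 0.9))
  expect_true(all(ev$contaminant_fraction < 0.005))
})
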