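test_that("RLE size factors match the median-of-ratios hand computation", {
  tab <- tibble::tibble(sample_id = c("s1", "s2"), a = c(2L, 1L), b = c(4L, 2L))
  sf <- rle_size_factors(tab)
  expect_equal(sf$size_factor, c(sqrt(2), 1 / sqrt(2)))
  # identical samples: all factors 1
  same <- tibble::tibble(sample_id = c("x", "y", "z"), a = 3L, b = 9L)
  expect_equal(rle_size_factors(same)$size_factor, rep(1, 3))
  # invariant to permuting taxa
  tab2 <- random_table(4, 7, lambda = 30)
  perm <- tab2[c(1, sample(2:8))]
  perm <- perm[c("sample_id", sample(setdiff(names(perm), "sample_id")))]
  expect_equal(rle_size_factors(tab2), rle_size_factors(perm))
  # no all-positive taxon
  disjoint <- tibble::tibble(sample_id = c("s1", "s2"),
                             a = c(3L, 0L), b = c(0L, 5L))
  expect_error(rle_size_factors(disjoint), "pseudocount")
})

test_that("RLE size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  tab <- random_table(6, 25, lambda = 40)
  mine <- rle_size_factors(tab)$size_factor
  ref <- DESeq2::estimateSizeFactorsForMatrix(t(as.matrix(tab[-1])))
  # both are defined up to a common scale; compare after geometric-mean scaling
  ref <- ref / exp(mean(log(ref)))
  expect_equal(mine, unname(ref), tolerance = 1e-10)
})

make_fc_meta <- function(runs, n_rep = 3) {
  tidyr::expand_grid(run = runs, library = "Seq", site = "A",
                     plot = "1", replicate = as.character(seq_len(n_rep))) %>%
    dplyr::mutate(sample_id = paste(run, replicate, sep = "_"),
                  sample_type = "soil")
}

test_that("log2fc against the reference baseline has the right limits", {
  meta <- make_fc_meta(c("ref", "same", "doubled"))
  base <- c(t1 = 100L, t2 = 300L, t3 = 600L)
  counts <- meta %>%
    dplyr::transmute(sample_id,
                     t1 = base["t1"] * ifelse(run == "doubled", 2L, 1L),
                     t2 = base["t2"], t3 = base["t3"])
  fc <- log2fc_vs_reference(counts, meta, reference_runs = "ref",
                            pseudocount = 1e-9)
  same <- fc %>% dplyr::filter(run == "same")
  expect_equal(same$log2fc, rep(0, 3), tolerance = 1e-6)
  doubled <- fc %>% dplyr::filter(run == "doubled")
  # doubling t1's counts doubles its relative share only approximately (CPM
  # renormalises); the exact expectation follows from composition arithmetic
  tot_d <- 2 * 100 + 300 + 600
  expect_equal(doubled$log2fc[doubled$taxon == "t1"],
               log2((200 / tot_d) / (100 / 1000)), tolerance = 1e-6)
  expect_error(log2fc_vs_reference(counts, meta, reference_runs = "nope"),
               "reference_runs")
})

test_that("log2fc ranges are max minus min with monotone growth", {
  fc <- tibble::tibble(run = c("a", "b", "c"), library = "Seq",
                       taxon = "t", log2fc = c(1, -2, 0.5))
  expect_equal(log2fc_range(fc)$range, 3)
  const <- fc %>% dplyr::mutate(log2fc = 0.7)
  expect_equal(log2fc_range(const)$range, 0)
  # adding a run can only increase a taxon's range
  more <- dplyr::bind_rows(fc, tibble::tibble(run = "d", library = "Seq",
                                              taxon = "t", log2fc = 5))
  expect_gte(log2fc_range(more)$range, log2fc_range(fc)$range)
  expect_error(log2fc_range(fc[1, ]), "2 runs")
})

test_that("site contrasts are antisymmetric and detect planted effects", {
  set.seed(5)
  meta <- tidyr::expand_grid(site = c("A", "B"), replicate = as.character(1:6)) %>%
    dplyr::mutate(sample_id = paste0(site, replicate), run = "R1",
                  library = "Seq", plot = "1", sample_type = "soil")
  mu <- 500
  counts <- meta %>%
    dplyr::rowwise() %>%
    dplyr::mutate(t1 = rpois(1, ifelse(site == "B", 4 * mu, mu)),  # log2fc 2
                  t2 = rpois(1, mu), t3 = rpois(1, mu),
                  t4 = rpois(1, mu)) %>%
    dplyr::ungroup() %>%
    dplyr::select(sample_id, t1, t2, t3, t4)
  fc <- log2fc_site_contrast(counts, meta, n_perm = 499, seed = 2)
  hit <- fc %>% dplyr::filter(taxon == "t1")
  expect_gt(hit$log2fc, 1)            # positive sign, near 2 up to composition
  expect_lt(hit$p_adj, 0.05)
  # swapping site labels negates every log2fc
  meta_sw <- meta %>% dplyr::mutate(site = ifelse(site == "A", "B", "A"))
  fc_sw <- log2fc_site_contrast(counts, meta_sw, n_perm = 99, seed = 2)
  expect_equal(fc_sw$log2fc, -fc$log2fc)
  # a context missing a site is skipped with a warning
  meta_bad <- dplyr::bind_rows(
    meta, meta %>% dplyr::slice(1:3) %>%
      dplyr::mutate(run = "R2", sample_id = paste0("x", 1:3)))
  counts_bad <- dplyr::bind_rows(
    counts, counts %>% dplyr::slice(1:3) %>%
      dplyr::mutate(sample_id = paste0("x", 1:3)))
  expect_warning(log2fc_site_contrast(counts_bad, meta_bad, n_perm = 49,
                                      seed = 1), "skipped")
})

test_that("repeated-measures ANOVA handles identical and ordered ranges", {
  libs <- lib_levels()
  ranges0 <- tidyr::expand_grid(taxon = paste0("t", 1:12), library = libs) %>%
    dplyr::mutate(range = 2)
  rma0 <- rm_anova_variability(ranges0)
  expect_equal(rma0$anova$statistic, 0)
  expect_equal(rma0$anova$p.value, 1)
  expect_equal(rma0$pairwise$p.value, rep(1, 3))
  # p-values are probabilities; BH never decreases them
  set.seed(3)
  ranges <- tidyr::expand_grid(taxon = paste0("t", 1:30), library = libs) %>%
    dplyr::mutate(range = abs(rnorm(dplyr::n(), 2, 0.5)))
  rma <- rm_anova_variability(ranges)
  expect_true(rma$anova$p.value >= 0 && rma$anova$p.value <= 1)
  expect_true(all(rma$pairwise$p_adj >= rma$pairwise$p.value))
  expect_true(all(rma$means$ci_low <= rma$means$mean &
                    rma$means$mean <= rma$means$ci_high))
  # taxa with missing levels are dropped and counted
  rma_dropped <- rm_anova_variability(ranges[-1, ])
  expect_equal(rma_dropped$n_dropped, 1)
  expect_equal(rma_dropped$n_subjects, 29)
  # a strong planted ordering is detected with the right direction
  planted <- tidyr::expand_grid(taxon = paste0("t", 1:30), library = libs) %>%
    dplyr::mutate(range = abs(rnorm(
      dplyr::n(), match(library, libs), 0.2)))
  rmap <- rm_anova_variability(planted)
  expect_lt(rmap$anova$p.value, 1e-6)
  m <- stats::setNames(rmap$means$mean, rmap$means$library)
  expect_true(m[["Seq"]] < m[["PCR/Seq"]] && m[["PCR/Seq"]] < m[["Ext/PCR/Seq"]])
  # tidy/glance accessors
  expect_s3_class(generics::tidy(rmap), "tbl_df")
  expect_equal(nrow(generics::glance(rmap)), 1)
})

test_that("log2fc is invariant to a global CPM rescaling", {
  meta <- make_fc_meta(c("ref", "other"))
  counts <- meta %>%
    dplyr::transmute(sample_id, t1 = 10L + dplyr::row_number(),
                     t2 = 50L, t3 = 100L)
  fc1 <- log2fc_vs_reference(counts, meta, "ref")
  scaled <- counts %>% dplyr::mutate(dplyr::across(-sample_id, ~ .x * 13L))
  fc2 <- log2fc_vs_reference(scaled, meta, "ref")
  expect_equal(fc1$log2fc, fc2$log2fc, tolerance = 1e-12)
})
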