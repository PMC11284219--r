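test_that("Hellinger transform matches hand arithmetic and is depth-invariant", {
  h <- hellinger_transform(tibble::tibble(sample_id = "s", a = 1L, b = 1L, c = 2L))
  expect_equal(unlist(h[1, -1]), c(a = 0.5, b = 0.5, c = sqrt(0.5)))
  expect_equal(sum(unlist(h[1, -1])^2), 1)
  single <- hellinger_transform(tibble::tibble(sample_id = "s", a = 7L))
  expect_equal(single$a, 1)
  tab <- random_table(4, 6)
  scaled <- tab %>% dplyr::mutate(dplyr::across(-sample_id, ~ .x * 10L))
  expect_equal(hellinger_transform(tab), hellinger_transform(scaled))
  expect_warning(hellinger_transform(tibble::tibble(sample_id = "z", a = 0L)),
                 "zero-sum")
})

test_that("Bray-Curtis matches the written formula", {
  d <- bray_curtis(tibble::tibble(sample_id = c("x", "y"),
                                  a = c(1, 0), b = c(0, 1)))
  expect_equal(as.numeric(d), 1)
  d2 <- bray_curtis(tibble::tibble(sample_id = c("x", "y"),
                                   a = c(2, 2), b = c(3, 3)))
  expect_equal(as.numeric(d2), 0)
  d3 <- bray_curtis(tibble::tibble(sample_id = c("x", "y"),
                                   a = c(2, 1), b = c(2, 3)))
  expect_equal(as.numeric(d3), 0.25)
  expect_warning(
    dz <- bray_curtis(tibble::tibble(sample_id = c("x", "y"),
                                     a = c(0, 0), b = c(0, 0))),
    "all-zero")
  expect_equal(as.numeric(dz), 0)
})

test_that("Morisita follows the classical formula, clamped with raw side channel", {
  same <- morisita(tibble::tibble(sample_id = c("x", "y"),
                                  a = c(10L, 10L), b = c(0L, 0L)))
  expect_equal(as.numeric(same), 0)
  disjoint <- morisita(tibble::tibble(sample_id = c("x", "y"),
                                      a = c(10L, 0L), b = c(0L, 10L)))
  expect_equal(as.numeric(disjoint), 1)
  # C > 1 for small counts: clamped, raw retained
  d <- morisita(tibble::tibble(sample_id = c("x", "y"),
                               a = c(5L, 5L), b = c(1L, 1L)))
  expect_equal(as.numeric(d), 0)
  expect_lt(as.numeric(attr(d, "raw")), 0)
  expect_error(morisita(tibble::tibble(sample_id = c("x", "y"),
                                       a = c(0.5, 1), b = c(1, 1))),
               "integer")
  expect_error(morisita(tibble::tibble(sample_id = c("x", "y"),
                                       a = c(1L, 1L), b = c(0L, 0L))),
               ">= 2")
  # Morisita-Horn accepts relative abundances
  mh <- morisita(tibble::tibble(sample_id = c("x", "y"),
                                a = c(0.5, 0.5), b = c(0.5, 0.5)),
                 variant = "horn")
  expect_equal(as.numeric(mh), 0)
})

test_that("Morisita agrees with an independent implementation", {
  set.seed(12)
  for (i in 1:10) {
    tab <- random_table(4, 6)
    # vegan floors small-count artefacts (C > 1) at distance 0, as does the
    # default clamp
    mine <- as.matrix(morisita(tab))
    ref <- as.matrix(vegan::vegdist(as.matrix(tab[-1]), method = "morisita"))
    expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
  }
})

test_that("distance/similarity conversion is an involution", {
  d <- bray_curtis(random_table(4, 5))
  s <- distance_to_similarity(d)
  expect_equal(as.numeric(s), 1 - as.numeric(d))
  expect_equal(distance_to_similarity(s), d)
  expect_equal(distance_to_similarity(0), 1)
  expect_equal(distance_to_similarity(1), 0)
})

test_that("PCoA recovers Euclidean configurations and orders eigenvalues", {
  # three equidistant points: two equal positive eigenvalues
  m <- matrix(1, 3, 3) - diag(3)
  rownames(m) <- colnames(m) <- paste0("s", 1:3)
  ord <- pcoa(stats::as.dist(m))
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-10]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  # Euclidean round trip: recovered inter-point distances match the input
  set.seed(4)
  pts <- matrix(rnorm(20), 10, 2)
  rownames(pts) <- paste0("p", 1:10)
  d <- stats::dist(pts)
  ord2 <- pcoa(d)
  rec <- as.matrix(ord2$points[, c("Axis1", "Axis2")])
  expect_equal(as.numeric(stats::dist(rec)), as.numeric(d), tolerance = 1e-8)
  expect_lte(sum(ord2$explained), 1 + 1e-12)
  expect_true(all(diff(ord2$explained) <= 1e-12))
  expect_error(pcoa(stats::dist(pts[1:2, ])), ">= 3")
})

test_that("perMANOVA separates signal, stays flat under exchangeability", {
  # all between-sample distances equal: no group structure, p near 1
  m <- matrix(1, 8, 8) - diag(8)
  rownames(m) <- colnames(m) <- paste0("s", 1:8)
  flat <- permanova(stats::as.dist(m), rep(c("a", "b"), 4), n_perm = 199,
                    seed = 1)
  expect_gt(flat$p.value, 0.9)
  # two well-separated clusters: p at the permutation floor (up to the rare
  # permutations that reproduce the same partition by label symmetry)
  set.seed(2)
  tab <- rbind(matrix(rpois(8 * 10, 5), 8, 10),
               matrix(rpois(8 * 10, 5) + 60, 8, 10))
  rownames(tab) <- paste0("s", 1:16)
  d <- bray_curtis(tibble::as_tibble(cbind(tibble::tibble(sample_id = rownames(tab)),
                                           tibble::as_tibble(tab, .name_repair = "minimal"))))
  sep <- permanova(d, rep(c("a", "b"), each = 8), n_perm = 999, seed = 3)
  expect_lte(sep$p.value, 3 / 1000)
  # invariance to relabeling groups
  g <- rep(c("a", "b"), each = 8)
  relab <- ifelse(g == "a", "group2", "group1")
  expect_equal(permanova(d, g, n_perm = 199, seed = 7)$p.value,
               permanova(d, relab, n_perm = 199, seed = 7)$p.value)
  expect_equal(permanova(d, g, n_perm = 199, seed = 7)$statistic,
               permanova(d, relab, n_perm = 199, seed = 7)$statistic)
  expect_error(permanova(d, c("a", rep("b", 15)), n_perm = 99, seed = 1),
               "singleton")
})

test_that("perMANOVA pseudo-F matches a hand-rolled permutation test", {
  # independent oracle: direct within/between decomposition of squared
  # distances plus explicit label permutations
  set.seed(9)
  tab <- random_table(8, 6)
  d <- bray_curtis(tab)
  g <- rep(c("a", "b"), each = 4)
  dm <- as.matrix(d)^2
  n <- 8
  ss_tot <- sum(dm[upper.tri(dm)]) / n
  ss_win <- sum(vapply(split(seq_len(n), g), function(idx) {
    sub <- dm[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  f_oracle <- ((ss_tot - ss_win) / 1) / (ss_win / (n - 2))
  fit <- permanova(d, g, n_perm = 199, seed = 5)
  expect_equal(fit$statistic, f_oracle, tolerance = 1e-10)
})

test_that("variance partitioning attributes distance structure to factors", {
  expect_warning(
    vp0 <- variance_partition(bray_curtis(random_table(6, 8)),
                              data.frame(only = rep("x", 6),
                                         other = rep(c("u", "v"), 3))),
    "aliased")
  expect_equal(vp0$R2_adj[vp0$factor == "only"], 0)
  # distances generated purely by site shifts: site R2 >> run R2
  set.seed(13)
  site <- rep(c("A", "B"), each = 8)
  run <- rep(paste0("r", 1:4), times = 4)
  m <- matrix(rpois(16 * 12, 20), 16, 12) +
    40 * outer(site == "B", rep(c(1, 0), 6))
  rownames(m) <- paste0("s", 1:16)
  d <- bray_curtis(tibble::as_tibble(cbind(tibble::tibble(sample_id = rownames(m)),
                                           tibble::as_tibble(m, .name_repair = "minimal"))))
  vp <- variance_partition(d, data.frame(site = site, run = run))
  expect_gt(vp$R2_adj[vp$factor == "site"], 5 * max(0.01, vp$R2_adj[vp$factor == "run"]))
  expect_true(all(vp$R2_adj <= 1))
})
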