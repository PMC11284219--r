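# Alpha diversity and saturation diagnostics: rarefaction, observed richness,
# richness ANOVA with partial eta^2, Michaelis-Menten saturation fits, and
# Lineweaver-Burk per-run deviation tests.
#
# Observed richness saturates with sequencing effort; modelling richness S
# against the original per-sample read count R as a rectangular hyperbola
# S = Smax * R / (K + R) separates community richness (Smax) from sampling
# effort (K), and the linearised Lineweaver-Burk form 1/S = 1/Smax +
# (K/Smax) * (1/R) turns per-run deviations into testable regression
# contrasts: an intercept shift means a different asymptotic richness, a slope
# shift a different saturation rate.

#' Rarefy one sample's counts to a fixed depth
#'
#' Multivariate-hypergeometric subsampling without replacement (a single seeded
#' draw). Rarefying to the full sample depth is the identity.
#'
#' @param counts Non-negative integer vector (one sample).
#' @param depth Target depth; must not exceed `sum(counts)`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Integer vector summing to `depth`, elementwise `<= counts`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  total <- sum(counts)
  if (depth > total) {
    abort(sprintf("cannot rarefy %d reads to depth %d", total, as.integer(depth)))
  }
  if (depth == total) return(stats::setNames(as.integer(counts), names(counts)))
  draw <- function() {
    pool <- rep.int(seq_along(counts), counts)
    taken <- pool[sample.int(total, depth)]
    tabulate(taken, nbins = length(counts))
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  stats::setNames(as.integer(out), names(counts))
}

#' Rarefy every sample of a count table
#'
#' Samples with fewer reads than `depth` are excluded with a warning (their ids
#' are kept in the `excluded` attribute, never silently dropped).
#'
#' @param table Count table.
#' @param depth Target depth.
#' @param seed Integer seed; each sample gets its own derived substream so the
#'   result does not depend on sample order.
#' @return Rarefied count table with attribute `excluded`.
#' @export
rarefy_table <- function(table, depth, seed = 1L) {
  m <- ct_matrix(table)
  tot <- rowSums(m)
  excluded <- rownames(m)[tot < depth]
  if (length(excluded)) {
    warn(paste0(length(excluded), " sample(s) below rarefaction depth ",
                depth, " excluded: ", paste(excluded, collapse = ", ")))
  }
  keep <- which(tot >= depth)
  out <- matrix(0L, nrow = length(keep), ncol = ncol(m),
                dimnames = list(rownames(m)[keep], colnames(m)))
  for (j in seq_along(keep)) {
    i <- keep[j]
    out[j, ] <- rarefy(m[i, ], depth, seed = mix_seed(seed, i))
  }
  res <- ct_tibble(out)
  attr(res, "excluded") <- excluded
  res
}

#' Observed richness
#'
#' Number of taxa with count > 0. For a table, one value per sample.
#'
#' @param x Count table (tibble) or a single sample's numeric vector.
#' @return Tibble `sample_id`, `richness` (or an integer for a vector).
#' @export
observed_richness <- function(x) {
  if (is.data.frame(x)) {
    m <- ct_matrix(x)
    return(tibble(sample_id = rownames(m),
                  richness = as.integer(rowSums(m > 0))))
  }
  as.integer(sum(x > 0))
}

#' Rarefied observed richness
#'
#' Convenience wrapper: rarefies to `depth` and computes observed richness,
#' optionally averaging richness over `n` independent rarefaction draws.
#'
#' @inheritParams rarefy_table
#' @param n Number of rarefaction draws to average richness over (default 1, a
#'   single draw).
#' @return Tibble `sample_id`, `richness` with attribute `excluded`.
#' @export
rarefied_richness <- function(table, depth, seed = 1L, n = 1) {
  m <- ct_matrix(table)
  excluded <- rownames(m)[rowSums(m) < depth]
  if (length(excluded)) {
    warn(paste0(length(excluded), " sample(s) below rarefaction depth ",
                depth, " excluded: ", paste(excluded, collapse = ", ")))
  }
  draws <- lapply(seq_len(n), function(k) {
    r <- suppressWarnings(
      rarefy_table(table, depth, seed = mix_seed(seed, 1000L * k)))
    observed_richness(r)
  })
  out <- dplyr::bind_rows(draws) %>%
    group_by(.data$sample_id) %>%
    summarise(richness = mean(.data$richness), .groups = "drop")
  attr(out, "excluded") <- excluded
  out
}

#' Richness ANOVA with partial effect sizes
#'
#' Fits `richness ~ site + library + library:run` (sequence run nested in
#' library) by sequential ANOVA and reports, per effect, the F statistic, the
#' p-value and partial eta^2 = SS_effect / (SS_effect + SS_residual).
#'
#' @param richness Tibble `sample_id`, `richness` (e.g. from
#'   [rarefied_richness()]).
#' @param metadata Sample metadata; only soil samples are used.
#' @return Tibble `effect`, `df`, `sumsq`, `statistic` (F), `p.value`,
#'   `partial_eta2`.
#' @export
richness_anova <- function(richness, metadata) {
  d <- richness %>%
    inner_join(metadata, by = "sample_id") %>%
    filter(.data$sample_type == "soil")
  for (f in c("site", "library", "run")) {
    if (length(unique(d[[f]])) < 2) {
      abort(paste0("factor '", f, "' has a single level; cannot test it"))
    }
  }
  fit <- stats::aov(richness ~ site + library + library:run, data = d)
  tab <- summary(fit)[[1]]
  eff <- trimws(rownames(tab))
  resid_ss <- tab[eff == "Residuals", "Sum Sq"]
  keep <- eff != "Residuals"
  tibble(effect = eff[keep],
         df = tab[keep, "Df"],
         sumsq = tab[keep, "Sum Sq"],
         statistic = tab[keep, "F value"],
         p.value = tab[keep, "Pr(>F)"],
         partial_eta2 = ifelse(tab[keep, "Sum Sq"] <= 1e-12, 0,
                               tab[keep, "Sum Sq"] /
                                 (tab[keep, "Sum Sq"] + resid_ss)))
}

# Lineweaver-Burk initial values for the MM fit; falls back to crude values
# when the linearisation is degenerate.
lb_start <- function(reads, richness) {
  ok <- richness > 0 & reads > 0
  if (sum(ok) >= 2 && stats::sd(richness[ok]) > 0) {
    co <- stats::coef(stats::lm(I(1 / richness[ok]) ~ I(1 / reads[ok])))
    smax <- 1 / co[1]
    k <- co[2] * smax
    if (is.finite(smax) && is.finite(k) && smax > 0) {
      return(c(Smax = unname(smax), K = unname(max(k, 1e-6))))
    }
  }
  c(Smax = max(richness) * 1.2, K = stats::median(reads))
}

#' Michaelis-Menten saturation fit of richness vs sequencing effort
#'
#' Least-squares fit of `S = Smax * R / (K + R)` per group (e.g. per site),
#' initialised from the Lineweaver-Burk linearisation, with asymptotic standard
#' errors. Constant-richness groups are returned as the degenerate saturated
#' limit (`Smax = S`, `K = 0`) and flagged; negative parameter estimates are
#' flagged.
#'
#' @param data Tibble with columns `reads` and `richness` (and the grouping
#'   column if `group` is given).
#' @param group Optional name of a grouping column; `NULL` fits all points as
#'   one group.
#' @return A tibble of class `mm_fit`: `group`, `Smax`, `Smax_se`, `K`, `K_se`,
#'   `df_residual`, `flagged`.
#' @export
fit_michaelis_menten <- function(data, group = NULL) {
  data <- as_tibble(data)
  if (any(data$reads <= 0)) abort("reads must be positive")
  groups <- if (is.null(group)) list(all = data) else split(data, data[[group]])
  rows <- purrr::imap(groups, function(d, g) {
    if (nrow(d) < 3) abort(paste0("group '", g, "' has fewer than 3 points"))
    if (stats::sd(d$richness) == 0) {
      return(tibble(group = g, Smax = d$richness[1], Smax_se = NA_real_,
                    K = 0, K_se = NA_real_, df_residual = nrow(d) - 2,
                    flagged = TRUE))
    }
    start <- lb_start(d$reads, d$richness)
    # Bounded Gauss-Newton ("port") tolerates the K ~ 0 boundary of nearly
    # saturated data; fall back on cruder starts before giving up.
    starts <- list(start,
                   c(Smax = max(d$richness) * 1.2, K = stats::median(d$reads)),
                   c(Smax = max(d$richness) * 2, K = max(d$reads)))
    fit <- NULL
    last_err <- NULL
    for (s0 in starts) {
      fit <- tryCatch(
        stats::nls(richness ~ Smax * reads / (K + reads), data = d,
                   start = as.list(s0), algorithm = "port",
                   lower = c(Smax = 1e-8, K = 0),
                   control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
        error = function(e) {
          last_err <<- conditionMessage(e)
          NULL
        }
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      abort(sprintf(
        "Michaelis-Menten fit failed for group '%s' (start Smax=%.4g, K=%.4g): %s",
        g, start["Smax"], start["K"], last_err))
    }
    s <- summary(fit)$coefficients
    tibble(group = g,
           Smax = s["Smax", "Estimate"], Smax_se = s["Smax", "Std. Error"],
           K = s["K", "Estimate"], K_se = s["K", "Std. Error"],
           df_residual = stats::df.residual(fit),
           flagged = s["Smax", "Estimate"] <= 0 || s["K", "Estimate"] <= 1e-6)
  })
  structure(dplyr::bind_rows(rows), class = c("mm_fit", class(tibble())))
}

# Two-sided p for a regression contrast, mapping the exact-zero contrast on
# noise-free data (0/0 t statistics) to p = 1.
contrast_p <- function(estimate, se, df) {
  if (!is.finite(se) || se == 0) {
    return(if (abs(estimate) < 1e-10) 1 else 0)
  }
  2 * stats::pt(abs(estimate / se), df, lower.tail = FALSE)
}

#' Lineweaver-Burk per-run fits and deviation tests
#'
#' Ordinary least squares on the linearised model `1/S = b0 + b1 * (1/R)`,
#' fitted per run, plus a deviation test of each run against the pooled fit of
#' all other runs: the model `1/S ~ 1/R * I(run == r)` is fitted and the
#' indicator main effect (intercept shift) and interaction (slope shift) are
#' tested by two-sided t-tests. Raw p-values are reported alongside
#' Benjamini-Hochberg adjusted ones (across runs, per coefficient).
#'
#' @param data Tibble with columns `reads`, `richness` and the run column.
#' @param run Name of the run column (default `"run"`).
#' @return A tibble of class `lb_fit`: per run, `intercept`, `intercept_se`,
#'   `slope`, `slope_se`, `delta_intercept`, `p_intercept`, `delta_slope`,
#'   `p_slope`, `p_intercept_adj`, `p_slope_adj`, `n`.
#' @export
fit_lineweaver_burk <- function(data, run = "run") {
  d <- as_tibble(data)
  zero <- d$richness <= 0 | d$reads <= 0
  if (any(zero)) {
    warn(paste0(sum(zero), " point(s) with zero richness or reads excluded"))
    d <- d[!zero, ]
  }
  d$._run <- as.character(d[[run]])
  counts <- table(d$._run)
  if (any(counts < 3)) {
    abort(paste0("runs with fewer than 3 points: ",
                 paste(names(counts)[counts < 3], collapse = ", ")))
  }
  d$x <- 1 / d$reads
  d$y <- 1 / d$richness
  runs <- sort(unique(d$._run))
  rows <- purrr::map(runs, function(r) {
    own <- stats::lm(y ~ x, data = d[d$._run == r, ])
    os <- summary(own)$coefficients
    out <- tibble(run = r,
                  intercept = os[1, 1], intercept_se = os[1, 2],
                  slope = os[2, 1], slope_se = os[2, 2],
                  delta_intercept = NA_real_, p_intercept = NA_real_,
                  delta_slope = NA_real_, p_slope = NA_real_,
                  n = sum(d$._run == r))
    if (length(runs) < 2) return(out)   # no "pooled others" to deviate from
    ind <- factor(ifelse(d$._run == r, "this", "others"), c("others", "this"))
    dev <- stats::lm(y ~ x * ind, data = d)
    sm <- summary(dev)
    cs <- sm$coefficients
    dfree <- stats::df.residual(dev)
    di <- if ("indthis" %in% rownames(cs)) cs["indthis", ] else c(0, 0, NA, NA)
    ds <- if ("x:indthis" %in% rownames(cs)) cs["x:indthis", ] else c(0, 0, NA, NA)
    # a numerically exact fit (noise-free data) has sigma at rounding level;
    # its contrasts are 0/0 and read as "no deviation"
    scale <- max(stats::sd(d$y), .Machine$double.eps)
    exact <- !is.finite(sm$sigma) || sm$sigma < 1e-10 * scale
    pval <- function(est, se) {
      if (exact) return(if (abs(est) < 1e-8 * scale) 1 else 0)
      contrast_p(est, se, dfree)
    }
    out$delta_intercept <- unname(di[1])
    out$p_intercept <- pval(di[1], di[2])
    out$delta_slope <- unname(ds[1])
    out$p_slope <- pval(ds[1], ds[2])
    out
  })
  out <- dplyr::bind_rows(rows) %>%
    mutate(p_intercept_adj = bh_adjust(.data$p_intercept),
           p_slope_adj = bh_adjust(.data$p_slope))
  structure(out, class = c("lb_fit", class(tibble())))
}
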