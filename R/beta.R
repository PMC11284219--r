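# Beta diversity: Hellinger transform, Bray-Curtis and Morisita distances,
# PCoA, perMANOVA and db-RDA variance partitioning.
#
# Bray-Curtis on raw counts is sensitive to library size; the classical
# Morisita index corrects for sampling via lambda = sum x(x-1) / (N(N-1)) and
# is largely depth-insensitive, which is why both are offered side by side for
# cross-run comparisons.

#' Hellinger transform
#'
#' Square root of per-sample relative abundances: `sqrt(count / row_sum)`.
#' Squared row values sum to 1; the transform is invariant to sequencing depth.
#'
#' @param table Count or abundance table.
#' @return Abundance table; all-zero rows stay zero with a warning.
#' @export
hellinger_transform <- function(table) {
  m <- ct_matrix(table)
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    warn(paste0("zero-sum samples left as zeros: ",
                paste(rownames(m)[zero], collapse = ", ")))
    rs[zero] <- 1
  }
  ct_tibble(sqrt(m / rs))
}

# Wrap a dist object with its metric label.
as_runqc_dist <- function(d, metric) {
  attr(d, "metric") <- metric
  d
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum |x - y| / sum (x + y)` on counts or abundances. The distance
#' between two all-zero samples is defined as 0 (with a warning).
#'
#' @param table Count or abundance table (samples x taxa).
#' @return A `stats::dist` object with a `metric` attribute.
#' @export
bray_curtis <- function(table) {
  m <- ct_matrix(table)
  if (any(m < 0)) abort("Bray-Curtis requires non-negative values")
  d <- vegan::vegdist(m, method = "bray")
  if (anyNA(d)) {
    warn("distance between all-zero samples defined as 0")
    d[is.na(d)] <- 0
  }
  as_runqc_dist(d, "bray_curtis")
}

# lambda of the classical Morisita index.
morisita_lambda <- function(x) {
  n <- sum(x)
  sum(x * (x - 1)) / (n * (n - 1))
}

#' Morisita (and Morisita-Horn) distance matrix
#'
#' Classical Morisita similarity
#' `C = 2 sum(x_i y_i) / ((lambda_x + lambda_y) N_x N_y)` with
#' `lambda = sum x(x-1) / (N(N-1))`; distance is `1 - C`. The classical index
#' requires integer counts (sample totals >= 2); the Morisita-Horn variant
#' (`variant = "horn"`, with `lambda = sum x^2 / N^2`) accepts relative
#' abundances. `C` can exceed 1 for small counts, so the distance is clamped to
#' `[0, 1]` by default with the raw values kept in the `raw` attribute.
#'
#' @param table Count table (integer counts for the classical index).
#' @param variant `"morisita"` (classical, default) or `"horn"`.
#' @param clamp Clamp distances to `[0, 1]` (default `TRUE`).
#' @return A `stats::dist` object with `metric` and (if clamped values differ)
#'   `raw` attributes.
#' @export
morisita <- function(table, variant = c("morisita", "horn"), clamp = TRUE) {
  variant <- match.arg(variant)
  m <- ct_matrix(table)
  if (variant == "morisita") {
    if (any(abs(m - round(m)) > 1e-8)) {
      abort(paste0("classical Morisita requires integer counts; ",
                   "use variant = \"horn\" for relative abundances"))
    }
    tot <- rowSums(m)
    if (any(tot < 2)) {
      abort(paste0("sample totals must be >= 2 for the classical Morisita ",
                   "index: ", paste(rownames(m)[tot < 2], collapse = ", ")))
    }
    lam <- apply(m, 1, morisita_lambda)
  } else {
    tot <- rowSums(m)
    if (any(tot <= 0)) abort("samples must have positive totals")
    lam <- rowSums(m^2) / tot^2
  }
  cross <- m %*% t(m)
  n <- nrow(m)
  C <- 2 * cross / (outer(lam, lam, `+`) * outer(tot, tot))
  raw <- 1 - C
  diag(raw) <- 0
  d_raw <- stats::as.dist(raw)
  d <- if (clamp) pmin(pmax(d_raw, 0), 1) else d_raw
  attributes(d) <- attributes(d_raw)
  d <- as_runqc_dist(d, if (variant == "morisita") "morisita" else "morisita_horn")
  if (clamp && any(d_raw != d)) attr(d, "raw") <- d_raw
  d
}

#' Convert distances to similarities (and back)
#'
#' Elementwise `s = 1 - d`; applying it twice is the identity.
#'
#' @param d A `dist` object or numeric matrix/vector.
#' @return Object of the same shape.
#' @export
distance_to_similarity <- function(d) {
  out <- 1 - d
  if (inherits(d, "dist")) {
    attributes(out) <- attributes(d)
    m <- attr(d, "metric")
    if (!is.null(m)) {
      attr(out, "metric") <- if (grepl("_similarity$", m)) {
        sub("_similarity$", "", m)
      } else {
        paste0(m, "_similarity")
      }
    }
  }
  out
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centering and eigendecomposition of the squared-distance matrix.
#' Axes are ordered by eigenvalue; negative eigenvalues are reported but
#' excluded from the explained-variance denominator by default.
#'
#' @param d A distance matrix (`dist`).
#' @param negative_in_denominator Include absolute negative eigenvalues in the
#'   explained-variance denominator.
#' @return A list of class `runqc_pcoa`: `points` (tibble, `sample_id` +
#'   `Axis1`, `Axis2`, ...), `eigenvalues`, `explained` (proportions on
#'   positive axes), `negative_eigenvalues` (count).
#' @export
pcoa <- function(d, negative_in_denominator = FALSE) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3) abort("PCoA needs a distance matrix over >= 3 samples")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  denom <- if (negative_in_denominator) sum(abs(eig)) else sum(eig[pos])
  pts <- fit$points[, seq_len(min(sum(pos), ncol(fit$points))), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(
    points = dplyr::bind_cols(tibble(sample_id = labels(d)),
                              as_tibble(pts, .name_repair = "minimal")),
    eigenvalues = eig,
    explained = eig[pos] / denom,
    negative_eigenvalues = sum(eig < 0)
  ), class = "runqc_pcoa")
}

#' perMANOVA
#'
#' Permutational multivariate ANOVA on a distance matrix: pseudo-F from the
#' within/between decomposition of squared distances, with
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)` under seeded free label
#' permutations (via `vegan::adonis2`).
#'
#' @param d Distance matrix (`dist`).
#' @param grouping Vector of group labels, one per sample (>= 2 groups, each
#'   with >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A list of class `runqc_permanova`: `statistic` (pseudo-F),
#'   `p.value`, `df`, `R2`, `n_perm`.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = 1L) {
  grouping <- as.factor(grouping)
  n <- attr(d, "Size")
  if (length(grouping) != n) abort("grouping length must match the distance matrix")
  sizes <- table(grouping)
  if (length(sizes) < 2) abort("perMANOVA needs >= 2 groups")
  if (any(sizes < 2)) {
    abort(paste0("singleton group(s): ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  dat <- data.frame(g = grouping)
  fit <- withr::with_seed(seed,
    vegan::adonis2(d ~ g, data = dat, permutations = n_perm))
  structure(list(statistic = fit$F[1], p.value = fit$`Pr(>F)`[1],
                 df = c(fit$Df[1], fit$Df[2]), R2 = fit$R2[1],
                 n_perm = n_perm),
            class = "runqc_permanova")
}

#' Variance partitioning by db-RDA adjusted R-squared
#'
#' Marginal (single-factor) distance-based redundancy analysis per factor, with
#' the Ezekiel-adjusted R-squared reported per factor. Perfectly aliased factor
#' pairs trigger a warning since their marginal fractions share variance.
#'
#' @param d Distance matrix (`dist`).
#' @param factors Data frame (or named list) of factor label vectors, one per
#'   sample.
#' @return Tibble `factor`, `R2`, `R2_adj`.
#' @export
variance_partition <- function(d, factors) {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  n <- attr(d, "Size")
  if (nrow(factors) != n) abort("factors must have one row per sample")
  combs <- utils::combn(names(factors), 2, simplify = FALSE)
  for (pr in combs) {
    tab <- table(factors[[pr[1]]], factors[[pr[2]]])
    if (all(rowSums(tab > 0) == 1) || all(colSums(tab > 0) == 1)) {
      warn(paste0("factors '", pr[1], "' and '", pr[2],
                  "' are aliased; their marginal fractions share variance"))
    }
  }
  rows <- purrr::map(names(factors), function(f) {
    dat <- data.frame(g = factor(factors[[f]]))
    if (nlevels(dat$g) < 2) {
      return(tibble(factor = f, R2 = 0, R2_adj = 0))
    }
    fit <- vegan::dbrda(d ~ g, data = dat)
    r2 <- vegan::RsquareAdj(fit)
    tibble(factor = f, R2 = r2$r.squared, R2_adj = r2$adj.r.squared)
  })
  dplyr::bind_rows(rows)
}
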