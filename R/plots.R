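# ggplot2 views of the diagnostic results. Each function returns a ggplot
# object the caller can style further.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_boxplot
#'   geom_hline geom_rect geom_errorbar labs facet_wrap autoplot
NULL

#' Plot QC funnel removal fractions
#'
#' Stage-wise removal fractions per run, with the accepted quality-removal band
#' shaded.
#'
#' @param fractions Output of [funnel_fractions()].
#' @param thresholds A [diagnostic_thresholds()].
#' @return A ggplot.
#' @export
plot_funnel <- function(fractions, thresholds = diagnostic_thresholds()) {
  long <- fractions %>%
    tidyr::pivot_longer(-"run", names_to = "stage", values_to = "removed") %>%
    mutate(stage = factor(.data$stage, c("demux_removed", "quality_removed",
                                         "length_removed")))
  band <- tibble(stage = factor("quality_removed",
                                levels(long$stage)),
                 lo = thresholds$quality_removal_band[1],
                 hi = thresholds$quality_removal_band[2])
  ggplot(long, aes(x = .data$run, y = .data$removed)) +
    geom_rect(data = band, aes(ymin = .data$lo, ymax = .data$hi),
              xmin = -Inf, xmax = Inf, fill = "grey80", alpha = 0.6,
              inherit.aes = FALSE) +
    geom_col(fill = "steelblue") +
    facet_wrap(~stage, scales = "free_y") +
    labs(x = NULL, y = "fraction of reads removed")
}

#' Lineweaver-Burk plot (1/richness vs 1/reads) coloured by run
#'
#' @param data Tibble with `reads`, `richness` and a run column.
#' @param run Name of the run column.
#' @return A ggplot.
#' @export
plot_lineweaver_burk <- function(data, run = "run") {
  d <- as_tibble(data) %>% filter(.data$richness > 0, .data$reads > 0)
  ggplot(d, aes(x = 1 / .data$reads, y = 1 / .data$richness,
                colour = .data[[run]])) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    labs(x = "1 / original reads", y = "1 / observed richness", colour = "run")
}

#' Saturation (Michaelis-Menten) plot of richness vs sequencing effort
#'
#' @param data Tibble with `reads`, `richness` and the grouping column.
#' @param fit An `mm_fit` from [fit_michaelis_menten()].
#' @param group Name of the grouping column used in the fit.
#' @return A ggplot.
#' @export
plot_saturation <- function(data, fit, group = "site") {
  d <- as_tibble(data)
  grid <- tidyr::expand_grid(
    group = fit$group,
    reads = seq(min(d$reads), max(d$reads), length.out = 100)
  ) %>%
    left_join(as_tibble(fit), by = "group") %>%
    mutate(richness = .data$Smax * .data$reads / (.data$K + .data$reads))
  names(grid)[names(grid) == "group"] <- group
  ggplot(d, aes(x = .data$reads, y = .data$richness,
                colour = .data[[group]])) +
    geom_point(alpha = 0.6) +
    geom_line(data = grid) +
    labs(x = "original reads per sample", y = "observed richness")
}

#' Boxplot of similarity diagnostics with the reference pool band
#'
#' @param x A `similarity_summary`.
#' @param pool_runs Optional pool run labels; when given, the pool
#'   median - IQR band is drawn.
#' @param band_multiplier Band width in pool IQRs.
#' @return A ggplot.
#' @export
plot_similarity <- function(x, pool_runs = NULL, band_multiplier = 1) {
  stopifnot(inherits(x, "similarity_summary"))
  p <- ggplot(x$values, aes(x = .data$run, y = .data$similarity)) +
    geom_boxplot(outlier.alpha = 0.5) +
    facet_wrap(~library) +
    labs(x = NULL, y = paste0("similarity (", x$metric, ")"),
         title = paste0(x$type, " similarity"))
  if (!is.null(pool_runs)) {
    b <- boxplot_stats(x$values$similarity[x$values$run %in% pool_runs])
    p <- p +
      geom_hline(yintercept = b$median, colour = "grey40") +
      geom_hline(yintercept = b$median - band_multiplier * b$iqr,
                 colour = "red", linetype = 2)
  }
  p
}

#' Mean log2FC range per library with confidence intervals
#'
#' @param x An `rm_anova_variability`.
#' @return A ggplot.
#' @export
plot_log2fc_range <- function(x) {
  stopifnot(inherits(x, "rm_anova_variability"))
  d <- x$means %>%
    mutate(library = factor(.data$library,
                            intersect(lib_levels(), .data$library)))
  ggplot(d, aes(x = .data$library, y = .data$mean)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.15,
                  colour = "steelblue") +
    labs(x = "library autonomy", y = "mean log2FC range")
}

#' PCoA ordination plot
#'
#' @param object A `runqc_pcoa`.
#' @param metadata Optional metadata joined on `sample_id`; when given, points
#'   are coloured by `colour` and shaped by `shape`.
#' @param colour,shape Metadata column names.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot runqc_pcoa
#' @export
autoplot.runqc_pcoa <- function(object, metadata = NULL, colour = "site",
                                shape = "run", ...) {
  d <- object$points
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i, 100 * object$explained[i])
  if (!is.null(metadata)) d <- d %>% left_join(metadata, by = "sample_id")
  p <- ggplot(d, aes(x = .data$Axis1, y = .data$Axis2))
  p <- if (!is.null(metadata)) {
    p + geom_point(aes(colour = .data[[colour]], shape = .data[[shape]]))
  } else {
    p + geom_point()
  }
  p + labs(x = lab(1), y = lab(2))
}
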