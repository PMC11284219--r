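# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.mm_fit
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(cols = c("Smax", "K"), names_to = "term",
                        values_to = "estimate") %>%
    mutate(std.error = ifelse(.data$term == "Smax", .data$Smax_se, .data$K_se)) %>%
    select("group", "term", "estimate", "std.error", "df_residual", "flagged")
}

#' Tidy saturation and Lineweaver-Burk fits
#'
#' `tidy()` on an `mm_fit` returns one row per (group, parameter); on an
#' `lb_fit` one row per (run, coefficient) with the deviation test against the
#' pooled other runs.
#'
#' @param x An `mm_fit` or `lb_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lb_fit
#' @export
tidy.lb_fit <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(cols = c("intercept", "slope"), names_to = "term",
                        values_to = "estimate") %>%
    mutate(
      std.error = ifelse(.data$term == "intercept",
                         .data$intercept_se, .data$slope_se),
      delta = ifelse(.data$term == "intercept",
                     .data$delta_intercept, .data$delta_slope),
      p.value = ifelse(.data$term == "intercept",
                       .data$p_intercept, .data$p_slope),
      p.adjusted = ifelse(.data$term == "intercept",
                          .data$p_intercept_adj, .data$p_slope_adj)
    ) %>%
    select("run", "term", "estimate", "std.error", "delta", "p.value",
           "p.adjusted", "n")
}

#' Glance at a perMANOVA result
#'
#' @param x A `runqc_permanova`.
#' @param ... Unused.
#' @return One-row tibble with `statistic` (pseudo-F), `p.value`, `R2`, `df`,
#'   `df.residual`, `n.permutations`.
#' @method glance runqc_permanova
#' @export
glance.runqc_permanova <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, R2 = x$R2,
         df = x$df[1], df.residual = x$df[2], n.permutations = x$n_perm)
}

#' @export
print.runqc_permanova <- function(x, ...) {
  cat(sprintf("perMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$df[1], x$df[2], x$R2, x$p.value, x$n_perm))
  invisible(x)
}

#' Tidy a repeated-measures variability ANOVA
#'
#' `tidy()` returns the pairwise library contrasts; `glance()` the omnibus
#' test.
#'
#' @param x An `rm_anova_variability`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rm_anova_variability
#' @export
tidy.rm_anova_variability <- function(x, ...) x$pairwise

#' @rdname tidy.rm_anova_variability
#' @method glance rm_anova_variability
#' @export
glance.rm_anova_variability <- function(x, ...) x$anova
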