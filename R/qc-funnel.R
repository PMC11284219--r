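# Per-run read-accounting diagnostics: stage-wise removal fractions and
# threshold flags.

#' Diagnostic thresholds
#'
#' Default values follow the recommendations distilled from cross-laboratory
#' nanopore soil sequencing: quality filtering should remove between 2% and 5%
#' of demultiplexed reads (inclusive band), negative controls should carry less
#' than 0.4% of a run's reads, mock communities should reach at least 0.860
#' Bray-Curtis similarity to their expected profile, and richness is computed
#' after rarefying to 12,000 reads.
#'
#' @param quality_removal_band Length-2 numeric, inclusive (low, high) band for
#'   the quality-step removal fraction.
#' @param control_read_fraction_max Maximum tolerated control read fraction.
#' @param mock_similarity_min Minimum mock similarity to pass.
#' @param rarefaction_depth Default rarefaction depth (reads).
#' @return A list of class `runqc_thresholds`.
#' @export
diagnostic_thresholds <- function(quality_removal_band = c(0.02, 0.05),
                                  control_read_fraction_max = 0.004,
                                  mock_similarity_min = 0.860,
                                  rarefaction_depth = 12000) {
  if (!(quality_removal_band[1] >= 0 &&
        quality_removal_band[1] < quality_removal_band[2] &&
        quality_removal_band[2] <= 1)) {
    abort("quality_removal_band must satisfy 0 <= low < high <= 1")
  }
  structure(list(quality_removal_band = quality_removal_band,
                 control_read_fraction_max = control_read_fraction_max,
                 mock_similarity_min = mock_similarity_min,
                 rarefaction_depth = rarefaction_depth),
            class = "runqc_thresholds")
}

#' Stage-wise removal fractions of a QC funnel
#'
#' For each run: `demux_removed = 1 - demux/raw`,
#' `quality_removed = 1 - qualfilt/demux`,
#' `length_removed = 1 - lenfilt/qualfilt`.
#'
#' @param funnels Funnel tibble (columns `run`, `raw_reads`, `demux_reads`,
#'   `qualfilt_reads`, `lenfilt_reads`).
#' @return Tibble with `run` and the three removal fractions, each in `[0, 1]`.
#' @export
funnel_fractions <- function(funnels) {
  f <- as_tibble(funnels)
  if (any(f$raw_reads == 0)) {
    abort(paste0("zero raw reads for run(s): ",
                 paste(f$run[f$raw_reads == 0], collapse = ", ")))
  }
  mono <- f$raw_reads >= f$demux_reads & f$demux_reads >= f$qualfilt_reads &
    f$qualfilt_reads >= f$lenfilt_reads & f$lenfilt_reads >= 0
  if (!all(mono)) {
    abort(paste0("funnel counts must be non-increasing; violated for run(s): ",
                 paste(f$run[!mono], collapse = ", ")))
  }
  frac <- function(kept, total) ifelse(total == 0, 0, 1 - kept / total)
  tibble(run = f$run,
         demux_removed = frac(f$demux_reads, f$raw_reads),
         quality_removed = frac(f$qualfilt_reads, f$demux_reads),
         length_removed = frac(f$lenfilt_reads, f$qualfilt_reads))
}

#' Flag runs whose quality-step removal is outside the accepted band
#'
#' The band is inclusive: removal of exactly 2% or 5% is not flagged.
#'
#' @param fractions Output of [funnel_fractions()].
#' @param thresholds A [diagnostic_thresholds()].
#' @return Tibble `run`, `quality_removed`, `band_low`, `band_high`, `flag`.
#' @export
flag_quality_removal <- function(fractions, thresholds = diagnostic_thresholds()) {
  band <- thresholds$quality_removal_band
  fractions %>%
    select("run", "quality_removed") %>%
    mutate(band_low = band[1], band_high = band[2],
           # inclusive band; tolerance absorbs floating-point in the fractions
           flag = .data$quality_removed < band[1] - 1e-9 |
             .data$quality_removed > band[2] + 1e-9)
}

#' Per-run negative-control read fraction
#'
#' The fraction of each run's total reads (soil + mock + controls) carried by
#' its negative-control samples, flagged when it exceeds the threshold. With
#' `per_sample = TRUE` the rule is applied to each control sample's own
#' fraction and a run is flagged if any control exceeds the threshold.
#'
#' @param table Count table.
#' @param metadata Sample metadata; control samples have `sample_type`
#'   `ext_control` or `pcr_control`.
#' @param thresholds A [diagnostic_thresholds()].
#' @param per_sample Apply the rule per control sample instead of summed.
#' @return Tibble `run`, `control_reads`, `total_reads`, `fraction`, `flag`.
#'   Runs without control samples get `NA` fraction with a warning.
#' @export
control_read_fraction <- function(table, metadata,
                                  thresholds = diagnostic_thresholds(),
                                  per_sample = FALSE) {
  sizes <- library_sizes(table) %>%
    inner_join(metadata, by = "sample_id") %>%
    mutate(is_control = .data$sample_type %in% c("ext_control", "pcr_control"))
  out <- sizes %>%
    group_by(.data$run) %>%
    summarise(
      control_reads = sum(.data$library_size[.data$is_control]),
      total_reads = sum(.data$library_size),
      n_controls = sum(.data$is_control),
      max_single = if (any(.data$is_control))
        max(.data$library_size[.data$is_control]) else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(
      fraction = ifelse(.data$n_controls == 0, NA_real_,
                        .data$control_reads / .data$total_reads),
      flag = if (per_sample) {
        !is.na(.data$fraction) &
          .data$max_single / .data$total_reads > thresholds$control_read_fraction_max
      } else {
        !is.na(.data$fraction) &
          .data$fraction > thresholds$control_read_fraction_max
      }
    )
  if (any(out$n_controls == 0)) {
    warn(paste0("no control samples for run(s): ",
                paste(out$run[out$n_controls == 0], collapse = ", "),
                "; control fraction reported as missing"))
  }
  out %>% select("run", "control_reads", "total_reads", "fraction", "flag")
}
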