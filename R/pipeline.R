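# End-to-end orchestration: run every diagnostic stage on a study and render a
# single, deterministic diagnostic report.

#' Pipeline configuration
#'
#' Inputs are either the four artefact paths (`counts`, `metadata`, `lineage`,
#' `funnels`) or a [synthetic_config()] via `simulate`. All seeds derive from
#' `seed`; two runs of the same configuration produce byte-identical reports.
#'
#' @param counts,metadata,lineage,funnels Paths to the study TSVs (ignored when
#'   `simulate` is given).
#' @param simulate Optional [synthetic_config()] to generate the study instead
#'   of reading files.
#' @param reference_runs Primary-lab run labels (default: the synthetic
#'   study's reference runs, else required).
#' @param pool_runs Runs forming the flag-rule reference pool (default: all
#'   runs, a robust self-calibrating band; pass the known-clean runs when they
#'   are established).
#' @param thresholds A [diagnostic_thresholds()].
#' @param metric Similarity metric for the run diagnostics.
#' @param rank Rank for the variability analysis (default `"genus"`).
#' @param n_perm Permutations for perMANOVA and site contrasts.
#' @param pseudocount Pseudocount (CPM units) for log2 fold-changes.
#' @param seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, lineage = NULL,
                            funnels = NULL, simulate = NULL,
                            reference_runs = NULL, pool_runs = NULL,
                            thresholds = diagnostic_thresholds(),
                            metric = c("bc_hellinger", "morisita"),
                            rank = "genus", n_perm = 999, pseudocount = 0.5,
                            seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(simulate)) {
    paths <- list(counts = counts, metadata = metadata, lineage = lineage,
                  funnels = funnels)
    missing <- names(paths)[vapply(paths, is.null, logical(1))]
    if (length(missing)) {
      abort(paste0("missing input path(s): ", paste(missing, collapse = ", ")))
    }
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent)) {
      abort(paste0("input file(s) not found: ", paste(absent, collapse = ", ")))
    }
  }
  structure(list(counts = counts, metadata = metadata, lineage = lineage,
                 funnels = funnels, simulate = simulate,
                 reference_runs = reference_runs, pool_runs = pool_runs,
                 thresholds = thresholds, metric = metric, rank = rank,
                 n_perm = n_perm, pseudocount = pseudocount,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(report, name, deps, expr) {
  failed <- vapply(deps, function(d) {
    !is.null(report[[d]]$status) && report[[d]]$status != "ok"
  }, logical(1))
  if (any(failed)) {
    report[[name]] <- list(status = "skipped",
                           reason = paste0("upstream stage failed: ",
                                           paste(deps[failed], collapse = ", ")))
    return(report)
  }
  report[[name]] <- tryCatch(
    c(list(status = "ok"), expr()),
    error = function(e) list(status = "failed", error = conditionMessage(e))
  )
  report
}

#' Run the full diagnostic pipeline
#'
#' Executes the stages qc (funnel fractions and flags, control read fraction),
#' alpha (rarefied richness, richness ANOVA, Michaelis-Menten per site,
#' Lineweaver-Burk per run), beta (genus-rank Hellinger Bray-Curtis: PCoA,
#' perMANOVA on site, db-RDA variance partitioning), diagnose (within-run and
#' reference-soil similarities, IQR flags, mock evaluation) and variability
#' (log2FC vs the primary-lab baseline, ranges, repeated-measures ANOVA).
#' A failed stage is recorded as failed and its dependents skipped; the report
#' is returned either way.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `runqc_report` with one entry per stage plus a
#'   `provenance` block sufficient to reproduce the run.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()

  report <- run_stage(report, "inputs", character(), function() {
    if (!is.null(config$simulate)) {
      study <- simulate_study(config$simulate)
      list(source = "simulated",
           data = study[c("counts", "metadata", "lineage", "funnels")],
           reference_runs = config$reference_runs %||%
             study$truth$reference_runs)
    } else {
      data <- list(counts = read_count_table(config$counts),
                   metadata = read_metadata(config$metadata),
                   lineage = read_lineage(config$lineage),
                   funnels = read_funnels(config$funnels))
      if (is.null(config$reference_runs)) {
        abort("reference_runs is required for file-based input")
      }
      list(source = "files", data = data,
           reference_runs = config$reference_runs)
    }
  })
  d <- report$inputs$data
  refs <- report$inputs$reference_runs
  pool <- config$pool_runs %||% sort(unique(d$metadata$run))
  thr <- config$thresholds

  report <- run_stage(report, "qc", "inputs", function() {
    fr <- funnel_fractions(d$funnels)
    list(fractions = fr,
         quality_flags = flag_quality_removal(fr, thr),
         control_fraction = control_read_fraction(d$counts, d$metadata, thr))
  })

  report <- run_stage(report, "alpha", "inputs", function() {
    soil_meta <- d$metadata %>% filter(.data$sample_type == "soil")
    soil <- d$counts %>% filter(.data$sample_id %in% soil_meta$sample_id)
    rich <- suppressWarnings(
      rarefied_richness(soil, thr$rarefaction_depth,
                        seed = mix_seed(config$seed, 11L)))
    fr <- funnel_fractions(d$funnels)
    reads <- library_sizes(soil) %>%
      inner_join(soil_meta, by = "sample_id") %>%
      left_join(fr, by = "run") %>%
      mutate(reads = .data$library_size /
               ((1 - .data$quality_removed) * (1 - .data$length_removed)))
    pts <- rich %>%
      inner_join(reads %>% select("sample_id", "reads", "run", "site"),
                 by = "sample_id")
    # runs left with < 3 points after rarefaction exclusion cannot support a
    # per-run line; they are dropped from the LB tests and recorded
    lb_drop <- pts %>% dplyr::count(.data$run) %>% filter(.data$n < 3)
    list(richness = rich,
         excluded = attr(rich, "excluded"),
         lb_excluded_runs = lb_drop$run,
         anova = richness_anova(rich, d$metadata),
         mm = fit_michaelis_menten(pts, group = "site"),
         lb = fit_lineweaver_burk(pts %>%
                                    filter(!.data$run %in% lb_drop$run)))
  })

  report <- run_stage(report, "beta", "inputs", function() {
    soil_meta <- d$metadata %>% filter(.data$sample_type == "soil")
    soil <- d$counts %>% filter(.data$sample_id %in% soil_meta$sample_id)
    gen <- aggregate_to_rank(soil, d$lineage, "genus")
    dd <- bray_curtis(hellinger_transform(gen))
    ord <- pcoa(dd)
    soil_meta <- soil_meta[match(labels(dd), soil_meta$sample_id), ]
    list(
      explained = ord$explained[1:min(4, length(ord$explained))],
      permanova_site = unclass(permanova(dd, soil_meta$site,
                                         n_perm = config$n_perm,
                                         seed = mix_seed(config$seed, 21L))),
      variance_partition = variance_partition(
        dd, soil_meta[, c("site", "run", "library")])
    )
  })

  report <- run_stage(report, "diagnose", "inputs", function() {
    within <- within_run_similarity(d$counts, d$metadata, d$lineage,
                                    metric = config$metric)
    ref <- reference_similarity(d$counts, d$metadata, refs, d$lineage,
                                metric = config$metric)
    list(
      within_summaries = within$summaries,
      within_flags = flag_outlier_runs(within, pool),
      reference_summaries = ref$summaries,
      reference_flags = flag_outlier_runs(ref, pool),
      mock = evaluate_mocks(d$counts, d$metadata, d$lineage, thr)
    )
  })

  report <- run_stage(report, "variability", "inputs", function() {
    fc <- log2fc_vs_reference(d$counts, d$metadata, refs, d$lineage,
                              rank = config$rank,
                              pseudocount = config$pseudocount)
    ranges <- log2fc_range(fc)
    rma <- rm_anova_variability(ranges)
    list(mean_ranges = rma$means, anova = rma$anova, pairwise = rma$pairwise,
         n_dropped = rma$n_dropped)
  })

  cfg_hash <- rlang::hash(config)
  report$provenance <- list(
    config_hash = cfg_hash,
    seed = config$seed,
    n_perm = config$n_perm,
    metric = config$metric,
    rank = config$rank,
    thresholds = unclass(thr),
    reference_runs = refs,
    pool_runs = pool,
    package_version = as.character(utils::packageVersion("runqc")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  # The raw data is carried for downstream use but not serialised.
  structure(report, class = "runqc_report")
}

#' @export
print.runqc_report <- function(x, ...) {
  stages <- setdiff(names(x), "provenance")
  for (s in stages) {
    cat(sprintf("%-12s %s\n", s, x[[s]]$status))
  }
  flags <- x$diagnose$reference_flags
  if (!is.null(flags) && any(flags$flag)) {
    cat("flagged (reference similarity):\n")
    print(flags[flags$flag, c("run", "library", "statistic", "threshold")])
  }
  invisible(x)
}

# Render a tibble as a GitHub-style markdown table.
md_table <- function(df, digits = 4) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits, format = "g"))
  cells <- rbind(names(df), rep("---", ncol(df)), as.matrix(df))
  paste0("| ", apply(cells, 1, paste, collapse = " | "), " |")
}

#' Write a diagnostic report to disk
#'
#' Writes `report.json` (everything serialisable, deterministic byte-for-byte
#' for a fixed configuration) and `report.md` (funnel table, Lineweaver-Burk
#' test table, similarity flag table, mock table) into `dir`.
#'
#' @param report A `runqc_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- report
  ser$inputs$data <- NULL            # data stays on disk / in memory
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = 15,
                       pretty = TRUE, na = "null", force = TRUE)
  lines <- c("# Sequencing-run diagnostic report", "")
  if (identical(report$qc$status, "ok")) {
    lines <- c(lines, "## QC funnel removal fractions", "",
               md_table(report$qc$fractions), "")
  }
  if (identical(report$alpha$status, "ok")) {
    lines <- c(lines, "## Lineweaver-Burk per-run deviation tests", "",
               md_table(as.data.frame(report$alpha$lb)), "")
  }
  if (identical(report$diagnose$status, "ok")) {
    lines <- c(lines, "## Reference-soil similarity flags", "",
               md_table(report$diagnose$reference_flags), "",
               "## Mock-community evaluation", "",
               md_table(report$diagnose$mock), "")
  }
  if (identical(report$variability$status, "ok")) {
    lines <- c(lines, "## Log2FC range by library", "",
               md_table(report$variability$mean_ranges), "")
  }
  lines <- c(lines, "## Provenance", "",
             paste0("- config hash: ", report$provenance$config_hash),
             paste0("- seed: ", report$provenance$seed),
             paste0("- package: runqc ", report$provenance$package_version))
  md_path <- file.path(dir, "report.md")
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}
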