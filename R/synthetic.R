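# Synthetic multi-laboratory study generator.
#
# Emulates a pooled species-level count table from a cross-laboratory 16S
# amplicon study: two sites sampled in replicate plots, several single-flowcell
# sequence runs (one per laboratory), three library-autonomy levels per run
# (Seq < PCR/Seq < Ext/PCR/Seq), a mock community per (run, library), negative
# controls, between-run depth variation, and one aberrant run whose taxon bias
# enters at a configurable workflow stage (extraction / pcr / sequencing).
# Ground truth (true proportions, biased taxa, site effects) is returned so
# every diagnostic can be tested against a known answer.

#' Expected mock-community profile
#'
#' The theoretical 16S composition of the 8-species genomic-DNA community
#' standard used as the positive control, in percent.
#'
#' @param rank `"species"` (default) or `"genus"` (labels collapsed to genus,
#'   which is the rank mock samples are evaluated at).
#' @return A tibble with `taxon_id`, `genus` and `percent`; percents sum to 100.
#' @export
mock_expected_profile <- function(rank = c("species", "genus")) {
  rank <- match.arg(rank)
  prof <- tibble(
    taxon_id = c("Pseudomonas aeruginosa", "Escherichia coli",
                 "Salmonella enterica", "Lactobacillus fermentum",
                 "Enterococcus faecalis", "Staphylococcus aureus",
                 "Listeria monocytogenes", "Bacillus subtilis"),
    genus = c("Pseudomonas", "Escherichia", "Salmonella", "Lactobacillus",
              "Enterococcus", "Staphylococcus", "Listeria", "Bacillus"),
    percent = c(4.2, 10.1, 10.4, 18.4, 9.9, 15.5, 14.1, 17.4)
  )
  if (rank == "genus") prof$taxon_id <- prof$genus
  prof
}

#' Configuration for a synthetic multi-laboratory study
#'
#' Defaults describe a realistic six-run, two-site soil study: a long-tailed
#' lognormal base community, a site effect on a fraction of taxa, one aberrant
#' run with phylum-wide per-genus bias entering at the PCR stage, library
#' autonomy noise increasing Seq < PCR/Seq < Ext/PCR/Seq, one low-depth run and
#' one high-depth run, and Dirichlet-multinomial replicate overdispersion.
#'
#' @param n_phyla,n_classes_per_phylum,n_genera_per_class,n_species_per_genus
#'   Balanced taxonomy branching factors (defaults 8, 3, 14, 3: 1008 species
#'   and 336 genera, the scale of a soil community profile).
#' @param lognormal_mu,lognormal_sigma Base log-abundance distribution.
#' @param sites Site labels (first site is the reference level of the site
#'   contrast).
#' @param site_effect List with `fraction` of taxa affected and `log2_sd`, the
#'   SD of their log2 fold-changes between sites.
#' @param runs Tibble with columns `run`, `mean_depth`, `demux_removed`,
#'   `quality_removed`, `length_removed`, `aberrant`, `reference`.
#' @param aberrant_bias List: `phyla` (biased phylum labels; `NULL` = first
#'   two), `log2_sd` (SD of per-genus log2 bias), `stage` (one of
#'   `"extraction"`, `"pcr"`, `"sequencing"`), `within_sd` (extra per-sample
#'   lognormal noise in affected libraries of the aberrant run, degrading
#'   within-run replicate similarity).
#' @param library_noise Named per-library lognormal sigma of context-level
#'   autonomy noise.
#' @param n_plots,n_replicates Plots per site and replicate subsamples per plot.
#' @param overdispersion Dirichlet concentration scale theta (may be `Inf` for
#'   pure multinomial sampling).
#' @param depth_cv Lognormal CV of per-sample depth around the run mean.
#' @param mock_contaminant_fraction Mass moved from the mock profile onto
#'   contaminant taxa.
#' @param control_depth Mean (Poisson) read depth of negative controls.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_phyla = 8,
                             n_classes_per_phylum = 3,
                             n_genera_per_class = 14,
                             n_species_per_genus = 3,
                             lognormal_mu = 0,
                             lognormal_sigma = 2.5,
                             sites = c("ARDEC", "Pendleton"),
                             site_effect = list(fraction = 0.2, log2_sd = 1.5),
                             runs = NULL,
                             aberrant_bias = list(phyla = NULL, log2_sd = 1.5,
                                                  stage = "pcr", within_sd = 0.4),
                             library_noise = c("Seq" = 0, "PCR/Seq" = 0.10,
                                               "Ext/PCR/Seq" = 0.20),
                             n_plots = 4,
                             n_replicates = 2,
                             overdispersion = 10000,
                             depth_cv = 0.15,
                             mock_contaminant_fraction = 5e-4,
                             control_depth = 50,
                             seed = 1L) {
  if (is.null(runs)) {
    runs <- tibble(
      run = paste0("Run", 1:6),
      mean_depth = c(60000, 40000, 110000, 55000, 8000, 22000),
      demux_removed = c(0.42, 0.40, 0.38, 0.43, 0.55, 0.45),
      quality_removed = c(0.030, 0.035, 0.025, 0.030, 0.250, 0.040),
      length_removed = 0.005,
      aberrant = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
      reference = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
    )
  }
  cfg <- list(
    n_phyla = n_phyla, n_classes_per_phylum = n_classes_per_phylum,
    n_genera_per_class = n_genera_per_class,
    n_species_per_genus = n_species_per_genus,
    lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
    sites = sites, site_effect = site_effect, runs = as_tibble(runs),
    aberrant_bias = aberrant_bias, library_noise = library_noise,
    n_plots = n_plots, n_replicates = n_replicates,
    overdispersion = overdispersion, depth_cv = depth_cv,
    mock_contaminant_fraction = mock_contaminant_fraction,
    control_depth = control_depth, seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  bad <- character()
  br <- c(cfg$n_phyla, cfg$n_classes_per_phylum, cfg$n_genera_per_class,
          cfg$n_species_per_genus)
  if (any(br < 1)) bad <- c(bad, "taxonomy branching factors must be >= 1")
  if (length(cfg$sites) < 1) bad <- c(bad, "at least one site required")
  fr <- c(cfg$site_effect$fraction, cfg$runs$demux_removed,
          cfg$runs$quality_removed, cfg$runs$length_removed,
          cfg$mock_contaminant_fraction)
  if (any(fr < 0 | fr > 1)) bad <- c(bad, "fractions must lie in [0, 1]")
  if (any(cfg$runs$mean_depth < 1)) bad <- c(bad, "depths must be >= 1")
  if (!(cfg$overdispersion > 0)) bad <- c(bad, "overdispersion theta must be > 0")
  if (!cfg$aberrant_bias$stage %in% c("extraction", "pcr", "sequencing")) {
    bad <- c(bad, "aberrant_bias$stage must be extraction/pcr/sequencing")
  }
  if (!is.null(cfg$aberrant_bias$phyla)) {
    phyla <- sprintf("P%02d", seq_len(cfg$n_phyla))
    if (!all(cfg$aberrant_bias$phyla %in% phyla)) {
      bad <- c(bad, "aberrant_bias$phyla must be simulated phyla")
    }
  }
  if (!setequal(names(cfg$library_noise), lib_levels())) {
    bad <- c(bad, "library_noise must name Seq, PCR/Seq, Ext/PCR/Seq")
  }
  if (length(bad)) abort(paste0("invalid synthetic_config: ",
                                paste(bad, collapse = "; ")))
  invisible(cfg)
}

#' Build the balanced soil taxonomy of a synthetic configuration
#'
#' @param config A [synthetic_config()].
#' @return A lineage tibble (`taxon_id`, `genus`, `class`, `phylum`) with
#'   deterministic labels; one row per species.
#' @export
build_taxonomy <- function(config) {
  grid <- tidyr::expand_grid(
    p = seq_len(config$n_phyla),
    c = seq_len(config$n_classes_per_phylum),
    g = seq_len(config$n_genera_per_class),
    s = seq_len(config$n_species_per_genus)
  )
  tibble(
    taxon_id = sprintf("P%02d.C%d.G%d.S%d", grid$p, grid$c, grid$g, grid$s),
    genus = sprintf("P%02d.C%d.G%d", grid$p, grid$c, grid$g),
    class = sprintf("P%02d.C%d", grid$p, grid$c),
    phylum = sprintf("P%02d", grid$p)
  )
}

# Lineage rows for mock and contaminant taxa (zero in soil truth).
auxiliary_lineage <- function() {
  mock <- mock_expected_profile()
  dplyr::bind_rows(
    tibble(taxon_id = mock$taxon_id, genus = mock$genus,
           class = "MockClass", phylum = "MockPhylum"),
    tibble(taxon_id = c("Contaminant sp1", "Contaminant sp2"),
           genus = c("ContamG1", "ContamG2"),
           class = "ContamClass", phylum = "ContamPhylum")
  )
}

#' Draw a base soil community
#'
#' Species proportions are normalised `exp(Normal(mu, sigma))` draws, giving a
#' long-tailed rank-abundance curve typical of soils; `sigma = 0` degenerates
#' to the uniform community.
#'
#' @param lineage Lineage tibble from [build_taxonomy()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Tibble with `taxon_id` and `proportion` (sums to 1).
#' @export
simulate_base_community <- function(lineage, config, seed = config$seed) {
  n <- nrow(lineage)
  x <- withr::with_seed(mix_seed(seed, 1L),
                        exp(stats::rnorm(n, config$lognormal_mu, config$lognormal_sigma)))
  tibble(taxon_id = lineage$taxon_id, proportion = x / sum(x))
}

#' Draw the fixed study-level effects
#'
#' Site fold-changes (a random fraction of species) and the aberrant run's
#' per-genus bias (all genera of the biased phyla) are drawn once per study and
#' shared by every sample the effect applies to.
#'
#' @inheritParams simulate_base_community
#' @return List with `site_taxa` (tibble `taxon_id`, `log2fc`), `bias`
#'   (tibble `taxon_id`, `genus`, `log2_bias`) and `biased_phyla`.
#' @export
study_effects <- function(lineage, config, seed = config$seed) {
  withr::with_seed(mix_seed(seed, 2L), {
    n <- nrow(lineage)
    n_aff <- round(config$site_effect$fraction * n)
    aff <- sample(lineage$taxon_id, n_aff)
    site_taxa <- tibble(taxon_id = aff,
                        log2fc = stats::rnorm(n_aff, 0, config$site_effect$log2_sd))
    phyla <- config$aberrant_bias$phyla %||%
      utils::head(sort(unique(lineage$phylum)), 2)
    genera <- lineage %>% filter(.data$phylum %in% phyla) %>%
      distinct(.data$genus)
    gbias <- stats::rnorm(nrow(genera), 0, config$aberrant_bias$log2_sd)
    bias <- lineage %>% filter(.data$phylum %in% phyla) %>%
      select("taxon_id", "genus") %>%
      left_join(tibble(genus = genera$genus, log2_bias = gbias), by = "genus")
    list(site_taxa = site_taxa, bias = bias, biased_phyla = phyla)
  })
}

#' True community proportions for one (site, run, library) context
#'
#' Applies, in order: the site fold-changes, the aberrant-run bias (only when
#' the run is aberrant and the library's autonomy covers the bias entry stage
#' -- a PCR-stage bias reaches PCR/Seq and Ext/PCR/Seq but not Seq), and
#' multiplicative lognormal autonomy noise at the library's noise level; the
#' result is renormalised.
#'
#' @param base Tibble `taxon_id`, `proportion` from [simulate_base_community()].
#' @param config A [synthetic_config()].
#' @param context List or one-row data frame with `site`, `run`, `library`.
#' @param effects Fixed effects from [study_effects()].
#' @param noise_seed Integer seed for the autonomy noise, or `NULL` for no
#'   noise (deterministic truth).
#' @return Tibble `taxon_id`, `proportion` (sums to 1).
#' @export
apply_effects <- function(base, config, context, effects = NULL,
                          noise_seed = NULL) {
  effects <- effects %||% list(site_taxa = tibble(taxon_id = character(),
                                                  log2fc = numeric()),
                               bias = tibble(taxon_id = character(),
                                             log2_bias = numeric()),
                               biased_phyla = character())
  if (!context$site %in% config$sites) {
    abort(paste0("unknown site: ", context$site))
  }
  if (!context$run %in% config$runs$run) {
    abort(paste0("unknown run: ", context$run))
  }
  if (!context$library %in% lib_levels()) {
    abort(paste0("unknown library: ", context$library))
  }
  p <- base$proportion
  names(p) <- base$taxon_id
  # Site effect: applied to the non-reference site(s); the first site is the
  # baseline community.
  if (context$site != config$sites[1] && nrow(effects$site_taxa)) {
    i <- match(effects$site_taxa$taxon_id, names(p))
    p[i] <- p[i] * 2^effects$site_taxa$log2fc
  }
  aberrant <- config$runs$aberrant[match(context$run, config$runs$run)]
  if (isTRUE(aberrant) &&
      config$aberrant_bias$stage %in% lib_stages(context$library) &&
      nrow(effects$bias)) {
    i <- match(effects$bias$taxon_id, names(p))
    p[i] <- p[i] * 2^effects$bias$log2_bias
  }
  sigma <- unname(config$library_noise[context$library])
  if (!is.null(noise_seed) && sigma > 0) {
    noise <- withr::with_seed(noise_seed, stats::rlnorm(length(p), 0, sigma))
    p <- p * noise
  }
  tibble(taxon_id = names(p), proportion = unname(p / sum(p)))
}

#' Draw counts for one sample
#'
#' Dirichlet-multinomial sampling: `p ~ Dirichlet(theta * proportions)`, then
#' `counts ~ Multinomial(depth, p)`. `theta = Inf` gives pure multinomial
#' sampling.
#'
#' @param proportions Tibble `taxon_id`, `proportion`, or a named numeric
#'   vector summing to 1.
#' @param depth Positive integer read depth.
#' @param theta Dirichlet concentration scale (> 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Named integer vector of counts summing to `depth`.
#' @export
sample_counts <- function(proportions, depth, theta = 300, seed = NULL) {
  if (is.data.frame(proportions)) {
    p <- proportions$proportion
    names(p) <- proportions$taxon_id
  } else {
    p <- proportions
  }
  if (depth < 1) abort("depth must be a positive integer")
  if (!(theta > 0)) abort("theta must be > 0")
  draw <- function() {
    if (is.finite(theta)) {
      g <- stats::rgamma(length(p), shape = theta * p)
      q <- if (sum(g) > 0) g / sum(g) else p
    } else {
      q <- p
    }
    stats::rmultinom(1, size = depth, prob = q)[, 1]
  }
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  stats::setNames(as.integer(counts), names(p))
}

#' Simulate a full multi-laboratory study
#'
#' Generates one soil sample per (run, library, site, plot, replicate), one
#' mock sample per (run, library), one extraction and one PCR negative control
#' per run (contaminant taxa only, tiny Poisson depth), per-run QC funnels
#' consistent with the configured removal fractions, and the ground truth that
#' produced everything. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_study`: `counts` (pooled species-level
#'   count table), `metadata`, `lineage`, `funnels`, `truth`, `config`.
#' @export
simulate_study <- function(config) {
  validate_synthetic_config(config)
  soil_lineage <- build_taxonomy(config)
  lineage <- dplyr::bind_rows(soil_lineage, auxiliary_lineage())
  base <- simulate_base_community(soil_lineage, config)
  effects <- study_effects(soil_lineage, config)
  taxa <- lineage$taxon_id
  mock_prof <- mock_expected_profile()
  contam <- c("Contaminant sp1", "Contaminant sp2")

  # Context-level truths (site x run x library), autonomy noise included.
  ctx <- tidyr::expand_grid(run = config$runs$run, library = lib_levels(),
                            site = config$sites)
  ctx_prop <- matrix(0, nrow = nrow(ctx), ncol = length(taxa),
                     dimnames = list(NULL, taxa))
  for (i in seq_len(nrow(ctx))) {
    pr <- apply_effects(base, config, ctx[i, ], effects,
                        noise_seed = mix_seed(config$seed, 100L + i))
    ctx_prop[i, pr$taxon_id] <- pr$proportion
  }

  soil <- tidyr::expand_grid(
    run = config$runs$run, library = lib_levels(), site = config$sites,
    plot = sprintf("P%d", seq_len(config$n_plots)),
    replicate = LETTERS[seq_len(config$n_replicates)]
  ) %>%
    mutate(sample_type = "soil")
  mocks <- tidyr::expand_grid(run = config$runs$run, library = lib_levels()) %>%
    mutate(site = "-", plot = "-", replicate = "-", sample_type = "mock")
  ctrls <- tidyr::expand_grid(run = config$runs$run,
                              sample_type = c("ext_control", "pcr_control")) %>%
    mutate(library = "Ext/PCR/Seq", site = "-", plot = "-", replicate = "-")
  meta <- dplyr::bind_rows(soil, mocks, ctrls) %>%
    mutate(sample_id = paste(.data$run,
                             gsub("/", "", .data$library),
                             .data$site, .data$plot, .data$replicate,
                             substr(.data$sample_type, 1, 4), sep = "_")) %>%
    select("sample_id", "run", "library", "site", "plot", "replicate",
           "sample_type")

  aber_run <- config$runs$run[config$runs$aberrant]
  within_sd <- config$aberrant_bias$within_sd %||% 0
  run_depth <- stats::setNames(config$runs$mean_depth, config$runs$run)

  counts <- matrix(0L, nrow = nrow(meta), ncol = length(taxa),
                   dimnames = list(meta$sample_id, taxa))
  depths <- integer(nrow(meta))
  mock_p <- stats::setNames(numeric(length(taxa)), taxa)
  mock_p[mock_prof$taxon_id] <- mock_prof$percent / 100 *
    (1 - config$mock_contaminant_fraction)
  mock_p[contam] <- config$mock_contaminant_fraction / length(contam)
  ctrl_p <- stats::setNames(numeric(length(taxa)), taxa)
  ctrl_p[contam] <- 1 / length(contam)

  withr::with_seed(mix_seed(config$seed, 3L), {
    for (i in seq_len(nrow(meta))) {
      row <- meta[i, ]
      if (row$sample_type == "soil") {
        j <- which(ctx$run == row$run & ctx$library == row$library &
                     ctx$site == row$site)
        p <- ctx_prop[j, ]
        aberrant_here <- length(aber_run) && row$run %in% aber_run &&
          config$aberrant_bias$stage %in% lib_stages(row$library)
        if (aberrant_here && within_sd > 0) {
          p <- p * stats::rlnorm(length(p), 0, within_sd)
          p <- p / sum(p)
        }
        depth <- max(500L, as.integer(round(
          stats::rlnorm(1, log(run_depth[row$run]), config$depth_cv))))
      } else if (row$sample_type == "mock") {
        p <- mock_p
        depth <- as.integer(round(run_depth[row$run]))
      } else {
        p <- ctrl_p
        depth <- max(1L, stats::rpois(1, config$control_depth))
      }
      counts[i, ] <- sample_counts(p, depth, config$overdispersion)
      depths[i] <- depth
    }
  })

  # Drop taxa never observed anywhere (the pooled table only contains taxa the
  # classifier reported).
  keep <- colSums(counts) > 0
  table <- ct_tibble(counts[, keep, drop = FALSE])

  lenfilt <- tapply(rowSums(counts), meta$run, sum)[config$runs$run]
  funnels <- config$runs %>%
    mutate(lenfilt_reads = as.numeric(lenfilt),
           qualfilt_reads = round(.data$lenfilt_reads / (1 - .data$length_removed)),
           demux_reads = round(.data$qualfilt_reads / (1 - .data$quality_removed)),
           raw_reads = round(.data$demux_reads / (1 - .data$demux_removed))) %>%
    select("run", "raw_reads", "demux_reads", "qualfilt_reads", "lenfilt_reads")

  truth <- list(
    base = base,
    contexts = dplyr::bind_cols(ctx, as_tibble(ctx_prop, .name_repair = "minimal")),
    site_taxa = effects$site_taxa,
    bias = effects$bias,
    biased_phyla = effects$biased_phyla,
    aberrant_run = aber_run,
    reference_runs = config$runs$run[config$runs$reference],
    sample_depths = tibble(sample_id = meta$sample_id, depth = depths)
  )
  structure(list(counts = table, metadata = meta, lineage = lineage,
                 funnels = funnels, truth = truth, config = config),
            class = "synthetic_study")
}

#' Write the artefacts of a synthetic study to a directory
#'
#' Writes `counts.tsv` (taxa as rows), `metadata.tsv`, `lineage.tsv`,
#' `funnels.tsv` and `ground_truth.json`.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(study$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(study$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  readr::write_tsv(study$lineage, file.path(dir, "lineage.tsv"), progress = FALSE)
  readr::write_tsv(study$funnels, file.path(dir, "funnels.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(aberrant_run = study$truth$aberrant_run,
         reference_runs = study$truth$reference_runs,
         biased_phyla = study$truth$biased_phyla,
         site_taxa = study$truth$site_taxa,
         sample_depths = study$truth$sample_depths),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
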