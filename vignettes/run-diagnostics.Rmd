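---
title: "Diagnosing aberrant sequencing runs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing aberrant sequencing runs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runqc)
```

## The problem

A multi-laboratory amplicon study pools soil samples prepared at three levels
of workflow autonomy — a ready-made library the secondary lab only sequences
(Seq), a DNA extract it amplifies and sequences (PCR/Seq), and raw soil it
extracts, amplifies and sequences (Ext/PCR/Seq) — into one flow-cell run per
laboratory. Errors can enter at any step, and a systematically biased run may
look perfectly healthy on the usual per-run metrics: its read counts,
quality-filtering profile and mock-community recovery can all be normal while
whole phyla are shifted several fold. This package operationalises the
diagnostics that do work: read-accounting funnels with threshold rules,
richness-saturation regressions, depth-aware beta-diversity comparisons, and
above all the comparison of every sample against a reference soil sequenced
by a trusted (primary) laboratory.

## The diagnostics and their assumptions

### Read-accounting funnel

Per run, reads surviving demultiplexing, quality filtering and length
filtering define three removal fractions. The quality-step rule — flag when
removal is below 2% or above 5% of demultiplexed reads — is an inclusive band;
exactly 2% or 5% does not flag. The fractions depend on the order of
processing steps, so the band is configurable (`diagnostic_thresholds()`).
The control rule flags a run when its negative controls jointly carry more
than 0.4% of the run's reads; a per-control-sample variant is available
(`per_sample = TRUE`) because summed and per-sample readings of that rule
differ when runs carry several controls.

### Richness saturation

Observed richness is the sole alpha-diversity metric; samples are first
rarefied (single seeded multivariate-hypergeometric draw per sample, by
default to 12,000 reads; samples below depth are excluded and reported, never
silently dropped; `rarefied_richness(n = ...)` averages several draws when
wanted). Richness is then modelled against the *original* per-sample read
count — reconstructed as the demultiplexed-equivalent count from each sample's
final reads and its run's removal fractions, since a pooled count table no
longer carries per-stage per-sample counts.

The Michaelis–Menten fit `S = Smax·R/(K+R)` uses bounded Gauss–Newton
(`nls(algorithm = "port")`, `Smax > 0`, `K ≥ 0`) initialised from the
Lineweaver–Burk linearisation, with two cruder fallback starts; constant-S
groups return the saturated limit (`Smax = S`, `K = 0`) flagged as degenerate,
and a fitted `K` at the zero boundary is likewise flagged. The Lineweaver–Burk
regressions are ordinary least squares on `1/S` vs `1/R`, unweighted — the
transform is known to be heteroscedastic, which is why the MM fit is the
primary estimator and LB the diagnostic view. Per-run deviations are tested by
fitting `1/S ~ (1/R) × I(run = r)` and reading the indicator main effect
(intercept shift = different asymptotic richness) and interaction (slope shift
= different saturation rate) as two-sided t contrasts against the pooled other
runs; raw p-values are reported alongside Benjamini–Hochberg-adjusted ones
since both readings are useful. On numerically exact (noise-free) data the
contrasts are 0/0; they are reported as p = 1, i.e. "no deviation".

### Beta diversity

Bray–Curtis on Hellinger-transformed genus abundances is the sensitive
metric; the classical Morisita index on raw genus counts is the
depth-robust one. Morisita's `C` can exceed 1 for small counts (its
unbiasedness correction `λ = Σx(x−1)/(N(N−1))` overshoots); distances are
clamped to [0, 1] by default with the raw values retained in the `raw`
attribute, matching the floor applied by the standard community-ecology
implementation. The classical index requires integer counts and totals ≥ 2;
a Morisita–Horn variant accepts relative abundances. perMANOVA uses free,
seeded label permutations (no strata) with `p = (1 + #{F* ≥ F})/(1 + n_perm)`;
variance partitioning reports marginal (single-factor) db-RDA adjusted R² per
factor, matching additive reporting of site/run/library fractions — a joint
decomposition is deliberately not the default because the design confounds
run with depth.

### Reference-soil and replicate similarity

Within-run similarity compares replicate subsamples of the same (site, plot);
reference similarity compares each evaluated sample to the sample of the same
(site, plot, replicate) and library in each reference run, falling back to
another replicate of the same plot when the exact replicate is missing, and
skipping (with a warning) samples with no match. One similarity per (sample,
reference run) is recorded — values against two reference runs are pooled,
not averaged. Flag rule: a (run, library) is flagged when its median falls
below the pool's `median − IQR`. Two readings of the published band were
possible (± IQR vs ± IQR/2); the full-IQR band is the default and
`band_multiplier = 0.5` gives the other. Flagging is one-sided because low
similarity is the failure mode. The band is computed **per library** by
default: between-run variability genuinely grows with library autonomy, so a
single pooled band is simultaneously too tight for Ext/PCR/Seq (false flags
at ~15% per run in null simulations) and too loose for Seq; with per-library
bands the simulated false-flag rate is ≤ 2% per run while the planted
aberrant run is still detected in ~99% of simulations. `per_library = FALSE`
restores the single pooled band.

### Log2FC range variability

CPM-normalised abundances at a chosen rank are compared per (run, library)
against the pooled mean of the reference runs' soil samples; the per-taxon
range of these log2 fold-changes across runs, within a library, is the
between-run variability statistic. Zeros are kept finite with a pseudocount
(default 0.5 CPM, configurable and reported); how zeros were handled upstream
is not recoverable from a count table, so the pseudocount is explicit rather
than hidden. The repeated-measures ANOVA treats taxon as the subject and
library as the within-subject effect; the Greenhouse–Geisser correction is
applied to the default p-value (sphericity of ranges across libraries has no
reason to hold) with the uncorrected p also reported. Site contrasts replace
a negative-binomial GLM with RLE (median-of-ratios) normalisation plus a
seeded two-sided permutation test per taxon, BH-adjusted — a deliberate
simplification that trades a parametric model whose type-I behaviour is
debated for an exact, assumption-light test of the same contrast.

## The synthetic study: what it emulates, and what it does not

`synthetic_config()` states the simulated world once; its defaults are chosen
to mirror the design and printed summaries of a real six-laboratory nanopore
soil study and are not adjusted per analysis:

* **Taxonomy** 8 phyla × 3 classes × 14 genera × 3 species = 1008 species and
  336 genera — the order of magnitude of a genus-level soil profile. Mock taxa
  (the 8-genus community standard) and two contaminant species are appended
  with their own lineage; soil truth places zero mass on them.
* **Base community** proportions are normalised `exp(N(0, 2.5))` draws: a
  long-tailed rank-abundance curve, the dominant feature of soil communities.
* **Sites** two, with 20% of species affected by `N(0, 1.5)` log2
  fold-changes — enough planted signal for the site-contrast tests to have
  something to find.
* **Runs** six, one per laboratory; two reference (primary-lab) runs. Mean
  depths 60k/40k/110k/55k/8k/22k reads: one high-depth and one low-depth run,
  the latter below the 12,000-read rarefaction default so the exclusion path
  is always exercised. Demultiplex removal ≈ 42%, quality removal 2.5–4%
  except 25% for the low-depth run (the ~10× quality-removal phenotype),
  length removal 0.5%.
* **Aberrant run** Run2 carries per-genus `N(0, 1.5)` log2 biases on two of
  the eight phyla — phylum-wide systematic bias, not contamination — entering
  at the PCR stage, so it propagates into PCR/Seq and Ext/PCR/Seq but not
  Seq. The bias magnitude is not published anywhere; 1.5 keeps detection
  genuinely probabilistic (weak draws occasionally evade the flag rule).
  An extra per-sample lognormal noise (σ = 0.4) in the affected libraries
  degrades the aberrant run's within-run replicate similarity to the ~0.80
  median reported for the real aberrant run.
* **Autonomy noise** multiplicative lognormal noise per (run, library, site)
  context with σ = 0 (Seq), 0.10 (PCR/Seq), 0.20 (Ext/PCR/Seq) — variability
  increasing with each self-performed step (s1 = s2 = 0.10).
* **Replicate noise** Dirichlet-multinomial sampling with concentration
  θ = 10,000, calibrated once so that within-run Bray–Curtis replicate
  similarity at genus rank sits at the published ≈ 0.906 median.
* **Controls** negative controls draw Poisson(50) reads of contaminant taxa
  only, keeping every run below the 0.4% control-read rule; mocks draw the
  expected profile with 0.05% contaminant mass.

Reproducibility: every stage derives its own substream seed from the single
config seed, so identical configurations give byte-identical studies and
reports.

**What a green test does not establish.** The generator draws each sample's
counts exchangeably per read. A mathematical consequence is that rarefied
richness cannot depend on the original depth — whereas real data show a
strong richness–depth relationship even after rarefaction, driven by
classifier behaviour (EM-redistributed abundances, depth-dependent detection)
that this generator deliberately does not model. The saturation diagnostics
are therefore validated on directly generated Michaelis–Menten data (exact
inversion, Poisson-noise recovery), while on simulated studies the fitted
curves are nearly flat and the low-depth run drops out of the LB tests when
rarefaction excludes its samples (runs left with < 3 points are dropped from
the per-run regressions and recorded in the report). Similarly, the real
low-depth laboratory showed reference similarities depressed by ~0.2 under
Bray–Curtis; sampling depth alone reproduces the direction of that signature
(all three libraries depressed under Bray–Curtis, none under Morisita) but at
a much smaller magnitude, because the real depression also contained
classifier and handling effects. Tests assert the direction, not the
magnitude.

## Validation worlds for the property simulations

Two criterion-specific configurations restrict the default world rather than
extend it:

* **Detection power / false-flag calibration** uses six runs at comparable
  depths (20k–60k) whose *only* pathology is the PCR-stage bias, with the
  clean runs as the flag pool. Including the extreme 8k run would conflate
  the bias detector with Bray–Curtis depth sensitivity, which is a true
  signal (and tested separately), not a false positive.
* **Variability ordering** uses the same depth-comparable world with no
  aberrant run: the planted phylum bias enters PCR/Seq and Ext/PCR/Seq
  identically and would mask the ordering induced by autonomy noise that the
  criterion isolates.

Both configurations are stated in the test helpers
(`biased_run_config()`) and were fixed before the simulations were scored.

## Numerical choices and degenerate inputs

* Quantiles everywhere are type-7 (linear interpolation), stated because
  quartile conventions differ across software.
* The quality-band comparison carries a 1e-9 tolerance so a fraction that is
  exactly 2% or 5% up to floating point does not flag.
* Zero-sum samples: relative abundance and Hellinger return zero rows with a
  warning; CPM refuses (a zero-depth sample has no meaningful CPM). The
  Bray–Curtis distance between two all-zero samples is defined as 0 with a
  warning.
* `rle_size_factors()` requires a taxon positive in all samples; the site
  contrast falls back to a +1 pseudocount *for factor estimation only* when
  none exists.
* Pooling tables unions taxa and zero-fills; whether the original study
  pooled by union or intersection is unstated, and union loses nothing.
* EMU-style relative-abundance input is converted to pseudo-counts by
  `round(abundance × reads)` and documented as lossy.
* The pipeline treats a failed stage as data, not as an exception: the stage
  records its error, dependants are skipped, and the report still renders.

## Known limitations

* The generator does not model classifier noise, chimeras or barcode
  cross-talk; diagnostics sensitive to those mechanisms are validated only
  for the mechanisms the generator does contain (depth, bias, autonomy
  noise).
* The LB deviation tests inherit the heteroscedasticity of the reciprocal
  transform; they are diagnostics, not estimators.
* Marginal variance partitioning double-counts shared variance between
  aliased factors (a warning is raised when factors are fully aliased).
* The mock evaluation shares the real standard's blind spot by construction:
  eight genera cannot witness a bias in phyla they do not contain. That is
  the point the reference-soil diagnostic exists to make.
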