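---
title: "Methods: simulation and quantification of repetitive-element methylation by qMSP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and quantification of repetitive-element methylation by qMSP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmspr)
```

## The measurement problem

Global DNA methylation is commonly proxied by the methylation of the LINE-1
and Alu retrotransposon families, quantified by bisulfite quantitative
methylation-specific PCR (qMSP). After bisulfite conversion, a
methylation-specific primer set (MSP) amplifies only templates that were
methylated, while a methylation-independent primer set (MIP) amplifies every
converted template and serves as the normalizing reference. Relative
methylation is then a ratio of ratios against a fully methylated calibrator
that defines the 100% level.

The weak link is the MIP reference: if its primers amplify
originally-methylated and originally-unmethylated converted templates at
different per-cycle efficiencies ("PCR amplification bias"), the recovered
methylation level is systematically distorted, up to inverting
hypo/hypermethylation calls between sample groups. This package implements
the full quantification pipeline together with a mechanistic simulator, so
that calibration, formula choice, exclusion rules and bias classification can
all be validated against a known generating truth.

## The mechanistic simulation model

One well contains two template pools: `N_m` copies of converted
originally-methylated template and `N_u` of originally-unmethylated, derived
from the sample's methylation fraction `m`:

    N_total = mass_pg x copies_per_pg x bisulfite_recovery x template_fraction
    N_m = N_total x (m + (1 - m) x conversion_failure)
    N_u = N_total x (1 - m) x (1 - conversion_failure)

An MSP assay sees `N_m` plus `cross_reactivity x N_u` (0 by default); a MIP
assay sees both pools. Each pool grows as `(1 + e)^t` with its own
efficiency, and the threshold cycle is the unique `t` solving

    N_m (1 + e_meth)^t + N_u (1 + e_unmeth)^t = Q,

found by bracketed root-finding to 1e-9 cycles (`mixture_ct()`); with a
single pool the closed form `t = log(Q/N_0) / log(1 + e)` applies
(`closed_form_ct()`). Gaussian noise is then added to the CT and values
beyond `max_cycles` become undetermined (`NA`). CT is the atomic observable:
no fluorescence traces and no sequence-level chemistry are modelled.

Biased MIP primers are expressed directly as `e_meth != e_unmeth`. Because
the faster pool dominates the summed signal, the reference CT shifts with
sample composition and the recovered level deviates from the input level.
The direction is fixed by the algebra, not by assay labels: with a fully
methylated calibrator, a reference that amplifies the calibrator-type
(methylated) template *better* than the sample's unmethylated templates
under-measures the reference signal in partially methylated samples and
therefore *over*-estimates their methylation, and vice versa. The simulator
supports both signs, and the test suite asserts this forced direction.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `copies_per_pg` | 0.303/pg haploid genomes x 1.5e5 (LINE-1) or 1.1e6 (Alu) | order-of-magnitude repeat copy densities; affect only CT intercepts |
| `threshold_copies` Q | 1e12 | places CTs of pg-scale inputs in the instrument's 20-30 cycle range and keeps Q above any simulated initial copy number (back-computed from typical CT cutoffs at their limit-of-detection masses) |
| `max_cycles` | 40 | standard run length |
| `ct_noise_sd` | 0.1 cycles | typical instrument repeatability for replicate wells |
| `n_replicates` | 2 | duplicate wells, the study design |
| `template_fraction` | 2/20 | 2 uL of a 20 uL bisulfite eluate per well |
| dilution grid | 1000, 250, 62.5, 15.625, 3.125 pg | the standard-curve design |
| mixture grid | 0, 12.5, 25, 50, 75, 100 % at 200 pg | defined-methylation controls for bias assessment |
| bias verdict | slope in 1 +/- 0.1, intercept within +/- 5 points | operationalizes "recovered nearly identical to input" |
| formula rule | Livak iff dCT slope magnitude < 0.1 and p > 0.05 | the published decision rule |
| exclusion | both replicates above the assay CT cutoff | the published rule; a single passing replicate is used alone and flagged |

The optional mass-dependent conversion failure
`saturating_conversion_failure(f_max = 0.15, K = 5000)` emulates overloading
the bisulfite reaction: failure rises with input mass and saturates at
`f_max`, which reproduces the qualitative increase of dCT(MIP − MSP) with
excess DNA input. Note the reassignment acts on unmethylated molecules, so a
100% methylated sample is unaffected; simulations probing this effect use
`m < 1`.

## Quantification conventions

- CT aggregation is the mean of determined replicate CTs at or below the
  assay's cutoff; a sample x assay is excluded only when *every* replicate
  fails. Calibrator CTs are replicate means from the same run.
- Livak: `100 x 2^-ddCT`. Pfaffl:
  `100 x (1+E_target)^dCT_target / (1+E_ref)^dCT_ref` with efficiencies from
  standard curves fitted on fully methylated DNA
  (`E = 10^(-1/slope) - 1`). Pfaffl with the true efficiencies is exact for
  unbiased assays (noise-free simulate-then-quantify returns the generating
  fraction to 1e-6); Livak is exact when every assay doubles perfectly, and
  otherwise carries the mild `m^(log 2 / log(1+E))` compression inherent to
  the method.
- Levels above 100% are preserved (they occur legitimately, e.g. under
  reference bias); no capping or flooring.
- A sample with no accepted MSP signal but a valid reference reports 0% with
  status `ZERO_SIGNAL` — the limit of the ratio as methylated copies vanish —
  rather than being excluded; an invalid reference is `EXCLUDED`.
- For a noise-free dilution series the dCT regression fits exactly and the
  slope test's p-value is undefined; the formula decision then rests on the
  slope magnitude alone.
- Cross-normalization (a target quantified against the other element's
  reference) is configured through `run_config()` pairs; the formula choice
  is per target/reference pair.

## Statistical gating

Two-group comparisons are gated by Shapiro-Wilk normality at alpha = 0.05 —
on each group when unpaired (Student's t vs Mann-Whitney U), on the paired
differences when paired (paired t vs Wilcoxon signed rank). Differences that
are all exactly zero carry no signal and return p = 1. Three or more groups
use Kruskal-Wallis; age correlations use Spearman's rank test. No
multiple-testing correction is applied, matching the analysis design this
pipeline mirrors. The gate's type-I error is verified at or below 0.06 under
a normal null.

Cohort simulation draws per-sample methylation through quantile functions of
shared or independent Unif(0,1) latent draws: paired groups share draws, so
identical group distributions produce exactly matched pairs (a clean no-signal
null), while a distributional shift becomes a within-pair effect.

## Numerical and design choices

- Root-finding brackets the mixture CT between the closed-form CTs at the
  faster and slower efficiency; the unit suite cross-checks against an
  independent cycle-by-cycle accumulation oracle to 0.01 cycles.
- CT cutoffs are the fitted curve's prediction at the limit-of-detection
  mass (less noise-sensitive than the observed mean, which is reported
  alongside); the LOD defaults to the smallest mass at which every replicate
  amplified, with a configurable override.
- Seeding: each generator applies `set.seed(config$seed)` on entry, giving
  bit-reproducible tables; zero noise gives fully deterministic CTs.
- Undetermined CTs are serialized as the literal `NA` and never imputed.
- Well tables round-trip through CSV at full double precision; result
  reports are written at 6 significant digits identically as TSV and JSON.

## What the simulations do and do not show

The generator reproduces the *mechanisms* the pipeline must be robust to —
allele-differential amplification, cross-reactivity, conversion failure,
stochastic CT noise, undetermined wells, cohort structure. It does not
emulate real cfDNA fragmentomics, copy-number variation between individuals,
inhibitors, or between-run calibrator drift; passing tests demonstrate the
correctness of the computations and the detectability of the modelled
biases, not clinical performance on patient material.

Problem sizes used in the packaged checks (chosen to make stochastic rates
stable at desk scale): 200 seeded mixture panels per bias-power arm, 50-60
seeded cohorts of n = 100 pairs for power and null calibration, 10,000
repetitions for the type-I error of the normality gate, and 100-1000 random
draws for each numerical property.

One stochastic guarantee deserves a caveat: with duplicate wells and CT
noise sd 0.1, the calibrator's own noise multiplies every recovered level of
a run by a common factor with ~6% log-sd. A recovered-vs-input regression
slope therefore leaves the 1 +/- 0.1 band in roughly a fifth of unbiased
panels, so the unbiased-verdict rate under these conditions is ~80%, not
near-certain; detecting a genuine 0.10 allele-efficiency gap is unaffected
(~100%). Raising calibrator replication is the practical remedy.

## Worked example

```{r example, eval = FALSE}
msp <- assay_spec("L1-Me", "MSP", "LINE1", e_meth = 0.90)
mip <- assay_spec("L1-Ref", "MIP", "LINE1", e_meth = 0.90)

std_msp <- simulate_dilution_series(msp, config = sim_config(seed = 1))
std_mip <- simulate_dilution_series(mip, config = sim_config(seed = 2))
fit <- fit_standard_curve(std_mip)
choice <- select_formula(std_msp, std_mip)

panel <- simulate_mixture_panel(msp, mip, config = sim_config(seed = 3))
cfg <- run_config(
  data.frame(assay_id = c("L1-Me", "L1-Ref"), role = c("MSP", "MIP"),
             element = "LINE1", efficiency = fit$efficiency_pct / 100,
             ct_cutoff = NA),
  calibrator_id = "CAL",
  pairs = data.frame(element = "LINE1", target_assay = "L1-Me",
                     reference_assay = "L1-Ref", formula = choice$choice))
classify_bias(recovered_series(panel, cfg))
```
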