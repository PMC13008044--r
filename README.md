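# qmspr

Relative methylation quantification of repetitive elements (LINE-1, Alu) by
bisulfite quantitative methylation-specific PCR (qMSP), for epigenomics
researchers who run repeat-element methylation assays or need to vet the
references those assays are normalized by.

In qMSP, a methylation-specific primer set (MSP) amplifies the
bisulfite-converted methylated target and a methylation-independent primer
set (MIP) amplifies all converted templates as the normalizing reference.
Against a fully methylated calibrator that defines the 100% level, relative
methylation is computed either by the Livak (comparative ΔΔCT) formula

    level = 100 × 2^−[(CT_me,s − CT_ref,s) − (CT_me,cal − CT_ref,cal)]

or, when target and reference amplify at different efficiencies, by the
efficiency-corrected Pfaffl formula

    level = 100 × (1+E_me)^(CT_me,cal − CT_me,s) / (1+E_ref)^(CT_ref,cal − CT_ref,s)

with each amplicon's efficiency fitted from a standard curve,
E = 10^(−1/slope) − 1. The choice between formulas follows the ΔCT-slope
rule: regress ΔCT = CT(MIP) − CT(MSP) on log10(input mass); a flat slope
(|slope| < 0.1, p > 0.05) means matched efficiencies and Livak, otherwise
Pfaffl. A MIP reference that amplifies originally-methylated and
originally-unmethylated templates at unequal per-cycle efficiencies ("PCR
amplification bias") distorts every downstream level; the package detects
this by quantifying defined-methylation mixtures and regressing recovered
against input methylation.

The package provides:

- a mechanistic simulator of bisulfite-converted two-allele qPCR reactions
  (`simulate_dilution_series()`, `simulate_mixture_panel()`,
  `simulate_cohort()`, built on the kinetics in `closed_form_ct()` /
  `mixture_ct()`), with allele-specific efficiencies, MSP cross-reactivity,
  conversion failure, CT noise and undetermined wells;
- standard-curve calibration and formula selection (`fit_standard_curve()`,
  `determine_ct_cutoff()`, `select_formula()`);
- calibrator-normalized quantification with replicate aggregation and
  CT-cutoff exclusion (`quantify_samples()`, `livak_level()`,
  `pfaffl_level()`);
- amplification-bias assessment (`recovered_series()`, `classify_bias()`);
- group statistics with a normality-gated test choice
  (`summarize_group()`, `compare_two_groups()`, `compare_multi()`,
  `correlate_age()`);
- CSV/TSV/JSON/YAML IO for well tables, results and run configurations
  (`read_ct_table()`, `write_results()`, `read_run_config()`).

See `vignettes/qmsp-methods.Rmd` for the model, parameter rationale and
numerical conventions.

## Worked example

Calibrate a simulated biased reference (the MIP amplifies unmethylated
template at efficiency 0.78 against 0.90 for methylated) and let the bias
assessment catch it:

```r
library(qmspr)

msp <- assay_spec("L1-Me", "MSP", "LINE1", e_meth = 0.90)
mip <- assay_spec("L1-Ref", "MIP", "LINE1", e_meth = 0.90, e_unmeth = 0.78)

std_msp <- simulate_dilution_series(msp, config = sim_config(seed = 1, ct_noise_sd = 0.05))
std_mip <- simulate_dilution_series(mip, config = sim_config(seed = 2, ct_noise_sd = 0.05))
(fit <- fit_standard_curve(std_mip))
#> <standard_curve_fit> L1-Ref
#>   CT = 29.9753 -3.6082 x log10(pg)   (n = 10, undetermined 0)
#>   R2 = 0.99982, efficiency = 89.30%
#>   CT cutoff 28.19 (observed 28.20) at LOD 3.125 pg
(choice <- select_formula(std_msp, std_mip))
#> <formula_choice> LIVAK  (dCT slope -0.0135, p 0.31; |slope| < 0.1 and p > 0.05 => LIVAK)

panel <- simulate_mixture_panel(msp, mip, config = sim_config(seed = 3))
cfg <- run_config(
  data.frame(assay_id = c("L1-Me", "L1-Ref"), role = c("MSP", "MIP"),
             element = "LINE1", efficiency = c(0.9, fit$efficiency_pct / 100),
             ct_cutoff = NA),
  calibrator_id = "CAL",
  pairs = data.frame(element = "LINE1", target_assay = "L1-Me",
                     reference_assay = "L1-Ref", formula = choice$choice))
(rs <- recovered_series(panel, cfg))
#>   input_pct recovered_pct n_replicates
#> 1       0.0       0.00000            0
#> 2      12.5      40.14328            2
#> 3      25.0      56.90298            2
#> 4      50.0      73.05922            2
#> 5      75.0      93.14983            2
#> 6     100.0      99.02207            2
classify_bias(rs)
#> <bias_verdict> BIASED
#>   recovered = 21.379 + 0.8914 x input  (R2 0.8679, n 6)
#>   unbiased iff slope in [0.90, 1.10] and |intercept| <= 5
```

Reading the output: the standard curve is tight (R² > 0.999) with a fitted
efficiency of 89.3%, and the ΔCT slope on fully methylated template is flat
— on methylated DNA alone both assays amplify alike, so nothing there
betrays the reference. The mixture panel exposes it: a 12.5% input is
recovered as 40%, because the biased reference under-amplifies the
unmethylated majority of the template and the normalization inflates the
level. The recovered-vs-input regression (intercept 21.4 points) is
classified `BIASED`; an unbiased pair lands on the identity line. With
unbiased assays the same pipeline recovers the generating methylation
exactly in noise-free runs, and fully methylated 200 pg inputs average 100%
under instrument noise.

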