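# Specification objects consumed by the bisulfite-qPCR simulator.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  bad <- x < lower || x > upper ||
    (open_lower && x == lower) || (open_upper && x == upper)
  if (bad) {
    stop("'", name, "' must lie in ",
         if (open_lower) "(" else "[", lower, ", ", upper,
         if (open_upper) ")" else "]", call. = FALSE)
  }
  x
}

.check_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("'", name, "' must be a non-empty string", call. = FALSE)
  }
  x
}

#' Element copy number per picogram of genomic DNA
#'
#' Default copy densities for the two repeat families, derived from 0.303
#' haploid genome equivalents per pg of human DNA and per-genome element
#' counts of 1.5e5 (LINE-1 5'UTR) and 1.1e6 (Alu). These defaults only shift
#' simulated CT intercepts; every relative quantity in the pipeline is
#' invariant to them.
#'
#' @param element `"LINE1"` or `"ALU"`.
#' @return Copies per pg (numeric scalar).
#' @export
#' @examples
#' repeat_copies_per_pg("ALU") / repeat_copies_per_pg("LINE1")
repeat_copies_per_pg <- function(element = c("LINE1", "ALU")) {
  element <- match.arg(element)
  0.303 * switch(element, LINE1 = 1.5e5, ALU = 1.1e6)
}

#' Define a qPCR assay (primer set) with allele-specific efficiencies
#'
#' An assay is either methylation-specific (`MSP`, amplifying only the
#' bisulfite-converted originally-methylated allele, plus an optional
#' cross-reacting fraction of the unmethylated pool) or methylation
#' independent (`MIP`, amplifying every converted template and therefore the
#' normalizing reference). Per-cycle amplification efficiencies may differ
#' between the originally-methylated and originally-unmethylated template
#' pools; an assay is unbiased exactly when `e_meth == e_unmeth`.
#'
#' @param assay_id Assay name, e.g. `"L1-Me"` or `"Alu-Ref"`.
#' @param role `"MSP"` or `"MIP"`.
#' @param element Repeat family targeted, `"LINE1"` or `"ALU"`.
#' @param e_meth Fractional per-cycle efficiency on originally-methylated
#'   template, in (0, 1] (1 = perfect doubling).
#' @param e_unmeth Same for originally-unmethylated template; defaults to
#'   `e_meth` (an unbiased assay).
#' @param cross_reactivity For MSP assays, the fraction in \[0, 1\] of the
#'   converted-unmethylated pool the primers can still amplify (default 0).
#'   MIP assays amplify all converted templates, so the value is fixed at 1.
#' @param threshold_copies Amplicon copy number at which fluorescence crosses
#'   the detection threshold. Must exceed any initial copy number entering a
#'   well; the default 1e12 corresponds to threshold cycles in the 20-30
#'   range for picogram inputs at the default copy densities.
#' @param max_cycles Run length; CTs beyond it are undetermined (default 40).
#' @return An object of class `assay_spec`.
#' @export
#' @examples
#' assay_spec("L1-Me", "MSP", "LINE1", e_meth = 0.94)
#' assay_spec("L1-Ref1", "MIP", "LINE1", e_meth = 0.80, e_unmeth = 0.95)
assay_spec <- function(assay_id, role = c("MSP", "MIP"),
                       element = c("LINE1", "ALU"),
                       e_meth, e_unmeth = e_meth, cross_reactivity = NULL,
                       threshold_copies = 1e12, max_cycles = 40L) {
  role <- match.arg(role)
  element <- match.arg(element)
  .check_string(assay_id, "assay_id")
  .check_number(e_meth, "e_meth", 0, 1, open_lower = TRUE)
  .check_number(e_unmeth, "e_unmeth", 0, 1, open_lower = TRUE)
  .check_number(threshold_copies, "threshold_copies", 0, Inf, open_lower = TRUE)
  max_cycles <- .check_number(max_cycles, "max_cycles", 1, Inf)
  if (role == "MIP") {
    if (!is.null(cross_reactivity) && cross_reactivity != 1) {
      stop("MIP assays amplify every converted template; ",
           "'cross_reactivity' is 1 by definition")
    }
    cross_reactivity <- 1
  } else {
    cross_reactivity <- cross_reactivity %||% 0
    .check_number(cross_reactivity, "cross_reactivity", 0, 1)
  }
  structure(
    list(assay_id = assay_id, role = role, element = element,
         e_meth = e_meth, e_unmeth = e_unmeth,
         cross_reactivity = cross_reactivity,
         threshold_copies = threshold_copies,
         max_cycles = as.numeric(max_cycles)),
    class = "assay_spec")
}

#' @export
print.assay_spec <- function(x, ...) {
  cat(sprintf("<assay_spec> %s [%s, %s]\n", x$assay_id, x$role, x$element))
  cat(sprintf("  efficiency: meth %.3f / unmeth %.3f (%s)\n",
              x$e_meth, x$e_unmeth,
              if (x$e_meth == x$e_unmeth) "unbiased" else "biased"))
  cat(sprintf("  cross-reactivity %.3g, threshold %.3g copies, %g cycles\n",
              x$cross_reactivity, x$threshold_copies, x$max_cycles))
  invisible(x)
}

#' Define a simulated DNA sample entering bisulfite conversion
#'
#' @param sample_id Sample name.
#' @param true_methylation Generating methylation fraction m in \[0, 1\].
#' @param input_mass_pg Mass of DNA entering bisulfite conversion, pg.
#' @param group Free-text group label (default `"control"`).
#' @param copies_per_pg Element copies per pg, or `NULL` (the default) to use
#'   [repeat_copies_per_pg()] for the amplifying assay's element.
#' @param bisulfite_recovery Fraction in (0, 1] of molecules surviving
#'   conversion and clean-up.
#' @param conversion_failure Fraction in \[0, 1) of unmethylated molecules
#'   that read as methylated after conversion, either a number or a function
#'   of `input_mass_pg` (see [saturating_conversion_failure()]).
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, true_methylation, input_mass_pg,
                        group = "control", copies_per_pg = NULL,
                        bisulfite_recovery = 1, conversion_failure = 0) {
  .check_string(sample_id, "sample_id")
  .check_string(group, "group")
  .check_number(true_methylation, "true_methylation", 0, 1)
  .check_number(input_mass_pg, "input_mass_pg", 0, Inf, open_lower = TRUE)
  if (!is.null(copies_per_pg)) {
    .check_number(copies_per_pg, "copies_per_pg", 0, Inf, open_lower = TRUE)
  }
  .check_number(bisulfite_recovery, "bisulfite_recovery", 0, 1,
                open_lower = TRUE)
  if (!is.function(conversion_failure)) {
    .check_number(conversion_failure, "conversion_failure", 0, 1,
                  open_upper = TRUE)
  }
  structure(
    list(sample_id = sample_id, group = group,
         true_methylation = true_methylation,
         input_mass_pg = input_mass_pg, copies_per_pg = copies_per_pg,
         bisulfite_recovery = bisulfite_recovery,
         conversion_failure = conversion_failure),
    class = "sample_spec")
}

#' @export
print.sample_spec <- function(x, ...) {
  cat(sprintf("<sample_spec> %s (group %s): m = %.3f, %g pg\n",
              x$sample_id, x$group, x$true_methylation, x$input_mass_pg))
  invisible(x)
}

#' Simulation settings shared by all generators
#'
#' @param seed Integer seed; every generator calls `set.seed(seed)` on entry,
#'   so repeated calls with the same configuration are bit-reproducible.
#' @param ct_noise_sd Standard deviation of additive Gaussian noise on CT,
#'   in cycles (default 0.1, a typical instrument repeatability; 0 makes the
#'   simulation deterministic).
#' @param n_replicates Wells per sample x assay (default 2, duplicate wells).
#' @param template_fraction Fraction of the bisulfite eluate pipetted into
#'   one PCR well (default 2/20, i.e. 2 uL out of a 20 uL eluate).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ct_noise_sd = 0.1, n_replicates = 2L,
                       template_fraction = 2 / 20) {
  seed <- as.integer(.check_number(seed, "seed"))
  .check_number(ct_noise_sd, "ct_noise_sd", 0, Inf)
  n_replicates <- as.integer(.check_number(n_replicates, "n_replicates",
                                           1, Inf))
  .check_number(template_fraction, "template_fraction", 0, 1,
                open_lower = TRUE)
  structure(
    list(seed = seed, ct_noise_sd = ct_noise_sd,
         n_replicates = n_replicates, template_fraction = template_fraction),
    class = "sim_config")
}

#' Mass-dependent bisulfite conversion failure
#'
#' Returns a saturating function of input mass, `f_max * mass / (mass + K)`,
#' usable as the `conversion_failure` field of a [sample_spec()]. It emulates
#' the loss of conversion fidelity when the bisulfite reaction is overloaded
#' with DNA: negligible failure at picogram inputs, approaching `f_max` at
#' masses far above the half-saturation constant `K`.
#'
#' @param f_max Asymptotic failure fraction in \[0, 1) (default 0.15).
#' @param K Half-saturation mass in pg (default 5000, i.e. 5 ng).
#' @return A function of mass (pg) returning a failure fraction.
#' @export
saturating_conversion_failure <- function(f_max = 0.15, K = 5000) {
  .check_number(f_max, "f_max", 0, 1, open_upper = TRUE)
  .check_number(K, "K", 0, Inf, open_lower = TRUE)
  function(mass_pg) f_max * mass_pg / (mass_pg + K)
}

#' Truncated-normal methylation distribution for cohort simulation
#'
#' Builds a quantile function mapping Unif(0,1) draws to methylation
#' fractions, normal with the given mean and sd, clamped to \[0, 1\]. Using
#' quantile functions lets paired cohort groups share latent draws, so that
#' two groups with identical distributions yield exactly matched pairs.
#'
#' @param mean,sd Location and spread of the methylation fraction.
#' @return A function of probabilities.
#' @export
methylation_dist <- function(mean, sd) {
  .check_number(mean, "mean")
  .check_number(sd, "sd", 0, Inf)
  function(p) pmin(pmax(stats::qnorm(p, mean, sd), 0), 1)
}
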