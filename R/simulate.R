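# Mechanistic generators: bisulfite conversion -> two-allele amplification
# -> CT readout, for dilution series, defined-methylation mixture panels and
# two-group cohorts.

# Partition the post-conversion template of one well into the
# methylated-origin and unmethylated-origin pools seen by an assay.
.initial_copies <- function(sample, assay, config) {
  m <- sample$true_methylation
  cf <- sample$conversion_failure
  if (is.function(cf)) cf <- cf(sample$input_mass_pg)
  cpp <- sample$copies_per_pg %||% repeat_copies_per_pg(assay$element)
  n_tot <- sample$input_mass_pg * cpp * sample$bisulfite_recovery *
    config$template_fraction
  n_m <- n_tot * (m + (1 - m) * cf)
  n_u <- n_tot * (1 - m) * (1 - cf)
  if (assay$role == "MSP") n_u <- n_u * assay$cross_reactivity
  list(n_m = n_m, n_u = n_u)
}

.well_row <- function(sample, assay, replicate, ct) {
  data.frame(sample_id = sample$sample_id, assay_id = assay$assay_id,
             replicate = as.integer(replicate), ct = ct,
             input_mass_pg = sample$input_mass_pg, group = sample$group,
             stringsAsFactors = FALSE)
}

.as_ct_table <- function(rows, truth = NULL) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  if (!is.null(truth)) attr(out, "truth") <- truth
  out
}

#' Simulate one qPCR well
#'
#' Computes the per-well template pools (eluate fraction, conversion-failure
#' reassignment of unmethylated molecules, MSP cross-reactivity weighting),
#' solves the mixture amplification kinetics for the threshold cycle, adds
#' Gaussian CT noise, and truncates to undetermined (`NA`) beyond the
#' assay's run length. Uses the current RNG state; the higher-level
#' generators seed it from their configuration.
#'
#' @param sample A [sample_spec()].
#' @param assay An [assay_spec()].
#' @param config A [sim_config()].
#' @param replicate Replicate index recorded in the well.
#' @return One-row data.frame with columns `sample_id`, `assay_id`,
#'   `replicate`, `ct` (`NA` when undetermined), `input_mass_pg`, `group`.
#' @export
simulate_well <- function(sample, assay, config = sim_config(),
                          replicate = 1L) {
  stopifnot(inherits(sample, "sample_spec"), inherits(assay, "assay_spec"),
            inherits(config, "sim_config"))
  pools <- .initial_copies(sample, assay, config)
  ct <- tryCatch(
    mixture_ct(pools$n_m, pools$n_u, assay$e_meth, assay$e_unmeth,
               assay$threshold_copies),
    qmspr_no_template = function(cnd) NA_real_)
  if (!is.na(ct) && config$ct_noise_sd > 0) {
    ct <- ct + stats::rnorm(1L, 0, config$ct_noise_sd)
  }
  if (!is.na(ct) && ct > assay$max_cycles) ct <- NA_real_
  .well_row(sample, assay, replicate, ct)
}

.simulate_sample_wells <- function(samples, assays, config) {
  rows <- vector("list", length(samples) * length(assays) *
                   config$n_replicates)
  k <- 0L
  for (sample in samples) {
    for (assay in assays) {
      for (r in seq_len(config$n_replicates)) {
        k <- k + 1L
        rows[[k]] <- simulate_well(sample, assay, config, r)
      }
    }
  }
  rows
}

#' Simulate a fully methylated standard-curve dilution series
#'
#' Generates `n_replicates` wells per input mass for one assay on fully
#' methylated template, the design used to fit standard curves and estimate
#' amplification efficiency. The default mass grid is a serial dilution from
#' 1000 pg down to 3.125 pg.
#'
#' @param assay An [assay_spec()].
#' @param masses_pg Positive input masses in pg; processed in descending
#'   order.
#' @param config A [sim_config()]; its seed is applied on entry.
#' @return A `ct_table` data.frame of wells (group `"standard"`).
#' @export
#' @examples
#' a <- assay_spec("L1-Ref", "MIP", "LINE1", e_meth = 0.9)
#' std <- simulate_dilution_series(a, config = sim_config(ct_noise_sd = 0))
#' fit_standard_curve(std)
simulate_dilution_series <- function(assay,
                                     masses_pg = c(1000, 250, 62.5,
                                                   15.625, 3.125),
                                     config = sim_config()) {
  stopifnot(inherits(assay, "assay_spec"), inherits(config, "sim_config"))
  if (length(masses_pg) == 0L) {
    stop("at least one input mass is required")
  }
  if (!is.numeric(masses_pg) || any(!is.finite(masses_pg)) ||
      any(masses_pg <= 0)) {
    stop("all input masses must be positive finite numbers")
  }
  masses_pg <- sort(unique(masses_pg), decreasing = TRUE)
  set.seed(config$seed)
  samples <- lapply(masses_pg, function(mass) {
    sample_spec(sprintf("std_%gpg", mass), true_methylation = 1,
                input_mass_pg = mass, group = "standard")
  })
  .as_ct_table(.simulate_sample_wells(samples, list(assay), config))
}

#' Simulate a defined-methylation mixture panel
#'
#' Emulates control samples created by mixing fully methylated and fully
#' unmethylated DNA to defined methylation levels, bisulfite-converted and
#' amplified with one MSP and one MIP assay -- the design used to assess PCR
#' amplification bias. A fully methylated calibrator sample is always
#' emitted alongside the panel.
#'
#' @param msp,mip [assay_spec()]s with roles `"MSP"` and `"MIP"`.
#' @param levels_pct Input methylation levels in percent, within \[0, 100\].
#' @param mass_pg DNA mass per control sample entering conversion
#'   (default 200 pg).
#' @param config A [sim_config()]; its seed is applied on entry.
#' @param calibrator_id Sample id of the emitted 100% calibrator.
#' @return A `ct_table` with an attached `truth` attribute (data.frame of
#'   `sample_id`, `group`, `true_methylation`).
#' @export
simulate_mixture_panel <- function(msp, mip,
                                   levels_pct = c(0, 12.5, 25, 50, 75, 100),
                                   mass_pg = 200, config = sim_config(),
                                   calibrator_id = "CAL") {
  stopifnot(inherits(msp, "assay_spec"), inherits(mip, "assay_spec"),
            inherits(config, "sim_config"))
  if (msp$role != "MSP" || mip$role != "MIP") {
    stop("'msp' must have role MSP and 'mip' role MIP")
  }
  if (length(levels_pct) == 0L || !is.numeric(levels_pct) ||
      any(!is.finite(levels_pct)) ||
      any(levels_pct < 0 | levels_pct > 100)) {
    stop("mixture levels must lie in [0, 100] percent")
  }
  .check_number(mass_pg, "mass_pg", 0, Inf, open_lower = TRUE)
  set.seed(config$seed)
  samples <- lapply(sort(unique(levels_pct), decreasing = TRUE),
                    function(level) {
    sample_spec(sprintf("mix%06.2f", level), true_methylation = level / 100,
                input_mass_pg = mass_pg, group = "mixture")
  })
  samples <- c(samples,
               list(sample_spec(calibrator_id, true_methylation = 1,
                                input_mass_pg = mass_pg,
                                group = "calibrator")))
  truth <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    group = vapply(samples, `[[`, "", "group"),
    true_methylation = vapply(samples, `[[`, 0, "true_methylation"),
    stringsAsFactors = FALSE)
  .as_ct_table(.simulate_sample_wells(samples, list(msp, mip), config),
               truth = truth)
}

#' Simulate a multi-group cohort with per-sample methylation draws
#'
#' Each group is a list with fields `label`, `n`, `methylation` (a fraction,
#' or a quantile function of Unif(0,1) draws such as [methylation_dist()]),
#' and optionally `mass_pg` (number or quantile function, default 200),
#' `bisulfite_recovery` and `conversion_failure`. Every sample is amplified
#' with every supplied assay, `n_replicates` wells each -- with one MSP and
#' one MIP assay per element that is the study's four reactions per sample.
#' When `paired = TRUE` all groups must have equal `n` and share the latent
#' uniform draws, so samples with the same index form a matched pair and
#' identical group distributions give identical pairs.
#'
#' @param groups List of group definitions (see Details above).
#' @param assays List of [assay_spec()]s.
#' @param config A [sim_config()]; its seed is applied on entry.
#' @param paired Should groups share latent draws pairwise?
#' @param include_calibrator Emit a fully methylated calibrator sample
#'   (id `calibrator_id`, group `"calibrator"`)?
#' @param calibrator_id,calibrator_mass_pg Calibrator identity and mass.
#' @return A `ct_table` with a `truth` attribute giving each sample's
#'   generating methylation fraction.
#' @export
simulate_cohort <- function(groups, assays, config = sim_config(),
                            paired = FALSE, include_calibrator = TRUE,
                            calibrator_id = "CAL",
                            calibrator_mass_pg = 200) {
  stopifnot(is.list(groups), length(groups) >= 1L, is.list(assays),
            length(assays) >= 1L, inherits(config, "sim_config"))
  for (a in assays) stopifnot(inherits(a, "assay_spec"))
  ns <- vapply(groups, function(g) {
    n <- g$n %||% stop("each group needs an 'n'")
    as.integer(.check_number(n, "n", 1, Inf))
  }, 1L)
  if (paired && length(unique(ns)) != 1L) {
    stop("paired groups must have equal sample sizes")
  }
  set.seed(config$seed)
  p_shared <- if (paired) stats::runif(ns[1]) else NULL
  samples <- list()
  for (g in groups) {
    label <- .check_string(g$label %||% stop("each group needs a 'label'"),
                           "label")
    n <- as.integer(g$n)
    p <- p_shared %||% stats::runif(n)
    mfun <- g$methylation %||% stop("each group needs a 'methylation'")
    m <- if (is.function(mfun)) mfun(p) else rep(mfun, n)
    if (any(!is.finite(m)) || any(m < 0 | m > 1)) {
      stop("group '", label, "': methylation draws must lie in [0, 1]")
    }
    massfun <- g$mass_pg %||% 200
    mass <- if (is.function(massfun)) massfun(stats::runif(n))
            else rep(massfun, n)
    for (i in seq_len(n)) {
      samples[[length(samples) + 1L]] <- sample_spec(
        sprintf("%s_%03d", label, i), true_methylation = m[i],
        input_mass_pg = mass[i], group = label,
        bisulfite_recovery = g$bisulfite_recovery %||% 1,
        conversion_failure = g$conversion_failure %||% 0)
    }
  }
  if (include_calibrator) {
    samples[[length(samples) + 1L]] <- sample_spec(
      calibrator_id, true_methylation = 1,
      input_mass_pg = calibrator_mass_pg, group = "calibrator")
  }
  truth <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    group = vapply(samples, `[[`, "", "group"),
    true_methylation = vapply(samples, `[[`, 0, "true_methylation"),
    stringsAsFactors = FALSE)
  .as_ct_table(.simulate_sample_wells(samples, assays, config),
               truth = truth)
}
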