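# Standard-curve calibration: amplification efficiency, R-squared, CT
# cutoffs at the limit-of-detection mass, and the delta-CT slope rule that
# chooses between the Livak and Pfaffl quantification formulas.

#' Fit a standard curve from dilution-series wells
#'
#' Ordinary least squares of CT on log10(input mass, pg) for one assay.
#' The amplification efficiency is recovered from the slope as
#' `E(%) = 100 * (10^(-1/slope) - 1)`; a perfectly doubling assay has slope
#' -1/log10(2) = -3.3219 and 100% efficiency. Undetermined wells are
#' excluded from the fit but counted, and the limit-of-detection mass
#' defaults to the smallest mass at which every replicate amplified; the CT
#' cutoff is the fitted line's prediction at that mass (the observed mean CT
#' there is reported alongside).
#'
#' @param wells Dilution-series wells (one assay) as produced by
#'   [simulate_dilution_series()] or [read_ct_table()].
#' @return An object of class `standard_curve_fit` with fields `assay_id`,
#'   `slope`, `intercept`, `r2`, `efficiency_pct`, `n_points`,
#'   `n_undetermined`, `lod_mass_pg`, `ct_cutoff`, `ct_cutoff_observed`,
#'   `mass_range` and `flagged` (`TRUE` when the slope is non-negative and
#'   the efficiency therefore undefined).
#' @export
fit_standard_curve <- function(wells) {
  wells <- as.data.frame(wells)
  ids <- unique(wells$assay_id)
  if (length(ids) != 1L) {
    stop("wells must come from a single assay (got ",
         length(ids), ")")
  }
  det <- wells[!is.na(wells$ct), , drop = FALSE]
  if (length(unique(det$input_mass_pg)) < 3L) {
    stop("need determined CTs at >= 3 distinct input masses")
  }
  fit <- stats::lm(ct ~ log10(input_mass_pg), data = det)
  cf <- unname(stats::coef(fit))
  slope <- cf[2]
  flagged <- !is.finite(slope) || slope >= 0
  if (flagged) {
    warning("non-negative standard-curve slope; efficiency undefined")
  }
  # suppressWarnings: a noise-free series fits exactly and summary.lm warns
  r2 <- suppressWarnings(summary(fit)$r.squared)
  all_det <- tapply(!is.na(wells$ct), wells$input_mass_pg, all)
  full_masses <- as.numeric(names(all_det))[all_det]
  lod <- if (length(full_masses)) min(full_masses) else min(det$input_mass_pg)
  structure(list(
    assay_id = ids, slope = slope, intercept = cf[1],
    r2 = r2,
    efficiency_pct = if (flagged) NA_real_ else 100 * (10^(-1 / slope) - 1),
    n_points = nrow(det), n_undetermined = sum(is.na(wells$ct)),
    lod_mass_pg = lod,
    ct_cutoff = cf[1] + slope * log10(lod),
    ct_cutoff_observed = mean(det$ct[det$input_mass_pg == lod]),
    mass_range = range(det$input_mass_pg), flagged = flagged),
    class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf("<standard_curve_fit> %s\n", x$assay_id))
  cat(sprintf("  CT = %.4f %+.4f x log10(pg)   (n = %d, undetermined %d)\n",
              x$intercept, x$slope, x$n_points, x$n_undetermined))
  cat(sprintf("  R2 = %.5f, efficiency = %s%%\n", x$r2,
              if (is.na(x$efficiency_pct)) "NA"
              else sprintf("%.2f", x$efficiency_pct)))
  cat(sprintf("  CT cutoff %.2f (observed %.2f) at LOD %g pg\n",
              x$ct_cutoff, x$ct_cutoff_observed, x$lod_mass_pg))
  invisible(x)
}

#' Predicted CT cutoff at a limit-of-detection mass
#'
#' The maximum CT accepted as genuine detection, read off the fitted
#' standard curve at the given mass; any CT above it is treated as false.
#' Decreasing the LOD mass raises the cutoff monotonically (for an
#' amplifying assay with negative slope).
#'
#' @param fit A [fit_standard_curve()] result.
#' @param lod_mass_pg Mass within the fitted range.
#' @return Cutoff in cycles.
#' @export
determine_ct_cutoff <- function(fit, lod_mass_pg) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  .check_number(lod_mass_pg, "lod_mass_pg", 0, Inf, open_lower = TRUE)
  if (lod_mass_pg < fit$mass_range[1] || lod_mass_pg > fit$mass_range[2]) {
    stop("lod_mass_pg ", lod_mass_pg, " outside the fitted mass range [",
         fit$mass_range[1], ", ", fit$mass_range[2], "]")
  }
  unname(fit$intercept + fit$slope * log10(lod_mass_pg))
}

#' Choose the Livak or Pfaffl formula from paired dilution series
#'
#' Per input mass, replicate CTs are averaged and the difference
#' `dCT = mean CT(MIP) - mean CT(MSP)` is regressed on log10(mass). A flat
#' dCT (absolute slope below `slope_threshold` with a non-significant slope
#' t-test) means the two assays amplify at matched efficiencies, so the
#' efficiency terms cancel and the Livak delta-delta-CT formula applies;
#' otherwise the efficiency-corrected Pfaffl formula is selected. For a
#' noise-free series the regression is exact and its p-value undefined; the
#' decision then rests on the slope magnitude alone.
#'
#' @param msp_wells,mip_wells Dilution series over identical mass grids.
#' @param slope_threshold Cycles per log10(pg); default 0.1.
#' @param alpha Significance level for the slope t-test; default 0.05.
#' @return An object of class `formula_choice` with `dct_slope`, `p_value`
#'   and `choice` (`"LIVAK"` or `"PFAFFL"`).
#' @export
select_formula <- function(msp_wells, mip_wells, slope_threshold = 0.1,
                           alpha = 0.05) {
  msp_wells <- as.data.frame(msp_wells)
  mip_wells <- as.data.frame(mip_wells)
  per_mass <- function(w) {
    w <- w[!is.na(w$ct), , drop = FALSE]
    tapply(w$ct, w$input_mass_pg, mean)
  }
  a <- per_mass(msp_wells)
  b <- per_mass(mip_wells)
  if (!setequal(names(a), names(b))) {
    stop("the MSP and MIP series must cover identical mass grids")
  }
  mass <- as.numeric(names(a))
  if (length(mass) < 3L) stop("need >= 3 distinct masses")
  dct <- as.numeric(b[names(a)]) - as.numeric(a)
  fit <- stats::lm(dct ~ log10(mass))
  # a noise-free series fits exactly; summary.lm warns and its p is NaN
  sm <- suppressWarnings(summary(fit)$coefficients)
  slope <- unname(stats::coef(fit)[2])
  p <- if (nrow(sm) >= 2) unname(sm[2, 4]) else NaN
  if (!is.finite(p)) p <- NA_real_
  livak <- abs(slope) < slope_threshold && (is.na(p) || p > alpha)
  structure(list(dct_slope = slope, p_value = p,
                 choice = if (livak) "LIVAK" else "PFAFFL",
                 slope_threshold = slope_threshold, alpha = alpha,
                 n_masses = length(mass)),
            class = "formula_choice")
}

#' @export
print.formula_choice <- function(x, ...) {
  cat(sprintf(
    "<formula_choice> %s  (dCT slope %.4f, p %s; |slope| < %g and p > %g => LIVAK)\n",
    x$choice, x$dct_slope,
    if (is.na(x$p_value)) "NA" else sprintf("%.3g", x$p_value),
    x$slope_threshold, x$alpha))
  invisible(x)
}
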