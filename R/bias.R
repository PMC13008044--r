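# PCR amplification bias assessment: quantify a defined-methylation mixture
# panel, regress recovered against input methylation, classify the MSP+MIP
# assay pair as biased or unbiased.

#' Recovered-versus-input methylation series from a mixture panel
#'
#' Quantifies each defined-methylation control sample against the panel's
#' fully methylated calibrator with the configured formula and pairs the
#' recovered level (unrounded) with the known input level. `ZERO_SIGNAL`
#' samples (no methylation-specific signal at the 0% level) enter as
#' recovered 0 by default; `EXCLUDED` samples are dropped.
#'
#' @param wells Mixture-panel wells, e.g. from [simulate_mixture_panel()].
#' @param config A [run_config()] declaring exactly one target/reference
#'   pair. The calibrator must be present in `wells`.
#' @param choices Formula choices for `"AUTO"` pairs (see
#'   [quantify_samples()]).
#' @param truth Data.frame mapping `sample_id` to `true_methylation`;
#'   defaults to the `truth` attribute the simulator attaches.
#' @param drop_zero_signal Drop `ZERO_SIGNAL` points instead of scoring
#'   them as recovered 0?
#' @return Data.frame with `input_pct`, `recovered_pct`, `n_replicates`,
#'   sorted by input level.
#' @export
recovered_series <- function(wells, config, choices = NULL,
                             truth = attr(wells, "truth"),
                             drop_zero_signal = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (nrow(config$pairs) != 1L) {
    stop("'config' must declare exactly one target/reference pair")
  }
  if (is.null(truth)) {
    stop("no generating truth available; supply 'truth' with sample_id ",
         "and true_methylation")
  }
  res <- quantify_samples(wells, config, choices)
  res <- res[res$group != "calibrator", , drop = FALSE]
  if (drop_zero_signal) {
    res <- res[res$status != "ZERO_SIGNAL", , drop = FALSE]
  }
  res <- res[res$status != "EXCLUDED", , drop = FALSE]
  i <- match(res$sample_id, truth$sample_id)
  if (anyNA(i)) stop("samples missing from 'truth'")
  out <- data.frame(input_pct = 100 * truth$true_methylation[i],
                    recovered_pct = res$methylation_pct,
                    n_replicates = res$n_used_target,
                    stringsAsFactors = FALSE)
  out <- out[order(out$input_pct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an assay pair as biased or unbiased
#'
#' Ordinary least squares of recovered on input methylation. The pair is
#' `UNBIASED` when the slope lies within `1 +/- slope_tol` and the intercept
#' within `+/- intercept_tol` percentage points -- an operational version of
#' the visual "recovered nearly identical to input" criterion; anything else
#' is `BIASED`. Requires at least 4 points spanning at least 50 percentage
#' points of input.
#'
#' @param series A [recovered_series()] data.frame.
#' @param slope_tol Allowed slope deviation from 1 (default 0.1).
#' @param intercept_tol Allowed absolute intercept, percentage points
#'   (default 5).
#' @return An object of class `bias_verdict` with regression diagnostics
#'   and per-point deviations.
#' @export
classify_bias <- function(series, slope_tol = 0.1, intercept_tol = 5) {
  series <- as.data.frame(series)
  stopifnot(all(c("input_pct", "recovered_pct") %in% names(series)))
  .check_number(slope_tol, "slope_tol", 0, Inf)
  .check_number(intercept_tol, "intercept_tol", 0, Inf)
  if (nrow(series) < 4L) stop("need >= 4 recovered-vs-input points")
  span <- diff(range(series$input_pct))
  if (span == 0) stop("degenerate series: all input levels identical")
  if (span < 50) {
    stop("input levels must span >= 50 percentage points (got ", span, ")")
  }
  fit <- stats::lm(recovered_pct ~ input_pct, data = series)
  cf <- unname(stats::coef(fit))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  verdict <- if (abs(cf[2] - 1) <= slope_tol &&
                 abs(cf[1]) <= intercept_tol) "UNBIASED" else "BIASED"
  structure(list(slope = cf[2], intercept = cf[1],
                 r2 = r2, verdict = verdict,
                 slope_tol = slope_tol, intercept_tol = intercept_tol,
                 n_points = nrow(series),
                 deviations = series$recovered_pct - series$input_pct,
                 series = series),
            class = "bias_verdict")
}

#' @export
print.bias_verdict <- function(x, ...) {
  cat(sprintf("<bias_verdict> %s\n", x$verdict))
  cat(sprintf(
    "  recovered = %.3f + %.4f x input  (R2 %.4f, n %d)\n",
    x$intercept, x$slope, x$r2, x$n_points))
  cat(sprintf("  unbiased iff slope in [%.2f, %.2f] and |intercept| <= %g\n",
              1 - x$slope_tol, 1 + x$slope_tol, x$intercept_tol))
  invisible(x)
}
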