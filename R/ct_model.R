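# Exponential amplification kinetics: the closed-form single-allele CT and
# the two-allele mixture CT that underlie all standard-curve algebra.

.signal_no_template <- function() {
  stop(errorCondition("no amplifiable template in reaction",
                      class = c("qmspr_no_template", "error", "condition")))
}

#' Threshold cycle of a single exponentially amplifying template pool
#'
#' With `n0` starting copies amplified at per-cycle efficiency `e`, the
#' amplicon count after `t` cycles is `n0 * (1 + e)^t`; the continuous cycle
#' number at which it reaches the detection threshold `q` is
#' `t = log(q / n0) / log(1 + e)`.
#'
#' @param n0 Initial copy number (> 0; a non-positive value signals a
#'   no-template condition of class `qmspr_no_template`, which
#'   [simulate_well()] maps to an undetermined CT).
#' @param e Fractional per-cycle efficiency in (0, 1].
#' @param q Detection threshold in copies; must exceed `n0`.
#' @return Continuous cycle number (numeric scalar).
#' @seealso [mixture_ct()]
#' @export
#' @examples
#' closed_form_ct(1000, 1.0, 1024000) # exactly 10 cycles of doubling
closed_form_ct <- function(n0, e, q) {
  .check_number(e, "e", 0, 1, open_lower = TRUE)
  .check_number(q, "q", 0, Inf, open_lower = TRUE)
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0)) {
    stop("'n0' must be a single finite number")
  }
  if (n0 <= 0) .signal_no_template()
  if (q <= n0) {
    stop("detection threshold 'q' must exceed the initial copy number")
  }
  log(q / n0) / log1p(e)
}

#' Threshold cycle of a two-allele template mixture
#'
#' Solves for the unique `t` with
#' `n_m * (1 + e_m)^t + n_u * (1 + e_u)^t = q`,
#' the cycle at which the summed amplicons of the originally-methylated and
#' originally-unmethylated pools cross the detection threshold. When the two
#' efficiencies differ the faster pool progressively dominates the reaction;
#' this is the mechanism by which allele-preferential (biased) primers
#' distort recovered methylation. The root is bracketed between the CTs
#' obtained by amplifying the combined pool at the faster and at the slower
#' efficiency and located to an absolute tolerance of 1e-9 cycles; when one
#' pool is empty the closed form applies.
#'
#' @param n_m,n_u Initial copies of the methylated-origin and
#'   unmethylated-origin pools (both zero signals `qmspr_no_template`).
#' @param e_m,e_u Fractional per-cycle efficiencies in (0, 1].
#' @param q Detection threshold in copies; must exceed `n_m + n_u`.
#' @param tol Absolute tolerance on the returned cycle number.
#' @return Continuous cycle number (numeric scalar).
#' @export
#' @examples
#' # equal efficiencies collapse to the single-pool closed form
#' mixture_ct(500, 500, 0.9, 0.9, 1e7)
#' closed_form_ct(1000, 0.9, 1e7)
mixture_ct <- function(n_m, n_u, e_m, e_u, q, tol = 1e-9) {
  if (!is.numeric(n_m) || length(n_m) != 1L || !is.finite(n_m) ||
      !is.numeric(n_u) || length(n_u) != 1L || !is.finite(n_u)) {
    stop("'n_m' and 'n_u' must be single finite numbers")
  }
  if (n_m <= 0 && n_u <= 0) .signal_no_template()
  if (n_m <= 0) return(closed_form_ct(n_u, e_u, q))
  if (n_u <= 0) return(closed_form_ct(n_m, e_m, q))
  .check_number(e_m, "e_m", 0, 1, open_lower = TRUE)
  .check_number(e_u, "e_u", 0, 1, open_lower = TRUE)
  .check_number(q, "q", 0, Inf, open_lower = TRUE)
  n0 <- n_m + n_u
  if (q <= n0) {
    stop("detection threshold 'q' must exceed the total initial copy number")
  }
  t_fast <- log(q / n0) / log1p(max(e_m, e_u))
  t_slow <- log(q / n0) / log1p(min(e_m, e_u))
  if (t_slow - t_fast < tol) return((t_fast + t_slow) / 2)
  f <- function(t) n_m * (1 + e_m)^t + n_u * (1 + e_u)^t - q
  stats::uniroot(f, lower = t_fast, upper = t_slow,
                 tol = min(tol, 1e-9) / 10)$root
}
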