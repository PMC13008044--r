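# Calibrator-normalized relative methylation: replicate aggregation with
# CT-cutoff exclusion, the Livak and Pfaffl formulas, and the per-sample
# quantification driver.

#' Aggregate replicate CTs under a CT cutoff
#'
#' The mean of determined CTs at or below the cutoff. A sample x assay is
#' excluded only when every replicate is undetermined or above the cutoff;
#' when a single replicate passes it is used alone and the result flagged
#' for audit.
#'
#' @param cts Numeric replicate CTs (`NA` = undetermined).
#' @param ct_cutoff Maximum CT accepted as genuine detection (default `Inf`,
#'   no cutoff).
#' @return A list with `mean_ct`, `n_used`, `n_total`, `excluded`,
#'   `flagged`, `reason`.
#' @export
#' @examples
#' aggregate_replicates(c(31.0, 30.5), ct_cutoff = 30.25) # excluded
#' aggregate_replicates(c(29.9, 31.0), ct_cutoff = 30.25) # one-sided pass
aggregate_replicates <- function(cts, ct_cutoff = Inf) {
  if (!is.numeric(cts) || length(cts) < 1L) {
    stop("'cts' must be a non-empty numeric vector")
  }
  if (!is.numeric(ct_cutoff) || length(ct_cutoff) != 1L || is.na(ct_cutoff)) {
    stop("'ct_cutoff' must be a single number (Inf disables the cutoff)")
  }
  pass <- !is.na(cts) & cts <= ct_cutoff
  if (!any(pass)) {
    return(list(mean_ct = NA_real_, n_used = 0L, n_total = length(cts),
                excluded = TRUE, flagged = FALSE,
                reason = "all replicates undetermined or above CT cutoff"))
  }
  list(mean_ct = mean(cts[pass]), n_used = sum(pass),
       n_total = length(cts), excluded = FALSE,
       flagged = sum(pass) < length(cts),
       reason = if (sum(pass) < length(cts)) {
         "replicate(s) undetermined or above CT cutoff; remainder used"
       } else "")
}

.check_ct <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("undetermined CT '", name, "': level not computable",
         call. = FALSE)
  }
  x
}

#' Livak (delta-delta-CT) relative methylation level
#'
#' `100 * 2^-((ct_me_s - ct_ref_s) - (ct_me_cal - ct_ref_cal))`, the
#' comparative-CT ratio under an assumed per-cycle doubling, on the percent
#' scale set by the fully methylated calibrator. Values above 100% are legal
#' and preserved.
#'
#' @param ct_me_s,ct_ref_s Sample mean CTs for the methylation-specific and
#'   reference assays.
#' @param ct_me_cal,ct_ref_cal Calibrator mean CTs for the same assays.
#' @return Methylation level in percent.
#' @export
#' @examples
#' livak_level(26, 20, 25, 20) # one extra target cycle -> 50%
livak_level <- function(ct_me_s, ct_ref_s, ct_me_cal, ct_ref_cal) {
  .check_ct(ct_me_s, "ct_me_s"); .check_ct(ct_ref_s, "ct_ref_s")
  .check_ct(ct_me_cal, "ct_me_cal"); .check_ct(ct_ref_cal, "ct_ref_cal")
  100 * 2^(-((ct_me_s - ct_ref_s) - (ct_me_cal - ct_ref_cal)))
}

#' Pfaffl efficiency-corrected relative methylation level
#'
#' `100 * (1+e_me)^(ct_me_cal - ct_me_s) / (1+e_ref)^(ct_ref_cal - ct_ref_s)`
#' with each amplicon's own fitted fractional efficiency; collapses to the
#' Livak formula when both efficiencies are 1.
#'
#' @param ct_me_s,ct_me_cal Sample and calibrator mean CTs of the
#'   methylation-specific assay.
#' @param e_me,e_ref Fractional efficiencies in (0, 1\] from the standard
#'   curves.
#' @param ct_ref_s,ct_ref_cal Sample and calibrator mean CTs of the
#'   reference assay.
#' @return Methylation level in percent.
#' @export
#' @examples
#' pfaffl_level(26, 25, 0.9, 20, 20, 0.85) # 100 / 1.9
pfaffl_level <- function(ct_me_s, ct_me_cal, e_me,
                         ct_ref_s, ct_ref_cal, e_ref) {
  .check_ct(ct_me_s, "ct_me_s"); .check_ct(ct_me_cal, "ct_me_cal")
  .check_ct(ct_ref_s, "ct_ref_s"); .check_ct(ct_ref_cal, "ct_ref_cal")
  .check_number(e_me, "e_me", 0, 1, open_lower = TRUE)
  .check_number(e_ref, "e_ref", 0, 1, open_lower = TRUE)
  100 * (1 + e_me)^(ct_me_cal - ct_me_s) /
    (1 + e_ref)^(ct_ref_cal - ct_ref_s)
}

#' Quantify relative methylation for every sample in a CT table
#'
#' For each configured target/reference pair, replicates are aggregated
#' under the assay CT cutoffs, the calibrator's mean CTs anchor the 100%
#' level, and the configured formula (or the [select_formula()] choice for
#' `"AUTO"` pairs) converts CT differences to percent methylation.
#' Per-sample outcomes: `OK` (level computed; above 100% is preserved),
#' `ZERO_SIGNAL` (no accepted methylation-specific signal but a valid
#' reference: reported as 0%, the limiting value as methylated copies
#' vanish), or `EXCLUDED` (reference wells all undetermined or above the
#' cutoff; no level reported).
#'
#' @param tbl A `ct_table` of wells.
#' @param config A [run_config()]. An undetermined calibrator for any used
#'   assay is a hard error.
#' @param choices Named list of [select_formula()] results keyed
#'   `"<target_assay>|<reference_assay>"`, required for `"AUTO"` pairs.
#' @return A `methylation_result` data.frame, one row per sample x pair,
#'   ordered by (element, reference assay, sample) so the output is
#'   invariant to input row order.
#' @export
quantify_samples <- function(tbl, config, choices = NULL) {
  tbl <- as.data.frame(tbl)
  stopifnot(inherits(config, "run_config"))
  cal <- config$calibrator_id
  if (!cal %in% tbl$sample_id) {
    stop("calibrator sample '", cal, "' absent from the CT table")
  }
  assays <- config$assays
  arow <- function(id) {
    i <- match(id, assays$assay_id)
    if (is.na(i)) stop("assay '", id, "' not declared in the configuration")
    assays[i, , drop = FALSE]
  }
  out <- list()
  for (k in seq_len(nrow(config$pairs))) {
    p <- config$pairs[k, , drop = FALSE]
    formula <- p$formula
    if (formula == "AUTO") {
      key <- paste(p$target_assay, p$reference_assay, sep = "|")
      ch <- choices[[key]]
      if (is.null(ch)) {
        stop("pair ", key, " has formula AUTO but no formula_choice ",
             "was supplied")
      }
      formula <- ch$choice
    }
    ta <- arow(p$target_assay)
    ra <- arow(p$reference_assay)
    cut_t <- if (is.na(ta$ct_cutoff)) Inf else ta$ct_cutoff
    cut_r <- if (is.na(ra$ct_cutoff)) Inf else ra$ct_cutoff
    if (formula == "PFAFFL" &&
        (is.na(ta$efficiency) || is.na(ra$efficiency))) {
      stop("PFAFFL requires fitted efficiencies for assays ",
           ta$assay_id, " and ", ra$assay_id)
    }
    wells_of <- function(s, a) tbl$ct[tbl$sample_id == s & tbl$assay_id == a]
    cal_t <- aggregate_replicates(wells_of(cal, p$target_assay))
    cal_r <- aggregate_replicates(wells_of(cal, p$reference_assay))
    if (cal_t$excluded || cal_r$excluded) {
      stop("calibrator '", cal, "' has no determined CT for assay ",
           if (cal_t$excluded) p$target_assay else p$reference_assay)
    }
    for (s in sort(setdiff(unique(tbl$sample_id), cal))) {
      ct_t <- wells_of(s, p$target_assay)
      ct_r <- wells_of(s, p$reference_assay)
      if (!length(ct_t) || !length(ct_r)) next
      at <- aggregate_replicates(ct_t, cut_t)
      ar <- aggregate_replicates(ct_r, cut_r)
      grp <- tbl$group[tbl$sample_id == s][1]
      if (ar$excluded) {
        status <- "EXCLUDED"; pct <- NA_real_
      } else if (at$excluded) {
        status <- "ZERO_SIGNAL"; pct <- 0
      } else {
        status <- "OK"
        pct <- if (formula == "LIVAK") {
          livak_level(at$mean_ct, ar$mean_ct, cal_t$mean_ct, cal_r$mean_ct)
        } else {
          pfaffl_level(at$mean_ct, cal_t$mean_ct, ta$efficiency,
                       ar$mean_ct, cal_r$mean_ct, ra$efficiency)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, group = grp, element = p$element,
        target_assay = p$target_assay,
        reference_assay = p$reference_assay, formula = formula,
        methylation_pct = pct, status = status,
        n_used_target = at$n_used, n_used_reference = ar$n_used,
        flagged = at$flagged || ar$flagged,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no quantifiable sample/pair combinations found")
  res <- do.call(rbind, out)
  res <- res[order(res$element, res$reference_assay, res$sample_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("methylation_result", "data.frame")
  res
}
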