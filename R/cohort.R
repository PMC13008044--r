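# Group-level summaries and comparisons of methylation results. The tests
# themselves are the standard stats routines; this module's contract is the
# gating logic (paired/unpaired x normality) and the summary conventions.

#' Median / IQR summaries per group
#'
#' Summarizes `OK` and `ZERO_SIGNAL` methylation levels (medians and
#' quartiles by linear interpolation, plus mean and sd) for every
#' group x element x reference combination; `EXCLUDED` rows are omitted and
#' counted.
#'
#' @param results A [quantify_samples()] result.
#' @return Data.frame with one row per group x element x reference assay.
#' @export
summarize_group <- function(results) {
  results <- as.data.frame(results)
  used <- results[results$status != "EXCLUDED", , drop = FALSE]
  if (nrow(used) == 0L) stop("no usable (non-EXCLUDED) results")
  keys <- unique(used[, c("group", "element", "reference_assay")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- used$group == k$group & used$element == k$element &
      used$reference_assay == k$reference_assay
    x <- used$methylation_pct[sel]
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    n_exc <- sum(results$group == k$group &
                   results$element == k$element &
                   results$reference_assay == k$reference_assay &
                   results$status == "EXCLUDED")
    data.frame(group = k$group, element = k$element,
               reference_assay = k$reference_assay,
               n = length(x), n_excluded = n_exc,
               median_pct = qs[2], q1 = qs[1], q3 = qs[3],
               mean = mean(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shapiro-Wilk p, NA when the test is inapplicable (constant data, n out of
# range); NA routes the gate to the rank-based test.
.normality_p <- function(x) {
  if (length(x) < 3L || length(x) > 5000L) return(NA_real_)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

#' Compare methylation levels between two groups
#'
#' Normality-gated two-group comparison: Shapiro-Wilk at `alpha_normality`
#' on each group (or on the paired differences) chooses between the t-test
#' (Student/paired) and the rank-based alternative (Mann-Whitney U /
#' Wilcoxon matched-pairs signed rank); all p-values two-sided. Paired
#' differences that are all exactly zero carry no signal and return p = 1
#' with `test_name` `"degenerate"`.
#'
#' @param a,b Numeric methylation levels (percent); for `paired = TRUE`
#'   equal lengths in matched order.
#' @param paired Matched-pair design?
#' @param alpha_normality Significance level of the normality gate
#'   (default 0.05).
#' @return An object of class `comparison_result` with `test_name`,
#'   `statistic`, `p_value`, `normality_p`, `paired`, `n`.
#' @export
compare_two_groups <- function(a, b, paired = FALSE,
                               alpha_normality = 0.05) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 3L || length(b) < 3L) stop("need >= 3 values per group")
  if (paired && length(a) != length(b)) {
    stop("paired groups must have equal lengths")
  }
  if (paired) {
    d <- a - b
    if (all(d == 0)) {
      return(structure(list(test_name = "degenerate",
                            statistic = NA_real_, p_value = 1,
                            normality_p = NA_real_, paired = TRUE,
                            n = length(a)),
                       class = "comparison_result"))
    }
    np <- .normality_p(d)
    normal <- !is.na(np) && np > alpha_normality
    ht <- if (normal) {
      stats::t.test(a, b, paired = TRUE)
    } else {
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    }
    name <- if (normal) "paired t-test" else "wilcoxon signed-rank"
  } else {
    np <- c(.normality_p(a), .normality_p(b))
    normal <- !anyNA(np) && all(np > alpha_normality)
    ht <- if (normal) {
      stats::t.test(a, b)
    } else {
      stats::wilcox.test(a, b, exact = FALSE)
    }
    name <- if (normal) "unpaired t-test" else "mann-whitney u"
  }
  structure(list(test_name = name, statistic = unname(ht$statistic),
                 p_value = ht$p.value, normality_p = np, paired = paired,
                 n = c(length(a), length(b))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s%s: statistic %.4g, p = %.4g\n",
              x$test_name, if (x$paired) " (paired)" else "",
              x$statistic, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis comparison of three or more groups
#'
#' @param groups Named list of numeric vectors, length >= 3. Constant data
#'   across all groups carries no signal and returns p = 1.
#' @return A `comparison_result` with the H statistic.
#' @export
compare_multi <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 3L) stop("need >= 3 groups (use compare_two_groups)")
  for (g in groups) stopifnot(is.numeric(g))
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    return(structure(list(test_name = "degenerate", statistic = NA_real_,
                          p_value = 1, normality_p = NA_real_,
                          paired = FALSE,
                          n = lengths(groups)),
                     class = "comparison_result"))
  }
  ht <- stats::kruskal.test(groups)
  structure(list(test_name = "kruskal-wallis",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 normality_p = NA_real_, paired = FALSE,
                 n = lengths(groups)),
            class = "comparison_result")
}

#' Spearman correlation of age with methylation level
#'
#' @param ages,levels Equal-length numeric vectors, n >= 5; constant input
#'   is an error.
#' @return List with `rho`, `p_value`, `n`.
#' @export
correlate_age <- function(ages, levels) {
  stopifnot(is.numeric(ages), is.numeric(levels))
  if (length(ages) != length(levels)) stop("unequal vector lengths")
  if (length(ages) < 5L) stop("need n >= 5")
  if (length(unique(ages)) == 1L || length(unique(levels)) == 1L) {
    stop("constant input vector: correlation undefined")
  }
  ht <- stats::cor.test(ages, levels, method = "spearman", exact = FALSE)
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(ages))
}
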