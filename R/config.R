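# Run configuration: assay declarations, calibrator identity and the
# target/reference quantification pairs, serializable as YAML.

#' Assemble a pipeline run configuration
#'
#' @param assays A data.frame with columns `assay_id`, `role`
#'   (`"MSP"`/`"MIP"`), `element` (`"LINE1"`/`"ALU"`) and optionally
#'   `efficiency` (fractional, for the Pfaffl formula) and `ct_cutoff`
#'   (cycles; `NA` disables the cutoff).
#' @param calibrator_id Sample id of the fully methylated calibrator that
#'   defines the 100% methylation level.
#' @param pairs A data.frame with columns `element`, `target_assay`,
#'   `reference_assay`, `formula` (`"LIVAK"`, `"PFAFFL"` or `"AUTO"`).
#'   Defaults to every element's MSP assay crossed with every declared MIP
#'   assay (the cross-normalization design) with formula `"AUTO"`.
#' @param slope_threshold,alpha Decision thresholds for the
#'   formula-selection rule (defaults 0.1 cycles per log10(pg) and 0.05).
#' @return An object of class `run_config`.
#' @export
run_config <- function(assays, calibrator_id, pairs = NULL,
                       slope_threshold = 0.1, alpha = 0.05) {
  assays <- as.data.frame(assays, stringsAsFactors = FALSE)
  need <- c("assay_id", "role", "element")
  missing <- setdiff(need, names(assays))
  if (length(missing)) {
    stop("'assays' lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(assays$assay_id)) stop("duplicated assay_id in 'assays'")
  if (!all(assays$role %in% c("MSP", "MIP"))) {
    stop("assay roles must be MSP or MIP")
  }
  if (!all(assays$element %in% c("LINE1", "ALU"))) {
    stop("assay elements must be LINE1 or ALU")
  }
  if (is.null(assays$efficiency)) assays$efficiency <- NA_real_
  if (is.null(assays$ct_cutoff)) assays$ct_cutoff <- NA_real_
  .check_string(calibrator_id, "calibrator_id")
  if (is.null(pairs)) {
    msp <- assays[assays$role == "MSP", , drop = FALSE]
    mip <- assays[assays$role == "MIP", , drop = FALSE]
    if (nrow(msp) == 0L || nrow(mip) == 0L) {
      stop("default pairs need at least one MSP and one MIP assay")
    }
    pairs <- expand.grid(target_assay = msp$assay_id,
                         reference_assay = mip$assay_id,
                         stringsAsFactors = FALSE)
    pairs$element <- msp$element[match(pairs$target_assay, msp$assay_id)]
    pairs$formula <- "AUTO"
    pairs <- pairs[, c("element", "target_assay", "reference_assay",
                       "formula")]
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  need <- c("element", "target_assay", "reference_assay", "formula")
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    stop("'pairs' lacks column(s): ", paste(missing, collapse = ", "))
  }
  pairs$formula <- toupper(pairs$formula)
  if (!all(pairs$formula %in% c("AUTO", "LIVAK", "PFAFFL"))) {
    stop("pair formulas must be AUTO, LIVAK or PFAFFL")
  }
  undeclared <- setdiff(c(pairs$target_assay, pairs$reference_assay),
                        assays$assay_id)
  if (length(undeclared)) {
    stop("pair references undeclared assay(s): ",
         paste(undeclared, collapse = ", "))
  }
  .check_number(slope_threshold, "slope_threshold", 0, Inf)
  .check_number(alpha, "alpha", 0, 1)
  structure(list(assays = assays, calibrator_id = calibrator_id,
                 pairs = pairs, slope_threshold = slope_threshold,
                 alpha = alpha),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> calibrator:", x$calibrator_id, "\n")
  cat("  assays:\n")
  print(x$assays, row.names = FALSE)
  cat("  pairs:\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' The YAML layout mirrors [run_config()]: an `assays` sequence of mappings,
#' a `calibrator_id`, an optional `pairs` sequence, and optional
#' `slope_threshold` / `alpha` scalars.
#'
#' @param path Path to a YAML file.
#' @return For `read_run_config`, a `run_config`; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(lst) {
    do.call(rbind, lapply(lst, function(row) {
      as.data.frame(row, stringsAsFactors = FALSE)
    }))
  }
  assays <- to_df(y$assays)
  pairs <- if (!is.null(y$pairs)) to_df(y$pairs) else NULL
  run_config(assays, y$calibrator_id, pairs,
             slope_threshold = y$slope_threshold %||% 0.1,
             alpha = y$alpha %||% 0.05)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  df_to_list <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row <- lapply(row, function(v) if (is.factor(v)) as.character(v) else v)
      row[!vapply(row, function(v) length(v) == 1L && is.na(v), TRUE)]
    })
  }
  yaml::write_yaml(list(assays = df_to_list(config$assays),
                        calibrator_id = config$calibrator_id,
                        pairs = df_to_list(config$pairs),
                        slope_threshold = config$slope_threshold,
                        alpha = config$alpha),
                   path)
  invisible(path)
}
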