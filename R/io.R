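# CT-table and report IO. The on-disk dialect is deliberately minimal:
# comma-separated, UTF-8, dot decimal, header
# sample_id,assay_id,replicate,ct,input_mass_pg,group, undetermined CTs as
# the literal "NA", optional leading "# key: value" metadata lines.

.ct_table_columns <- c("sample_id", "assay_id", "replicate", "ct",
                       "input_mass_pg", "group")

#' Read a CT table from a delimited file
#'
#' Validates each row; malformed rows (unparseable or non-positive CT,
#' mass or replicate) are collected into a rejects report attached as
#' `attr(x, "rejects")` rather than silently dropped. A missing required
#' column or a duplicated (sample, assay, replicate) key is a hard error.
#' Leading `# key: value` lines are parsed into `attr(x, "meta")`.
#'
#' @param path Path to a CSV file with header
#'   `sample_id,assay_id,replicate,ct,input_mass_pg,group`.
#' @return A `ct_table` data.frame; undetermined CTs are `NA`.
#' @seealso [write_ct_table()]
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  meta_lines <- head_lines[cumprod(startsWith(head_lines, "#")) == 1]
  meta <- list()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         comment.char = "#", check.names = FALSE,
                         na.strings = character(0))
  missing <- setdiff(.ct_table_columns, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[, .ct_table_columns]
  n <- nrow(raw)
  reason <- character(n)
  rep_num <- suppressWarnings(as.numeric(raw$replicate))
  ct_num <- suppressWarnings(as.numeric(raw$ct))
  ct_na <- trimws(raw$ct) %in% c("NA", "")
  mass_num <- suppressWarnings(as.numeric(raw$input_mass_pg))
  bad_rep <- is.na(rep_num) | rep_num < 1 | rep_num != round(rep_num)
  bad_ct <- !ct_na & (is.na(ct_num) | ct_num <= 0)
  bad_mass <- is.na(mass_num) | mass_num <= 0
  bad_id <- !nzchar(trimws(raw$sample_id)) | !nzchar(trimws(raw$assay_id))
  reason[bad_id] <- "empty sample or assay id"
  reason[bad_mass] <- "input_mass_pg not a positive number"
  reason[bad_ct] <- "ct not a positive number or 'NA'"
  reason[bad_rep] <- "replicate not a positive integer"
  keep <- !nzchar(reason)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- data.frame(sample_id = raw$sample_id[keep],
                    assay_id = raw$assay_id[keep],
                    replicate = as.integer(rep_num[keep]),
                    ct = ifelse(ct_na[keep], NA_real_, ct_num[keep]),
                    input_mass_pg = mass_num[keep],
                    group = raw$group[keep],
                    stringsAsFactors = FALSE)
  key <- paste(out$sample_id, out$assay_id, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (sample_id, assay_id, replicate) key: ",
         dup$sample_id, " / ", dup$assay_id, " / ", dup$replicate)
  }
  class(out) <- c("ct_table", "data.frame")
  attr(out, "rejects") <- rejects
  attr(out, "meta") <- meta
  out
}

#' Write a CT table to a CSV file
#'
#' CT and mass values are serialized with full double precision so that
#' `read_ct_table(write_ct_table(x))` round-trips exactly; undetermined CTs
#' become the literal `NA`.
#'
#' @param x A `ct_table` (or compatible data.frame).
#' @param path Output path.
#' @param meta Optional named list written as leading `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, meta = attr(x, "meta")) {
  x <- as.data.frame(x)
  missing <- setdiff(.ct_table_columns, names(x))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- character(0)
  if (length(meta)) {
    lines <- sprintf("# %s: %s", names(meta),
                     vapply(meta, as.character, ""))
  }
  lines <- c(lines, paste(.ct_table_columns, collapse = ","),
             paste(x$sample_id, x$assay_id, as.integer(x$replicate),
                   fmt(x$ct), fmt(x$input_mass_pg), x$group, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as TSV or JSON
#'
#' Numeric columns are rounded to 6 significant digits before writing, so
#' the two formats encode identical content and outputs are diffable.
#'
#' @param results Non-empty data.frame of results.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("'results' must be non-empty")
  num <- vapply(results, is.numeric, TRUE)
  results[num] <- lapply(results[num], signif, digits = 6)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return A data.frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    out <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    out
  }
}
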