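#' Validate a quotient record table
#'
#' Checks the schema shared by [classify_quotients()] and the I/O layer:
#' `id` and `q_alb` are required, ids must be unique, every present
#' quotient must lie in (0, 1) or be `NA`.  Problems are collected and
#' reported together with their row numbers.
#'
#' @param records A data.frame with columns `id`, `q_alb` and optionally
#'   `q_igg`, `q_iga`, `q_igm`.
#' @return The validated data.frame (ids coerced to character), invisibly
#'   usable downstream.
#' @export
validate_quotient_records <- function(records) {
  .validate_records(records)
}

.validate_records <- function(records, extra_problems = character()) {
  if (!is.data.frame(records))
    stop("'records' must be a data.frame", call. = FALSE)
  problems <- extra_problems
  if (!all(c("id", "q_alb") %in% names(records))) {
    stop("'records' must have columns 'id' and 'q_alb'", call. = FALSE)
  }
  records$id <- as.character(records$id)
  dup <- duplicated(records$id)
  if (any(dup))
    problems <- c(problems, paste0("duplicate id(s) in row(s) ",
                                   paste(which(dup), collapse = ", ")))
  q_cols <- intersect(c("q_alb", "q_igg", "q_iga", "q_igm"), names(records))
  for (col in q_cols) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        problems <- c(problems, paste0("non-numeric ", col, " in row(s) ",
                                       paste(bad, collapse = ", ")))
      records[[col]] <- vn
      v <- vn
    }
    out_of_range <- which(!is.na(v) & (v <= 0 | v >= 1))
    if (length(out_of_range))
      problems <- c(problems,
                    paste0(col, " outside (0, 1) in row(s) ",
                           paste(out_of_range, collapse = ", ")))
  }
  missing_alb <- which(is.na(records$q_alb))
  if (length(missing_alb))
    problems <- c(problems, paste0("missing q_alb in row(s) ",
                                   paste(missing_alb, collapse = ", ")))
  if (length(problems))
    stop("invalid quotient records:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  records
}

#' Read a patient quotient table
#'
#' Reads a CSV or TSV file with header columns `id,q_alb[,q_igg,q_iga,q_igm]`
#' into a validated record table.  Quotients are stored internally as
#' absolute dimensionless fractions; tables written on the customary
#' x 10^-3 scale are converted with `scale = 1e-3`.
#'
#' @param path Path to the delimited file.
#' @param scale Multiplier applied to all quotient columns on input:
#'   1 (absolute fractions, default) or 1e-3.
#' @param sep Field delimiter; sniffed from the header line (tab vs comma)
#'   when `NULL`.
#' @return A validated data.frame of patient records.
#' @export
read_quotient_table <- function(path, scale = 1, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!scale %in% c(1, 1e-3))
    stop("'scale' must be 1 or 1e-3", call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           strip.white = TRUE)
  problems <- character()
  for (col in intersect(c("q_alb", "q_igg", "q_iga", "q_igm"), names(raw))) {
    v <- raw[[col]]
    suppressWarnings(vn <- as.numeric(v))
    bad <- which(!is.na(v) & nzchar(v) & is.na(vn))
    if (length(bad))
      problems <- c(problems, paste0("non-numeric ", col, " in row(s) ",
                                     paste(bad, collapse = ", ")))
    raw[[col]] <- vn * scale
  }
  .validate_records(raw, extra_problems = problems)
}

#' Write results to CSV or JSON
#'
#' Writes a result data.frame (classification tables, recovery reports,
#' ...) with a deterministic column order, or any list-like result as
#' JSON.  Numeric values survive a CSV round-trip at better than 12
#' significant digits.  An empty data.frame produces a header-only file
#' with a warning.
#'
#' @param results A data.frame (for `format = "csv"`) or any
#'   jsonlite-serializable object (for `format = "json"`).
#' @param path Output path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(results))
      stop("CSV output requires a data.frame", call. = FALSE)
    if (nrow(results) == 0L)
      warning("writing header-only file: no result rows", call. = FALSE)
    out <- results
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) {
      formatted <- formatC(v, digits = 15, format = "g")
      ifelse(is.na(v), NA_character_, trimws(formatted))
    })
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     na = "")
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  }
  invisible(path)
}
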