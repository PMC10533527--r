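#' Cohort tables
#'
#' A cohort table is one row per subject: a character `subject_id` column plus
#' named variable columns that are either continuous (numeric; e.g. MDI/PDI
#' points, length-for-age z-score units, grams, days, weeks, SES score units)
#' or binary (logical). Missing values are allowed per cell and are removed by
#' [filter_complete_cases()] before any network stage.
#'
#' @param data a data.frame with a `subject_id` column and the variables named
#'   in `kinds`.
#' @param kinds named character vector mapping each variable to `"continuous"`
#'   or `"binary"`.
#' @param id_col name of the subject identifier column.
#' @return an object of class `cohort_table` (a data.frame with a `kinds`
#'   attribute).
#' @examples
#' df <- data.frame(subject_id = c("S1", "S2"), MDI = c(85, 64),
#'                  dGV = c(TRUE, FALSE))
#' cohort_table(df, kinds = c(MDI = "continuous", dGV = "binary"))
#' @export
cohort_table <- function(data, kinds, id_col = "subject_id") {
  stopifnot(is.data.frame(data))
  if (!id_col %in% names(data)) {
    abort("missing subject identifier column '", id_col, "'",
          class = "svbn_schema_error")
  }
  if (is.null(names(kinds)) || any(!nzchar(names(kinds)))) {
    abort("'kinds' must be a named character vector", class = "svbn_schema_error")
  }
  missing_cols <- setdiff(names(kinds), names(data))
  if (length(missing_cols)) {
    abort("missing required column(s): ", paste(missing_cols, collapse = ", "),
          class = "svbn_schema_error")
  }
  bad <- setdiff(unname(kinds), c("continuous", "binary"))
  if (length(bad)) {
    abort("unknown column kind(s): ", paste(unique(bad), collapse = ", "),
          class = "svbn_schema_error")
  }
  ids <- as.character(data[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort("duplicate subject_id(s): ", paste(dup, collapse = ", "),
          class = "svbn_validation_error")
  }
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (v in names(kinds)) {
    col <- data[[v]]
    if (kinds[[v]] == "continuous") {
      if (!is.numeric(col)) {
        abort("column '", v, "' declared continuous but is not numeric",
              class = "svbn_schema_error")
      }
      out[[v]] <- as.numeric(col)
    } else {
      if (!is.logical(col)) {
        abort("column '", v, "' declared binary but is not logical",
              class = "svbn_schema_error")
      }
      out[[v]] <- col
    }
  }
  structure(out, kinds = kinds, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  kinds <- attr(x, "kinds")
  cat(sprintf("<cohort_table> %d subjects, %d variables (%d continuous, %d binary)\n",
              nrow(x), length(kinds),
              sum(kinds == "continuous"), sum(kinds == "binary")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Column kinds of a cohort table
#' @param table a `cohort_table`.
#' @return named character vector of `"continuous"` / `"binary"`.
#' @export
cohort_kinds <- function(table) attr(table, "kinds")

#' Read a cohort table from TSV/CSV
#'
#' Reads a delimited file with a header row, validates it against a schema of
#' column kinds, and returns a [cohort_table()]. The delimiter is inferred
#' from the file extension (`.csv` comma, otherwise tab) unless `sep` is
#' given. Cells matching one of `missing_tokens` (case-insensitive; empty
#' string, `NA`, `NaN` by default) become missing. Any other token that does
#' not parse under the declared kind is an error naming the row and column.
#'
#' @param path path to the file.
#' @param schema named character vector: column name -> `"continuous"` or
#'   `"binary"`. Columns absent from the schema are ignored.
#' @param sep field separator; `NULL` (default) infers from the extension.
#' @param missing_tokens character vector of tokens treated as missing,
#'   case-insensitively.
#' @param id_col name of the subject identifier column.
#' @return a `cohort_table`; row count equals the file's data rows.
#' @export
read_cohort <- function(path, schema, sep = NULL,
                        missing_tokens = c("", "NA", "NaN"),
                        id_col = "subject_id") {
  if (!file.exists(path)) abort("file not found: ", path, class = "svbn_io_error")
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (!id_col %in% names(raw)) {
    abort("missing subject identifier column '", id_col, "'",
          class = "svbn_schema_error")
  }
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols)) {
    abort("missing required column(s): ", paste(missing_cols, collapse = ", "),
          class = "svbn_schema_error")
  }
  low_missing <- tolower(missing_tokens)
  parsed <- data.frame(subject_id = as.character(raw[[id_col]]),
                       stringsAsFactors = FALSE)
  for (v in names(schema)) {
    tok <- trimws(raw[[v]])
    is_na <- tolower(tok) %in% low_missing
    if (schema[[v]] == "continuous") {
      num <- suppressWarnings(as.numeric(tok))
      bad <- which(!is_na & is.na(num))
      if (length(bad)) {
        abort("non-numeric value ", sQuote(tok[bad[1L]]), " in continuous column '",
              v, "', row ", bad[1L], class = "svbn_parse_error")
      }
      num[is_na] <- NA_real_
      parsed[[v]] <- num
    } else {
      lowtok <- tolower(tok)
      val <- rep(NA, length(tok))
      val[lowtok %in% c("true", "t", "1", "yes")] <- TRUE
      val[lowtok %in% c("false", "f", "0", "no")] <- FALSE
      bad <- which(!is_na & is.na(val))
      if (length(bad)) {
        abort("unrecognized binary value ", sQuote(tok[bad[1L]]),
              " in column '", v, "', row ", bad[1L],
              class = "svbn_parse_error")
      }
      parsed[[v]] <- as.logical(val)
    }
  }
  cohort_table(parsed, kinds = schema, id_col = "subject_id")
}

#' Keep only subjects complete on the named variables
#'
#' Complete-case filtering ahead of network learning: rows with a missing cell
#' in any of `variables` are dropped; row order is preserved. The number of
#' removed rows is recorded in the `n_removed` attribute.
#'
#' @param table a `cohort_table`.
#' @param variables character vector of column names; an empty vector keeps
#'   every row.
#' @return the filtered `cohort_table` with attribute `n_removed`.
#' @export
filter_complete_cases <- function(table, variables) {
  stopifnot(inherits(table, "cohort_table"))
  unknown <- setdiff(variables, names(cohort_kinds(table)))
  if (length(unknown)) {
    abort("unknown variable(s): ", paste(unknown, collapse = ", "),
          class = "svbn_validation_error")
  }
  keep <- rep(TRUE, nrow(table))
  for (v in variables) keep <- keep & !is.na(table[[v]])
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kinds") <- cohort_kinds(table)
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(table)
  out
}
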