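#' Read a spreadsheet into a raw table of cells
#'
#' Reads one sheet of an .xlsx workbook. The first row is always the
#' header; every cell below it is kept as text so that validation, not the
#' reader's type guessing, decides what is numeric. Blank cells become
#' `NA`. Duplicated column names are rejected outright: silently renaming
#' them risks the user selecting the wrong column.
#'
#' @param path Path to an existing .xlsx file.
#' @param sheet Sheet name or 1-based index; default the first sheet.
#' @return A data frame of character columns (the raw table).
#' @export
dx_read_xlsx <- function(path, sheet = 1) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop(sprintf("cannot read input file: %s", path), call. = FALSE)
  }
  if (tolower(tools::file_ext(path)) != "xlsx") {
    stop(sprintf("input must be an .xlsx workbook: %s", path),
         call. = FALSE)
  }
  tbl <- tryCatch(
    readxl::read_excel(path, sheet = sheet, col_types = "text",
                       .name_repair = "minimal"),
    error = function(e) {
      stop(sprintf("cannot read input file: %s (%s)", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  tbl <- as.data.frame(tbl, stringsAsFactors = FALSE)
  if (anyDuplicated(names(tbl))) {
    stop("duplicated column names in the input sheet; please make headers unique",
         call. = FALSE)
  }
  if (nrow(tbl) == 0) stop("no data rows", call. = FALSE)
  tbl
}

# Parse spreadsheet text cells to numbers; non-numeric text gives NA while
# genuinely blank cells were already NA before parsing.
parse_cell_numeric <- function(x) {
  suppressWarnings(as.numeric(trimws(x)))
}

is_binary01 <- function(x) {
  !is.na(x) & (x == 0 | x == 1)
}

#' Validate and clean the selected test/reference columns
#'
#' Applies the validation rules of the analysis workflow: rows with a
#' missing value in either selected column are dropped first (missingness
#' in other columns is irrelevant), then the remaining values are checked
#' and the exact error message for the first violated rule is raised:
#'
#' * qualitative test with values other than 0/1 —
#'   `"For qualitative tests, the test variable must contain only 0 and 1
#'   values."`
#' * quantitative test with non-numeric entries —
#'   `"For quantitative tests, the test variable must be numeric."`
#' * reference with values other than 0/1 —
#'   `"The reference variable must contain only 0 and 1 values."`
#' * reference missing a level after cleaning —
#'   `"The reference variable must contain both 0 and 1 after removing
#'   missing values."`
#'
#' Cells stored as text that parse as decimal numbers are accepted
#' (spreadsheets routinely store numbers as text); for 0/1 columns the
#' parsed value must equal 0 or 1 exactly, so `"1.0"` passes and `"0.5"`
#' does not.
#'
#' @param table A raw table from [dx_read_xlsx()] (or any data frame).
#' @param test_col,ref_col Names of the test and reference columns; must
#'   be distinct existing columns.
#' @param test_kind `"quantitative"` or `"qualitative"`.
#' @return A list of class `dx_dataset`: `test_values` (numeric),
#'   `ref_values` (integer 0/1), `test_kind`, and `n_dropped`, the number
#'   of removed rows.
#' @export
dx_clean <- function(table, test_col, ref_col,
                     test_kind = c("quantitative", "qualitative")) {
  test_kind <- match.arg(test_kind)
  stopifnot(is.data.frame(table))
  for (col in c(test_col, ref_col)) {
    if (!col %in% names(table)) {
      stop(sprintf("column '%s' not found in the input table", col),
           call. = FALSE)
    }
  }
  if (identical(test_col, ref_col)) {
    stop("test and reference columns must be distinct", call. = FALSE)
  }
  test_raw <- as.character(table[[test_col]])
  ref_raw <- as.character(table[[ref_col]])
  missing_cell <- function(x) is.na(x) | !nzchar(trimws(x))
  keep <- !missing_cell(test_raw) & !missing_cell(ref_raw)
  n_dropped <- sum(!keep)
  test_raw <- test_raw[keep]
  ref_raw <- ref_raw[keep]
  if (length(test_raw) == 0) {
    stop("no complete rows remain after removing missing values",
         call. = FALSE)
  }

  test_num <- parse_cell_numeric(test_raw)
  if (test_kind == "qualitative") {
    if (!all(is_binary01(test_num))) {
      stop("For qualitative tests, the test variable must contain only 0 and 1 values.",
           call. = FALSE)
    }
  } else if (anyNA(test_num)) {
    stop("For quantitative tests, the test variable must be numeric.",
         call. = FALSE)
  }

  ref_num <- parse_cell_numeric(ref_raw)
  if (!all(is_binary01(ref_num))) {
    stop("The reference variable must contain only 0 and 1 values.",
         call. = FALSE)
  }
  if (!(any(ref_num == 0) && any(ref_num == 1))) {
    stop("The reference variable must contain both 0 and 1 after removing missing values.",
         call. = FALSE)
  }

  structure(
    list(test_values = test_num, ref_values = as.integer(ref_num),
         test_kind = test_kind, n_dropped = as.integer(n_dropped)),
    class = "dx_dataset"
  )
}

#' @export
print.dx_dataset <- function(x, ...) {
  cat(sprintf("%s test, n = %d (%d diseased, %d non-diseased), %d row(s) dropped\n",
              x$test_kind, length(x$test_values), sum(x$ref_values == 1),
              sum(x$ref_values == 0), x$n_dropped))
  invisible(x)
}
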