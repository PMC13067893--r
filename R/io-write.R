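# ---- minimal .xlsx writer -------------------------------------------------
# Single-sheet Office Open XML workbook written from scratch (no installed
# package writes .xlsx). Cells are either numbers or inline strings, which
# is all the exporters need; readxl reads the result back.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# column index (1-based) -> spreadsheet letters: 1 -> A, 27 -> AA
col_letter <- function(i) {
  out <- ""
  while (i > 0) {
    r <- (i - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    i <- (i - 1) %/% 26
  }
  out
}

cell_xml <- function(ref, value) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) return("")
  if (is.numeric(value)) {
    sprintf('<c r="%s" t="n"><v>%s</v></c>', ref,
            format(value, digits = 15, scientific = FALSE, trim = TRUE))
  } else {
    sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            ref, xml_escape(as.character(value)))
  }
}

#' Write rows of cells to a one-sheet .xlsx workbook
#'
#' Low-level writer behind the confusion-matrix, metrics and dataset
#' exporters. `rows` is a list of rows; each row is a list (or vector) of
#' cells, each cell a single number or string. `NA` cells are left blank.
#'
#' @param rows List of rows of cells.
#' @param path Output path ending in .xlsx.
#' @param sheet_name Name of the single sheet.
#' @return `path`, invisibly.
#' @export
dx_write_xlsx <- function(rows, path, sheet_name = "Sheet1") {
  stopifnot(is.list(rows))
  row_xml <- vapply(seq_along(rows), function(r) {
    cells <- as.list(rows[[r]])
    body <- paste0(vapply(seq_along(cells), function(c_i) {
      cell_xml(paste0(col_letter(c_i), r), cells[[c_i]])
    }, character(1)), collapse = "")
    sprintf('<row r="%d">%s</row>', r, body)
  }, character(1))

  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste0(row_xml, collapse = ""), '</sheetData></worksheet>'
  )
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    sprintf('<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets>',
            xml_escape(sheet_name)),
    '</workbook>'
  )
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '<Relationship Id="rId2" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
    '</Relationships>'
  )
  styles <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="1"><xf xfId="0"/></cellXfs>',
    '</styleSheet>'
  )
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    '</Types>'
  )
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'
  )

  dir_ok <- dir.exists(dirname(path)) || dir.create(dirname(path),
                                                   recursive = TRUE,
                                                   showWarnings = FALSE)
  if (!dir_ok) stop(sprintf("cannot write to %s", path), call. = FALSE)
  stage <- tempfile("xlsx_")
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  dir.create(file.path(stage, "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "worksheets"), recursive = TRUE)
  writer <- function(text, ...) {
    con <- file(file.path(stage, ...), open = "wb")
    writeLines(text, con, sep = "", useBytes = TRUE)
    close(con)
  }
  writer(content_types, "[Content_Types].xml")
  writer(root_rels, "_rels", ".rels")
  writer(workbook, "xl", "workbook.xml")
  writer(wb_rels, "xl", "_rels", "workbook.xml.rels")
  writer(styles, "xl", "styles.xml")
  writer(sheet, "xl", "worksheets", "sheet1.xml")
  # pin timestamps so identical content zips to identical bytes
  for (f in list.files(stage, recursive = TRUE, all.files = TRUE,
                       include.dirs = TRUE, full.names = TRUE)) {
    Sys.setFileTime(f, as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))
  }

  out <- tryCatch({
    tmp_zip <- tempfile(fileext = ".xlsx")
    zip::zip(tmp_zip,
             files = c("[Content_Types].xml", "_rels", "xl"),
             root = stage, mode = "mirror")
    if (!file.copy(tmp_zip, path, overwrite = TRUE)) {
      stop("copy failed")
    }
    unlink(tmp_zip)
    path
  }, error = function(e) {
    stop(sprintf("cannot write to %s (%s)", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(out)
}

# data frame -> list of rows (header + typed cells) for dx_write_xlsx
df_to_rows <- function(df) {
  header <- as.list(names(df))
  body <- lapply(seq_len(nrow(df)), function(r) {
    lapply(df, function(col) col[[r]])
  })
  c(list(header), body)
}

#' Export a confusion matrix as an .xlsx file
#'
#' Writes the 2x2 layout (rows: test positive/negative; columns: disease
#' present/absent) followed by the four labelled counts as a summarized
#' list. Zero counts are written as the number 0, never blank.
#'
#' @param cm A [dx_confusion()] object.
#' @param path Output .xlsx path.
#' @return `path`, invisibly.
#' @export
dx_write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "dx_confusion"))
  rows <- list(
    list("", "Disease present", "Disease absent"),
    list("Test positive", cm$tp, cm$fp),
    list("Test negative", cm$fn, cm$tn),
    list("", "", ""),
    list("True positives (TP)", cm$tp, ""),
    list("False positives (FP)", cm$fp, ""),
    list("False negatives (FN)", cm$fn, ""),
    list("True negatives (TN)", cm$tn, "")
  )
  dx_write_xlsx(rows, path, sheet_name = "Confusion matrix")
}

#' Export a metrics table as an .xlsx file
#'
#' One row per metric with columns `metric`, `estimate`, `ci_lower`,
#' `ci_upper`. Values are written as fixed three-decimal text via
#' [dx_round()], with missing values rendered as `"NA"`. An empty report
#' produces a header-only file.
#'
#' @param report A `dx_metrics` data frame from [dx_metrics()].
#' @param path Output .xlsx path.
#' @return `path`, invisibly.
#' @export
dx_write_metrics <- function(report, path) {
  stopifnot(is.data.frame(report))
  rows <- c(
    list(list("metric", "estimate", "ci_lower", "ci_upper")),
    lapply(seq_len(nrow(report)), function(r) {
      list(report$metric[r], dx_round(report$estimate[r]),
           dx_round(report$lower[r]), dx_round(report$upper[r]))
    })
  )
  dx_write_xlsx(rows, path, sheet_name = "Metrics")
}

#' Export ROC coordinates as CSV
#'
#' UTF-8 CSV with columns `threshold`, `sensitivity`, `specificity`; the
#' infinite sentinel thresholds are serialized as `-Inf`/`Inf`.
#'
#' @param curve A `dx_roc` object.
#' @param path Output .csv path.
#' @return `path`, invisibly.
#' @export
dx_write_roc_points <- function(curve, path) {
  stopifnot(inherits(curve, "dx_roc"))
  df <- as.data.frame(curve)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a dataset to an .xlsx workbook
#'
#' Persists a data frame (e.g. from [dx_simulate()]) with its column names
#' as the header row; numeric columns become number cells.
#'
#' @param data A data frame.
#' @param path Output .xlsx path.
#' @return `path`, invisibly.
#' @export
dx_write_dataset <- function(data, path) {
  stopifnot(is.data.frame(data))
  dx_write_xlsx(df_to_rows(data), path, sheet_name = "data")
}
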