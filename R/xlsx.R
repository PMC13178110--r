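# Minimal single-sheet xlsx writer (SpreadsheetML in a zip container).
# Only what a Bonsai-style frame log needs: one sheet, a header row of
# strings (inline strings, so no shared-string table) and numeric cells.
# Entry mtimes are pinned so identical data yield identical bytes.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

write_minimal_xlsx <- function(df, path, sheet = "Sheet1") {
  stopifnot(is.data.frame(df))
  nc <- ncol(df)
  letters_ <- col_letter(seq_len(nc))

  header <- paste0(
    '<c r="', letters_, '1" t="inlineStr"><is><t>',
    xml_escape(names(df)), "</t></is></c>", collapse = ""
  )
  body_rows <- vapply(seq_len(nrow(df)), function(r) {
    vals <- vapply(seq_len(nc), function(c) {
      v <- df[[c]][r]
      if (is.na(v)) return(sprintf('<c r="%s%d"/>', letters_[c], r + 1))
      sprintf('<c r="%s%d"><v>%s</v></c>', letters_[c], r + 1,
              sprintf("%.17g", as.numeric(v)))
    }, character(1))
    sprintf('<row r="%d">%s</row>', r + 1, paste(vals, collapse = ""))
  }, character(1))

  sheet_xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>",
    sprintf('<row r="1">%s</row>', header),
    paste(body_rows, collapse = ""),
    "</sheetData></worksheet>"
  )
  workbook_xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="', xml_escape(sheet),
    '" sheetId="1" r:id="rId1"/></sheets></workbook>'
  )
  workbook_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet1.xml"/></Relationships>'
  )
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>'
  )
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ',
    'ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ',
    'ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ',
    'ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>"
  )

  staging <- tempfile("xlsx_")
  dir.create(file.path(staging, "_rels"), recursive = TRUE)
  dir.create(file.path(staging, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(staging, "xl", "worksheets"), recursive = TRUE)
  files <- c(
    "[Content_Types].xml" = content_types,
    "_rels/.rels" = root_rels,
    "xl/workbook.xml" = workbook_xml,
    "xl/_rels/workbook.xml.rels" = workbook_rels,
    "xl/worksheets/sheet1.xml" = sheet_xml
  )
  for (f in names(files)) {
    writeLines(files[[f]], file.path(staging, f), useBytes = TRUE)
    Sys.setFileTime(file.path(staging, f), "2000-01-01 00:00:00 UTC")
  }
  if (file.exists(path)) unlink(path)
  zip::zip(zipfile = file.path(normalizePath(dirname(path)), basename(path)),
           files = names(files), root = staging, recurse = FALSE,
           include_directories = FALSE, mode = "mirror")
  unlink(staging, recursive = TRUE)
  invisible(path)
}
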