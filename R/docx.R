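# Minimal WordprocessingML (.docx) writer. A .docx is a ZIP archive whose
# word/document.xml holds the content; this writer supports the elements the
# report needs: headings, paragraphs, simple tables, and inline PNG images.

EMU_PER_CM <- 360000

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Start an empty docx document builder
#' @return A mutable `docx_builder`.
#' @export
docx_document <- function() {
  env <- new.env(parent = emptyenv())
  env$body <- character(0)
  env$images <- list()
  structure(list(env = env), class = "docx_builder")
}

docx_run <- function(text, bold = FALSE, size_halfpt = NULL) {
  props <- c(if (bold) "<w:b/>",
             if (!is.null(size_halfpt)) sprintf('<w:sz w:val="%d"/>', size_halfpt))
  rpr <- if (length(props)) paste0("<w:rPr>", paste(props, collapse = ""), "</w:rPr>") else ""
  sprintf('<w:r>%s<w:t xml:space="preserve">%s</w:t></w:r>', rpr, xml_escape(text))
}

#' Append a heading paragraph
#' @param doc A `docx_builder`.
#' @param text Heading text.
#' @param level 1 (title-sized) or 2 (section-sized).
#' @return `doc`, invisibly.
#' @export
docx_add_heading <- function(doc, text, level = 1L) {
  size <- if (level <= 1L) 36L else 28L
  doc$env$body <- c(doc$env$body,
                    paste0("<w:p>", docx_run(text, bold = TRUE, size_halfpt = size), "</w:p>"))
  invisible(doc)
}

#' Append a body paragraph
#' @param doc A `docx_builder`.
#' @param text Paragraph text.
#' @return `doc`, invisibly.
#' @export
docx_add_paragraph <- function(doc, text) {
  doc$env$body <- c(doc$env$body, paste0("<w:p>", docx_run(text), "</w:p>"))
  invisible(doc)
}

#' Append a table from a data frame
#'
#' Writes a bordered table with a bold header row taken from `names(df)`.
#' Numeric cells are formatted to `digits` decimals.
#'
#' @param doc A `docx_builder`.
#' @param df Data frame.
#' @param digits Decimals for numeric columns.
#' @return `doc`, invisibly.
#' @export
docx_add_table <- function(doc, df, digits = 2L) {
  cell <- function(text, bold = FALSE)
    paste0("<w:tc><w:tcPr><w:tcBorders>",
           paste(sprintf('<w:%s w:val="single" w:sz="4"/>',
                         c("top", "bottom", "left", "right")), collapse = ""),
           "</w:tcBorders></w:tcPr><w:p>", docx_run(text, bold = bold), "</w:p></w:tc>")
  fmt <- function(v) if (is.numeric(v) && any(v != round(v))) fmt_num(v, digits)
                     else as.character(v)
  header <- paste0("<w:tr>", paste(vapply(names(df), cell, "", bold = TRUE),
                                   collapse = ""), "</w:tr>")
  cols <- lapply(df, fmt)
  body <- vapply(seq_len(nrow(df)), function(i)
    paste0("<w:tr>",
           paste(vapply(cols, function(cl) cell(cl[[i]]), ""), collapse = ""),
           "</w:tr>"), "")
  doc$env$body <- c(doc$env$body,
                    paste0('<w:tbl><w:tblPr><w:tblW w:w="0" w:type="auto"/></w:tblPr>',
                           header, paste(body, collapse = ""), "</w:tbl>"))
  invisible(doc)
}

png_dimensions <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 24L)
  if (length(hdr) < 24L || !identical(hdr[1:8], as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))))
    hp_stop("io_error", "%s is not a PNG file", path)
  dims <- readBin(hdr[17:24], "integer", n = 2L, size = 4L, endian = "big")
  list(width = dims[1], height = dims[2])
}

#' Append an embedded PNG image with a caption
#'
#' The image is embedded inline at a fixed display width (default 16 cm) with
#' height scaled to preserve the aspect ratio.
#'
#' @param doc A `docx_builder`.
#' @param path PNG file path.
#' @param caption Caption paragraph written under the image.
#' @param width_cm Display width in centimetres.
#' @return `doc`, invisibly.
#' @export
docx_add_image <- function(doc, path, caption = NULL, width_cm = 16) {
  dims <- png_dimensions(path)
  cx <- round(width_cm * EMU_PER_CM)
  cy <- round(cx * dims$height / dims$width)
  id <- length(doc$env$images) + 1L
  rid <- sprintf("rIdImg%d", id)
  doc$env$images[[id]] <- list(rid = rid, path = path,
                               target = sprintf("media/image%d.png", id))
  drawing <- sprintf(paste0(
    '<w:p><w:r><w:drawing><wp:inline distT="0" distB="0" distL="0" distR="0">',
    '<wp:extent cx="%d" cy="%d"/><wp:docPr id="%d" name="Figure %d"/>',
    '<a:graphic xmlns:a="http://schemas.openxmlformats.org/drawingml/2006/main">',
    '<a:graphicData uri="http://schemas.openxmlformats.org/drawingml/2006/picture">',
    '<pic:pic xmlns:pic="http://schemas.openxmlformats.org/drawingml/2006/picture">',
    '<pic:nvPicPr><pic:cNvPr id="%d" name="Figure %d"/><pic:cNvPicPr/></pic:nvPicPr>',
    '<pic:blipFill><a:blip r:embed="%s"/><a:stretch><a:fillRect/></a:stretch></pic:blipFill>',
    '<pic:spPr><a:xfrm><a:off x="0" y="0"/><a:ext cx="%d" cy="%d"/></a:xfrm>',
    '<a:prstGeom prst="rect"><a:avLst/></a:prstGeom></pic:spPr>',
    '</pic:pic></a:graphicData></a:graphic></wp:inline></w:drawing></w:r></w:p>'),
    cx, cy, id, id, id, id, rid, cx, cy)
  doc$env$body <- c(doc$env$body, drawing)
  if (!is.null(caption)) docx_add_paragraph(doc, caption)
  invisible(doc)
}

document_xml <- function(doc) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<w:document xmlns:w="http://schemas.openxmlformats.org/wordprocessingml/2006/main" ',
    'xmlns:wp="http://schemas.openxmlformats.org/drawingml/2006/wordprocessingDrawing" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<w:body>", paste(doc$env$body, collapse = ""),
    '<w:sectPr><w:pgSz w:w="11906" w:h="16838"/></w:sectPr>',
    "</w:body></w:document>")
}

content_types_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Default Extension="png" ContentType="image/png"/>',
    '<Override PartName="/word/document.xml" ContentType="application/vnd.openxmlformats-officedocument.wordprocessingml.document.main+xml"/>',
    "</Types>")
}

root_rels_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="word/document.xml"/>',
    "</Relationships>")
}

document_rels_xml <- function(doc) {
  imgs <- vapply(doc$env$images, function(im) sprintf(
    '<Relationship Id="%s" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/image" Target="%s"/>',
    im$rid, im$target), "")
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(imgs, collapse = ""), "</Relationships>")
}

#' Write the assembled document to a .docx file
#' @param doc A `docx_builder`.
#' @param path Output .docx path.
#' @return `path`, invisibly.
#' @export
docx_save <- function(doc, path) {
  stage <- tempfile("docx_stage_")
  on.exit(unlink(stage, recursive = TRUE))
  dir.create(file.path(stage, "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "word", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "word", "media"), recursive = TRUE, showWarnings = FALSE)
  writeLines(content_types_xml(), file.path(stage, "[Content_Types].xml"))
  writeLines(root_rels_xml(), file.path(stage, "_rels", ".rels"))
  writeLines(document_xml(doc), file.path(stage, "word", "document.xml"))
  writeLines(document_rels_xml(doc), file.path(stage, "word", "_rels", "document.xml.rels"))
  for (im in doc$env$images)
    file.copy(im$path, file.path(stage, "word", im$target), overwrite = TRUE)
  files <- c("[Content_Types].xml", "_rels/.rels", "word/document.xml",
             "word/_rels/document.xml.rels",
             vapply(doc$env$images, function(im) file.path("word", im$target), ""))
  path <- file.path(normalizePath(dirname(path), mustWork = TRUE), basename(path))
  tryCatch(
    zip::zip(zipfile = path, files = files, root = stage, mode = "mirror"),
    error = function(e)
      hp_stop("io_error", "failed to write %s: %s", path, conditionMessage(e)))
  invisible(path)
}
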