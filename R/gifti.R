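# Minimal GIFTI reader/writer for surface geometry (.surf.gii) and per-vertex
# metric (.shape.gii) files. Covers the conventions used by hippocampal
# segmentation tools: one POINTSET + TRIANGLE pair per surface, one
# per-vertex float array per metric. Supported encodings: ASCII,
# Base64Binary and GZipBase64Binary (little-endian). Writing uses ASCII so
# that generated fixtures remain plain text.

gifti_datatype_info <- function(dt) {
  switch(dt,
    "NIFTI_TYPE_FLOAT32" = list(what = "double", size = 4L),
    "NIFTI_TYPE_FLOAT64" = list(what = "double", size = 8L),
    "NIFTI_TYPE_INT32"   = list(what = "integer", size = 4L),
    abort_aidhs(sprintf("unsupported GIFTI data type '%s'", dt),
                "aidhs_format_error")
  )
}

gifti_read_darray <- function(node) {
  att <- xml2::xml_attrs(node)
  encoding <- att[["Encoding"]]
  dt <- att[["DataType"]]
  dims <- as.integer(att[grep("^Dim[0-9]$", names(att))])
  n <- prod(dims)
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  vals <- switch(encoding,
    "ASCII" = {
      v <- scan(text = txt, what = numeric(), quiet = TRUE)
      v
    },
    "Base64Binary" = ,
    "GZipBase64Binary" = {
      raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (encoding == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      info <- gifti_datatype_info(dt)
      readBin(raw, what = info$what, n = n, size = info$size,
              endian = "little")
    },
    abort_aidhs(sprintf("unsupported GIFTI encoding '%s'", encoding),
                "aidhs_format_error")
  )
  if (length(vals) != n) {
    abort_aidhs("GIFTI data array length does not match its dimensions",
                "aidhs_format_error")
  }
  if (length(dims) > 1) {
    # GIFTI arrays are row-major by default
    order <- att[["ArrayIndexingOrder"]] %||% "RowMajorOrder"
    if (identical(order, "RowMajorOrder")) {
      vals <- matrix(vals, ncol = dims[2], byrow = TRUE)
    } else {
      vals <- matrix(vals, ncol = dims[2])
    }
  }
  list(intent = att[["Intent"]], values = vals)
}

gifti_read <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(nodes, gifti_read_darray)
}

gifti_darray_xml <- function(values, intent, datatype) {
  if (is.matrix(values)) {
    dims <- sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"',
                    nrow(values), ncol(values))
    flat <- as.vector(t(values))
  } else {
    dims <- sprintf('Dimensionality="1" Dim0="%d"', length(values))
    flat <- values
  }
  txt <- if (datatype == "NIFTI_TYPE_INT32") {
    paste(format(as.integer(flat), scientific = FALSE), collapse = " ")
  } else {
    paste(format(flat, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = " ")
  }
  paste0(
    '<DataArray Intent="', intent, '" DataType="', datatype,
    '" ArrayIndexingOrder="RowMajorOrder" ', dims,
    ' Encoding="ASCII" Endian="LittleEndian" ExternalFileName=""',
    ' ExternalFileOffset="">\n<Data>', txt, "</Data>\n</DataArray>"
  )
}

gifti_write <- function(darrays, path) {
  body <- vapply(darrays, function(d) {
    gifti_darray_xml(d$values, d$intent, d$datatype)
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="', length(darrays), '">\n',
    paste(body, collapse = "\n"), "\n</GIFTI>\n"
  )
  writeLines(xml, path)
  invisible(path)
}

#' Read and write GIFTI metric files
#'
#' Per-vertex metric (shape) files hold one float value per vertex of the
#' reference surface. `read_gifti_metric()` returns a numeric vector;
#' `write_gifti_metric()` writes ASCII-encoded GIFTI.
#'
#' @param path file path (conventionally `*.shape.gii`).
#' @param values numeric vector of per-vertex values.
#' @return `read_gifti_metric()`: numeric vector.
#' @export
read_gifti_metric <- function(path) {
  arrays <- gifti_read(path)
  as.numeric(arrays[[1]]$values)
}

#' @rdname read_gifti_metric
#' @export
write_gifti_metric <- function(values, path) {
  gifti_write(list(list(values = as.numeric(values),
                        intent = "NIFTI_INTENT_SHAPE",
                        datatype = "NIFTI_TYPE_FLOAT32")), path)
}

#' Read and write GIFTI surface files
#'
#' Surface files hold a POINTSET (n x 3 vertex coordinates) and a TRIANGLE
#' (m x 3, 0-based) array. The anterior-posterior coordinate is not part of
#' the GIFTI geometry; it travels in a companion metric file.
#'
#' @param path file path (conventionally `*.surf.gii`).
#' @param ap_path path of the companion per-vertex anterior-posterior
#'   coordinate metric file.
#' @param surface a [hip_surface()].
#' @param hemisphere hemisphere tag for the loaded surface.
#' @return `read_gifti_surface()`: a [hip_surface()].
#' @export
read_gifti_surface <- function(path, ap_path, hemisphere = NA_character_) {
  arrays <- gifti_read(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  pts <- arrays[[match("NIFTI_INTENT_POINTSET", intents)]]$values
  tri <- arrays[[match("NIFTI_INTENT_TRIANGLE", intents)]]$values
  ap <- read_gifti_metric(ap_path)
  hip_surface(pts, tri + 1L, ap, hemisphere = hemisphere)
}

#' @rdname read_gifti_surface
#' @export
write_gifti_surface <- function(surface, path, ap_path) {
  gifti_write(list(
    list(values = surface$vertices, intent = "NIFTI_INTENT_POINTSET",
         datatype = "NIFTI_TYPE_FLOAT32"),
    list(values = surface$faces - 1L, intent = "NIFTI_INTENT_TRIANGLE",
         datatype = "NIFTI_TYPE_INT32")
  ), path)
  write_gifti_metric(surface$ap_coord, ap_path)
  invisible(path)
}
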