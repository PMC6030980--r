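# cvParam accessions used in mzML binary data arrays
.MZML_CV <- list(
  float64 = "MS:1000523", float32 = "MS:1000521",
  zlib = "MS:1000574", none = "MS:1000576",
  mz_array = "MS:1000514", intensity_array = "MS:1000515"
)

# Decode one <binaryDataArray> node -> numeric vector.
.decode_binary_array <- function(bda_node) {
  cvs <- xml2::xml_find_all(bda_node, ".//cvParam")
  acc <- xml2::xml_attr(cvs, "accession")
  size <- if (.MZML_CV$float64 %in% acc) 8L
          else if (.MZML_CV$float32 %in% acc) 4L
          else stop("binary array without a supported float precision ",
                    "cvParam (need 32- or 64-bit float)", call. = FALSE)
  known_comp <- c(.MZML_CV$zlib, .MZML_CV$none)
  comp_acc <- setdiff(acc[grepl("compression",
                                xml2::xml_attr(cvs, "name"))], known_comp)
  if (length(comp_acc)) {
    stop("unsupported binary-data compression scheme: ",
         paste(xml2::xml_attr(cvs, "name")[match(comp_acc, acc)],
               collapse = ", "),
         " (", paste(comp_acc, collapse = ", "), ")", call. = FALSE)
  }
  compressed <- .MZML_CV$zlib %in% acc
  b64 <- xml2::xml_text(xml2::xml_find_first(bda_node, ".//binary"))
  b64 <- gsub("\\s", "", b64)
  bytes <- tryCatch(jsonlite::base64_dec(b64), error = function(e) {
    stop("base64 decode error in binary data array: ",
         conditionMessage(e), call. = FALSE)
  })
  if (compressed) {
    bytes <- tryCatch(memDecompress(bytes, type = "gzip"),
                      error = function(e) {
      stop("zlib decompression failed on binary data array",
           call. = FALSE)
    })
  }
  if (length(bytes) %% size != 0L) {
    stop("truncated binary data array: ", length(bytes),
         " bytes is not a multiple of ", size, call. = FALSE)
  }
  readBin(bytes, "double", n = length(bytes) %/% size, size = size,
          endian = "little")
}

#' Read spectra from an mzML file
#'
#' Parses `<spectrum>` elements and decodes their m/z and intensity binary
#' arrays (64- or 32-bit little-endian floats, zlib-compressed or plain).
#' Spectra are addressable by nativeID (`id` attribute) and by ordinal
#' index. `.gz`/`.zip` inputs are decompressed transparently.
#'
#' @param path path to an mzML document.
#' @return List of [spectrum()] objects, named by nativeID, each with
#'   `source$scan` = nativeID and `source$index` = ordinal (1-based).
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(.maybe_decompress(path))
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(nodes)) nodes <- xml2::xml_find_all(doc, ".//spectrum")
  out <- vector("list", length(nodes))
  ids <- character(length(nodes))
  for (k in seq_along(nodes)) {
    node <- nodes[[k]]
    id <- xml2::xml_attr(node, "id")
    ids[k] <- if (is.na(id)) paste0("index=", k - 1L) else id
    bdas <- xml2::xml_find_all(node, ".//binaryDataArray")
    mz <- numeric(); int <- numeric()
    for (bda in bdas) {
      acc <- xml2::xml_attr(xml2::xml_find_all(bda, ".//cvParam"),
                            "accession")
      vals <- .decode_binary_array(bda)
      if (.MZML_CV$mz_array %in% acc) mz <- vals
      if (.MZML_CV$intensity_array %in% acc) int <- vals
    }
    if (length(int) == 0L) int <- rep(0, length(mz))
    prec_node <- xml2::xml_find_first(
      node, ".//precursor//selectedIon")
    prec <- NULL
    if (!inherits(prec_node, "xml_missing")) {
      pcv <- xml2::xml_find_all(prec_node, ".//cvParam")
      pacc <- xml2::xml_attr(pcv, "accession")
      pval <- xml2::xml_attr(pcv, "value")
      pm <- pval[match("MS:1000744", pacc)] # selected ion m/z
      pz <- pval[match("MS:1000041", pacc)] # charge state
      prec <- list(mz = as.numeric(pm), charge = as.integer(pz))
    }
    out[[k]] <- spectrum(mz, int,
                         source = list(filename = path, scan = ids[k],
                                       index = k),
                         precursor = prec)
  }
  names(out) <- ids
  out
}

#' Fetch one spectrum from a read mzML file by nativeID or index
#' @param spectra result of [read_mzml()].
#' @param id nativeID string, or
#' @param index 1-based ordinal.
#' @return A [spectrum()].
#' @export
mzml_spectrum <- function(spectra, id = NULL, index = NULL) {
  if (!is.null(id)) {
    s <- spectra[[id]]
    if (is.null(s)) stop("no spectrum with nativeID '", id, "'",
                         call. = FALSE)
    s
  } else if (!is.null(index)) {
    if (index < 1L || index > length(spectra)) {
      stop("spectrum index out of range", call. = FALSE)
    }
    spectra[[index]]
  } else stop("give id= or index=", call. = FALSE)
}

# Encode a numeric vector as an mzML <binaryDataArray> body.
.encode_binary_array <- function(values, size = 8L, compress = FALSE) {
  bytes <- writeBin(as.numeric(values), raw(), size = size,
                    endian = "little")
  if (compress) bytes <- memCompress(bytes, type = "gzip") # zlib stream
  gsub("\n", "", jsonlite::base64_enc(bytes), fixed = TRUE)
}

#' Write spectra to a minimal mzML document
#'
#' Emits a small standalone mzML with one `<spectrum>` per input, m/z and
#' intensity encoded as little-endian floats (64-bit by default),
#' optionally zlib-compressed. Intended for fixtures and interchange of
#' synthetic data.
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output path.
#' @param compression `"none"` or `"zlib"`.
#' @param precision 64 or 32 (bits per float).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path, compression = c("none", "zlib"),
                       precision = 64L) {
  compression <- match.arg(compression)
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  size <- if (precision == 64L) 8L else 4L
  prec_acc <- if (precision == 64L) .MZML_CV$float64 else .MZML_CV$float32
  prec_name <- if (precision == 64L) "64-bit float" else "32-bit float"
  comp_acc <- if (compression == "zlib") .MZML_CV$zlib else .MZML_CV$none
  comp_name <- if (compression == "zlib") "zlib compression"
               else "no compression"
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  bda <- function(values, kind_acc, kind_name) {
    b64 <- .encode_binary_array(values, size, compression == "zlib")
    paste0(
      '      <binaryDataArray encodedLength="', nchar(b64), '">\n',
      '        <cvParam cvRef="MS" accession="', prec_acc, '" name="',
      prec_name, '"/>\n',
      '        <cvParam cvRef="MS" accession="', comp_acc, '" name="',
      comp_name, '"/>\n',
      '        <cvParam cvRef="MS" accession="', kind_acc, '" name="',
      kind_name, '"/>\n',
      '        <binary>', b64, '</binary>\n',
      '      </binaryDataArray>'
    )
  }
  blocks <- vapply(seq_along(spectra), function(k) {
    s <- spectra[[k]]
    id <- s$source$scan
    if (is.null(id) || is.na(id)) id <- paste0("scan=", k)
    prec_xml <- ""
    if (!is.null(s$precursor) && !is.na(s$precursor$mz)) {
      prec_xml <- paste0(
        '    <precursorList count="1"><precursor>',
        '<selectedIonList count="1"><selectedIon>\n',
        '      <cvParam cvRef="MS" accession="MS:1000744" ',
        'name="selected ion m/z" value="', s$precursor$mz, '"/>\n',
        if (!is.null(s$precursor$charge) && !is.na(s$precursor$charge)) {
          paste0('      <cvParam cvRef="MS" accession="MS:1000041" ',
                 'name="charge state" value="', s$precursor$charge, '"/>\n')
        } else "",
        '    </selectedIon></selectedIonList></precursor>',
        '</precursorList>\n')
    }
    paste0(
      '  <spectrum index="', k - 1L, '" id="', esc(id),
      '" defaultArrayLength="', nrow(s$peaks), '">\n',
      prec_xml,
      '    <binaryDataArrayList count="2">\n',
      bda(s$peaks$mz, .MZML_CV$mz_array, "m/z array"), "\n",
      bda(s$peaks$intensity, .MZML_CV$intensity_array, "intensity array"),
      "\n",
      '    </binaryDataArrayList>\n',
      '  </spectrum>'
    )
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<run id="run1">\n',
    '<spectrumList count="', length(spectra), '" ',
    'defaultDataProcessingRef="dp1">\n',
    paste(blocks, collapse = "\n"), "\n",
    '</spectrumList>\n</run>\n</mzML>\n'
  )
  writeLines(doc, path, sep = "")
  invisible(path)
}
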