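# Transparent decompression: .gz and .zip inputs are inflated once into a
# temporary file so that byte-offset indexing and seeking work on a plain
# file. Returns the path to read.
.maybe_decompress <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gz") {
    out <- tempfile(fileext = paste0(".", tools::file_ext(sub(
      "\\.gz$", "", path, ignore.case = TRUE))))
    inc <- gzfile(path, "rb")
    on.exit(close(inc), add = TRUE)
    ouc <- file(out, "wb")
    on.exit(close(ouc), add = TRUE)
    repeat {
      chunk <- readBin(inc, "raw", 1048576L)
      if (!length(chunk)) break
      writeBin(chunk, ouc)
    }
    out
  } else if (ext == "zip") {
    listing <- utils::unzip(path, list = TRUE)
    if (nrow(listing) < 1L) stop("empty zip archive: ", path, call. = FALSE)
    dir <- tempfile("unzip")
    utils::unzip(path, files = listing$Name[1L], exdir = dir)
    file.path(dir, listing$Name[1L])
  } else {
    path
  }
}

#' Read an MGF peak-list file with a byte-offset index
#'
#' Builds, in a single pass, a byte-offset index of every
#' `BEGIN IONS`/`END IONS` block, recording `TITLE`, `PEPMASS`, `CHARGE` and
#' `SCANS` headers. Individual spectra are then fetched lazily with
#' [mgf_spectrum()], which re-reads only the requested block's bytes.
#' `.gz` and `.zip` inputs are decompressed transparently.
#'
#' @param path path to an MGF file (optionally `.mgf.gz` or `.zip`).
#' @return Object of class `mgf_file`: list with `path` (the seekable file),
#'   `source_path` (as given) and `index`, a data frame with one row per
#'   spectrum (`index`, `begin_offset`, `end_offset`, `title`, `pepmass`,
#'   `charge`, `scans`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  plain <- .maybe_decompress(path)
  raw <- readBin(plain, "raw", file.size(plain))
  txt <- rawToChar(raw)
  # offsets of line starts (byte-accurate: MGF is ASCII)
  nl <- c(0L, which(raw == as.raw(10L)))
  line_start <- nl[-length(nl)] + 1L
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  lines <- sub("\r$", "", lines)
  if (length(lines) > length(line_start)) {
    line_start <- c(line_start, utils::tail(nl, 1L) + 1L)
  }

  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  rows <- list()
  used_ends <- 0L
  for (bi in seq_along(begins)) {
    b <- begins[bi]
    e <- ends[ends > b]
    e <- if (length(e)) e[1L] else NA_integer_
    if (is.na(e) || (bi < length(begins) && e > begins[bi + 1L])) {
      stop("malformed MGF block: BEGIN IONS at line ", b,
           " without END IONS", call. = FALSE)
    }
    hdr <- lines[(b + 1L):(e - 1L)]
    get <- function(key) {
      v <- grep(paste0("^", key, "="), hdr, value = TRUE)
      if (length(v)) sub(paste0("^", key, "="), "", v[1L]) else NA_character_
    }
    pep <- get("PEPMASS")
    pep_mz <- if (!is.na(pep)) as.numeric(strsplit(pep, "\\s+")[[1L]][1L])
              else NA_real_
    ch <- get("CHARGE")
    ch_n <- if (!is.na(ch)) as.integer(sub("\\+$", "", ch)) else NA_integer_
    rows[[bi]] <- data.frame(
      index = bi,
      begin_offset = line_start[b],
      end_offset = if (e < length(line_start)) line_start[e + 1L] - 1L
                   else length(raw),
      title = get("TITLE"),
      pepmass = pep_mz,
      charge = ch_n,
      scans = get("SCANS"),
      stringsAsFactors = FALSE
    )
  }
  idx <- if (length(rows)) do.call(rbind, rows) else data.frame(
    index = integer(), begin_offset = integer(), end_offset = integer(),
    title = character(), pepmass = numeric(), charge = integer(),
    scans = character(), stringsAsFactors = FALSE)
  structure(list(path = plain, source_path = path, index = idx),
            class = "mgf_file")
}

#' Fetch one spectrum from an indexed MGF file
#'
#' Seeks to the block's byte offset and reads only that block.
#'
#' @param mgf an [read_mgf()] result.
#' @param index ordinal spectrum number (1-based), or
#' @param scan a `SCANS` value, or
#' @param title a `TITLE` value.
#' @return A [spectrum()].
#' @export
mgf_spectrum <- function(mgf, index = NULL, scan = NULL, title = NULL) {
  stopifnot(inherits(mgf, "mgf_file"))
  i <- if (!is.null(index)) {
    match(index, mgf$index$index)
  } else if (!is.null(scan)) {
    match(as.character(scan), mgf$index$scans)
  } else if (!is.null(title)) {
    match(title, mgf$index$title)
  } else stop("give one of index=, scan=, title=", call. = FALSE)
  if (is.na(i)) stop("spectrum not found in MGF index", call. = FALSE)
  row <- mgf$index[i, ]
  con <- file(mgf$path, "rb")
  on.exit(close(con))
  seek(con, row$begin_offset - 1L)
  block <- readBin(con, "raw", row$end_offset - row$begin_offset + 1L)
  lines <- strsplit(rawToChar(block), "\n", fixed = TRUE)[[1L]]
  lines <- sub("\r$", "", lines)
  peak_lines <- grep("^[0-9]", lines, value = TRUE)
  mz <- numeric(); int <- numeric()
  if (length(peak_lines)) {
    parts <- strsplit(peak_lines, "[ \t]+")
    mz <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
    int <- vapply(parts, function(p)
      if (length(p) > 1L) as.numeric(p[2L]) else 0, numeric(1))
  }
  prec <- if (!is.na(row$pepmass)) {
    list(mz = row$pepmass, charge = row$charge)
  } else NULL
  spectrum(mz, int,
           source = list(filename = mgf$source_path, scan = row$scans,
                         index = row$index, title = row$title),
           precursor = prec)
}

#' Read all spectra from an MGF file
#' @param path MGF path (optionally compressed).
#' @return List of [spectrum()] objects in file order.
#' @export
read_mgf_spectra <- function(path) {
  mgf <- read_mgf(path)
  lapply(mgf$index$index, function(i) mgf_spectrum(mgf, index = i))
}

#' Write spectra to an MGF file
#'
#' m/z values are printed with 6 decimals and intensities with 4, so a
#' write/read round trip is peak-identical at the printed precision.
#'
#' @param spectra a [spectrum()] or list of spectra.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "wb") # binary mode: deterministic newlines
  on.exit(close(con))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    stopifnot(inherits(s, "spectrum"))
    out <- c("BEGIN IONS")
    ttl <- s$source$title
    out <- c(out, paste0("TITLE=", if (!is.null(ttl) && !is.na(ttl)) ttl
                         else paste0("spectrum_", k)))
    if (!is.null(s$precursor)) {
      out <- c(out, sprintf("PEPMASS=%.6f", s$precursor$mz))
      if (!is.null(s$precursor$charge) && !is.na(s$precursor$charge)) {
        out <- c(out, sprintf("CHARGE=%d+", s$precursor$charge))
      }
    }
    scn <- s$source$scan
    out <- c(out, paste0("SCANS=", if (!is.null(scn) && !is.na(scn)) scn
                         else k))
    out <- c(out, sprintf("%.6f %.4f", s$peaks$mz, s$peaks$intensity),
             "END IONS", "")
    writeBin(charToRaw(paste0(paste(out, collapse = "\n"), "\n")), con)
  }
  invisible(path)
}

#' @export
print.mgf_file <- function(x, ...) {
  cat("<mgf_file> ", basename(x$source_path), ": ", nrow(x$index),
      " spectra indexed\n", sep = "")
  invisible(x)
}
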