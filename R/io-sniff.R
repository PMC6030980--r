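#' Sniff the format of an input file
#'
#' Extension-based detection (`.mgf`, `.mzml`, `.mzid`/`.mzidentml`,
#' `.csv`, with `.gz`/`.zip` stripped first), falling back to content
#' sniffing: a `BEGIN IONS` line means MGF, an XML root of `mzML` or
#' `MzIdentML` the respective standard, a comma-separated header line CSV.
#'
#' @param path input file.
#' @return One of `"mgf"`, `"mzml"`, `"mzid"`, `"csv"`; errors when the
#'   format cannot be determined.
#' @export
sniff_format <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  name <- sub("\\.(gz|zip)$", "", path, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(name))
  if (ext == "mgf") return("mgf")
  if (ext == "mzml") return("mzml")
  if (ext %in% c("mzid", "mzidentml")) return("mzid")
  if (ext == "csv") return("csv")
  plain <- .maybe_decompress(path)
  head <- readLines(plain, n = 50L, warn = FALSE)
  if (any(grepl("^BEGIN IONS", head))) return("mgf")
  if (any(grepl("<mzML", head))) return("mzml")
  if (any(grepl("<MzIdentML", head, ignore.case = TRUE))) return("mzid")
  if (length(head) && grepl(",", head[1L]) &&
      grepl("pepSeq1", head[1L])) return("csv")
  stop("cannot determine format of ", path,
       " (supported formats: mgf, mzml, mzid, csv, optionally .gz/.zip)",
       call. = FALSE)
}
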