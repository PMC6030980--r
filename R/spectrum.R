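#' Construct a spectrum (peak list)
#'
#' @param mz numeric vector of peak m/z values (Th); stored sorted
#'   ascending.
#' @param intensity numeric vector of non-negative intensities (same
#'   length).
#' @param source list with provenance: `filename`, `scan` (identifier) and/or
#'   `index` (ordinal).
#' @param precursor optional list with `mz` and `charge`.
#' @return Object of class `spectrum`: list with `peaks` (data frame with
#'   columns `mz`, `intensity`), `source`, `precursor`.
#' @export
#' @examples
#' spectrum(c(100.1, 250.2), c(10, 20))
spectrum <- function(mz = numeric(), intensity = numeric(),
                     source = list(), precursor = NULL) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  ord <- order(mz)
  structure(list(
    peaks = data.frame(mz = as.numeric(mz[ord]),
                       intensity = as.numeric(intensity[ord])),
    source = source,
    precursor = precursor
  ), class = "spectrum")
}

#' Number of peaks in a spectrum
#' @param spec a [spectrum()].
#' @return Integer peak count.
#' @export
n_peaks <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  nrow(spec$peaks)
}

#' @export
print.spectrum <- function(x, ...) {
  src <- x$source
  cat("<spectrum> ", n_peaks(x), " peaks",
      if (!is.null(src$scan)) paste0("  scan=", src$scan),
      if (!is.null(src$filename)) paste0("  file=", basename(src$filename)),
      "\n", sep = "")
  invisible(x)
}
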