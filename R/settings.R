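#' Parse a tolerance string
#'
#' Accepts forms like `"10ppm"`, `"0.02Da"` (case-insensitive, optional
#' whitespace) or an already-parsed tolerance list.
#'
#' @param x tolerance string, number (interpreted as ppm), or list with
#'   `value` and `unit`.
#' @return List with elements `value` (> 0) and `unit` (`"ppm"` or `"da"`).
#' @export
#' @examples
#' parse_tolerance("10ppm")
#' parse_tolerance("0.02 Da")
parse_tolerance <- function(x) {
  if (is.list(x) && all(c("value", "unit") %in% names(x))) {
    x$unit <- tolower(x$unit)
  } else if (is.numeric(x)) {
    x <- list(value = x, unit = "ppm")
  } else if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(ppm|da)\\s*$", x,
                               ignore.case = TRUE))[[1L]]
    if (length(m) != 3L) {
      stop("cannot parse tolerance '", x,
           "' (expected e.g. '10ppm' or '0.02Da')", call. = FALSE)
    }
    x <- list(value = as.numeric(m[2L]), unit = tolower(m[3L]))
  } else {
    stop("invalid tolerance", call. = FALSE)
  }
  if (!is.finite(x$value) || x$value <= 0) {
    stop("tolerance value must be > 0", call. = FALSE)
  }
  if (!x$unit %in% c("ppm", "da")) {
    stop("tolerance unit must be ppm or Da", call. = FALSE)
  }
  x[c("value", "unit")]
}

# Half-width of the tolerance window in Da around a theoretical m/z.
.tolerance_da <- function(tolerance, theoretical_mz) {
  if (tolerance$unit == "ppm") {
    tolerance$value * theoretical_mz / 1e6
  } else {
    rep_len(tolerance$value, length(theoretical_mz))
  }
}

#' Annotation settings: the re-annotation hypothesis
#'
#' Bundles everything that controls which theoretical fragments are generated
#' and how peaks are matched.
#'
#' @param tolerance matching tolerance, e.g. `"10ppm"` or `"0.02Da"`
#'   (see [parse_tolerance()]).
#' @param ion_types subset of `c("precursor","b","c","y","z")`.
#' @param max_fragment_charge upper bound on fragment charge; the effective
#'   ceiling is `min(max_fragment_charge, precursor_charge)`.
#' @param losses_enabled generate H2O/NH3 neutral-loss fragment variants?
#' @param z_radical use the radical z-dot convention (classical z + 1 H)?
#' @return Object of class `annotation_settings`.
#' @export
#' @examples
#' annotation_settings("20ppm", ion_types = c("b", "y"))
annotation_settings <- function(tolerance = "10ppm",
                                ion_types = c("precursor", "b", "y"),
                                max_fragment_charge = 2L,
                                losses_enabled = FALSE,
                                z_radical = FALSE) {
  allowed <- c("precursor", "b", "c", "y", "z")
  ion_types <- unique(as.character(ion_types))
  if (!all(ion_types %in% allowed)) {
    stop("ion_types must be a subset of {",
         paste(allowed, collapse = ","), "}", call. = FALSE)
  }
  structure(list(
    tolerance = parse_tolerance(tolerance),
    ion_types = ion_types,
    max_fragment_charge = as.integer(max_fragment_charge),
    losses_enabled = isTRUE(losses_enabled),
    z_radical = isTRUE(z_radical)
  ), class = "annotation_settings")
}

#' @export
print.annotation_settings <- function(x, ...) {
  cat("<annotation_settings> tol=", x$tolerance$value, x$tolerance$unit,
      " ions=", paste(x$ion_types, collapse = ","),
      " zmax=", x$max_fragment_charge,
      " losses=", x$losses_enabled,
      " z_radical=", x$z_radical, "\n", sep = "")
  invisible(x)
}
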