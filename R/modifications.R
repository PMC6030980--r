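#' Build a modification registry
#'
#' A modification registry maps lowercase tokens (the tokens that may appear
#' in a peptide sequence string, e.g. `"Mox"` for oxidised methionine) to mass
#' deltas and residue specificities. Registries are plain data frames and are
#' handled functionally: [register_modification()] returns an updated copy.
#'
#' @param name character vector of tokens, each matching `[a-z][a-z0-9]*`.
#' @param mass_delta numeric vector of mass shifts in Da.
#' @param specificity character vector (same length) of residue codes the
#'   modification applies to, e.g. `"M"` or `"STY"`; `"Nterm"`/`"Cterm"` mark
#'   terminal specificity; `"*"` means any residue.
#' @param origin `"input-data"` or `"user-defined"` per entry (recycled).
#'
#' @return A data frame of class `mod_registry` with columns `name`,
#'   `mass_delta`, `specificity`, `origin`.
#' @export
#' @examples
#' reg <- modification_registry("ox", 15.99491, "M")
modification_registry <- function(name = character(), mass_delta = numeric(),
                                  specificity = character(),
                                  origin = "user-defined") {
  stopifnot(length(name) == length(mass_delta))
  if (length(specificity) == 0L && length(name) > 0L) specificity <- "*"
  bad <- name[!grepl("^[a-z][a-z0-9]*$", name)]
  if (length(bad)) {
    stop("invalid modification name(s): ", paste(bad, collapse = ", "),
         " (must match [a-z][a-z0-9]*)", call. = FALSE)
  }
  if (any(!is.finite(mass_delta))) {
    stop("modification mass_delta must be finite", call. = FALSE)
  }
  reg <- data.frame(
    name        = as.character(name),
    mass_delta  = as.numeric(mass_delta),
    specificity = rep_len(as.character(specificity), length(name)),
    origin      = rep_len(as.character(origin), length(name)),
    stringsAsFactors = FALSE
  )
  class(reg) <- c("mod_registry", "data.frame")
  reg
}

#' Default modification registry
#'
#' Starter registry shipped with the package: oxidation `ox` (+15.99491, M),
#' carbamidomethyl `cm` (+57.02146, C), phospho `ph` (+79.96633, S/T/Y),
#' deamidation `deam` (+0.98402, N/Q) and acetyl `ac` (+42.01057, K or
#' N-terminus). Users may extend or override it with
#' [register_modification()] or replace it entirely via
#' [read_modifications()].
#'
#' @return A `mod_registry` data frame.
#' @export
default_modifications <- function() {
  modification_registry(
    name        = c("ox", "cm", "ph", "deam", "ac"),
    mass_delta  = c(15.99491, 57.02146, 79.96633, 0.98402, 42.01057),
    specificity = c("M", "C", "STY", "NQ", "K"),
    origin      = "input-data"
  )
}

#' Register (or overwrite) a modification
#'
#' Adds a modification token to a registry so that subsequent
#' [parse_sequence()] calls resolve it. Re-registering an existing name
#' overwrites its mass, mirroring an editable modification table.
#'
#' @param registry a `mod_registry`.
#' @param name lowercase token (`[a-z][a-z0-9]*`).
#' @param mass_delta mass shift in Da (finite).
#' @param specificity residue specificity string (default `"*"` = any).
#' @param origin provenance tag, default `"user-defined"`.
#' @return The updated registry.
#' @export
#' @examples
#' reg <- register_modification(default_modifications(), "dss", 138.06808, "K")
register_modification <- function(registry, name, mass_delta,
                                  specificity = "*",
                                  origin = "user-defined") {
  stopifnot(inherits(registry, "mod_registry"))
  new <- modification_registry(name, mass_delta, specificity, origin)
  registry <- registry[registry$name != name, , drop = FALSE]
  out <- rbind(registry, new)
  rownames(out) <- NULL
  class(out) <- c("mod_registry", "data.frame")
  out
}

#' Look up a modification token
#' @param registry a `mod_registry`.
#' @param name token to look up.
#' @return One-row data frame, or an error if the token is unknown.
#' @export
lookup_modification <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown modification token: '", name, "'", call. = FALSE)
  }
  registry[i, , drop = FALSE]
}

#' Read / write a modification registry as a plain-text table
#'
#' The on-disk format is whitespace- or tab-separated with columns
#' `name`, `mass_delta` and optionally `specificity`; lines starting with
#' `#` are comments. This lets users supply their own registry.
#'
#' @param path file path.
#' @return [read_modifications()] returns a `mod_registry`;
#'   [write_modifications()] returns `path` invisibly.
#' @export
read_modifications <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "mass_delta") %in% names(tab))) {
    stop("modification table needs columns 'name' and 'mass_delta'",
         call. = FALSE)
  }
  spec <- if ("specificity" %in% names(tab)) tab$specificity else "*"
  modification_registry(tab$name, tab$mass_delta, spec, "input-data")
}

#' @rdname read_modifications
#' @param registry a `mod_registry` to write.
#' @export
write_modifications <- function(registry, path) {
  stopifnot(inherits(registry, "mod_registry"))
  utils::write.table(
    registry[, c("name", "mass_delta", "specificity")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
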