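#' Construct a peptide
#'
#' @param sequence character vector of one-letter residue codes, or a single
#'   string of uppercase residues (no modification tokens; use
#'   [parse_sequence()] for the full grammar).
#' @param mods data frame with columns `position` (1-based residue index;
#'   0 = N-terminus, length+1 = C-terminus), `name` (token) and `mass_delta`
#'   (Da). May be `NULL`.
#' @return An object of class `peptide`: list with elements `sequence`
#'   (character vector) and `mods` (data frame).
#' @export
#' @examples
#' peptide("PEPTIDE")
peptide <- function(sequence, mods = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  }
  if (length(sequence) < 1L) stop("peptide sequence must be non-empty",
                                  call. = FALSE)
  known <- names(.residue_composition)
  bad <- which(!(sequence %in% known))
  if (length(bad)) {
    stop("unknown residue code '", sequence[bad[1L]], "' at position ",
         bad[1L], call. = FALSE)
  }
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), name = character(),
                       mass_delta = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("position", "name", "mass_delta") %in% names(mods)))
  n <- length(sequence)
  if (any(mods$position < 0L | mods$position > n + 1L)) {
    stop("modification position out of range [0, length+1]", call. = FALSE)
  }
  structure(list(sequence = sequence, mods = mods), class = "peptide")
}

#' Parse a peptide sequence string
#'
#' Grammar: uppercase letters are residues; a lowercase alphanumeric run
#' immediately following a residue names a modification on that residue
#' (resolved against `registry`); a `#` immediately following a residue (or
#' its modification token) marks the cross-link site; at most one `#` is
#' allowed.
#'
#' @param text sequence string, e.g. `"KMoxQK#L"`.
#' @param registry modification registry used to resolve lowercase tokens.
#' @return List with elements `peptide` (a [peptide()]) and `link_position`
#'   (1-based residue index, or `NA_integer_` if no `#` present).
#' @export
#' @examples
#' parse_sequence("GK#")            # link on K
#' parse_sequence("Mox")            # oxidised methionine
parse_sequence <- function(text, registry = default_modifications()) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("sequence string must be a non-empty character scalar",
         call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  residues <- character()
  mods <- list()
  link <- NA_integer_
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[A-Z]$", ch)) {
      if (!(ch %in% names(.residue_composition))) {
        stop("unknown residue letter '", ch, "' at position ", i,
             call. = FALSE)
      }
      residues <- c(residues, ch)
      i <- i + 1L
    } else if (grepl("^[a-z]$", ch)) {
      if (length(residues) == 0L) {
        stop("modification token at position ", i,
             " precedes any residue", call. = FALSE)
      }
      j <- i
      while (j <= n && grepl("^[a-z0-9]$", chars[j])) j <- j + 1L
      token <- paste(chars[i:(j - 1L)], collapse = "")
      entry <- lookup_modification(registry, token)
      mods[[length(mods) + 1L]] <- data.frame(
        position = length(residues), name = token,
        mass_delta = entry$mass_delta, stringsAsFactors = FALSE
      )
      i <- j
    } else if (ch == "#") {
      if (!is.na(link)) {
        stop("multiple cross-link symbols '#' in sequence", call. = FALSE)
      }
      if (length(residues) == 0L) {
        stop("cross-link symbol '#' at position ", i,
             " precedes any residue", call. = FALSE)
      }
      link <- length(residues)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' at position ", i, call. = FALSE)
    }
  }
  mods <- if (length(mods)) do.call(rbind, mods) else NULL
  list(peptide = peptide(residues, mods), link_position = link)
}

#' Render a peptide back to its canonical sequence string
#'
#' Inverse of [parse_sequence()] on canonical strings: each residue is
#' followed by its modification tokens (in parse order) and then by `#` if it
#' is the cross-link site. Terminal modifications (position 0 or length+1)
#' render adjacent to the first/last residue.
#'
#' @param p a [peptide()].
#' @param link_position optional 1-based cross-link site.
#' @return Character scalar.
#' @export
render_sequence <- function(p, link_position = NA_integer_) {
  stopifnot(inherits(p, "peptide"))
  n <- length(p$sequence)
  out <- character(n)
  for (i in seq_len(n)) {
    pos <- p$mods$position
    pos[pos == 0L] <- 1L
    pos[pos == n + 1L] <- n
    toks <- p$mods$name[pos == i]
    out[i] <- paste0(p$sequence[i], paste(toks, collapse = ""),
                     if (!is.na(link_position) && link_position == i) "#"
                     else "")
  }
  paste(out, collapse = "")
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of the residue masses, plus one water (the termini), plus all
#' modification mass deltas.
#'
#' @param p a [peptide()].
#' @return Neutral mass in Da.
#' @export
#' @examples
#' peptide_neutral_mass(peptide("G"))  # 75.03203
peptide_neutral_mass <- function(p) {
  stopifnot(inherits(p, "peptide"))
  masses <- residue_masses()
  sum(masses[p$sequence]) + physical_constants$water_mass +
    sum(p$mods$mass_delta)
}

#' Convert between neutral mass and m/z
#'
#' `mz_from_neutral()` computes (neutral + z * proton) / z for a positive
#' ion of charge z; `neutral_from_mz()` is its inverse.
#'
#' @param neutral neutral mass in Da.
#' @param charge positive integer charge state.
#' @return m/z in Thompson (resp. neutral mass in Da).
#' @export
#' @examples
#' mz_from_neutral(799.35996, 2)
mz_from_neutral <- function(neutral, charge) {
  if (any(charge < 1L) || any(charge != round(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (neutral + charge * physical_constants$proton_mass) / charge
}

#' @rdname mz_from_neutral
#' @param mz m/z in Thompson.
#' @export
neutral_from_mz <- function(mz, charge) {
  if (any(charge < 1L) || any(charge != round(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  mz * charge - charge * physical_constants$proton_mass
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", render_sequence(x), "  (", length(x$sequence),
      " residues, ", nrow(x$mods), " mods, M = ",
      sprintf("%.5f", peptide_neutral_mass(x)), " Da)\n", sep = "")
  invisible(x)
}
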