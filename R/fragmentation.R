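# Sum of residue + modification masses over residue range lo..hi of a
# peptide. Terminal modifications (position 0 / length+1) are attributed to
# the first/last residue for range membership.
.range_mass <- function(p, lo, hi) {
  masses <- residue_masses()
  m <- sum(masses[p$sequence[lo:hi]])
  if (nrow(p$mods)) {
    n <- length(p$sequence)
    pos <- p$mods$position
    pos[pos == 0L] <- 1L
    pos[pos == n + 1L] <- n
    m <- m + sum(p$mods$mass_delta[pos >= lo & pos <= hi])
  }
  m
}

#' Generate theoretical fragment ions for a PSM
#'
#' Produces precursor, b, c, y and z ions for each peptide of a linear or
#' cross-linked PSM, at every charge from 1 to
#' `min(precursor_charge, settings$max_fragment_charge)`.
#'
#' Neutral masses follow the standard backbone-cleavage arithmetic:
#' `b_i` = sum of residues 1..i (plus in-range modifications);
#' `y_j` = sum of the last j residues plus water; `c_i = b_i + NH3`;
#' `z_j = y_j - NH3` (plus one H when `settings$z_radical`). A fragment of
#' one peptide whose residue range covers its cross-link site additionally
#' carries the cross-linker mass plus the entire neutral mass of the partner
#' peptide; the precursor ion is the full (cross-linked) assembly.
#'
#' @param psm an [xl_psm()].
#' @param settings an [annotation_settings()].
#' @return A data frame of class `fragment_ions`, one row per fragment ion,
#'   with columns `label`, `series`, `index`, `peptide_id`, `charge`,
#'   `neutral_mass`, `mz`, `loss`, `contains_link`. The generating PSM is
#'   attached as attribute `psm` (used by [apply_neutral_losses()]).
#' @export
#' @examples
#' psm <- psm_from_sequences("PEPTIDE")
#' generate_fragments(psm, annotation_settings(ion_types = c("b", "y")))
generate_fragments <- function(psm, settings = annotation_settings()) {
  stopifnot(inherits(psm, "xl_psm"), inherits(settings, "annotation_settings"))
  if (settings$max_fragment_charge < 1L) {
    stop("max_fragment_charge must be >= 1", call. = FALSE)
  }
  charges <- seq_len(min(psm$precursor_charge, settings$max_fragment_charge))
  consts <- physical_constants
  xl <- is_crosslinked(psm)
  pep_neutral <- vapply(psm$peptides, peptide_neutral_mass, numeric(1))
  ids <- c("alpha", "beta")[seq_along(psm$peptides)]

  rows <- list()
  add <- function(series, index, pid, neutral, contains_link) {
    for (z in charges) {
      rows[[length(rows) + 1L]] <<- data.frame(
        label = if (series == "precursor") "P" else paste0(series, index),
        series = series, index = index, peptide_id = pid, charge = z,
        neutral_mass = neutral, mz = mz_from_neutral(neutral, z),
        loss = "none", contains_link = contains_link,
        stringsAsFactors = FALSE
      )
    }
  }

  series <- setdiff(settings$ion_types, "precursor")
  for (k in seq_along(psm$peptides)) {
    p <- psm$peptides[[k]]
    n <- length(p$sequence)
    link <- psm$link_positions[k]
    partner <- if (xl) psm$crosslinker_mass + pep_neutral[-k][1L] else 0
    if (n < 2L || !length(series)) next
    for (i in seq_len(n - 1L)) {
      prefix <- .range_mass(p, 1L, i)
      suffix <- .range_mass(p, i + 1L, n)
      j <- n - i  # suffix length for the complementary y/z ion
      pre_link <- xl && !is.na(link) && link <= i
      suf_link <- xl && !is.na(link) && link > i
      b <- prefix + if (pre_link) partner else 0
      y <- suffix + consts$water_mass + if (suf_link) partner else 0
      if ("b" %in% series) add("b", i, ids[k], b, pre_link)
      if ("c" %in% series) add("c", i, ids[k], b + consts$ammonia_mass,
                               pre_link)
      if ("y" %in% series) add("y", j, ids[k], y, suf_link)
      if ("z" %in% series) {
        z_mass <- y - consts$ammonia_mass +
          if (settings$z_radical) consts$hydrogen_mass else 0
        add("z", j, ids[k], z_mass, suf_link)
      }
    }
  }
  if ("precursor" %in% settings$ion_types) {
    neutral <- sum(pep_neutral) + if (xl) psm$crosslinker_mass else 0
    add("precursor", 0L, "alpha", neutral, xl)
  }

  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    label = character(), series = character(), index = integer(),
    peptide_id = character(), charge = integer(), neutral_mass = numeric(),
    mz = numeric(), loss = character(), contains_link = logical(),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "psm") <- psm
  class(out) <- c("fragment_ions", "data.frame")
  out
}

# Residue range (within its own peptide) covered by a fragment row.
.fragment_range <- function(frag_row, psm) {
  k <- if (frag_row$peptide_id == "beta") 2L else 1L
  p <- psm$peptides[[k]]
  n <- length(p$sequence)
  switch(frag_row$series,
    precursor = list(k = k, lo = 1L, hi = n),
    b = ,
    c = list(k = k, lo = 1L, hi = frag_row$index),
    y = ,
    z = list(k = k, lo = n - frag_row$index + 1L, hi = n)
  )
}

#' Add neutral-loss fragment variants
#'
#' When enabled, each fragment whose own residue range contains S, T, E or D
#' gains a water-loss variant (neutral - H2O) and each whose range contains
#' R, K, N or Q gains an ammonia-loss variant (neutral - NH3). Only the
#' fragment's own peptide range is consulted, except for the precursor of a
#' cross-linked PSM, which consults both sequences. At most one loss per
#' variant; base fragments are always retained.
#'
#' @param fragments a `fragment_ions` data frame from [generate_fragments()].
#' @param enabled logical; when `FALSE` the input is returned unchanged.
#' @return Augmented `fragment_ions` data frame.
#' @export
apply_neutral_losses <- function(fragments, enabled = TRUE) {
  stopifnot(inherits(fragments, "fragment_ions"))
  if (!enabled || nrow(fragments) == 0L) return(fragments)
  psm <- attr(fragments, "psm")
  consts <- physical_constants
  extra <- list()
  for (r in seq_len(nrow(fragments))) {
    row <- fragments[r, , drop = FALSE]
    rng <- .fragment_range(row, psm)
    res <- psm$peptides[[rng$k]]$sequence[rng$lo:rng$hi]
    if (row$series == "precursor" && is_crosslinked(psm)) {
      res <- c(res, psm$peptides[[2L]]$sequence)
    }
    mk <- function(loss_name, delta) {
      v <- row
      v$loss <- loss_name
      v$neutral_mass <- row$neutral_mass - delta
      v$mz <- mz_from_neutral(v$neutral_mass, v$charge)
      v$label <- paste0(row$label, "-", loss_name)
      v
    }
    if (any(res %in% c("S", "T", "E", "D"))) {
      extra[[length(extra) + 1L]] <- mk("H2O", consts$water_mass)
    }
    if (any(res %in% c("R", "K", "N", "Q"))) {
      extra[[length(extra) + 1L]] <- mk("NH3", consts$ammonia_mass)
    }
  }
  out <- rbind(as.data.frame(fragments), do.call(rbind, c(
    list(data.frame()), extra)))
  rownames(out) <- NULL
  attr(out, "psm") <- psm
  class(out) <- c("fragment_ions", "data.frame")
  out
}
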