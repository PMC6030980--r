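# ---- annotation JSON (versioned, schema shipped in inst/extdata) --------

.ANNOTATION_FORMAT_VERSION <- "1.0"

.peptide_to_list <- function(p, link) {
  list(
    sequence = paste(p$sequence, collapse = ""),
    mods = if (nrow(p$mods)) lapply(seq_len(nrow(p$mods)), function(i) {
      list(position = p$mods$position[i], name = p$mods$name[i],
           mass_delta = p$mods$mass_delta[i])
    }) else list(),
    link_position = if (is.na(link)) NULL else link
  )
}

#' Serialize an annotation to the annotation JSON document
#'
#' The document (format version 1.0; schema shipped at
#' `system.file("extdata", "annotation-schema.json", package =
#' "fragmatch")`) contains the peptides with modifications and link sites,
#' the settings, the peak list, the theoretical fragments and the matches
#' with signed errors — everything needed to re-render the spectrum,
#' fragmentation-key and QC views without recomputation.
#'
#' @param ann an [annotate()]d spectrum.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_annotation_json <- function(ann, path = NULL) {
  stopifnot(inherits(ann, "annotated_spectrum"))
  psm <- ann$psm
  doc <- list(
    format_version = .ANNOTATION_FORMAT_VERSION,
    peptides = lapply(seq_along(psm$peptides), function(k) {
      .peptide_to_list(psm$peptides[[k]], psm$link_positions[k])
    }),
    crosslinker_mass = if (is.na(psm$crosslinker_mass)) NULL
                       else psm$crosslinker_mass,
    precursor = list(charge = psm$precursor_charge,
                     mz = if (is.na(psm$precursor_mz)) NULL
                          else psm$precursor_mz),
    settings = list(
      tolerance = ann$settings$tolerance,
      ion_types = as.list(ann$settings$ion_types),
      max_fragment_charge = ann$settings$max_fragment_charge,
      losses_enabled = ann$settings$losses_enabled,
      z_radical = ann$settings$z_radical
    ),
    peaks = ann$spectrum$peaks,
    fragments = as.data.frame(ann$fragments),
    matches = ann$matches
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    invisible(as.character(json))
  } else {
    as.character(json)
  }
}

#' Read an annotation JSON document back into an `annotated_spectrum`
#'
#' Validates the document against the shipped schema first.
#'
#' @param path path to a JSON file written by [write_annotation_json()].
#' @return An `annotated_spectrum`.
#' @export
read_annotation_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  v <- validate_annotation(doc)
  if (!isTRUE(v)) stop("annotation JSON fails schema validation: ", v,
                       call. = FALSE)
  peps <- doc$peptides
  pep_list <- lapply(seq_len(nrow(peps)), function(k) {
    mods <- peps$mods[[k]]
    mods_df <- if (is.data.frame(mods) && nrow(mods)) {
      data.frame(position = as.integer(mods$position), name = mods$name,
                 mass_delta = as.numeric(mods$mass_delta),
                 stringsAsFactors = FALSE)
    } else NULL
    peptide(peps$sequence[k], mods_df)
  })
  links <- if ("link_position" %in% names(peps)) {
    ifelse(is.na(peps$link_position), NA_integer_,
           as.integer(peps$link_position))
  } else rep(NA_integer_, length(pep_list))
  psm <- xl_psm(
    pep_list, link_positions = links,
    crosslinker_mass = if (is.null(doc$crosslinker_mass)) NA_real_
                       else doc$crosslinker_mass,
    precursor_charge = doc$precursor$charge,
    precursor_mz = if (is.null(doc$precursor$mz)) NA_real_
                   else doc$precursor$mz
  )
  settings <- annotation_settings(
    tolerance = doc$settings$tolerance,
    ion_types = doc$settings$ion_types,
    max_fragment_charge = doc$settings$max_fragment_charge,
    losses_enabled = doc$settings$losses_enabled,
    z_radical = doc$settings$z_radical
  )
  spec <- spectrum(doc$peaks$mz, doc$peaks$intensity,
                   source = list(filename = path))
  frags <- doc$fragments
  frags$index <- as.integer(frags$index)
  frags$charge <- as.integer(frags$charge)
  attr(frags, "psm") <- psm
  class(frags) <- c("fragment_ions", "data.frame")
  matches <- doc$matches
  if (is.data.frame(matches) && nrow(matches)) {
    matches$peak_index <- as.integer(matches$peak_index)
    matches$fragment_index <- as.integer(matches$fragment_index)
    matches$isotope_peak <- as.integer(matches$isotope_peak)
  } else {
    matches <- data.frame(peak_index = integer(),
                          fragment_index = integer(),
                          isotope_peak = integer(), error_Da = numeric(),
                          error_ppm = numeric())
  }
  structure(list(spectrum = spec, psm = psm, settings = settings,
                 fragments = frags, matches = matches, original = NULL),
            class = "annotated_spectrum")
}

# ---- minimal JSON-Schema validation ------------------------------------

# Validates `x` (parsed JSON, R lists/data frames) against the subset of
# JSON Schema used by the shipped annotation schema: type (incl. union
# types and "null"), required, properties, items, enum.
.check_schema <- function(x, schema, where = "$") {
  types <- schema$type
  ok_type <- function(x, t) {
    switch(t,
      "object"  = is.list(x) && !is.null(names(x)) || is.data.frame(x),
      "array"   = (is.list(x) && is.null(names(x))) || is.data.frame(x) ||
                  is.atomic(x),
      "number"  = is.numeric(x) && length(x) == 1L,
      "integer" = is.numeric(x) && length(x) == 1L &&
                  (is.na(x) || x == round(x)),
      "string"  = is.character(x) && length(x) == 1L,
      "boolean" = is.logical(x) && length(x) == 1L,
      "null"    = is.null(x) || (length(x) == 1L && is.na(x)),
      FALSE)
  }
  if (!is.null(types)) {
    if (!any(vapply(unlist(types), ok_type, logical(1), x = x))) {
      return(paste0(where, ": expected type ",
                    paste(unlist(types), collapse = "|")))
    }
  }
  if (!is.null(schema$enum) && is.atomic(x) && length(x) == 1L &&
      !is.na(x)) {
    if (!x %in% unlist(schema$enum)) {
      return(paste0(where, ": value '", x, "' not in enum"))
    }
  }
  if (!is.null(schema$properties) &&
      (is.data.frame(x) || (is.list(x) && !is.null(names(x))))) {
    for (req in unlist(schema$required)) {
      if (!req %in% names(x)) {
        return(paste0(where, ": missing required property '", req, "'"))
      }
    }
    for (nm in names(schema$properties)) {
      if (nm %in% names(x) && !is.data.frame(x)) {
        res <- .check_schema(x[[nm]], schema$properties[[nm]],
                             paste0(where, ".", nm))
        if (!isTRUE(res)) return(res)
      }
    }
  }
  if (!is.null(schema$items)) {
    if (is.data.frame(x)) {
      for (req in unlist(schema$items$required)) {
        if (!req %in% names(x)) {
          return(paste0(where, "[]: missing required property '", req,
                        "'"))
        }
      }
      for (nm in intersect(names(schema$items$properties), names(x))) {
        col_schema <- schema$items$properties[[nm]]
        col <- x[[nm]]
        if (!is.list(col)) {
          for (i in seq_along(col)) {
            res <- .check_schema(col[i], col_schema,
                                 paste0(where, "[", i, "].", nm))
            if (!isTRUE(res)) return(res)
          }
        }
      }
    } else if (is.list(x)) {
      for (i in seq_along(x)) {
        res <- .check_schema(x[[i]], schema$items,
                             paste0(where, "[", i, "]"))
        if (!isTRUE(res)) return(res)
      }
    }
  }
  TRUE
}

#' Validate an annotation document against the shipped schema
#'
#' @param doc parsed JSON (from [jsonlite::fromJSON()]), a JSON string, or
#'   a path to a JSON file.
#' @return `TRUE` if valid, otherwise a character message describing the
#'   first violation.
#' @export
validate_annotation <- function(doc) {
  if (is.character(doc) && length(doc) == 1L) {
    doc <- jsonlite::fromJSON(doc)
  }
  schema_path <- system.file("extdata", "annotation-schema.json",
                             package = "fragmatch")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  .check_schema(doc, schema)
}
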