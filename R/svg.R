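#' Rendering style for SVG export
#'
#' @param color_alpha hex colour for peptide alpha (default red).
#' @param color_beta hex colour for peptide beta (default blue).
#' @param loss_lightening fraction in (0,1] by which neutral-loss elements
#'   are mixed toward white.
#' @param highlight_color hex colour for highlighted elements.
#' @param show_loss_labels draw labels of neutral-loss fragments?
#' @param width,height canvas size in pixels.
#' @return Object of class `render_style`.
#' @export
render_style <- function(color_alpha = "#d40000", color_beta = "#0044cc",
                         loss_lightening = 0.5,
                         highlight_color = "#ffcc00",
                         show_loss_labels = TRUE,
                         width = 760, height = 400) {
  stopifnot(grepl("^#[0-9a-fA-F]{6}$", color_alpha),
            grepl("^#[0-9a-fA-F]{6}$", color_beta),
            grepl("^#[0-9a-fA-F]{6}$", highlight_color),
            width > 0, height > 0,
            loss_lightening > 0, loss_lightening <= 1)
  structure(list(
    color_alpha = color_alpha, color_beta = color_beta,
    loss_lightening = loss_lightening, highlight_color = highlight_color,
    show_loss_labels = isTRUE(show_loss_labels),
    width = width, height = height
  ), class = "render_style")
}

# Mix a hex colour toward white by fraction f.
.lighten <- function(hex, f) {
  rgb_ <- grDevices::col2rgb(hex)[, 1L]
  mixed <- round(rgb_ + (255 - rgb_) * f)
  sprintf("#%02x%02x%02x", mixed[1L], mixed[2L], mixed[3L])
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.svg_open <- function(style, class) {
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
    'width="%g" height="%g" viewBox="0 0 %g %g" class="%s">\n'),
    style$width, style$height, style$width, style$height, class)
}

# Linear scale factory mapping domain [d0,d1] -> range [r0,r1].
.scale <- function(d0, d1, r0, r1) {
  if (d1 == d0) d1 <- d0 + 1
  function(x) r0 + (x - d0) / (d1 - d0) * (r1 - r0)
}

.fmt <- function(x) sprintf("%.2f", x)

# Axis line + ticks + labels; pretty() keeps placement deterministic.
.svg_axes <- function(xs, ys, xlim, ylim, xlab, ylab) {
  out <- character()
  out <- c(out, sprintf(
    '<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
    .fmt(xs(xlim[1])), .fmt(ys(ylim[1])), .fmt(xs(xlim[2])),
    .fmt(ys(ylim[1]))))
  out <- c(out, sprintf(
    '<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
    .fmt(xs(xlim[1])), .fmt(ys(ylim[1])), .fmt(xs(xlim[1])),
    .fmt(ys(ylim[2]))))
  for (t in pretty(xlim, 6)) {
    if (t < xlim[1] || t > xlim[2]) next
    out <- c(out, sprintf(
      '<line class="tick" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
      .fmt(xs(t)), .fmt(ys(ylim[1])), .fmt(xs(t)),
      .fmt(ys(ylim[1]) + 4)),
      sprintf(
        '<text class="tick-label" x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
        .fmt(xs(t)), .fmt(ys(ylim[1]) + 16), format(t)))
  }
  for (t in pretty(ylim, 5)) {
    if (t < ylim[1] || t > ylim[2]) next
    out <- c(out, sprintf(
      '<line class="tick" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
      .fmt(xs(xlim[1]) - 4), .fmt(ys(t)), .fmt(xs(xlim[1])), .fmt(ys(t))),
      sprintf(
        '<text class="tick-label" x="%s" y="%s" font-size="10" text-anchor="end">%s</text>',
        .fmt(xs(xlim[1]) - 6), .fmt(ys(t) + 3), format(t)))
  }
  c(out, sprintf(
    '<text class="axis-label" x="%s" y="%s" font-size="11" text-anchor="middle">%s</text>',
    .fmt(mean(xs(xlim))), .fmt(ys(ylim[1]) + 32), .xml_escape(xlab)),
    sprintf(
      '<text class="axis-label" x="12" y="%s" font-size="11" text-anchor="middle" transform="rotate(-90 12 %s)">%s</text>',
      .fmt(mean(ys(ylim))), .fmt(mean(ys(ylim))), .xml_escape(ylab)))
}

# Colour for a fragment row under a style.
.fragment_color <- function(peptide_id, loss, style) {
  base <- if (peptide_id == "beta") style$color_beta else style$color_alpha
  if (loss != "none") .lighten(base, style$loss_lightening) else base
}

#' Render the annotated spectrum view as SVG
#'
#' One vertical line per peak: unmatched peaks neutral gray, matched peaks
#' coloured by peptide (alpha/beta), neutral-loss matches lighter. Fragment
#' labels sit above their peaks with a deterministic greedy de-overlap
#' (crowded labels are raised and connected with a dashed leader line);
#' loss labels can be suppressed via `style$show_loss_labels`.
#'
#' @param ann an [annotate()]d spectrum.
#' @param style a [render_style()].
#' @return SVG 1.1 document as a character scalar.
#' @export
spectrum_svg <- function(ann, style = render_style()) {
  stopifnot(inherits(ann, "annotated_spectrum"),
            inherits(style, "render_style"))
  peaks <- ann$spectrum$peaks
  margin <- c(left = 50, right = 15, top = 20, bottom = 40)
  xlim <- if (nrow(peaks)) range(peaks$mz) + c(-1, 1) *
            diff(range(peaks$mz)) * 0.03 else c(0, 1000)
  if (diff(xlim) == 0) xlim <- xlim + c(-1, 1)
  maxint <- if (nrow(peaks) && max(peaks$intensity) > 0)
    max(peaks$intensity) else 1
  xs <- .scale(xlim[1], xlim[2], margin["left"],
               style$width - margin["right"])
  ys <- .scale(0, 100, style$height - margin["bottom"], margin["top"])
  out <- .svg_open(style, "spectrum-view")
  out <- c(out, .svg_axes(xs, ys, xlim, c(0, 100), "m/z",
                          "relative intensity (%)"))
  mono <- ann$matches[ann$matches$isotope_peak == 0L, , drop = FALSE]
  peak_frag <- split(mono$fragment_index, mono$peak_index)
  iso_peaks <- unique(ann$matches$peak_index[ann$matches$isotope_peak > 0L])
  labels <- list()
  for (i in seq_len(nrow(peaks))) {
    rel <- peaks$intensity[i] / maxint * 100
    frs <- peak_frag[[as.character(i)]]
    if (!is.null(frs)) {
      fr <- ann$fragments[frs[1L], ]
      col <- .fragment_color(fr$peptide_id, fr$loss, style)
      cls <- paste0("peak matched ", fr$peptide_id,
                    if (fr$loss != "none") " loss")
      lab_txt <- paste(unique(vapply(frs, function(f) {
        paste0(ann$fragments$label[f],
               if (ann$fragments$charge[f] > 1L)
                 paste0("(", ann$fragments$charge[f], "+)") else "")
      }, character(1))), collapse = ",")
      show <- style$show_loss_labels || fr$loss == "none"
      if (show) {
        labels[[length(labels) + 1L]] <- list(
          x = xs(peaks$mz[i]), y = ys(rel) - 4, text = lab_txt, col = col)
      }
    } else if (i %in% iso_peaks) {
      col <- "#999999"
      cls <- "peak isotope"
    } else {
      col <- "#bbbbbb"
      cls <- "peak unassigned"
    }
    out <- c(out, sprintf(
      '<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5"/>',
      cls, .fmt(xs(peaks$mz[i])), .fmt(ys(0)), .fmt(xs(peaks$mz[i])),
      .fmt(ys(rel)), col))
  }
  # greedy label de-overlap: left-to-right, raise a label that would sit
  # within 30 px of the previous one and add a dashed leader line
  if (length(labels)) {
    ord <- order(vapply(labels, `[[`, numeric(1), "x"))
    last_x <- -Inf
    last_y <- Inf
    for (k in ord) {
      lb <- labels[[k]]
      y <- lb$y
      if (lb$x - last_x < 30) {
        y <- min(last_y - 12, lb$y)
        if (y < 12) y <- 12
        out <- c(out, sprintf(
          '<line class="leader" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-dasharray="2,2" stroke-width="0.5"/>',
          .fmt(lb$x), .fmt(y + 2), .fmt(lb$x), .fmt(lb$y + 2), lb$col))
      }
      out <- c(out, sprintf(
        '<text class="frag-label" x="%s" y="%s" font-size="9" text-anchor="middle" fill="%s">%s</text>',
        .fmt(lb$x), .fmt(y), lb$col, .xml_escape(lb$text)))
      last_x <- lb$x
      last_y <- y
    }
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}

#' Render the peptide fragmentation key as SVG
#'
#' One row of one-letter residues per peptide; a tick above each inter-residue
#' gap with a matched prefix-series fragment (b/c) and below each gap with a
#' matched suffix-series fragment (y/z); cross-linked PSMs show both rows
#' connected by a line between the linked residues.
#'
#' @param ann an [annotate()]d spectrum.
#' @param style a [render_style()].
#' @return SVG 1.1 document as a character scalar.
#' @export
fragkey_svg <- function(ann, style = render_style()) {
  stopifnot(inherits(ann, "annotated_spectrum"),
            inherits(style, "render_style"))
  psm <- ann$psm
  mono <- ann$matches[ann$matches$isotope_peak == 0L, , drop = FALSE]
  mf <- ann$fragments[mono$fragment_index, , drop = FALSE]
  step <- 22
  x0 <- 40
  rows_y <- c(60, 140)
  out <- .svg_open(style, "fragkey-view")
  for (k in seq_along(psm$peptides)) {
    pid <- c("alpha", "beta")[k]
    col <- if (k == 1L) style$color_alpha else style$color_beta
    p <- psm$peptides[[k]]
    n <- length(p$sequence)
    y <- rows_y[k]
    for (i in seq_len(n)) {
      x <- x0 + (i - 1) * step
      modded <- nrow(p$mods) && any(pmin(pmax(p$mods$position, 1L), n) == i)
      out <- c(out, sprintf(
        '<text class="residue %s" x="%s" y="%s" font-size="16" font-family="monospace" text-anchor="middle" fill="%s"%s>%s</text>',
        pid, .fmt(x), .fmt(y), col,
        if (modded) ' text-decoration="underline"' else "",
        p$sequence[i]))
    }
    # cleavage ticks: prefix series above, suffix series below
    sel <- mf$peptide_id == pid & mf$series %in% c("b", "c", "y", "z")
    if (any(sel)) {
      sub <- mf[sel, , drop = FALSE]
      cleav_prefix <- unique(sub$index[sub$series %in% c("b", "c")])
      cleav_suffix <- unique(n - sub$index[sub$series %in% c("y", "z")])
      for (i in cleav_prefix) {
        x <- x0 + (i - 0.5) * step
        out <- c(out, sprintf(
          '<path class="cleavage prefix" d="M %s %s L %s %s L %s %s" stroke="%s" fill="none" stroke-width="1.5"/>',
          .fmt(x - 6), .fmt(y - 16), .fmt(x), .fmt(y - 12), .fmt(x),
          .fmt(y - 2), col))
      }
      for (i in cleav_suffix) {
        x <- x0 + (i - 0.5) * step
        out <- c(out, sprintf(
          '<path class="cleavage suffix" d="M %s %s L %s %s L %s %s" stroke="%s" fill="none" stroke-width="1.5"/>',
          .fmt(x + 6), .fmt(y + 8), .fmt(x), .fmt(y + 4), .fmt(x),
          .fmt(y - 6), col))
      }
    }
  }
  if (is_crosslinked(psm)) {
    xa <- x0 + (psm$link_positions[1L] - 1) * step
    xb <- x0 + (psm$link_positions[2L] - 1) * step
    out <- c(out, sprintf(
      '<line class="crosslink" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333" stroke-width="2"/>',
      .fmt(xa), .fmt(rows_y[1L] + 8), .fmt(xb), .fmt(rows_y[2L] - 16)))
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}

#' Render a QC error plot as SVG
#'
#' Scatter of per-match errors (ppm) over peak intensity or m/z, coloured
#' by peptide with neutral-loss points lighter.
#'
#' @param points a [qc_points()] data frame.
#' @param axis `"intensity"` or `"mz"` (x-axis label only; the x values
#'   come from `points$x`).
#' @param style a [render_style()].
#' @param absolute were the errors folded to absolute values? (affects the
#'   y-axis range)
#' @return SVG 1.1 document as a character scalar.
#' @export
qc_svg <- function(points, axis = c("intensity", "mz"),
                   style = render_style(), absolute = FALSE) {
  axis <- match.arg(axis)
  stopifnot(inherits(style, "render_style"))
  margin <- c(left = 50, right = 15, top = 20, bottom = 40)
  xlim <- if (nrow(points)) range(points$x) else c(0, 1)
  if (diff(xlim) == 0) xlim <- xlim + c(-0.5, 0.5)
  xlim <- xlim + c(-1, 1) * diff(xlim) * 0.04
  ymax <- if (nrow(points)) max(abs(points$error_ppm), 1e-6) * 1.1 else 10
  ylim <- if (absolute) c(0, ymax) else c(-ymax, ymax)
  xs <- .scale(xlim[1], xlim[2], margin["left"],
               style$width - margin["right"])
  ys <- .scale(ylim[1], ylim[2], style$height - margin["bottom"],
               margin["top"])
  out <- .svg_open(style, paste0("qc-view qc-", axis))
  out <- c(out, .svg_axes(xs, ys, xlim, ylim,
                          if (axis == "intensity") "peak intensity"
                          else "m/z",
                          if (absolute) "|error| (ppm)" else "error (ppm)"))
  if (!absolute) {
    out <- c(out, sprintf(
      '<line class="zero" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888888" stroke-dasharray="4,3" stroke-width="0.5"/>',
      .fmt(xs(xlim[1])), .fmt(ys(0)), .fmt(xs(xlim[2])), .fmt(ys(0))))
  }
  for (i in seq_len(nrow(points))) {
    col <- .fragment_color(points$peptide_id[i], points$loss[i], style)
    out <- c(out, sprintf(
      '<circle class="qc-point %s%s" cx="%s" cy="%s" r="3" fill="%s"><title>%s</title></circle>',
      points$peptide_id[i],
      if (points$loss[i] != "none") " loss" else "",
      .fmt(xs(points$x[i])), .fmt(ys(points$error_ppm[i])), col,
      .xml_escape(points$label[i])))
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}
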