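#' Style configuration for SVG rendering
#'
#' @param width,height canvas size in pixels.
#' @param margin outer margin in pixels.
#' @param y_range vertical axis range (logits for Rasch maps, percentage
#'   difficulty for facility maps); auto-expanded when the layout holds
#'   positions outside it.
#' @param strength_colour,weakness_colour ellipse colours for flagged
#'   clusters.
#' @param font_family,font_size label typography (labels are anchored,
#'   never measured, so no font metrics are required).
#' @return A list of class `style_config`.
#' @export
style_config <- function(width = 900, height = 600, margin = 50,
                         y_range = c(-4, 4),
                         strength_colour = "#1a9641",
                         weakness_colour = "#d7191c",
                         font_family = "sans-serif", font_size = 11) {
  stopifnot(width > 0, height > 0, margin >= 0, diff(y_range) > 0)
  structure(list(width = width, height = height, margin = margin,
                 y_range = y_range,
                 strength_colour = strength_colour,
                 weakness_colour = weakness_colour,
                 font_family = font_family, font_size = font_size),
            class = "style_config")
}

# fixed-format number for byte-stable output
fmt <- function(x, digits = 2) sprintf(paste0("%.", digits, "f"), x)

#' Render a GIM layout as an SVG document
#'
#' Produces a deterministic SVG 1.1 document: a central vertical
#' latent-scale axis with tick labels, subject-cluster columns mirrored
#' left (correct) and right (incorrect) of it, group labels with
#' parenthesised counts, a horizontal ability line, an optional pass
#' line, and ellipse outlines around flagged clusters (green strengths,
#' red weaknesses). Identical inputs yield byte-identical output.
#' Overlapping labels within a column are separated by a fixed
#' 0.1-logit nudge applied in document order.
#'
#' @param layout a `gim_layout`.
#' @param style a [style_config()].
#' @param path optional output file; when given, the SVG is written
#'   there and the path returned invisibly.
#' @return The SVG document as a single character string.
#' @export
render_svg <- function(layout, style = style_config(), path = NULL) {
  stopifnot(inherits(layout, "gim_layout"))
  if (nrow(layout$placed) == 0L) {
    stop("cannot render an empty layout", call. = FALSE)
  }
  yr <- style$y_range
  ys <- c(layout$groups$y, layout$ability_line, layout$pass_line)
  yr <- c(min(yr[1], floor(min(ys))), max(yr[2], ceiling(max(ys))))
  m <- style$margin
  w <- style$width
  h <- style$height
  plot_h <- h - 2 * m
  # affine logit -> pixel map, higher logit = higher on the page
  ypix <- function(y) m + (yr[2] - y) / (yr[2] - yr[1]) * plot_h
  cx <- w / 2
  cols <- layout$columns
  k <- length(cols)
  half <- (w / 2 - m - 30) / max(k, 1L)   # column width on each side
  col_x <- function(cl, side) {
    i <- match(cl, cols)
    if (side == "left_correct") cx - 30 - (i - 0.5) * half
    else cx + 30 + (i - 0.5) * half
  }

  out <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            fmt(w, 0), fmt(h, 0), fmt(w, 0), fmt(h, 0)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="white"/>',
            fmt(w, 0), fmt(h, 0)),
    sprintf(paste0('<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" ',
                   'stroke="black" stroke-width="1.5"/>'),
            fmt(cx), fmt(m), fmt(cx), fmt(h - m)))
  # axis ticks every logit
  for (tick in seq(ceiling(yr[1]), floor(yr[2]))) {
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
              fmt(cx - 4), fmt(ypix(tick)), fmt(cx + 4), fmt(ypix(tick))),
      sprintf(paste0('<text x="%s" y="%s" font-family="%s" font-size="%s" ',
                     'text-anchor="middle">%s</text>'),
              fmt(cx), fmt(ypix(tick) - 6), style$font_family,
              fmt(style$font_size * 0.8, 1), fmt(tick, 0)))
  }
  # column headers
  for (cl in cols) {
    for (side in c("left_correct", "right_incorrect")) {
      out <- c(out, sprintf(
        paste0('<text class="header" x="%s" y="%s" font-family="%s" ',
               'font-size="%s" text-anchor="middle" font-weight="bold">',
               '%s</text>'),
        fmt(col_x(cl, side)), fmt(m - 10), style$font_family,
        fmt(style$font_size, 1), cl))
    }
  }
  # ability line (full width) and optional pass line (dashed)
  out <- c(out, sprintf(
    paste0('<line class="ability" x1="%s" y1="%s" x2="%s" y2="%s" ',
           'stroke="#2166ac" stroke-width="1.5"/>'),
    fmt(m), fmt(ypix(layout$ability_line)), fmt(w - m),
    fmt(ypix(layout$ability_line))))
  if (!is.null(layout$pass_line)) {
    out <- c(out, sprintf(
      paste0('<line class="pass" x1="%s" y1="%s" x2="%s" y2="%s" ',
             'stroke="#636363" stroke-width="1.5" stroke-dasharray="6,4"/>'),
      fmt(m), fmt(ypix(layout$pass_line)), fmt(w - m),
      fmt(ypix(layout$pass_line))))
  }
  # group labels with deterministic overlap nudge (document order)
  g <- layout$groups
  nudge <- 0.1  # logits
  last_y <- list()
  for (i in seq_len(nrow(g))) {
    key <- paste(g$subject_cluster[i], g$side[i])
    yv <- g$y[i]
    prev <- last_y[[key]]
    if (!is.null(prev) && abs(yv - prev) < nudge) {
      yv <- prev + nudge
    }
    last_y[[key]] <- yv
    out <- c(out, sprintf(
      paste0('<text class="group" x="%s" y="%s" font-family="%s" ',
             'font-size="%s" text-anchor="middle" data-y="%s">%s</text>'),
      fmt(col_x(g$subject_cluster[i], g$side[i])), fmt(ypix(yv)),
      style$font_family, fmt(style$font_size, 1), fmt(g$y[i], 4),
      g$label[i]))
  }
  # ellipses around flagged clusters (bounding outline of the cluster's
  # groups on its dominant side: misses for weaknesses, hits for strengths)
  for (cl in names(layout$flags)) {
    flag <- layout$flags[[cl]]
    if (flag == "none") next
    side <- if (flag == "weakness") "right_incorrect" else "left_correct"
    sub <- g[g$subject_cluster == cl & g$side == side, , drop = FALSE]
    if (nrow(sub) == 0L) next
    y_top <- ypix(max(sub$y)) - 12
    y_bot <- ypix(min(sub$y)) + 12
    colr <- if (flag == "weakness") style$weakness_colour
            else style$strength_colour
    out <- c(out, sprintf(
      paste0('<ellipse class="flag" cx="%s" cy="%s" rx="%s" ry="%s" ',
             'fill="none" stroke="%s" stroke-width="2"/>'),
      fmt(col_x(cl, side)), fmt((y_top + y_bot) / 2), fmt(half * 0.45),
      fmt((y_bot - y_top) / 2), colr))
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(path))
  }
  doc
}

#' Render a GIM layout as a plain-text map
#'
#' A monospaced grid with one row per 0.25 units of the vertical axis,
#' a central `|` axis column, `CLUSTER (n)` tokens placed left of the
#' axis for correct groups and right for incorrect ones, and the
#' candidate's ability row marked. Intended for terminals and as a
#' render target that is trivially diffable in tests.
#'
#' @param layout a `gim_layout`.
#' @param width total character width (at least 40).
#' @return Character vector of lines.
#' @export
render_text <- function(layout, width = 78) {
  stopifnot(inherits(layout, "gim_layout"))
  if (width < 40) stop("width must be at least 40", call. = FALSE)
  band <- 0.25
  ys <- c(layout$groups$y, layout$ability_line, layout$pass_line)
  top <- ceiling(max(ys) / band) * band
  bot <- floor(min(ys) / band) * band
  rows <- seq(top, bot, by = -band)
  axis_col <- floor(width / 2)
  side_w <- axis_col - 8     # label space each side, after the y scale
  lines <- character(0)
  header <- sprintf("%-7s %s", "logit",
                    paste0(strrep(" ", side_w - 8), "CORRECT |INCORRECT"))
  lines <- c(lines, substr(header, 1L, width))
  g <- layout$groups
  for (rv in rows) {
    in_band <- abs(g$y - rv) <= band / 2 & (g$y > rv - band / 2)
    left_tok <- g$label[in_band & g$side == "left_correct"]
    right_tok <- g$label[in_band & g$side == "right_incorrect"]
    left_txt <- paste(left_tok, collapse = " ")
    right_txt <- paste(right_tok, collapse = " ")
    mark <- "|"
    if (abs(layout$ability_line - rv) <= band / 2 &&
        layout$ability_line > rv - band / 2) {
      mark <- "T"   # candidate ability row
    } else if (!is.null(layout$pass_line) &&
               abs(layout$pass_line - rv) <= band / 2 &&
               layout$pass_line > rv - band / 2) {
      mark <- "P"   # pass standard row
    }
    # left side right-justified so tokens hug the axis
    left_part <- formatC(left_txt, width = side_w)
    lines <- c(lines,
               sprintf("%6s  %s %s %s", fmt(rv, 2), left_part, mark,
                       right_txt))
  }
  legend <- sprintf("T = ability (%s logits)%s", fmt(layout$ability_line, 2),
                    if (!is.null(layout$pass_line)) {
                      sprintf("; P = pass standard (%s logits)",
                              fmt(layout$pass_line, 2))
                    } else "")
  flagged <- layout$flags[layout$flags != "none"]
  flag_line <- if (length(flagged) > 0L) {
    paste("flags:", paste(names(flagged), unlist(flagged), sep = "=",
                          collapse = " "))
  } else "flags: none"
  c(lines, "", legend, flag_line)
}
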