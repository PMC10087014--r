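#' Rendering options for static plots
#'
#' @param format `"svg"` (source of truth) or `"png"` (rasterized from the
#'   same geometry via the `grDevices` png device)
#' @param width,height output size in pixels
#' @param dpi resolution used by the png device
#' @param interpolated_label annotation appended to the labels of
#'   interpolated time points (distinguishes measured from estimated)
#' @param therapy_label annotation appended to the labels of
#'   therapy-estimated time points
#' @param clone_labels draw clone labels inside the bands / next to nodes?
#' @return a list of class `render_options`
#' @export
render_options <- function(format = c("svg", "png"), width = 800,
                           height = 500, dpi = 96,
                           interpolated_label = "*",
                           therapy_label = "†", clone_labels = TRUE) {
  format <- match.arg(format)
  if (width <= 0 || height <= 0) {
    stop("`width` and `height` must be positive", call. = FALSE)
  }
  structure(list(format = format, width = width, height = height, dpi = dpi,
                 interpolated_label = interpolated_label,
                 therapy_label = therapy_label, clone_labels = clone_labels),
            class = "render_options")
}

fmt <- function(z) sprintf("%.3f", z)

# densify a boundary with a monotone (shape-preserving) cubic through the
# support points; straight segments for polygon shape or < 3 points
boundary_points <- function(x, y, shape, samples = 8) {
  if (length(x) < 3 || shape == "polygon") return(list(x = x, y = y))
  xs <- unique(unlist(lapply(seq_len(length(x) - 1), function(i) {
    seq(x[i], x[i + 1], length.out = samples + 1)
  })))
  f <- stats::splinefun(x, y, method = "monoH.FC")
  list(x = xs, y = f(xs))
}

band_path_d <- function(b, shape) {
  up <- boundary_points(b$x, b$upper, shape)
  lo <- boundary_points(b$x, b$lower, shape)
  pts_up <- paste0(fmt(up$x), ",", fmt(up$y), collapse = " L")
  pts_lo <- paste0(fmt(rev(lo$x)), ",", fmt(rev(lo$y)), collapse = " L")
  paste0("M", pts_up, " L", pts_lo, " Z")
}

tp_annotation <- function(kind, options) {
  ifelse(kind == "interpolated", options$interpolated_label,
         ifelse(kind == "therapy", options$therapy_label, ""))
}

# shared scaffold: maps data coordinates to pixels
make_mapper <- function(xlim, ylim, width, height, margin = c(50, 20, 40, 20)) {
  # margin: left, right, bottom, top
  px <- function(x) margin[1] +
    (x - xlim[1]) / max(xlim[2] - xlim[1], 1e-12) * (width - margin[1] - margin[2])
  py <- function(y) height - margin[3] -
    (y - ylim[1]) / max(ylim[2] - ylim[1], 1e-12) * (height - margin[3] - margin[4])
  list(px = px, py = py)
}

svg_open <- function(width, height) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            as.integer(width), as.integer(height), as.integer(width),
            as.integer(height)),
    '<rect width="100%" height="100%" fill="#ffffff"/>')
}

svg_axis <- function(mapper, tps, labels, kind, options, y_axis) {
  out <- character(0)
  y0 <- mapper$py(y_axis)
  out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333" stroke-width="1"/>',
                        fmt(mapper$px(tps[1])), fmt(y0),
                        fmt(mapper$px(tps[length(tps)])), fmt(y0)))
  ann <- tp_annotation(kind, options)
  for (i in seq_along(tps)) {
    x <- mapper$px(tps[i])
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333" stroke-width="1"/>',
                          fmt(x), fmt(y0), fmt(x), fmt(y0 + 5)))
    lab <- paste0(labels[i], ann[i])
    out <- c(out, sprintf('<text x="%s" y="%s" font-size="11" font-family="sans-serif" text-anchor="middle">%s</text>',
                          fmt(x), fmt(y0 + 18), xml_escape(lab)))
  }
  out
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

color_of <- function(colors, clone) {
  hex <- colors$hex[match(clone, colors$clone)]
  ifelse(is.na(hex), "#999999", hex)
}

# draw order: parents first so children overlay them
band_draw_order <- function(layout) {
  nonempty <- names(layout$bands)[vapply(layout$bands, nrow, integer(1)) > 0]
  widths <- vapply(layout$bands[nonempty],
                   function(b) max(b$upper - b$lower), numeric(1))
  nonempty[order(-widths, nonempty)]
}

svg_bands <- function(layout, colors, mapper, options, mirror = FALSE,
                      fills = NULL) {
  out <- character(0)
  for (c in band_draw_order(layout)) {
    b <- layout$bands[[c]]
    if (mirror) b <- data.frame(x = b$x, lower = -b$upper, upper = -b$lower)
    bb <- data.frame(x = mapper$px(b$x), lower = mapper$py(b$lower),
                     upper = mapper$py(b$upper))
    fill <- if (is.null(fills)) color_of(colors, c) else fills[[c]]
    if (is.na(fill)) {
      out <- c(out, sprintf('<path d="%s" fill="none" stroke="#bbbbbb" stroke-width="0.6"/>',
                            band_path_d(bb, layout$shape)))
    } else {
      out <- c(out, sprintf('<path d="%s" fill="%s" fill-opacity="0.9" stroke="#ffffff" stroke-width="0.6"/>',
                            band_path_d(bb, layout$shape), fill))
    }
    if (options$clone_labels && !mirror && is.null(fills)) {
      th <- b$upper - b$lower
      i <- which.max(th)
      if (th[i] > 3) {
        out <- c(out, sprintf('<text x="%s" y="%s" font-size="10" font-family="sans-serif" text-anchor="middle" fill="#222222">%s</text>',
                              fmt(mapper$px(b$x[i])),
                              fmt(mapper$py((b$lower[i] + b$upper[i]) / 2) + 3),
                              xml_escape(c)))
      }
    }
  }
  out
}

render_dolphin_svg <- function(layout, colors, options) {
  xs <- range(c(layout$timepoint_x,
                unlist(lapply(layout$bands, function(b) b$x))))
  mapper <- make_mapper(xs, c(0, layout$height), options$width, options$height)
  out <- svg_open(options$width, options$height)
  out <- c(out, svg_bands(layout, colors, mapper, options))
  out <- c(out, svg_axis(mapper, layout$timepoint_x, layout$timepoint_labels,
                         layout$timepoint_kind, options, 0))
  c(out, "</svg>")
}

render_plaice_svg <- function(layout, colors, options) {
  up <- layout$upper
  xs <- range(c(up$timepoint_x, unlist(lapply(up$bands, function(b) b$x))))
  mapper <- make_mapper(xs, c(-up$height, up$height),
                        options$width, options$height)
  fills <- setNames(color_of(up$colors, layout$lower_fill),
                    names(layout$lower_fill))
  fills[is.na(layout$lower_fill)] <- NA_character_
  out <- svg_open(options$width, options$height)
  out <- c(out, svg_bands(up, colors, mapper, options))
  out <- c(out, svg_bands(up, colors, mapper, options, mirror = TRUE,
                          fills = fills))
  out <- c(out, svg_axis(mapper, up$timepoint_x, up$timepoint_labels,
                         up$timepoint_kind, options, 0))
  c(out, "</svg>")
}

render_shark_svg <- function(layout, colors, options) {
  nodes <- layout$nodes
  m <- ncol(layout$radii)
  # reserve the right third for the CCF bubble strip
  xlim <- c(-0.5, max(nodes$x) + 0.5 + 0.6 * m)
  ylim <- c(0.25, max(nodes$y) + 0.75)
  mapper <- make_mapper(xlim, ylim, options$width, options$height)
  out <- svg_open(options$width, options$height)
  for (i in seq_len(nrow(layout$edges))) {
    a <- match(layout$edges$from[i], nodes$clone)
    b <- match(layout$edges$to[i], nodes$clone)
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#555555" stroke-width="1.2"/>',
                          fmt(mapper$px(nodes$x[a])), fmt(mapper$py(nodes$y[a])),
                          fmt(mapper$px(nodes$x[b])), fmt(mapper$py(nodes$y[b]))))
  }
  for (i in seq_len(nrow(nodes))) {
    out <- c(out, sprintf('<circle cx="%s" cy="%s" r="8" fill="%s" stroke="#333333" stroke-width="0.8"/>',
                          fmt(mapper$px(nodes$x[i])), fmt(mapper$py(nodes$y[i])),
                          color_of(colors, nodes$clone[i])))
    if (options$clone_labels) {
      out <- c(out, sprintf('<text x="%s" y="%s" font-size="10" font-family="sans-serif" text-anchor="middle">%s</text>',
                            fmt(mapper$px(nodes$x[i])),
                            fmt(mapper$py(nodes$y[i]) - 11),
                            xml_escape(nodes$clone[i])))
    }
  }
  # bubble strip: one column per time point, radius grows with CCF
  strip0 <- max(nodes$x) + 1
  ann <- tp_annotation(layout$timepoint_kind, options)
  for (t in seq_len(m)) {
    xt <- strip0 + 0.6 * (t - 1)
    for (i in seq_len(nrow(nodes))) {
      r <- layout$radii[nodes$clone[i], t] * 0.8
      if (r > 0) {
        out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="0.85"/>',
                              fmt(mapper$px(xt)), fmt(mapper$py(nodes$y[i])),
                              fmt(r), color_of(colors, nodes$clone[i])))
      }
    }
    out <- c(out, sprintf('<text x="%s" y="%s" font-size="9" font-family="sans-serif" text-anchor="middle">%s</text>',
                          fmt(mapper$px(xt)), fmt(mapper$py(ylim[1]) + 14),
                          xml_escape(paste0(layout$timepoint_labels[t], ann[t]))))
  }
  c(out, "</svg>")
}

#' Render a layout to SVG or PNG
#'
#' A pure function of `(layout, colors, options)`: identical inputs produce
#' byte-identical SVG files. PNG output rasterizes the same geometry through
#' the `grDevices` png device.
#'
#' @param layout a `band_layout`, `shark_layout` or `plaice_layout`
#' @param colors a [assign_colors()] result; defaults to the colors stored
#'   in the layout (band/plaice layouts carry them)
#' @param options a [render_options()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
render_plot <- function(layout, colors = NULL, options = render_options(),
                        path) {
  if (is.null(colors)) {
    colors <- if (inherits(layout, "plaice_layout")) {
      layout$upper$colors
    } else if (inherits(layout, "band_layout")) {
      layout$colors
    } else {
      data.frame(clone = character(0), hex = character(0))
    }
  }
  if (!options$format %in% c("svg", "png")) {
    stop("unknown render format: ", options$format, call. = FALSE)
  }

  if (options$format == "svg") {
    lines <- if (inherits(layout, "band_layout")) {
      render_dolphin_svg(layout, colors, options)
    } else if (inherits(layout, "plaice_layout")) {
      render_plaice_svg(layout, colors, options)
    } else if (inherits(layout, "shark_layout")) {
      render_shark_svg(layout, colors, options)
    } else {
      stop("unsupported layout class: ", paste(class(layout), collapse = "/"),
           call. = FALSE)
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    if (!capabilities("png")) {
      stop("this R build cannot produce PNG output; use format = \"svg\"",
           call. = FALSE)
    }
    grDevices::png(path, width = options$width, height = options$height,
                   res = options$dpi)
    on.exit(grDevices::dev.off())
    draw_layout_base(layout, colors, options)
  }
  invisible(path)
}

# base-graphics rendering of the same geometry (png backend)
draw_layout_base <- function(layout, colors, options) {
  op <- graphics::par(mar = c(3, 1, 1, 1))
  on.exit(graphics::par(op))
  draw_bands <- function(lay, mirror = FALSE, fills = NULL) {
    for (c in band_draw_order(lay)) {
      b <- lay$bands[[c]]
      if (mirror) b <- data.frame(x = b$x, lower = -b$upper, upper = -b$lower)
      up <- boundary_points(b$x, b$upper, lay$shape)
      lo <- boundary_points(b$x, b$lower, lay$shape)
      fill <- if (is.null(fills)) color_of(colors, c) else fills[[c]]
      graphics::polygon(c(up$x, rev(lo$x)), c(up$y, rev(lo$y)),
                        col = if (is.na(fill)) NA else fill,
                        border = if (is.na(fill)) "#bbbbbb" else "#ffffff")
    }
  }
  if (inherits(layout, "band_layout")) {
    xs <- range(c(layout$timepoint_x,
                  unlist(lapply(layout$bands, function(b) b$x))))
    graphics::plot.new()
    graphics::plot.window(xlim = xs, ylim = c(0, layout$height))
    draw_bands(layout)
    graphics::axis(1, at = layout$timepoint_x,
                   labels = paste0(layout$timepoint_labels,
                                   tp_annotation(layout$timepoint_kind, options)))
  } else if (inherits(layout, "plaice_layout")) {
    up <- layout$upper
    xs <- range(c(up$timepoint_x, unlist(lapply(up$bands, function(b) b$x))))
    graphics::plot.new()
    graphics::plot.window(xlim = xs, ylim = c(-up$height, up$height))
    fills <- setNames(color_of(up$colors, layout$lower_fill),
                      names(layout$lower_fill))
    fills[is.na(layout$lower_fill)] <- NA_character_
    draw_bands(up)
    draw_bands(up, mirror = TRUE, fills = fills)
    graphics::abline(h = 0, col = "#333333")
    graphics::axis(1, at = up$timepoint_x,
                   labels = paste0(up$timepoint_labels,
                                   tp_annotation(up$timepoint_kind, options)))
  } else if (inherits(layout, "shark_layout")) {
    nodes <- layout$nodes
    m <- ncol(layout$radii)
    graphics::plot.new()
    graphics::plot.window(xlim = c(-0.5, max(nodes$x) + 0.5 + 0.6 * m),
                          ylim = c(0.25, max(nodes$y) + 0.75))
    for (i in seq_len(nrow(layout$edges))) {
      a <- match(layout$edges$from[i], nodes$clone)
      b <- match(layout$edges$to[i], nodes$clone)
      graphics::segments(nodes$x[a], nodes$y[a], nodes$x[b], nodes$y[b])
    }
    graphics::points(nodes$x, nodes$y, pch = 21, cex = 2,
                     bg = color_of(colors, nodes$clone))
    graphics::text(nodes$x, nodes$y + 0.2, nodes$clone, cex = 0.7)
    strip0 <- max(nodes$x) + 1
    for (t in seq_len(m)) {
      r <- layout$radii[, t]
      keep <- r > 0
      if (any(keep)) {
        graphics::symbols(rep(strip0 + 0.6 * (t - 1), sum(keep)),
                          nodes$y[match(rownames(layout$radii)[keep],
                                        nodes$clone)],
                          circles = r[keep] / 40, inches = FALSE, add = TRUE,
                          bg = color_of(colors, rownames(layout$radii)[keep]))
      }
    }
  } else {
    stop("unsupported layout class", call. = FALSE)
  }
  invisible(NULL)
}
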