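#' Layout configuration for dolphin and plaice plots
#'
#' @param shape band boundary shape: `"spline"` (monotone cubic,
#'   shape-preserving, rendered through the same support points) or
#'   `"polygon"` (straight borders)
#' @param vertical_mode `"centered"` (clones stacked symmetrically around the
#'   vertical middle, fish-plot style) or `"bottom"` (clones lying on the
#'   x-axis, with the longest branch at the bottom)
#' @param separate_independent insert a vertical gap between the stacks of
#'   independent (founder) clones?
#' @param birth_offset offset, in time-axis units, between the time point
#'   preceding a clone's first appearance and the x where its band starts
#'   with zero thickness (default 0.1; axis-unit dependent). The offset is
#'   clamped to half the enclosing interval for very narrow intervals.
#' @param independent_gap gap between founder stacks in percent of plot
#'   height (used when `separate_independent` is `TRUE`)
#' @param show_timepoint_labels draw time point labels when rendering?
#' @return a list of class `layout_config`
#' @export
layout_config <- function(shape = c("spline", "polygon"),
                          vertical_mode = c("centered", "bottom"),
                          separate_independent = FALSE,
                          birth_offset = 0.1, independent_gap = 2,
                          show_timepoint_labels = TRUE) {
  shape <- match.arg(shape)
  vertical_mode <- match.arg(vertical_mode)
  if (!is.numeric(birth_offset) || birth_offset <= 0) {
    stop("`birth_offset` must be > 0", call. = FALSE)
  }
  structure(list(shape = shape, vertical_mode = vertical_mode,
                 separate_independent = separate_independent,
                 birth_offset = birth_offset,
                 independent_gap = independent_gap,
                 show_timepoint_labels = show_timepoint_labels),
            class = "layout_config")
}

# x grid (time points plus birth coordinates) and per-clone piecewise-linear
# CCF values on it; clones absent at t_1 are 0 up to their birth x
band_values <- function(evo, birth_offset) {
  tol <- evo$tolerance
  tps <- evo$timepoints
  labels <- clone_labels(evo)
  fa <- first_appearance(evo$ccf, tol)

  birth_x <- setNames(rep(NA_real_, length(labels)), labels)
  for (c in labels) {
    f <- fa[[c]]
    if (!is.na(f) && f > 1) {
      gap <- tps[f] - tps[f - 1]
      birth_x[[c]] <- tps[f - 1] + min(birth_offset, gap / 2)
    }
  }
  grid <- sort(unique(c(tps, birth_x[!is.na(birth_x)])))

  V <- matrix(0, nrow = length(labels), ncol = length(grid),
              dimnames = list(labels, NULL))
  for (c in labels) {
    f <- fa[[c]]
    if (is.na(f)) next # all-zero clone: no geometry
    if (f == 1) {
      knots_x <- tps
      knots_y <- evo$ccf[c, ]
    } else {
      knots_x <- c(tps[seq_len(f - 1)], birth_x[[c]], tps[f:length(tps)])
      knots_y <- c(rep(0, f - 1), 0, evo$ccf[c, f:length(tps)])
    }
    V[c, ] <- if (length(knots_x) == 1) {
      rep(knots_y, length(grid))
    } else {
      stats::approx(knots_x, knots_y, xout = grid, rule = 2)$y
    }
  }
  list(grid = grid, V = V, birth_x = birth_x, fa = fa)
}

# stack all clones at one x; returns matrix cbind(lower, upper) by clone
stack_column <- function(evo, v, config, depth, tol) {
  labels <- clone_labels(evo)
  lower <- setNames(rep(NA_real_, length(labels)), labels)
  upper <- lower
  founders <- children_of(evo, NORMAL)

  if (config$vertical_mode == "centered") {
    founders <- order_siblings(evo, founders)
    place <- function(clone, y0) {
      h <- v[[clone]]
      lower[[clone]] <<- y0
      upper[[clone]] <<- y0 + h
      ch <- order_siblings(evo, labels[evo$parents == clone])
      if (length(ch) == 0) return(invisible())
      active <- v[ch] > tol
      gap <- max(0, (h - sum(v[ch])) / (sum(active) + 1))
      cursor <- y0
      for (x in ch) {
        if (v[[x]] > tol) {
          cursor <- cursor + gap
          place(x, cursor)
          cursor <- cursor + v[[x]]
        } else {
          place(x, cursor)
        }
      }
    }
    gap_f <- if (config$separate_independent) config$independent_gap else 0
    active_f <- founders[v[founders] > tol]
    total <- sum(v[founders]) + gap_f * max(0, length(active_f) - 1)
    cursor <- 50 - total / 2
    for (f in founders) {
      place(f, cursor)
      cursor <- cursor + v[[f]]
      if (v[[f]] > tol) cursor <- cursor + gap_f
    }
  } else {
    # bottom: deepest branch hugs the lower edge
    by_depth <- function(set) {
      if (length(set) <= 1) return(set)
      fa <- first_appearance(evo$ccf[set, , drop = FALSE], tol)
      fa[is.na(fa)] <- ncol(evo$ccf) + 1L
      set[order(-depth[set], fa, set)]
    }
    place <- function(clone, y0) {
      lower[[clone]] <<- y0
      upper[[clone]] <<- y0 + v[[clone]]
      cursor <- y0
      for (x in by_depth(labels[evo$parents == clone])) {
        place(x, cursor)
        if (v[[x]] > tol) cursor <- cursor + v[[x]]
      }
    }
    gap_f <- if (config$separate_independent) config$independent_gap else 0
    cursor <- 0
    for (f in by_depth(founders)) {
      place(f, cursor)
      cursor <- cursor + v[[f]]
      if (v[[f]] > tol) cursor <- cursor + gap_f
    }
  }
  cbind(lower = lower, upper = upper)
}

#' Band geometry for a dolphin (fish-plot style) plot
#'
#' Computes renderer-independent band geometry: for every clone an ordered
#' list of `(x, lower, upper)` support points, where the band thickness
#' `upper - lower` equals the clone's CCF (percent, mapped 1:1 to a plot
#' height of 100) at every measured time point. Bands of children lie within
#' the band of their parent. A clone first appearing at time point `t_f`
#' starts with zero thickness at `x(t_{f-1}) + birth_offset`.
#'
#' In centered mode the parent's unique CCF is split into equal gaps around
#' and between its children; in bottom mode clones lie on the x-axis and,
#' within each clone, the branch of greatest depth hugs the lower edge.
#'
#' @param evo a [clonal_evolution()] object
#' @param colors optional [assign_colors()] result (computed on demand)
#' @param config a [layout_config()]
#' @return an object of class `band_layout`: list with `bands` (named list
#'   of data frames `x`, `lower`, `upper`), `birth_x`, `timepoint_x`,
#'   `timepoint_labels`, `timepoint_kind`, `height`, `shape`,
#'   `vertical_mode`, `colors`
#' @export
dolphin_layout <- function(evo, colors = NULL, config = layout_config()) {
  stopifnot(is_clonal_evolution(evo))
  if (is.null(colors)) colors <- assign_colors(evo)
  tol <- evo$tolerance
  bv <- band_values(evo, config$birth_offset)
  labels <- clone_labels(evo)
  depth <- subtree_depths(evo$parents)

  G <- length(bv$grid)
  Ylow <- matrix(NA_real_, nrow = length(labels), ncol = G,
                 dimnames = list(labels, NULL))
  Yup <- Ylow
  for (g in seq_len(G)) {
    yy <- stack_column(evo, bv$V[, g], config, depth, tol)
    Ylow[, g] <- yy[, "lower"]
    Yup[, g] <- yy[, "upper"]
  }

  start_x <- ifelse(is.na(bv$birth_x), evo$timepoints[1], bv$birth_x)
  names(start_x) <- labels
  bands <- list()
  for (c in labels) {
    if (is.na(bv$fa[[c]])) {
      bands[[c]] <- data.frame(x = numeric(0), lower = numeric(0),
                               upper = numeric(0))
      next
    }
    keep <- bv$grid >= start_x[[c]] - 1e-12
    bands[[c]] <- data.frame(x = bv$grid[keep], lower = Ylow[c, keep],
                             upper = Yup[c, keep])
  }

  structure(list(bands = bands, birth_x = bv$birth_x,
                 timepoint_x = evo$timepoints,
                 timepoint_labels = evo$timepoint_labels,
                 timepoint_kind = evo$timepoint_kind,
                 height = 100, shape = config$shape,
                 vertical_mode = config$vertical_mode,
                 colors = colors),
            class = "band_layout")
}

#' Node-and-edge geometry for a shark (graph) plot
#'
#' Clones become nodes at `x = nested level`; parental relations become
#' edges. Independent founders form disconnected components, stacked
#' vertically. Optionally each time point contributes a bubble strip whose
#' radii grow with the clone's CCF (`radius = sqrt(ccf)`, so 0 exactly for
#' CCF 0).
#'
#' @param evo a [clonal_evolution()] object
#' @param config a [layout_config()] (only label settings are used)
#' @return an object of class `shark_layout`: list with `nodes` (data frame
#'   `clone`, `x`, `y`), `edges` (data frame `from`, `to`), `radii` (clones x
#'   time points matrix), `timepoint_labels`, `timepoint_kind`
#' @export
shark_layout <- function(evo, config = layout_config()) {
  stopifnot(is_clonal_evolution(evo))
  labels <- clone_labels(evo)
  lev <- nested_levels(evo)

  y <- setNames(rep(NA_real_, length(labels)), labels)
  leaf_counter <- 0
  assign_y <- function(clone) {
    ch <- order_siblings(evo, labels[evo$parents == clone])
    if (length(ch) == 0) {
      leaf_counter <<- leaf_counter + 1
      y[[clone]] <<- leaf_counter
    } else {
      for (x in ch) assign_y(x)
      y[[clone]] <<- mean(y[ch])
    }
  }
  for (f in order_siblings(evo, children_of(evo, NORMAL))) assign_y(f)

  edges <- data.frame(from = unname(evo$parents[evo$parents != NORMAL]),
                      to = labels[evo$parents != NORMAL],
                      stringsAsFactors = FALSE)
  structure(list(
    nodes = data.frame(clone = labels, x = unname(lev[labels]),
                       y = unname(y[labels]), stringsAsFactors = FALSE),
    edges = edges,
    radii = sqrt(evo$ccf),
    timepoint_labels = evo$timepoint_labels,
    timepoint_kind = evo$timepoint_kind),
    class = "shark_layout")
}

#' Mirrored band geometry for a plaice (allele-aware) plot
#'
#' The upper half is a bottom-mode dolphin layout showing clonal evolution;
#' the lower half is its exact reflection across the x-axis and visualises
#' the fraction of remaining healthy alleles of a gene of interest. By
#' default lower bands are not filled (100% healthy alleles). A clone whose
#' annotation names a color-source clone (e.g. a second hit completing a
#' first hit carried by an ancestor) is filled, below the axis, in the hue
#' of that source clone.
#'
#' @param evo a [clonal_evolution()] object
#' @param colors optional [assign_colors()] result
#' @param annotations named character vector: names are clones whose lower
#'   band should be filled, values are the clones providing the fill color
#'   (a clone may name itself, e.g. for hemizygous X/Y variants)
#' @param config a [layout_config()]; `vertical_mode` is forced to
#'   `"bottom"`
#' @return an object of class `plaice_layout`: list with `upper` (a
#'   `band_layout`), `lower` (mirrored bands), `lower_fill` (named vector,
#'   `NA` = unfilled)
#' @export
plaice_layout <- function(evo, colors = NULL, annotations = NULL,
                          config = layout_config()) {
  stopifnot(is_clonal_evolution(evo))
  config$vertical_mode <- "bottom"
  upper <- dolphin_layout(evo, colors, config)

  labels <- clone_labels(evo)
  lower_fill <- setNames(rep(NA_character_, length(labels)), labels)
  if (!is.null(annotations) && length(annotations) > 0) {
    annotations <- unlist(annotations)
    bad <- setdiff(c(names(annotations), annotations), labels)
    if (length(bad) > 0) {
      stop("plaice annotation names unknown clone(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    lower_fill[names(annotations)] <- annotations
  }

  lower <- lapply(upper$bands, function(b) {
    data.frame(x = b$x, lower = -b$upper, upper = -b$lower)
  })
  structure(list(upper = upper, lower = lower, lower_fill = lower_fill),
            class = "plaice_layout")
}

#' Serialize a layout as JSON
#'
#' Support points, colors and labels of a shark, dolphin or plaice layout,
#' so alternate renderers can consume the geometry.
#'
#' @param layout a `band_layout`, `shark_layout` or `plaice_layout`
#' @param path optional file path; when given, the JSON is written there
#' @return the JSON string, invisibly when `path` is given
#' @export
layout_json <- function(layout, path = NULL) {
  json <- jsonlite::toJSON(unclass_deep(layout), auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else {
    x
  }
}
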