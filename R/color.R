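#' Palette configuration for phylogeny-aware color coding
#'
#' The implementation constants behind the four coloring rules: hue,
#' saturation and lightness are assigned in HSL space. Founder clones
#' receive hues evenly spread over the wheel; each founder's subtree owns a
#' hue sector, recursively subdivided among sibling branches; lightness
#' steps down with nested level.
#'
#' @param max_independent capacity for clones developing from normal cells;
#'   fixed at 25
#' @param saturation base saturation in \[0,1\]
#' @param lightness_range two lightness endpoints `c(light, dark)`; clones
#'   at level 0 get the light end and lightness decreases by
#'   `diff/(max nested level + 1)` per level
#' @param sector_spread fraction (< 0.5) of a clone's hue sector handed down
#'   to its children in total; keeping it below 0.5 guarantees that hue
#'   variation within a branch stays smaller than the hue gap between
#'   subtrees of distinct founders
#' @param min_sector_width sector width in degrees below which a warning
#'   (not an error) is emitted
#' @return a list of class `palette_config`
#' @export
palette_config <- function(max_independent = 25, saturation = 0.65,
                           lightness_range = c(0.75, 0.35),
                           sector_spread = 0.4, min_sector_width = 1) {
  if (!identical(as.numeric(max_independent), 25)) {
    stop("`max_independent` is fixed at 25 independent clones", call. = FALSE)
  }
  stopifnot(sector_spread > 0, sector_spread < 0.5,
            length(lightness_range) == 2,
            lightness_range[1] > lightness_range[2])
  structure(list(max_independent = 25, saturation = saturation,
                 lightness_range = lightness_range,
                 sector_spread = sector_spread,
                 min_sector_width = min_sector_width),
            class = "palette_config")
}

# HSL (h in degrees, s/l in [0,1]) -> "#rrggbb"
hsl_to_hex <- function(h, s, l) {
  one <- function(h, s, l) {
    h <- (h %% 360) / 60
    c_ <- (1 - abs(2 * l - 1)) * s
    x <- c_ * (1 - abs(h %% 2 - 1))
    m <- l - c_ / 2
    rgb1 <- switch(floor(h) %% 6 + 1,
                   c(c_, x, 0), c(x, c_, 0), c(0, c_, x),
                   c(0, x, c_), c(x, 0, c_), c(c_, 0, x))
    grDevices::rgb(rgb1[1] + m, rgb1[2] + m, rgb1[3] + m)
  }
  mapply(one, h, s, l, USE.NAMES = FALSE)
}

#' Phylogeny-aware color assignment
#'
#' Assigns every clone an HSL color following four rules: (1) the higher the
#' nested level, the darker the color; (2) clones of the same branch share a
#' similar hue; (3) branches with a common ancestor get similar but
#' diverging hues; (4) branches without a common ancestor (independent
#' founders) get hues of maximum difference (evenly spread over the wheel).
#'
#' At most 25 independent clones (founders) are supported; related clones
#' are unlimited (sectors are subdivided recursively, with a warning once a
#' sector becomes narrower than `config$min_sector_width` degrees).
#'
#' @param evo a [clonal_evolution()] object
#' @param config a [palette_config()]
#' @return data frame of class `color_assignment` with columns `clone`,
#'   `hue` (degrees), `saturation`, `lightness`, `hex`, in clone order
#'
#' @examples
#' evo <- clonal_evolution(rbind(A = c(80, 90), B = c(30, 60)),
#'                         c("normal", "A"))
#' assign_colors(evo)
#' @export
assign_colors <- function(evo, config = palette_config()) {
  stopifnot(is_clonal_evolution(evo))
  labels <- clone_labels(evo)
  founders <- children_of(evo, NORMAL)
  kf <- length(founders)
  if (kf > config$max_independent) {
    cond <- structure(
      class = c("palette_capacity_error", "error", "condition"),
      list(message = sprintf(
        "%d independent clones requested, but at most %d independent clones (developing from normal cells) are supported",
        kf, config$max_independent), call = sys.call(-1),
        n_founders = kf, max_independent = config$max_independent))
    stop(cond)
  }

  lev <- nested_levels(evo)
  maxlev <- max(lev)
  lr <- config$lightness_range
  step <- (lr[1] - lr[2]) / (maxlev + 1)
  lightness <- lr[1] - step * lev

  # leaves below (and incl.) each clone, to size sibling sectors
  n_leaves <- setNames(rep(1L, length(labels)), labels)
  for (c in labels[order(lev, decreasing = TRUE)]) {
    ch <- labels[evo$parents == c]
    if (length(ch) > 0) n_leaves[[c]] <- sum(n_leaves[ch])
  }

  hue <- setNames(numeric(length(labels)), labels)
  narrow <- FALSE
  assign_sector <- function(clone, center, width) {
    hue[[clone]] <<- center %% 360
    if (width < config$min_sector_width) narrow <<- TRUE
    ch <- order_siblings(evo, labels[evo$parents == clone])
    if (length(ch) == 0) return(invisible())
    span <- width * config$sector_spread
    w <- span * n_leaves[ch] / sum(n_leaves[ch])
    left <- center - span / 2
    for (i in seq_along(ch)) {
      assign_sector(ch[i], left + w[i] / 2, w[i])
      left <- left + w[i]
    }
  }
  wf <- 360 / kf
  founders <- order_siblings(evo, founders)
  for (i in seq_along(founders)) {
    assign_sector(founders[i], (i - 1) * wf, wf)
  }
  if (narrow) {
    warning("some hue sectors are narrower than ", config$min_sector_width,
            " degrees; closely related clones may be hard to distinguish",
            call. = FALSE)
  }

  out <- data.frame(
    clone = labels,
    hue = unname(hue[labels]),
    saturation = config$saturation,
    lightness = unname(lightness[labels]),
    stringsAsFactors = FALSE)
  out$hex <- hsl_to_hex(out$hue, out$saturation, out$lightness)

  # hue sectors of closely related clones can collapse below the 8-bit RGB
  # resolution; separate residual duplicates by stepping saturation down
  # (saturation carries no phylogenetic meaning, hue and lightness do)
  guard <- 0
  while (anyDuplicated(out$hex) && guard < 40) {
    idx <- which(duplicated(out$hex))
    out$saturation[idx] <- pmax(0.2, out$saturation[idx] - 0.02)
    out$hex <- hsl_to_hex(out$hue, out$saturation, out$lightness)
    guard <- guard + 1
  }
  class(out) <- c("color_assignment", "data.frame")
  out
}

# deterministic sibling order: first appearance, then label
order_siblings <- function(evo, siblings) {
  if (length(siblings) <= 1) return(siblings)
  fa <- first_appearance(evo$ccf[siblings, , drop = FALSE], evo$tolerance)
  fa[is.na(fa)] <- ncol(evo$ccf) + 1L
  siblings[order(fa, siblings)]
}
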