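#' Reserved parent label for normal (non-tumor) cells
#'
#' Clones whose parent is `NORMAL` arise directly from normal cells
#' (founding clones / stemlines). On input, the strings `"normal"`
#' (case-insensitive), `"0"`, the number `0`, the empty string and `NA`
#' are all accepted and canonicalised to this value.
#'
#' @export
NORMAL <- "normal"

# canonicalise a vector of parent references; labels = clone labels in order
normalize_parents <- function(parents, labels) {
  if (length(parents) != length(labels)) {
    stop("`parents` must have one entry per clone (", length(labels),
         " expected, got ", length(parents), ")", call. = FALSE)
  }
  p <- as.character(parents)
  p[is.na(p)] <- NORMAL
  p[tolower(trimws(p)) %in% c("normal", "0", "")] <- NORMAL
  names(p) <- labels
  unknown <- setdiff(p, c(NORMAL, labels))
  if (length(unknown) > 0) {
    stop("unknown parent reference(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p
}

# returns NULL if the parent links form a forest, otherwise the labels of one cycle
find_cycle <- function(parents) {
  labels <- names(parents)
  for (start in labels) {
    seen <- character(0)
    cur <- start
    while (!identical(cur, NORMAL)) {
      if (cur %in% seen) {
        i <- match(cur, seen)
        return(seen[i:length(seen)])
      }
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
  }
  NULL
}

coerce_ccf_matrix <- function(ccf) {
  if (is.data.frame(ccf)) ccf <- as.matrix(ccf)
  if (!is.matrix(ccf) || !is.numeric(ccf)) {
    stop("`ccf` must be a numeric matrix (clones x time points)", call. = FALSE)
  }
  ccf
}

#' Construct a validated clonal evolution object
#'
#' Builds the central container of the package: an `n x m` matrix of cancer
#' cell fractions (CCFs, in percent) for `n` clones at `m` time points,
#' together with the parental relation of every clone. Construction enforces
#' the validity rules of [check_validity()]: children cannot exceed their
#' parents, founding clones cannot sum to more than 100% at any time point,
#' and neither a clone nor a thoroughly replaced parent can reappear.
#'
#' @param ccf numeric matrix of CCFs in percent (0-100), one row per clone,
#'   one column per time point. Row names are used as clone labels unless
#'   `labels` is given. Missing values are an error: absence must be encoded
#'   as an explicit 0.
#' @param parents character vector, one entry per clone: the label of the
#'   parent clone, or [NORMAL] (also accepted: `"0"`, `0`, `NA`, `""`) for
#'   clones arising directly from normal cells.
#' @param timepoints strictly increasing numeric time coordinates (arbitrary
#'   non-negative units, e.g. days). Defaults to the column names parsed as
#'   numbers (an optional leading `"t"` is stripped), or `0:(m-1)`.
#' @param labels clone labels; defaults to `rownames(ccf)` or `C1..Cn`.
#' @param timepoint_labels display labels for the time points; defaults to
#'   `t<coordinate>`.
#' @param timepoint_kind per-time-point tag, one of `"measured"`,
#'   `"interpolated"`, `"therapy"`. Defaults to all `"measured"`.
#' @param tolerance absolute tolerance in CCF percent used by all inequality
#'   checks (default `1e-9`).
#'
#' @return an object of class `clonal_evolution` with fields `ccf`,
#'   `parents`, `timepoints`, `timepoint_labels`, `timepoint_kind`,
#'   `tolerance`.
#'
#' @examples
#' evo <- clonal_evolution(
#'   rbind(A = c(80, 90), B = c(30, 60)),
#'   parents = c("normal", "A")
#' )
#' unique_ccf(evo)
#' @export
clonal_evolution <- function(ccf, parents, timepoints = NULL, labels = NULL,
                             timepoint_labels = NULL, timepoint_kind = NULL,
                             tolerance = 1e-9) {
  ccf <- coerce_ccf_matrix(ccf)
  n <- nrow(ccf)
  m <- ncol(ccf)
  if (n < 1 || m < 1) stop("need at least one clone and one time point", call. = FALSE)

  if (is.null(labels)) labels <- rownames(ccf)
  if (is.null(labels)) labels <- paste0("C", seq_len(n))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("clone labels must be unique: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  if (any(tolower(labels) == NORMAL)) {
    stop("'normal' is a reserved label and cannot name a clone", call. = FALSE)
  }

  if (anyNA(ccf)) {
    stop("missing CCF cells are not allowed; encode absence as an explicit 0",
         call. = FALSE)
  }
  if (any(ccf < 0 - tolerance) || any(ccf > 100 + tolerance)) {
    stop("CCF values must lie in [0, 100] percent", call. = FALSE)
  }
  if (all(ccf <= 1) && any(ccf > 0)) {
    stop("all CCF values are <= 1: input looks like fractions, but percent ",
         "values in [0, 100] are required (multiply by 100 if appropriate)",
         call. = FALSE)
  }

  if (is.null(timepoints)) timepoints <- parse_timepoint_coords(colnames(ccf), m)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != m) {
    stop("`timepoints` must have one coordinate per CCF column", call. = FALSE)
  }
  if (anyNA(timepoints) || any(diff(timepoints) <= 0)) {
    stop("time point coordinates must be strictly increasing", call. = FALSE)
  }
  if (any(timepoints < 0)) {
    stop("time point coordinates must be non-negative", call. = FALSE)
  }

  parents <- normalize_parents(parents, labels)
  cyc <- find_cycle(parents)
  if (!is.null(cyc)) {
    stop("parental relations contain a cycle: ",
         paste(c(cyc, cyc[1]), collapse = " -> "), call. = FALSE)
  }

  rownames(ccf) <- labels
  if (is.null(timepoint_labels)) {
    timepoint_labels <- colnames(ccf)
    if (is.null(timepoint_labels)) {
      timepoint_labels <- paste0("t", format(timepoints, trim = TRUE, digits = 6))
    }
  }
  colnames(ccf) <- timepoint_labels
  if (is.null(timepoint_kind)) timepoint_kind <- rep("measured", m)
  timepoint_kind <- match.arg(timepoint_kind,
                              c("measured", "interpolated", "therapy"),
                              several.ok = TRUE)
  if (length(timepoint_kind) == 1) timepoint_kind <- rep(timepoint_kind, m)

  rep_ <- check_validity(ccf, parents, tolerance = tolerance)
  if (!rep_$passed) {
    stop("CCF table fails the validity check:\n",
         paste(format_violations(rep_$violations), collapse = "\n"),
         call. = FALSE)
  }

  new_clonal_evolution(ccf, parents, timepoints, timepoint_labels,
                       timepoint_kind, tolerance)
}

# internal constructor: assumes all checks already done
new_clonal_evolution <- function(ccf, parents, timepoints, timepoint_labels,
                                 timepoint_kind, tolerance) {
  structure(
    list(ccf = ccf, parents = parents, timepoints = as.numeric(timepoints),
         timepoint_labels = as.character(timepoint_labels),
         timepoint_kind = as.character(timepoint_kind),
         tolerance = tolerance),
    class = "clonal_evolution"
  )
}

# rebuild an evolution from modified internals, re-running the validity check
rebuild_evolution <- function(evo, ccf = evo$ccf, timepoints = evo$timepoints,
                              timepoint_labels = evo$timepoint_labels,
                              timepoint_kind = evo$timepoint_kind) {
  rep_ <- check_validity(ccf, evo$parents, tolerance = evo$tolerance)
  if (!rep_$passed) {
    stop("internal error: derived CCF table fails the validity check:\n",
         paste(format_violations(rep_$violations), collapse = "\n"),
         call. = FALSE)
  }
  colnames(ccf) <- timepoint_labels
  new_clonal_evolution(ccf, evo$parents, timepoints, timepoint_labels,
                       timepoint_kind, evo$tolerance)
}

parse_timepoint_coords <- function(nms, m) {
  if (!is.null(nms)) {
    coords <- suppressWarnings(as.numeric(sub("^[tT]", "", nms)))
    if (!anyNA(coords)) return(coords)
  }
  seq_len(m) - 1
}

#' @export
print.clonal_evolution <- function(x, ...) {
  cat("<clonal_evolution>", nrow(x$ccf), "clone(s) x", ncol(x$ccf),
      "time point(s)\n")
  cat("  time points:",
      paste0(x$timepoint_labels, " (", substr(x$timepoint_kind, 1, 1), ")",
             collapse = ", "), "\n")
  founders <- clone_labels(x)[x$parents == NORMAL]
  cat("  founders:", paste(founders, collapse = ", "), "\n")
  invisible(x)
}

#' Test whether an object is a clonal evolution
#' @param x any object
#' @return logical scalar
#' @export
is_clonal_evolution <- function(x) inherits(x, "clonal_evolution")

#' Clone labels of a clonal evolution
#' @param evo a [clonal_evolution()] object
#' @return character vector of clone labels, in storage order
#' @export
clone_labels <- function(evo) rownames(evo$ccf)

#' Children of a clone
#'
#' @param evo a [clonal_evolution()] object
#' @param clone a clone label, or [NORMAL] to obtain all founding clones
#' @return character vector of the labels whose parent is `clone`
#' @export
children_of <- function(evo, clone) {
  stopifnot(is_clonal_evolution(evo))
  clone <- as.character(clone)
  if (!identical(clone, NORMAL) && !(clone %in% clone_labels(evo))) {
    stop("unknown clone label: ", clone, call. = FALSE)
  }
  clone_labels(evo)[evo$parents == clone]
}

# nested levels for a raw parents vector (names = labels)
compute_levels <- function(parents) {
  labels <- names(parents)
  lev <- integer(length(labels))
  names(lev) <- labels
  for (c in labels) {
    d <- 0L
    cur <- parents[[c]]
    while (!identical(cur, NORMAL)) {
      d <- d + 1L
      cur <- parents[[cur]]
    }
    lev[[c]] <- d
  }
  lev
}

#' Nested levels of all clones
#'
#' The nested level of a clone is its depth in the phylogeny: 0 for clones
#' arising directly from normal cells, and `level(parent) + 1` otherwise.
#' Clones of the same nested level are assumed to have developed at
#' approximately the same time; a higher nested level indicates development
#' at a later time.
#'
#' @param evo a [clonal_evolution()] object
#' @return named integer vector of levels, one per clone
#' @export
nested_levels <- function(evo) {
  stopifnot(is_clonal_evolution(evo))
  compute_levels(evo$parents)
}

#' @rdname nested_levels
#' @param clone a single clone label
#' @export
nested_level <- function(evo, clone) {
  clone <- as.character(clone)
  if (!(clone %in% clone_labels(evo))) {
    stop("unknown clone label: ", clone, call. = FALSE)
  }
  nested_levels(evo)[[clone]]
}

# uccf for a raw matrix + parents vector
compute_uccf <- function(ccf, parents) {
  uccf <- ccf
  labels <- rownames(ccf)
  for (c in labels) {
    ch <- labels[parents == c]
    if (length(ch) > 0) {
      uccf[c, ] <- ccf[c, ] - colSums(ccf[ch, , drop = FALSE])
    }
  }
  uccf
}

#' Unique CCF (ccf') of every clone
#'
#' The unique CCF of a clone at a time point is its CCF minus the summed
#' CCFs of its direct children: the fraction of cells belonging to exactly
#' that clone and none of its descendants.
#'
#' @param evo a [clonal_evolution()] object
#' @return numeric matrix of the same shape as `evo$ccf`
#' @export
unique_ccf <- function(evo) {
  stopifnot(is_clonal_evolution(evo))
  compute_uccf(evo$ccf, evo$parents)
}

#' Rebuild CCFs from unique CCFs
#'
#' Inverse of [unique_ccf()]: accumulates `ccf(c) = uccf(c) + sum of
#' children's ccf`, processing clones leaf-to-root.
#'
#' @param uccf numeric matrix of unique CCFs (percent), row names = clone
#'   labels; all values must be `>= -tolerance`
#' @param parents parent references as in [clonal_evolution()]
#' @param tolerance absolute tolerance for the non-negativity check
#' @return numeric CCF matrix of the same shape
#' @export
ccf_from_unique <- function(uccf, parents, tolerance = 1e-9) {
  uccf <- coerce_ccf_matrix(uccf)
  labels <- rownames(uccf)
  if (is.null(labels)) labels <- paste0("C", seq_len(nrow(uccf)))
  rownames(uccf) <- labels
  parents <- normalize_parents(parents, labels)
  if (any(uccf < -tolerance)) {
    bad <- which(uccf < -tolerance, arr.ind = TRUE)[1, ]
    stop("negative unique CCF for clone ", labels[bad[1]], " at time point ",
         bad[2], call. = FALSE)
  }
  accumulate_uccf(pmax(uccf, 0), parents)
}

# leaf-to-root accumulation, no checks
accumulate_uccf <- function(uccf, parents) {
  labels <- rownames(uccf)
  lev <- compute_levels(parents)
  ccf <- uccf
  for (c in labels[order(lev[labels], decreasing = TRUE)]) {
    ch <- labels[parents == c]
    if (length(ch) > 0) {
      ccf[c, ] <- uccf[c, ] + colSums(ccf[ch, , drop = FALSE])
    }
  }
  ccf
}

# maximum depth below a clone (0 for leaves), for every clone
subtree_depths <- function(parents) {
  labels <- names(parents)
  lev <- compute_levels(parents)
  depth <- setNames(integer(length(labels)), labels)
  for (c in labels[order(lev, decreasing = TRUE)]) {
    ch <- labels[parents == c]
    if (length(ch) > 0) depth[[c]] <- 1L + max(depth[ch])
  }
  depth
}

# index of first column with value > tol, or NA if the row never rises
first_appearance <- function(ccf, tolerance) {
  apply(ccf > tolerance, 1, function(r) {
    w <- which(r)
    if (length(w) == 0) NA_integer_ else w[1]
  })
}

# insert columns into an evolution after column `after` (0 = before first)
insert_timepoints <- function(evo, after, coords, values, kind, labels = NULL) {
  stopifnot(length(coords) == ncol(values))
  if (is.null(labels)) {
    labels <- paste0("t", format(coords, trim = TRUE, digits = 6))
  }
  m <- ncol(evo$ccf)
  left <- seq_len(after)
  right <- if (after < m) (after + 1):m else integer(0)
  ccf <- cbind(evo$ccf[, left, drop = FALSE], values,
               evo$ccf[, right, drop = FALSE])
  tps <- c(evo$timepoints[left], coords, evo$timepoints[right])
  tpl <- c(evo$timepoint_labels[left], labels, evo$timepoint_labels[right])
  tpk <- c(evo$timepoint_kind[left], rep(kind, length(coords)),
           evo$timepoint_kind[right])
  rebuild_evolution(evo, ccf = ccf, timepoints = tps, timepoint_labels = tpl,
                    timepoint_kind = tpk)
}
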