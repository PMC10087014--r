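#' Configuration for alternative-phylogeny enumeration
#'
#' @param max_permutations maximum number of filtered candidate
#'   parental-relation vectors that will be subjected to the thorough
#'   validity check; exceeding it aborts the enumeration (default 20000)
#' @param tolerance absolute CCF tolerance in percent
#' @return a list of class `explorer_config`
#' @export
explorer_config <- function(max_permutations = 20000, tolerance = 1e-9) {
  max_permutations <- as.numeric(max_permutations)
  if (length(max_permutations) != 1 || is.na(max_permutations) ||
      max_permutations < 1) {
    stop("`max_permutations` must be a positive number", call. = FALSE)
  }
  structure(list(max_permutations = max_permutations, tolerance = tolerance),
            class = "explorer_config")
}

#' Admissible parents for every clone of a CCF table
#'
#' Applies the two pre-filters used before enumerating alternative
#' phylogenies:
#'
#' 1. clone `c` cannot be the parent of clone `j` if `ccf(c, t) < ccf(j, t)`
#'    at any time point (a parent must always contain its child);
#' 2. if the parent of clone `j` can only be clone `c` (a singleton
#'    candidate set, only possible through explicit `known` constraints),
#'    then another clone `k` can only branch from `c` if
#'    `ccf(c, t) - ccf(j, t) >= ccf(k, t)` at every time point. This filter
#'    is re-applied until no candidate set changes.
#'
#' [NORMAL] is never removed by the CCF filters: any clone may in principle
#' arise from normal cells.
#'
#' @param ccf numeric CCF matrix (clones x time points, percent)
#' @param tolerance absolute CCF tolerance in percent; comparisons are
#'   strict beyond it
#' @param known optional named list of explicit constraints: for each named
#'   clone, the set of parent labels (possibly excluding [NORMAL]) it is
#'   allowed to have. Candidate sets are intersected with these before
#'   filter 2 runs.
#' @return named list, one character vector of admissible parent labels
#'   (including possibly [NORMAL]) per clone
#'
#' @examples
#' ccf <- rbind(A = c(90, 80), B = c(40, 50), C = c(10, 5))
#' candidate_parents(ccf)
#' @export
candidate_parents <- function(ccf, tolerance = 1e-9, known = list()) {
  ccf <- coerce_ccf_matrix(ccf)
  labels <- rownames(ccf)
  if (is.null(labels)) labels <- paste0("C", seq_len(nrow(ccf)))
  rownames(ccf) <- labels

  cand <- list()
  for (j in labels) {
    others <- setdiff(labels, j)
    # filter 1: c is excluded when its CCF ever falls below j's
    keep <- others[vapply(others, function(c) {
      !any(ccf[c, ] < ccf[j, ] - tolerance)
    }, logical(1))]
    cand[[j]] <- c(NORMAL, keep)
  }

  if (length(known) > 0) {
    bad <- setdiff(names(known), labels)
    if (length(bad) > 0) {
      stop("`known` names unknown clone(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (j in names(known)) {
      allowed <- as.character(known[[j]])
      allowed[tolower(allowed) %in% c("normal", "0")] <- NORMAL
      cand[[j]] <- intersect(cand[[j]], allowed)
    }
  }

  # filter 2, iterated to fixpoint
  repeat {
    changed <- FALSE
    for (j in labels) {
      s <- cand[[j]]
      if (length(s) == 1 && !identical(s, NORMAL)) {
        c <- s
        for (k in setdiff(labels, c(j, c))) {
          if (c %in% cand[[k]] &&
              any(ccf[c, ] - ccf[j, ] < ccf[k, ] - tolerance)) {
            cand[[k]] <- setdiff(cand[[k]], c)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  cand
}

# TRUE when the parent vector (named, values label or NORMAL) is a forest
is_forest <- function(parents) {
  labels <- names(parents)
  state <- setNames(integer(length(labels)), labels) # 0 new, 1 open, 2 done
  for (start in labels) {
    path <- character(0)
    cur <- start
    while (!identical(cur, NORMAL) && state[[cur]] == 0L) {
      state[[cur]] <- 1L
      path <- c(path, cur)
      cur <- parents[[cur]]
    }
    if (!identical(cur, NORMAL) && state[[cur]] == 1L) return(FALSE)
    state[path] <- 2L
  }
  TRUE
}

#' Enumerate all phylogenies consistent with a CCF table
#'
#' Builds the Cartesian product of the filtered candidate parent sets
#' (see [candidate_parents()]), removes vectors whose parent links are not a
#' forest, and keeps exactly those passing [check_validity()]. The result is
#' deterministically ordered: lexicographic by clone order, with [NORMAL]
#' sorting before clone labels (themselves sorted).
#'
#' If the filtered product exceeds `config$max_permutations`, the
#' enumeration aborts with an error of class `permutation_cap_error`
#' carrying fields `product_size` and `max_permutations`; no partial result
#' is returned.
#'
#' @param ccf numeric CCF matrix (clones x time points, percent)
#' @param config an [explorer_config()]
#' @param known explicit constraints, passed to [candidate_parents()]
#' @return list of named character parent vectors, with attribute `counts`
#'   (`n_total` = n^n, `n_filtered` = size of the filtered product,
#'   `n_valid`)
#'
#' @examples
#' trees <- enumerate_trees(rbind(A = c(90, 80), B = c(40, 50)))
#' length(trees)
#' @export
enumerate_trees <- function(ccf, config = explorer_config(), known = list()) {
  ccf <- coerce_ccf_matrix(ccf)
  labels <- rownames(ccf)
  if (is.null(labels)) labels <- paste0("C", seq_len(nrow(ccf)))
  rownames(ccf) <- labels
  n <- length(labels)

  cand <- candidate_parents(ccf, tolerance = config$tolerance, known = known)
  cand <- lapply(cand, function(s) {
    c(intersect(NORMAL, s), sort(setdiff(s, NORMAL)))
  })
  product <- prod(vapply(cand, length, numeric(1)))

  if (product > config$max_permutations) {
    cond <- structure(
      class = c("permutation_cap_error", "error", "condition"),
      list(message = sprintf(
        paste0("filtered candidate space contains %.0f parental-relation ",
               "vectors, exceeding the maximum of %.0f permutations ",
               "subjected to the validity check"),
        product, config$max_permutations),
        call = sys.call(-1),
        product_size = product,
        max_permutations = config$max_permutations))
    stop(cond)
  }

  out <- list()
  counts <- c(n_total = n^n, n_filtered = product, n_valid = 0)
  if (product > 0) {
    # reversed so the first clone varies slowest => lexicographic order
    grid <- expand.grid(rev(cand), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_along(cand)), drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      p <- setNames(as.character(grid[i, ]), labels)
      if (!is_forest(p)) next
      if (check_validity(ccf, p, tolerance = config$tolerance)$passed) {
        out[[length(out) + 1]] <- p
      }
    }
    counts[["n_valid"]] <- length(out)
  }
  attr(out, "counts") <- counts
  out
}
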