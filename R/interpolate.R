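#' Interpolate a tumor's development before the first measured time point
#'
#' Inserts as many interpolated time points before `t_1` as the maximum
#' nested level among the clones present at `t_1`. Clones of the highest
#' nested level are assumed to have developed last: walking backwards from
#' `t_1`, at each successively earlier inserted point the clones of the
#' currently highest remaining level have their CCF and unique CCF set to 0,
#' while the remaining initial clones keep their unique CCF from `t_1` and
#' have their CCF rebuilt from it.
#'
#' Inserted coordinates extend the axis leftwards in steps equal to the
#' smallest gap between measured time points (1.0 when only a single time
#' point exists) and may therefore be negative.
#'
#' @param evo a [clonal_evolution()] object
#' @return a new `clonal_evolution` with the inserted points tagged
#'   `"interpolated"`; unchanged when all initial clones are founders
#'
#' @examples
#' evo <- clonal_evolution(rbind(A = 80, B = 30), c("normal", "A"),
#'                         timepoints = 10)
#' interpolate_initial(evo)$ccf
#' @export
interpolate_initial <- function(evo) {
  stopifnot(is_clonal_evolution(evo))
  tol <- evo$tolerance
  init <- clone_labels(evo)[evo$ccf[, 1] > tol]
  lev <- nested_levels(evo)
  if (length(init) == 0) return(evo)
  L <- max(lev[init])
  if (L == 0) return(evo)

  m <- ncol(evo$ccf)
  step <- if (m >= 2) min(diff(evo$timepoints)) else 1.0
  coords <- evo$timepoints[1] - step * (L:1)

  uccf1 <- compute_uccf(evo$ccf, evo$parents)[, 1]
  values <- matrix(0, nrow = nrow(evo$ccf), ncol = L,
                   dimnames = list(clone_labels(evo), NULL))
  for (idx in seq_len(L)) {
    # column idx (earliest first): clones with level >= idx are zeroed
    u <- uccf1
    u[!(names(u) %in% init) | lev >= idx] <- 0
    values[, idx] <- accumulate_uccf(cbind(u), evo$parents)
  }
  insert_timepoints(evo, after = 0, coords = coords, values = values,
                    kind = "interpolated")
}

#' Interpolate a tumor's development between two measured time points
#'
#' For a pair of adjacent measured time points, inserts `(number of unique
#' nested levels among newly appearing clones) - 1` interpolated points,
#' evenly spaced unless explicit fractional positions are given. Clones
#' already present at the left endpoint develop linearly between the two
#' measurements. Newly appearing clones start successively by nested level:
#' a new clone whose level is preceded by `z` other unique new levels stays
#' at 0 for the first `z` inserted points and then develops linearly up to
#' its CCF at the right endpoint.
#'
#' If the combination of linear old clones and late-starting new clones
#' transiently drives a unique CCF below zero at an inserted point, the
#' unique CCF is floored at 0 and the parents' CCFs rebuilt, with a warning.
#' Measured columns are never modified.
#'
#' @param evo a [clonal_evolution()] object
#' @param interval index `i` of the interval between the i-th and (i+1)-th
#'   *measured* time points; the two must still be adjacent columns (no
#'   points inserted between them yet)
#' @param positions optional vector of fractions in (0,1) placing the
#'   inserted points inside the interval (default: evenly spaced); its
#'   length must equal the computed number of inserted points
#' @return a new `clonal_evolution` with inserted points tagged
#'   `"interpolated"`
#' @export
interpolate_between <- function(evo, interval, positions = NULL) {
  stopifnot(is_clonal_evolution(evo))
  tol <- evo$tolerance
  measured <- which(evo$timepoint_kind == "measured")
  if (interval < 1 || interval >= length(measured)) {
    stop("`interval` must index a pair of adjacent measured time points",
         call. = FALSE)
  }
  a <- measured[interval]
  b <- measured[interval + 1]
  if (b != a + 1) {
    stop("time points are already inserted between measured time points ",
         interval, " and ", interval + 1, call. = FALSE)
  }

  labels <- clone_labels(evo)
  lev <- nested_levels(evo)
  old <- evo$ccf[, a] > tol
  newc <- !old & evo$ccf[, b] > tol
  U <- sort(unique(lev[labels[newc]]))
  K <- max(0L, length(U) - 1L)
  if (K == 0) return(evo)

  ta <- evo$timepoints[a]
  tb <- evo$timepoints[b]
  if (is.null(positions)) positions <- seq_len(K) / (K + 1)
  if (length(positions) != K || any(positions <= 0) || any(positions >= 1)) {
    stop("`positions` must be ", K, " fractions strictly inside (0, 1)",
         call. = FALSE)
  }
  coords <- ta + (tb - ta) * sort(positions)

  values <- matrix(0, nrow = length(labels), ncol = K,
                   dimnames = list(labels, NULL))
  for (c in labels) {
    if (old[c]) {
      values[c, ] <- evo$ccf[c, a] +
        (evo$ccf[c, b] - evo$ccf[c, a]) * (coords - ta) / (tb - ta)
    } else if (newc[c]) {
      z <- sum(U < lev[[c]])
      if (z < K) {
        xz <- if (z == 0) ta else coords[z]
        j <- (z + 1):K
        values[c, j] <- evo$ccf[c, b] * (coords[j] - xz) / (tb - xz)
      }
    }
  }
  values <- repair_nesting(values, evo$parents, tol)
  insert_timepoints(evo, after = a, coords = coords, values = values,
                    kind = "interpolated")
}

# floor negative unique CCFs at 0 and rebuild parents' CCFs; warn when a
# genuinely negative value (beyond tolerance) had to be repaired
repair_nesting <- function(values, parents, tol) {
  uccf <- compute_uccf(values, parents)
  if (any(uccf < 0)) {
    if (any(uccf < -tol)) {
      warning("interpolated values transiently violated nesting; ",
              "negative unique CCFs were floored at 0 and parents rebuilt",
              call. = FALSE)
    }
    values <- accumulate_uccf(pmax(uccf, 0), parents)
  }
  values
}

#' Fully automatic time-point interpolation
#'
#' Applies [interpolate_initial()] and then [interpolate_between()] on every
#' pair of adjacent measured time points, left to right.
#'
#' Intervals that already contain inserted points (e.g. an estimated
#' therapy time point) are left untouched.
#'
#' @param evo a [clonal_evolution()] object
#' @param initial interpolate the development before the first measured time
#'   point as well? (default `TRUE`)
#' @return a new `clonal_evolution`; `timepoint_kind` distinguishes measured
#'   from interpolated points throughout
#' @export
interpolate_all <- function(evo, initial = TRUE) {
  stopifnot(is_clonal_evolution(evo))
  if (initial) evo <- interpolate_initial(evo)
  n_measured <- sum(evo$timepoint_kind == "measured")
  if (n_measured >= 2) {
    for (i in seq_len(n_measured - 1)) {
      measured <- which(evo$timepoint_kind == "measured")
      if (measured[i + 1] == measured[i] + 1) {
        evo <- interpolate_between(evo, i)
      }
    }
  }
  evo
}
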