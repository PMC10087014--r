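#' Describe a therapy window between two measured time points
#'
#' @param interval index `i` of the interval between the i-th and (i+1)-th
#'   measured time points during which therapy was applied
#' @param position optional fraction in (0,1) locating the estimated
#'   end-of-therapy time point inside the interval. By default the therapy
#'   point and any post-therapy interpolated points divide the interval into
#'   equal parts: with `k` post-therapy insertions the therapy point sits at
#'   fraction `1/(k+2)` (i.e. the midpoint when `k = 0`).
#' @param extra_interpolation interpolate the post-therapy re-expansion of
#'   newly developing clones as well? Default (`NULL`): `TRUE` exactly when
#'   new clones appear in the window.
#' @return a list of class `therapy_window`
#' @export
therapy_window <- function(interval, position = NULL,
                           extra_interpolation = NULL) {
  interval <- as.integer(interval)
  if (length(interval) != 1 || is.na(interval) || interval < 1) {
    stop("`interval` must be a positive measured-interval index", call. = FALSE)
  }
  if (!is.null(position)) {
    position <- as.numeric(position)
    if (length(position) != 1 || is.na(position) || position <= 0 ||
        position >= 1) {
      stop("`position` must be a fraction strictly inside (0, 1)", call. = FALSE)
    }
  }
  structure(list(interval = interval, position = position,
                 extra_interpolation = extra_interpolation),
            class = "therapy_window")
}

# resolve the two adjacent measured columns of a window; error otherwise
window_columns <- function(evo, window) {
  measured <- which(evo$timepoint_kind == "measured")
  i <- window$interval
  if (i < 1 || i >= length(measured)) {
    stop("therapy window must lie between two measured time points",
         call. = FALSE)
  }
  c(a = measured[i], b = measured[i + 1])
}

#' Insert an estimated end-of-therapy time point
#'
#' In the presence of therapy, any observed decrease of a clone's unique CCF
#' between two measured time points is attributed to the therapy. A single
#' time point (tagged `"therapy"`) is inserted inside the window; there,
#' every clone already present at the left endpoint gets
#' `ccf'(c) = min(ccf'(c, t_i), ccf'(c, t_{i+1}))`, CCFs are rebuilt from
#' the unique CCFs leaf-to-root, and clones absent at the left endpoint get
#' CCF 0 (they are assumed to have developed after therapy).
#'
#' @param evo a [clonal_evolution()] object
#' @param window a [therapy_window()]; its endpoints must still be adjacent
#'   columns (no points inserted between them yet)
#' @return a new `clonal_evolution` with the therapy point inserted
#'
#' @examples
#' evo <- clonal_evolution(rbind(A = c(70, 70), B = c(20, 60)),
#'                         c("normal", "A"), timepoints = c(0, 100))
#' estimate_therapy_effect(evo, therapy_window(1))$ccf
#' @export
estimate_therapy_effect <- function(evo, window) {
  stopifnot(is_clonal_evolution(evo), inherits(window, "therapy_window"))
  tol <- evo$tolerance
  ab <- window_columns(evo, window)
  a <- ab[["a"]]; b <- ab[["b"]]
  if (b != a + 1) {
    stop("time points are already inserted inside the therapy window",
         call. = FALSE)
  }

  labels <- clone_labels(evo)
  old <- evo$ccf[, a] > tol
  uccf <- compute_uccf(evo$ccf, evo$parents)
  u_tp <- pmin(uccf[, a], uccf[, b])
  u_tp[!old] <- 0
  u_tp <- pmax(u_tp, 0) # absorb floating noise in ccf'
  ccf_tp <- accumulate_uccf(cbind(u_tp), evo$parents)[, 1]

  # number of post-therapy insertions determines the default position
  therapy_clones <- labels[ccf_tp > tol]
  new_final <- labels[evo$ccf[, b] > tol & ccf_tp <= tol]
  extra <- window$extra_interpolation
  if (is.null(extra)) extra <- length(new_final) > 0
  k <- if (extra && length(new_final) > 0) {
    max(recalc_levels(evo$parents, new_final, therapy_clones))
  } else 0L

  position <- window$position
  if (is.null(position)) position <- 1 / (k + 2)
  ta <- evo$timepoints[a]; tb <- evo$timepoints[b]
  coord <- ta + (tb - ta) * position

  insert_timepoints(evo, after = a, coords = coord,
                    values = cbind(ccf_tp), kind = "therapy")
}

# nested levels counting only ancestors in `ignored_pool` complement:
# for each clone in `clones`, count ancestors NOT present in therapy_clones
recalc_levels <- function(parents, clones, therapy_clones) {
  vapply(clones, function(c) {
    d <- 0L
    cur <- parents[[c]]
    while (!identical(cur, NORMAL)) {
      if (!(cur %in% therapy_clones)) d <- d + 1L
      cur <- parents[[cur]]
    }
    d
  }, integer(1))
}

#' Recalculated nested levels after therapy
#'
#' For clones absent at the estimated therapy time point, the usual nested
#' level overstates how many developmental steps remain: ancestors that
#' survived therapy are already present. The recalculated level of a clone
#' counts only those ancestors that are themselves absent at the therapy
#' point (i.e. not in `therapy_clones`).
#'
#' @param evo a [clonal_evolution()] object
#' @param therapy_clones labels of the clones with nonzero CCF at the
#'   therapy time point
#' @return named integer vector over the clones absent from `therapy_clones`
#' @export
recalculated_nested_levels <- function(evo, therapy_clones) {
  stopifnot(is_clonal_evolution(evo))
  therapy_clones <- as.character(therapy_clones)
  bad <- setdiff(therapy_clones, clone_labels(evo))
  if (length(bad) > 0) {
    stop("unknown clone label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(clone_labels(evo), therapy_clones)
  recalc_levels(evo$parents, absent, therapy_clones)
}

#' Interpolate the post-therapy re-expansion
#'
#' After [estimate_therapy_effect()], inserts `max(recalculated nested
#' levels)` additional points between the therapy point and the right
#' endpoint of the window. A newly developing clone with recalculated level
#' `z` stays at 0 for the first `z` inserted points; afterwards childless
#' clones grow linearly towards their CCF at the right endpoint, while
#' clones with surviving children hold their unique CCF constant at
#' `ccf'(c, t_{i+1})`. Clones already present at the therapy point develop
#' linearly in unique CCF. CCFs are rebuilt from unique CCFs leaf-to-root.
#'
#' @param evo a [clonal_evolution()] object containing a therapy point
#'   inside the window
#' @param window the [therapy_window()] used for [estimate_therapy_effect()]
#' @return a new `clonal_evolution`; inserted points are tagged
#'   `"interpolated"`; a no-op when no clones newly appear
#' @export
interpolate_post_therapy <- function(evo, window) {
  stopifnot(is_clonal_evolution(evo), inherits(window, "therapy_window"))
  tol <- evo$tolerance
  ab <- window_columns(evo, window)
  a <- ab[["a"]]; b <- ab[["b"]]
  tp <- which(evo$timepoint_kind == "therapy" &
                seq_along(evo$timepoint_kind) > a &
                seq_along(evo$timepoint_kind) < b)
  if (length(tp) != 1) {
    stop("the therapy window does not contain exactly one therapy time point; ",
         "run estimate_therapy_effect() first", call. = FALSE)
  }

  labels <- clone_labels(evo)
  uccf <- compute_uccf(evo$ccf, evo$parents)
  therapy_clones <- labels[evo$ccf[, tp] > tol]
  final <- labels[evo$ccf[, b] > tol]
  new_final <- setdiff(final, therapy_clones)
  if (length(new_final) == 0) return(evo)

  z <- recalc_levels(evo$parents, new_final, therapy_clones)
  K <- max(z)
  if (K == 0) return(evo)

  x_tp <- evo$timepoints[tp]; tb <- evo$timepoints[b]
  coords <- x_tp + (tb - x_tp) * seq_len(K) / (K + 1)

  u_new <- matrix(0, nrow = length(labels), ncol = K,
                  dimnames = list(labels, NULL))
  for (c in therapy_clones) {
    u_new[c, ] <- uccf[c, tp] +
      (uccf[c, b] - uccf[c, tp]) * (coords - x_tp) / (tb - x_tp)
  }
  for (c in new_final) {
    zc <- z[[c]]
    if (zc >= K) next # zero at every inserted point
    j <- (zc + 1):K
    has_children <- any(evo$parents == c & evo$ccf[, b] > tol)
    if (has_children) {
      u_new[c, j] <- uccf[c, b]
    } else {
      xz <- if (zc == 0) x_tp else coords[zc]
      u_new[c, j] <- evo$ccf[c, b] * (coords[j] - xz) / (tb - xz)
    }
  }
  values <- accumulate_uccf(pmax(u_new, 0), evo$parents)
  insert_timepoints(evo, after = tp, coords = coords, values = values,
                    kind = "interpolated")
}

#' Estimate therapy effect and (optionally) the post-therapy re-expansion
#'
#' Convenience wrapper chaining [estimate_therapy_effect()] and, when the
#' window's `extra_interpolation` resolves to `TRUE`,
#' [interpolate_post_therapy()].
#'
#' @inheritParams estimate_therapy_effect
#' @return a new `clonal_evolution`
#' @export
apply_therapy <- function(evo, window) {
  tol <- evo$tolerance
  ab <- window_columns(evo, window)
  new_any <- any(evo$ccf[, ab[["a"]]] <= tol & evo$ccf[, ab[["b"]]] > tol)
  extra <- window$extra_interpolation
  if (is.null(extra)) extra <- new_any
  evo <- estimate_therapy_effect(evo, window)
  if (extra) evo <- interpolate_post_therapy(evo, window)
  evo
}
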