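#' Validity check for a CCF table with parental relations
#'
#' Checks a clones-by-time-points CCF matrix (percent values) against the
#' four logical rules of clonal evolution:
#'
#' * **V1** — a clone's CCF can never be smaller than the summed CCFs of its
#'   children ("children-clones cannot exceed their parents");
#' * **V2** — clones developing from normal cells cannot add up to more than
#'   100% at any time point;
#' * **V3** — a clone cannot reappear: once its CCF has been positive and
#'   then dropped to zero, it must stay zero;
#' * **V4** — the same rule applied to the unique CCF (ccf'): a parent
#'   thoroughly replaced by its children cannot reappear.
#'
#' Structural problems (unresolvable parent references, cycles, shape
#' mismatch) are reported as rule `"S"` violations and preempt the
#' evaluation of V1-V4.
#'
#' By default V3/V4 use the general reading of the reappearance rule
#' (positive, later zero, still later positive, at any distances).
#' `reappearance = "triple"` restricts the scan to consecutive triples of
#' time points, which tolerates patterns such as `5, 0, 0, 5`.
#'
#' @param ccf numeric matrix (clones x time points, percent) or a
#'   `clonal_evolution` object
#' @param parents parent references (ignored when `ccf` is a
#'   `clonal_evolution`)
#' @param tolerance absolute tolerance in percent; "zero" means `<= tolerance`
#' @param reappearance `"general"` (default) or `"triple"`
#' @return an object of class `validity_report`: a list with `passed`
#'   (logical) and `violations` (data frame with columns `rule`, `clone`,
#'   `timepoint`, `message`)
#'
#' @examples
#' check_validity(rbind(A = c(50, 60), B = c(70, 10)), c("normal", "A"))
#' @export
check_validity <- function(ccf, parents = NULL, tolerance = 1e-9,
                           reappearance = c("general", "triple")) {
  reappearance <- match.arg(reappearance)
  if (is_clonal_evolution(ccf)) {
    parents <- ccf$parents
    if (missing(tolerance)) tolerance <- ccf$tolerance
    ccf <- ccf$ccf
  }
  ccf <- coerce_ccf_matrix(ccf)
  labels <- rownames(ccf)
  if (is.null(labels)) labels <- paste0("C", seq_len(nrow(ccf)))
  rownames(ccf) <- labels

  viol <- list()
  add <- function(rule, clone, tp, msg) {
    viol[[length(viol) + 1]] <<- data.frame(
      rule = rule, clone = clone, timepoint = tp, message = msg,
      stringsAsFactors = FALSE)
  }

  # structural checks first
  structural_ok <- TRUE
  if (length(parents) != nrow(ccf)) {
    add("S", NA_character_, NA_integer_,
        sprintf("parents length %d does not match %d clones",
                length(parents), nrow(ccf)))
    structural_ok <- FALSE
  } else {
    p <- as.character(parents)
    p[is.na(p)] <- NORMAL
    p[tolower(trimws(p)) %in% c("normal", "0", "")] <- NORMAL
    names(p) <- labels
    unknown <- setdiff(unique(p), c(NORMAL, labels))
    if (length(unknown) > 0) {
      add("S", NA_character_, NA_integer_,
          paste("unknown parent reference(s):", paste(unknown, collapse = ", ")))
      structural_ok <- FALSE
    } else {
      cyc <- find_cycle(p)
      if (!is.null(cyc)) {
        add("S", cyc[1], NA_integer_,
            paste("cycle in parental relations:",
                  paste(c(cyc, cyc[1]), collapse = " -> ")))
        structural_ok <- FALSE
      }
    }
  }

  if (structural_ok) {
    parents <- p
    m <- ncol(ccf)
    childsum <- ccf * 0
    for (c in labels) {
      ch <- labels[parents == c]
      if (length(ch) > 0) childsum[c, ] <- colSums(ccf[ch, , drop = FALSE])
    }

    # V1: children exceed parent
    bad <- which(ccf + tolerance < childsum, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      for (i in seq_len(nrow(bad))) {
        c <- labels[bad[i, 1]]; t <- bad[i, 2]
        add("V1", c, t,
            sprintf("children of clone %s (sum %.6g%%) exceed its CCF (%.6g%%) at time point %d",
                    c, childsum[c, t], ccf[c, t], t))
      }
    }

    # V2: founders sum > 100
    founders <- labels[parents == NORMAL]
    fsum <- colSums(ccf[founders, , drop = FALSE])
    for (t in which(fsum > 100 + tolerance)) {
      add("V2", NA_character_, t,
          sprintf("clones developing from normal cells sum to %.6g%% (> 100%%) at time point %d",
                  fsum[t], t))
    }

    # V3 / V4: reappearance on ccf and ccf'
    uccf <- compute_uccf(ccf, parents)
    scan <- function(v) {
      pos <- v > tolerance
      if (reappearance == "general") {
        i <- which(pos)[1]
        if (is.na(i) || i >= length(v)) return(NA_integer_)
        j <- i + which(!pos[(i + 1):length(v)])[1]
        if (is.na(j) || j >= length(v)) return(NA_integer_)
        k <- j + which(pos[(j + 1):length(v)])[1]
        if (is.na(k)) NA_integer_ else k
      } else {
        if (length(v) < 3) return(NA_integer_)
        hit <- which(pos[1:(length(v) - 2)] & !pos[2:(length(v) - 1)] &
                       pos[3:length(v)])
        if (length(hit) == 0) NA_integer_ else hit[1] + 2L
      }
    }
    for (c in labels) {
      k <- scan(ccf[c, ])
      if (!is.na(k)) {
        add("V3", c, k,
            sprintf("clone %s reappears at time point %d after dropping to zero", c, k))
      }
      k <- scan(uccf[c, ])
      if (!is.na(k)) {
        add("V4", c, k,
            sprintf("replaced parent clone %s reappears (ccf') at time point %d", c, k))
      }
    }
  }

  violations <- if (length(viol) == 0) {
    data.frame(rule = character(0), clone = character(0),
               timepoint = integer(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, viol)
  }
  structure(list(passed = nrow(violations) == 0, violations = violations),
            class = "validity_report")
}

format_violations <- function(violations) {
  if (nrow(violations) == 0) return(character(0))
  sprintf("  [%s] %s", violations$rule, violations$message)
}

#' @export
print.validity_report <- function(x, ...) {
  if (x$passed) {
    cat("<validity_report> passed\n")
  } else {
    cat("<validity_report>", nrow(x$violations), "violation(s):\n")
    cat(format_violations(x$violations), sep = "\n")
    cat("\n")
  }
  invisible(x)
}

#' Serialize a validity report as JSON lines
#'
#' One JSON object per violation, with fields `rule`, `clone`, `timepoint`
#' and `message`. An empty character vector is returned for a passing report.
#'
#' @param report a `validity_report` from [check_validity()]
#' @return character vector of JSON lines
#' @export
validity_json <- function(report) {
  stopifnot(inherits(report, "validity_report"))
  v <- report$violations
  vapply(seq_len(nrow(v)), function(i) {
    jsonlite::toJSON(as.list(v[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
}
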