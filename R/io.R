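#' Read a CCF table from CSV or TSV
#'
#' Expected dialect: UTF-8, first column `clone`, optional second column
#' `parent`, remaining column headers numeric time coordinates (optionally
#' prefixed `t`, e.g. `t0, t53`), values in CCF percent. A second header row
#' starting with `#kind` (as written by [write_ccf_table()]) tags each time
#' point as measured / interpolated / therapy.
#'
#' @param path file path; tab-separated when the extension is `.tsv`/`.tab`
#'   or the header contains tabs, comma-separated otherwise
#' @return list with `ccf` (numeric matrix, clone row names), `parents`
#'   (canonicalised character vector, or `NULL` when the file has no parent
#'   column), `timepoints` (numeric), `timepoint_labels`, `timepoint_kind`
#' @export
read_ccf_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 2L)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE) ||
             grepl("\t", head_lines[1])) "\t" else ","
  kind <- NULL
  skip_rows <- 0L
  if (length(head_lines) >= 2 && startsWith(head_lines[2], "#kind")) {
    kind_row <- strsplit(head_lines[2], sep, fixed = TRUE)[[1]]
    kind <- kind_row[-1]
    skip_rows <- 1L
  }
  header <- strsplit(head_lines[1], sep, fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = sep, header = FALSE, skip = 1 + skip_rows,
                          col.names = header, colClasses = "character",
                          check.names = FALSE, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  if (tolower(header[1]) != "clone") {
    stop("first column must be named 'clone' (got '", header[1], "')",
         call. = FALSE)
  }
  labels <- df[[1]]
  if (anyDuplicated(labels)) {
    stop("duplicate clone label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  has_parent <- length(header) >= 2 && tolower(header[2]) == "parent"
  parents <- if (has_parent) normalize_parents(df[[2]], labels) else NULL
  tp_cols <- seq.int(if (has_parent) 3 else 2, length(header))
  if (length(tp_cols) < 1) stop("no time point columns found", call. = FALSE)
  coords <- suppressWarnings(as.numeric(sub("^[tT]", "", header[tp_cols])))
  if (anyNA(coords)) {
    stop("time point column headers must be numeric coordinates ",
         "(optionally prefixed 't'): ",
         paste(header[tp_cols][is.na(coords)], collapse = ", "), call. = FALSE)
  }
  if (any(diff(coords) <= 0)) {
    stop("time point columns must be strictly increasing", call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, tp_cols, drop = FALSE])),
           nrow = nrow(df),
           dimnames = list(labels, header[tp_cols])))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing CCF cell for clone ", labels[bad[1]],
         ", column ", header[tp_cols][bad[2]], call. = FALSE)
  }
  if (!is.null(kind)) {
    kind <- kind[tp_cols - 1] # kind row aligns with all non-clone columns
    if (length(kind) != length(tp_cols) ||
        !all(kind %in% c("measured", "interpolated", "therapy"))) {
      stop("malformed #kind header row", call. = FALSE)
    }
  } else {
    kind <- rep("measured", length(tp_cols))
  }
  list(ccf = vals, parents = parents, timepoints = coords,
       timepoint_labels = header[tp_cols], timepoint_kind = kind)
}

#' Write a clonal evolution as a CCF table
#'
#' Deterministic, byte-stable output in the dialect read by
#' [read_ccf_table()]: columns `clone`, `parent`, then one column per time
#' point (headers `t<coordinate>`), values with 6 significant digits, plus a
#' `#kind` second header row tagging each time point.
#'
#' @param evo a [clonal_evolution()] object
#' @param path output file path; `.tsv` selects tab separation
#' @return `path`, invisibly
#' @export
write_ccf_table <- function(evo, path) {
  stopifnot(is_clonal_evolution(evo))
  if (nrow(evo$ccf) == 0 || ncol(evo$ccf) == 0) {
    stop("refusing to write an empty evolution", call. = FALSE)
  }
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tp_headers <- paste0("t", format(evo$timepoints, trim = TRUE, digits = 15,
                                   scientific = FALSE))
  header <- paste(c("clone", "parent", tp_headers), collapse = sep)
  kind_row <- paste(c("#kind", "", evo$timepoint_kind), collapse = sep)
  rows <- vapply(seq_len(nrow(evo$ccf)), function(i) {
    paste(c(clone_labels(evo)[i], evo$parents[i],
            sprintf("%.6g", evo$ccf[i, ])), collapse = sep)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, kind_row, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Build a clonal evolution directly from a CCF table file
#'
#' @param path a CSV/TSV file in the [read_ccf_table()] dialect; it must
#'   contain a `parent` column (use [enumerate_trees()] on the bare matrix
#'   otherwise)
#' @param tolerance absolute CCF tolerance in percent
#' @return a [clonal_evolution()] object
#' @export
read_evolution <- function(path, tolerance = 1e-9) {
  tb <- read_ccf_table(path)
  if (is.null(tb$parents)) {
    stop("the CCF table has no 'parent' column; supply parental relations ",
         "or explore candidate trees with enumerate_trees()", call. = FALSE)
  }
  clonal_evolution(tb$ccf, tb$parents, timepoints = tb$timepoints,
                   timepoint_labels = tb$timepoint_labels,
                   timepoint_kind = tb$timepoint_kind, tolerance = tolerance)
}
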