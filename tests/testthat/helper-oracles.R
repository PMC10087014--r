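# Independent oracles and fixture generators. Deliberately written in a
# different style from the package internals so they can serve as
# independent references.

ORACLE_NORMAL <- "normal"

# direct evaluation of the four written validity rules; returns TRUE/FALSE.
# Assumes `parents` is already a forest of resolvable labels.
oracle_validity <- function(ccf, parents, tol = 1e-9) {
  labels <- rownames(ccf)
  names(parents) <- labels
  m <- ncol(ccf)
  kids <- lapply(labels, function(c) labels[parents == c])
  names(kids) <- labels

  uccf <- ccf
  for (c in labels) {
    for (t in seq_len(m)) {
      uccf[c, t] <- ccf[c, t] - sum(ccf[kids[[c]], t])
    }
  }

  # (i) children cannot exceed their parents
  for (c in labels) {
    for (t in seq_len(m)) {
      if (ccf[c, t] + tol < sum(ccf[kids[[c]], t])) return(FALSE)
    }
  }
  # (ii) founders cannot sum to more than 100%
  founders <- labels[parents == ORACLE_NORMAL]
  for (t in seq_len(m)) {
    if (sum(ccf[founders, t]) > 100 + tol) return(FALSE)
  }
  # (iii)/(iv) no reappearance: no <= tol gap strictly inside the positive
  # support of the trajectory
  has_gap <- function(v) {
    pos <- which(v > tol)
    length(pos) > 0 && any(v[seq(min(pos), max(pos))] <= tol)
  }
  for (c in labels) {
    if (has_gap(ccf[c, ])) return(FALSE)
    if (has_gap(uccf[c, ])) return(FALSE)
  }
  TRUE
}

# forest test by iterative root peeling (independent of the package's
# path-following implementation)
oracle_is_forest <- function(parents) {
  labels <- names(parents)
  known <- ORACLE_NORMAL
  repeat {
    addable <- labels[!(labels %in% known) & parents %in% known]
    if (length(addable) == 0) break
    known <- c(known, addable)
  }
  all(labels %in% known)
}

# exhaustive enumeration of all n^n parent vectors, filtered by forest-ness
# and the validity oracle; returns a sorted character vector of canonical
# tree encodings
oracle_trees <- function(ccf, tol = 1e-9) {
  labels <- rownames(ccf)
  options <- lapply(labels, function(c) c(ORACLE_NORMAL, setdiff(labels, c)))
  grid <- expand.grid(options, stringsAsFactors = FALSE)
  out <- character(0)
  for (i in seq_len(nrow(grid))) {
    p <- setNames(as.character(grid[i, ]), labels)
    if (!oracle_is_forest(p)) next
    if (oracle_validity(ccf, p, tol)) {
      out <- c(out, paste(p, collapse = ","))
    }
  }
  sort(out)
}

tree_key <- function(p) paste(p, collapse = ",")

# a random forest over n clones (possibly several founders)
rand_forest <- function(n) {
  labels <- paste0("K", seq_len(n))
  parents <- setNames(rep(ORACLE_NORMAL, n), labels)
  if (n > 1) {
    for (i in 2:n) {
      cand <- c(ORACLE_NORMAL, labels[seq_len(i - 1)])
      parents[i] <- sample(cand, 1)
    }
  }
  parents
}

# a raw random instance: a forest plus a CCF matrix that is usually invalid
# (uniform noise) but sometimes valid (scaled-down nested construction)
rand_raw_instance <- function(n, m) {
  parents <- rand_forest(n)
  labels <- names(parents)
  if (stats::runif(1) < 0.5) {
    ccf <- matrix(stats::runif(n * m, 0, 80), n, m,
                  dimnames = list(labels, NULL))
    ccf[stats::runif(n * m) < 0.3] <- 0
  } else {
    # nested construction, then occasional corruption
    uccf <- matrix(stats::runif(n * m, 0, 100 / n), n, m,
                   dimnames = list(labels, NULL))
    uccf[stats::runif(n * m) < 0.25] <- 0
    ccf <- uccf
    depth_order <- names(sort(vapply(labels, function(c) {
      d <- 0; cur <- parents[[c]]
      while (!identical(cur, ORACLE_NORMAL)) { d <- d + 1; cur <- parents[[cur]] }
      d
    }, numeric(1)), decreasing = TRUE))
    for (c in depth_order) {
      ch <- labels[parents == c]
      if (length(ch) > 0) ccf[c, ] <- uccf[c, ] + colSums(ccf[ch, , drop = FALSE])
    }
    if (stats::runif(1) < 0.5) {
      ccf[sample(n, 1), sample(m, 1)] <- stats::runif(1, 0, 100)
    }
  }
  list(ccf = ccf, parents = parents)
}

# random valid evolution via the package generator (varied shape)
rand_valid_evo <- function(seed, n_max = 7, m_max = 6) {
  set.seed(seed)
  n <- sample(seq_len(n_max), 1)
  m <- sample(seq_len(m_max), 1)
  model <- sample(c("mixed", "linear", "branched_dependent"), 1)
  simulate_evolution(simulation_spec(n, m, model, seed = seed))
}

expect_valid <- function(evo) {
  rep_ <- check_validity(evo)
  expect_true(rep_$passed,
              info = paste(rep_$violations$message, collapse = "; "))
}
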