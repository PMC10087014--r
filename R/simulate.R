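#' Specification for a simulated clonal evolution
#'
#' The generator emulates the structure of typical patient datasets: a
#' phylogenetic forest of one of the classical evolution models with
#' unique-CCF trajectories drawn as positive random walks (reflected above a
#' small floor), optional absorbing extinction, and per-time-point rescaling
#' so that founding clones never exceed 100%. Outputs are valid by
#' construction.
#'
#' @param n_clones number of clones (>= 1)
#' @param n_timepoints number of measured time points (>= 1)
#' @param model `"linear"` (single chain), `"branched_dependent"` (one
#'   founder, branching tree), `"branched_independent"` (>= 2 founders) or
#'   `"mixed"`
#' @param seed integer seed; identical specs yield identical evolutions
#' @param max_founders cap on clones developing from normal cells (<= 25 so
#'   the output stays colorable)
#' @param extinction_prob probability that a clone (whose subtree allows it)
#'   goes extinct before the last time point
#' @return a list of class `simulation_spec`
#' @export
simulation_spec <- function(n_clones, n_timepoints,
                            model = c("mixed", "linear", "branched_dependent",
                                      "branched_independent"),
                            seed = 1L, max_founders = 25,
                            extinction_prob = 0.1) {
  model <- match.arg(model)
  n_clones <- as.integer(n_clones)
  n_timepoints <- as.integer(n_timepoints)
  if (is.na(n_clones) || n_clones < 1) stop("`n_clones` must be >= 1", call. = FALSE)
  if (is.na(n_timepoints) || n_timepoints < 1) {
    stop("`n_timepoints` must be >= 1", call. = FALSE)
  }
  if (max_founders < 1 || max_founders > 25) {
    stop("`max_founders` must be in 1..25", call. = FALSE)
  }
  if (model == "branched_independent" && n_clones < 2) {
    stop("branched independent evolution requires at least 2 clones", call. = FALSE)
  }
  structure(list(n_clones = n_clones, n_timepoints = n_timepoints,
                 model = model, seed = as.integer(seed),
                 max_founders = as.integer(max_founders),
                 extinction_prob = extinction_prob),
            class = "simulation_spec")
}

# size-safe single draw (sample(x, 1) on a scalar would draw from 1:x)
sample_one <- function(x) x[sample.int(length(x), 1)]

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a valid clonal evolution
#'
#' @param spec a [simulation_spec()]
#' @return a [clonal_evolution()] object with `n_clones` clones and
#'   `n_timepoints` measured time points at unit coordinates `0..m-1`
#'
#' @examples
#' evo <- simulate_evolution(simulation_spec(5, 4, "branched_dependent",
#'                                           seed = 7))
#' check_validity(evo)$passed
#' @export
simulate_evolution <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, simulate_evolution_impl(spec))
}

simulate_evolution_impl <- function(spec) {
  n <- spec$n_clones
  m <- spec$n_timepoints
  labels <- paste0("C", seq_len(n))

  # phylogenetic forest per model
  parents <- setNames(rep(NORMAL, n), labels)
  if (n > 1) {
    if (spec$model == "linear") {
      parents[2:n] <- labels[1:(n - 1)]
    } else if (spec$model == "branched_dependent") {
      for (i in 2:n) parents[i] <- labels[sample.int(i - 1, 1)]
    } else {
      k <- if (spec$model == "branched_independent") {
        sample_one(seq.int(2, min(n, spec$max_founders)))
      } else {
        sample_one(seq_len(min(n, spec$max_founders)))
      }
      if (k < n) {
        for (i in (k + 1):n) parents[i] <- labels[sample.int(i - 1, 1)]
      }
    }
  }

  # birth columns: children appear at or after their parent, never later
  # than the last time point
  lev <- compute_levels(parents)
  birth <- setNames(integer(n), labels)
  first_founder <- labels[parents == NORMAL][1]
  for (c in labels[order(lev)]) {
    p <- parents[[c]]
    if (identical(p, NORMAL)) {
      # the first founder anchors the tumor at t_1
      birth[[c]] <- if (c == first_founder) 1L else sample.int(min(m, 2L), 1)
    } else {
      birth[[c]] <- min(m, birth[[p]] + sample(0:2, 1, prob = c(0.3, 0.5, 0.2)))
    }
  }

  # extinction: only after every child is born (so nobody is born to a
  # clone that already died), absorbing once it happens
  extinct_at <- setNames(rep(NA_integer_, n), labels)
  for (c in labels) {
    ch <- labels[parents == c]
    last_birth <- max(c(birth[[c]], birth[ch]))
    if (last_birth + 1 <= m && stats::runif(1) < spec$extinction_prob) {
      extinct_at[[c]] <- sample_one(seq.int(last_birth + 1, m))
    }
  }

  # unique-CCF trajectories: positive random walk while alive
  uccf <- matrix(0, nrow = n, ncol = m, dimnames = list(labels, NULL))
  for (c in labels) {
    to <- if (is.na(extinct_at[[c]])) m else extinct_at[[c]] - 1L
    cols <- seq.int(birth[[c]], to)
    v <- numeric(length(cols))
    v[1] <- stats::runif(1, 5, 40)
    if (length(cols) > 1) {
      for (j in 2:length(cols)) {
        v[j] <- max(0.5, v[j - 1] + stats::rnorm(1, sd = 8))
      }
    }
    uccf[c, cols] <- v
  }

  ccf <- accumulate_uccf(uccf, parents)
  founders <- labels[parents == NORMAL]
  fsum <- colSums(ccf[founders, , drop = FALSE])
  over <- fsum > 99
  if (any(over)) {
    ccf[, over] <- sweep(ccf[, over, drop = FALSE], 2, 99 / fsum[over], "*")
  }

  clonal_evolution(ccf, parents, timepoints = seq_len(m) - 1, labels = labels,
                   timepoint_labels = paste0("t", seq_len(m) - 1))
}
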