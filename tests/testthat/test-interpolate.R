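test_that("initial interpolation walks nested levels backwards from t_1", {
  evo <- clonal_evolution(rbind(A = 80, B = 30), c("normal", "A"),
                          timepoints = 10)
  out <- interpolate_initial(evo)
  expect_equal(ncol(out$ccf), 2)
  expect_equal(out$timepoint_kind, c("interpolated", "measured"))
  expect_equal(out$ccf["A", 1], 50, ignore_attr = TRUE) # = ccf'(A, t1)
  expect_equal(out$ccf["B", 1], 0, ignore_attr = TRUE)
  expect_true(check_validity(out)$passed)

  # all founders: nothing to interpolate
  evo2 <- clonal_evolution(rbind(A = c(40, 50), B = c(30, 20)),
                           c("normal", "normal"))
  expect_identical(interpolate_initial(evo2)$ccf, evo2$ccf)

  # linear chain present at t1: two insertions, emptied top-down
  evo3 <- clonal_evolution(rbind(A = 90, B = 60, C = 20),
                           c("normal", "A", "B"), timepoints = 5)
  out3 <- interpolate_initial(evo3)
  expect_equal(ncol(out3$ccf), 3)
  # nearest to t1: C gone, A and B rebuilt from their unique CCFs
  expect_equal(unname(out3$ccf[, 2]), c(30 + 40, 40, 0)) # A'=30, B'=40
  # earliest: only the founder remains
  expect_equal(unname(out3$ccf[, 1]), c(30, 0, 0))
})

test_that("initial insertions extend the axis by the smallest measured gap", {
  evo <- clonal_evolution(rbind(A = c(80, 80, 80), B = c(30, 40, 50)),
                          c("normal", "A"), timepoints = c(10, 30, 40))
  out <- interpolate_initial(evo)
  expect_equal(out$timepoints[1], 10 - 10) # min gap = 10
})

test_that("between-interpolation inserts (unique new levels - 1) points", {
  # old clone moves linearly through the midpoint
  evo <- clonal_evolution(
    rbind(A = c(40, 60), B = c(20, 20), C = c(0, 8)),
    c("normal", "A", "B"), timepoints = c(0, 10))
  out <- interpolate_between(evo, 1)
  # new clone C is the only new level: no insertion needed... but C is new
  # with one unique level -> zero points
  expect_identical(out$ccf, evo$ccf)

  # two new nested levels: one midpoint; lower level linear, higher at 0
  evo2 <- clonal_evolution(
    rbind(A = c(50, 90), B = c(0, 20), C = c(0, 8)),
    c("normal", "A", "B"), timepoints = c(0, 10))
  out2 <- interpolate_between(evo2, 1)
  expect_equal(ncol(out2$ccf), 3)
  expect_equal(out2$timepoints[2], 5)
  expect_equal(out2$timepoint_kind[2], "interpolated")
  expect_equal(out2$ccf["A", 2], 70, ignore_attr = TRUE) # old: linear
  expect_equal(out2$ccf["B", 2], 10, ignore_attr = TRUE) # new level 1: linear
  expect_equal(out2$ccf["C", 2], 0, ignore_attr = TRUE)  # new level 2: delayed
  expect_true(check_validity(out2)$passed)

  # explicit skewed positions
  out3 <- interpolate_between(evo2, 1, positions = 0.2)
  expect_equal(out3$timepoints[2], 2)
  expect_equal(out3$ccf["A", 2], 58, ignore_attr = TRUE)
})

test_that("interpolate_all composes initial and between insertions", {
  evo <- clonal_evolution(rbind(A = 80, B = 30), c("normal", "A"),
                          timepoints = 7)
  out <- interpolate_all(evo)
  expect_equal(out$timepoint_kind, c("interpolated", "measured"))

  evo2 <- clonal_evolution(rbind(A = c(40, 50), B = c(30, 20)),
                           c("normal", "normal"))
  expect_identical(interpolate_all(evo2)$ccf, evo2$ccf)
})

test_that("interpolation preserves measured columns, linearity and validity", {
  for (seed in 1:60) {
    evo <- rand_valid_evo(seed + 3000)
    out <- interpolate_all(evo)
    expect_true(check_validity(out)$passed, label = paste("seed", seed))

    measured <- which(out$timepoint_kind == "measured")
    expect_equal(out$ccf[, measured, drop = FALSE], evo$ccf,
                 ignore_attr = TRUE)
    expect_equal(out$timepoints[measured], evo$timepoints)

    # insertion-count formulas
    lev <- nested_levels(evo)
    init <- clone_labels(evo)[evo$ccf[, 1] > evo$tolerance]
    n_initial <- if (length(init)) max(lev[init]) else 0
    expect_equal(sum(out$timepoints < evo$timepoints[1]), n_initial)
    m <- ncol(evo$ccf)
    if (m >= 2) {
      for (i in seq_len(m - 1)) {
        inside <- out$timepoints > evo$timepoints[i] &
          out$timepoints < evo$timepoints[i + 1]
        old <- evo$ccf[, i] > evo$tolerance
        newc <- !old & evo$ccf[, i + 1] > evo$tolerance
        expected <- max(0, length(unique(lev[newc])) - 1)
        expect_equal(sum(inside), expected,
                     label = paste("seed", seed, "interval", i))

        # old clones are exactly linear at the inserted points
        for (c in clone_labels(evo)[old]) {
          frac <- (out$timepoints[inside] - evo$timepoints[i]) /
            (evo$timepoints[i + 1] - evo$timepoints[i])
          lin <- evo$ccf[c, i] + (evo$ccf[c, i + 1] - evo$ccf[c, i]) * frac
          expect_equal(unname(out$ccf[c, inside]), unname(lin),
                       tolerance = 1e-9)
        }
      }
    }
  }
})
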