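test_that("the therapy point takes the minimum unique CCF of the flanks", {
  # ccf'(A): 50 -> 10, ccf'(B): 20 -> 60
  evo <- clonal_evolution(rbind(A = c(70, 70), B = c(20, 60)),
                          c("normal", "A"), timepoints = c(0, 100))
  out <- estimate_therapy_effect(evo, therapy_window(1))
  expect_equal(out$timepoint_kind, c("measured", "therapy", "measured"))
  u <- unique_ccf(out)
  expect_equal(u["A", 2], 10, ignore_attr = TRUE)
  expect_equal(u["B", 2], 20, ignore_attr = TRUE)
  expect_equal(out$ccf["B", 2], 20, ignore_attr = TRUE)
  expect_equal(out$ccf["A", 2], 30, ignore_attr = TRUE)
  # no new clones: the single point defaults to the interval midpoint
  expect_equal(out$timepoints[2], 50)

  # identical ccf' at both ends stays unchanged
  evo2 <- clonal_evolution(rbind(A = c(40, 40)), "normal")
  out2 <- estimate_therapy_effect(evo2, therapy_window(1))
  expect_equal(out2$ccf["A", 2], 40, ignore_attr = TRUE)

  # clones appearing only at t_{i+1} are zero at the therapy point
  evo3 <- clonal_evolution(rbind(A = c(50, 60), B = c(0, 30)),
                           c("normal", "A"))
  out3 <- estimate_therapy_effect(evo3, therapy_window(1))
  expect_equal(out3$ccf["B", 2], 0, ignore_attr = TRUE)
})

test_that("therapy windows are validated", {
  evo <- clonal_evolution(rbind(A = c(50, 60)), "normal")
  expect_error(estimate_therapy_effect(evo, therapy_window(2)),
               "measured")
  expect_error(therapy_window(1, position = 1.2), "fraction")
  expect_error(therapy_window(0), "positive")
})

test_that("recalculated nested levels ignore clones surviving therapy", {
  # linear normal -> A -> B -> C plus independent founder D; C and D new
  evo <- clonal_evolution(
    rbind(A = c(60, 70), B = c(30, 50), C = c(0, 20), D = c(0, 10)),
    c("normal", "A", "B", "normal"))
  expect_equal(nested_level(evo, "C"), 2)
  expect_equal(nested_level(evo, "D"), 0)
  rl <- recalculated_nested_levels(evo, therapy_clones = c("A", "B"))
  expect_equal(rl[["C"]], 0)
  expect_equal(rl[["D"]], 0)

  # chain C -> E both new: one developmental step apart
  evo2 <- clonal_evolution(
    rbind(A = c(60, 70), B = c(30, 50), C = c(0, 20), E = c(0, 5)),
    c("normal", "A", "B", "C"))
  rl2 <- recalculated_nested_levels(evo2, therapy_clones = c("A", "B"))
  expect_equal(rl2[["C"]], 0)
  expect_equal(rl2[["E"]], 1)

  expect_error(recalculated_nested_levels(evo, "Z"), "unknown")
})

test_that("post-therapy interpolation schedules new clones by recalculated level", {
  # a new childless founder B (recalculated level 0) re-expands linearly;
  # its new child C (recalculated level 1) forces one extra inserted point
  evo <- clonal_evolution(rbind(A = c(50, 40), B = c(0, 30), C = c(0, 20)),
                          c("normal", "normal", "B"), timepoints = c(0, 30))
  out <- apply_therapy(evo, therapy_window(1))
  # therapy point + one interpolated point divide the window evenly
  expect_equal(out$timepoints, c(0, 10, 20, 30))
  expect_equal(out$timepoint_kind,
               c("measured", "therapy", "interpolated", "measured"))
  expect_equal(out$ccf["B", 2], 0, ignore_attr = TRUE)
  expect_equal(out$ccf["C", 3], 0, ignore_attr = TRUE) # level-1 delay
  # B has a child at t_b, so it holds ccf' = ccf'(B, t_b) = 10 while C is
  # still absent: ccf(B) at the inserted point is 10
  expect_equal(out$ccf["B", 3], 10, ignore_attr = TRUE)
  expect_true(check_validity(out)$passed)

  # a truly childless new founder re-expands linearly through the midpoint
  evo1b <- clonal_evolution(
    rbind(A = c(50, 40), B = c(0, 30), D = c(0, 20), E = c(0, 10)),
    c("normal", "normal", "A", "D"), timepoints = c(0, 30))
  out1b <- apply_therapy(evo1b, therapy_window(1))
  expect_equal(out1b$timepoints, c(0, 10, 20, 30))
  expect_equal(out1b$ccf["B", 3], 15, ignore_attr = TRUE) # linear midpoint
  expect_true(check_validity(out1b)$passed)

  # new chain C -> E: C keeps ccf'(C, t_{i+1}) while active (has a child)
  evo2 <- clonal_evolution(
    rbind(A = c(60, 70), B = c(30, 50), C = c(0, 20), E = c(0, 5)),
    c("normal", "A", "B", "C"), timepoints = c(0, 30))
  out2 <- apply_therapy(evo2, therapy_window(1))
  # max recalculated level 1: therapy point + 1 insertion -> spacing 10
  expect_equal(out2$timepoints, c(0, 10, 20, 30))
  u2 <- unique_ccf(out2)
  expect_equal(u2["C", 3], u2["C", 4], ignore_attr = TRUE) # held at ccf'(t_b)
  expect_equal(out2$ccf["E", 3], 0, ignore_attr = TRUE)    # level-1 delay
  expect_true(check_validity(out2)$passed)

  # no new clones: extra interpolation is a no-op
  evo3 <- clonal_evolution(rbind(A = c(50, 40)), "normal")
  out3 <- estimate_therapy_effect(evo3, therapy_window(1))
  expect_identical(interpolate_post_therapy(out3, therapy_window(1))$ccf,
                   out3$ccf)
})

test_that("therapy estimation satisfies its invariants on random instances", {
  for (seed in 1:50) {
    evo <- rand_valid_evo(seed + 7000)
    if (ncol(evo$ccf) < 2) next
    i <- sample(ncol(evo$ccf) - 1, 1)
    window <- therapy_window(i)
    out <- apply_therapy(evo, window)
    expect_true(check_validity(out)$passed, label = paste("seed", seed))

    measured <- which(out$timepoint_kind == "measured")
    expect_equal(out$ccf[, measured, drop = FALSE], evo$ccf,
                 ignore_attr = TRUE)

    tp <- which(out$timepoint_kind == "therapy")
    expect_length(tp, 1)
    u_out <- unique_ccf(out)
    u_in <- unique_ccf(evo)
    old <- evo$ccf[, i] > evo$tolerance
    for (c in clone_labels(evo)[old]) {
      expect_lte(u_out[c, tp], min(u_in[c, i], u_in[c, i + 1]) + 1e-9)
    }
    founders <- children_of(evo, NORMAL)
    burden <- sum(out$ccf[founders, tp])
    expect_lte(burden, sum(evo$ccf[founders, i]) + 1e-9)
    expect_lte(burden, sum(evo$ccf[founders, i + 1]) + 1e-9)

    # recalculated levels never exceed nested levels; equal when no
    # ancestor survives
    therapy_clones <- clone_labels(out)[out$ccf[, tp] > out$tolerance]
    rl <- recalculated_nested_levels(evo, intersect(therapy_clones,
                                                    clone_labels(evo)))
    lev <- nested_levels(evo)
    for (c in names(rl)) {
      expect_lte(rl[[c]], lev[[c]])
      anc <- character(0)
      cur <- evo$parents[[c]]
      while (!identical(cur, NORMAL)) { anc <- c(anc, cur); cur <- evo$parents[[cur]] }
      if (!any(anc %in% therapy_clones)) expect_equal(rl[[c]], lev[[c]])
    }
  }
})
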