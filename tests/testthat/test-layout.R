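band_thickness <- function(layout, clone, x) {
  b <- layout$bands[[clone]]
  i <- which(abs(b$x - x) < 1e-9)
  if (length(i) == 0) return(0)
  b$upper[i] - b$lower[i]
}

test_that("a single full clone occupies the whole height", {
  evo <- clonal_evolution(rbind(A = c(100, 100)), "normal")
  lay <- dolphin_layout(evo)
  expect_equal(band_thickness(lay, "A", 0), 100)
  expect_equal(band_thickness(lay, "A", 1), 100)
})

test_that("bands are born birth_offset after the preceding time point", {
  evo <- clonal_evolution(rbind(A = c(50, 50), B = c(0, 30)),
                          c("normal", "A"), timepoints = c(0, 1))
  lay <- dolphin_layout(evo)
  b <- lay$bands$B
  expect_equal(b$x[1] - lay$timepoint_x[1], 0.1)
  expect_equal(b$upper[1] - b$lower[1], 0) # zero thickness at birth
  # configurable, and clamped to half of narrow intervals
  lay2 <- dolphin_layout(evo, config = layout_config(birth_offset = 0.25))
  expect_equal(lay2$bands$B$x[1], 0.25)
})

test_that("centered mode splits the parent's unique CCF into equal gaps", {
  evo <- clonal_evolution(rbind(A = 80, B = 20, C = 20),
                          c("normal", "A", "A"), timepoints = 0)
  lay <- dolphin_layout(evo)
  a <- lay$bands$A; b <- lay$bands$B; c <- lay$bands$C
  gap <- (80 - 40) / 3
  expect_equal(a$lower, 50 - 40)
  expect_equal(b$lower, a$lower + gap)
  expect_equal(c$lower, b$upper + gap)
  expect_equal(a$upper - c$upper, gap)
})

test_that("bottom mode lays the deepest branch on the axis", {
  evo <- clonal_evolution(
    rbind(A = c(30, 30), B = c(60, 60), C = c(20, 40)),
    c("normal", "normal", "B"))
  lay <- dolphin_layout(evo, config = layout_config(vertical_mode = "bottom"))
  # B's branch is deeper, so B rests on y = 0 and C hugs B's lower edge
  expect_equal(lay$bands$B$lower, c(0, 0))
  expect_equal(lay$bands$C$lower, c(0, 0))
  expect_equal(lay$bands$A$lower, c(60, 60))
})

test_that("thickness at measured x equals the CCF; children nest in parents", {
  for (seed in 101:130) {
    evo <- rand_valid_evo(seed)
    for (mode in c("centered", "bottom")) {
      lay <- dolphin_layout(evo,
                            config = layout_config(vertical_mode = mode))
      for (c in clone_labels(evo)) {
        b <- lay$bands[[c]]
        if (nrow(b) == 0) next
        expect_true(all(b$upper - b$lower >= -1e-9))
        for (t in seq_along(lay$timepoint_x)) {
          x <- lay$timepoint_x[t]
          if (x >= b$x[1] - 1e-12) {
            expect_equal(band_thickness(lay, c, x), evo$ccf[c, t],
                         tolerance = 1e-6,
                         label = paste("seed", seed, mode, c, "tp", t))
          }
        }
        p <- evo$parents[[c]]
        if (!identical(p, NORMAL)) {
          bp <- lay$bands[[p]]
          for (i in seq_len(nrow(b))) {
            j <- which(abs(bp$x - b$x[i]) < 1e-9)
            expect_true(length(j) == 1 &&
                          b$lower[i] >= bp$lower[j] - 1e-9 &&
                          b$upper[i] <= bp$upper[j] + 1e-9,
                        label = paste("seed", seed, mode, c, "in", p))
          }
        }
      }
      # founders never exceed the plot height in total
      founders <- children_of(evo, NORMAL)
      grid <- sort(unique(unlist(lapply(lay$bands, function(b) b$x))))
      for (x in grid) {
        tot <- sum(vapply(founders, band_thickness, numeric(1),
                          layout = lay, x = x))
        expect_lte(tot, 100 + 1e-6)
      }
    }
  }
})

test_that("shark layout is a layered tree with CCF-scaled bubbles", {
  evo <- clonal_evolution(rbind(A = c(90, 90), B = c(50, 60), C = c(20, 30)),
                          c("normal", "A", "B"))
  lay <- shark_layout(evo)
  expect_equal(nrow(lay$edges), 2)
  expect_equal(lay$nodes$x, c(0, 1, 2))
  expect_length(unique(lay$nodes$y), 1) # collinear chain

  # two founders: disconnected components, no shared root
  evo2 <- clonal_evolution(rbind(A = c(40, 40), B = c(30, 30)),
                           c("normal", "normal"))
  lay2 <- shark_layout(evo2)
  expect_equal(nrow(lay2$edges), 0)
  expect_equal(lay2$nodes$x, c(0, 0))
  expect_false(lay2$nodes$y[1] == lay2$nodes$y[2])

  # radius 0 iff CCF 0; strictly increasing in CCF
  evo3 <- clonal_evolution(rbind(A = c(50, 60), B = c(0, 30)),
                           c("normal", "A"))
  lay3 <- shark_layout(evo3)
  expect_equal(lay3$radii["B", 1], 0, ignore_attr = TRUE)
  expect_gt(lay3$radii["B", 2], 0)
  expect_gt(lay3$radii["A", 2], lay3$radii["A", 1])

  # x strictly increases along every edge
  for (seed in 141:145) {
    evo4 <- rand_valid_evo(seed)
    lay4 <- shark_layout(evo4)
    for (i in seq_len(nrow(lay4$edges))) {
      xa <- lay4$nodes$x[match(lay4$edges$from[i], lay4$nodes$clone)]
      xb <- lay4$nodes$x[match(lay4$edges$to[i], lay4$nodes$clone)]
      expect_gt(xb, xa)
    }
  }
})

test_that("plaice lower half mirrors the upper and resolves annotations", {
  evo <- clonal_evolution(rbind(A = c(60, 70), B = c(20, 50)),
                          c("normal", "A"))
  pl <- plaice_layout(evo, annotations = c(B = "A"))
  expect_equal(pl$upper$vertical_mode, "bottom")
  for (c in clone_labels(evo)) {
    up <- pl$upper$bands[[c]]
    lo <- pl$lower[[c]]
    expect_equal(lo$x, up$x)
    expect_equal(lo$lower, -up$upper)
    expect_equal(lo$upper, -up$lower)
  }
  expect_identical(pl$lower_fill[["B"]], "A")
  expect_true(is.na(pl$lower_fill[["A"]]))

  # no annotations: nothing filled below the axis
  pl0 <- plaice_layout(evo)
  expect_true(all(is.na(pl0$lower_fill)))
  expect_error(plaice_layout(evo, annotations = c(Z = "A")), "unknown")
})

test_that("all-zero clones get colors but no geometry", {
  evo <- clonal_evolution(rbind(A = c(50, 60), Z = c(0, 0)),
                          c("normal", "A"))
  lay <- dolphin_layout(evo)
  expect_equal(nrow(lay$bands$Z), 0)
  expect_true("Z" %in% lay$colors$clone)
})
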