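test_that("construction validates structure and values", {
  evo <- clonal_evolution(matrix(c(100, 100), 1, 2,
                                 dimnames = list("A", NULL)), "normal")
  expect_s3_class(evo, "clonal_evolution")
  expect_equal(dim(evo$ccf), c(1, 2))
  expect_true(check_validity(evo)$passed)

  # child exceeds parent at t1
  expect_error(
    clonal_evolution(rbind(A = c(50, 60), B = c(70, 10)), c("normal", "A")),
    "V1")
  # two-cycle
  expect_error(
    clonal_evolution(rbind(A = c(50, 50), B = c(40, 40)), c("B", "A")),
    "cycle")
  # fraction-scale hint
  expect_error(
    clonal_evolution(rbind(A = c(0.5, 0.6)), "normal"),
    "fraction")
  # missing cells are an error, not implicit zeros
  expect_error(
    clonal_evolution(rbind(A = c(50, NA)), "normal"),
    "missing")
  expect_error(
    clonal_evolution(rbind(A = c(50, 50), Normal = c(10, 10)),
                     c("normal", "normal")),
    "reserved")
  expect_error(
    clonal_evolution(rbind(A = c(50, 50)), "normal", timepoints = c(3, 2)),
    "increasing")
  expect_error(
    clonal_evolution(rbind(A = c(50, 50), B = c(10, 10)), c("normal", "X")),
    "unknown parent")
})

test_that("parent encodings 0 / normal / NA are canonicalised", {
  for (p in list(c("normal", "A"), c("0", "A"), c(0, "A"), c(NA, "A"))) {
    evo <- clonal_evolution(rbind(A = c(80, 90), B = c(30, 60)), p)
    expect_identical(unname(evo$parents), c(NORMAL, "A"))
  }
})

test_that("children_of returns exact children sets", {
  evo <- clonal_evolution(
    rbind(A = c(90, 90), B = c(50, 60), C = c(20, 30), D = c(5, 10)),
    c("normal", "A", "A", "C"))
  expect_setequal(children_of(evo, "A"), c("B", "C"))
  expect_setequal(children_of(evo, "C"), "D")
  expect_length(children_of(evo, "D"), 0)
  expect_setequal(children_of(evo, NORMAL), "A")
  expect_error(children_of(evo, "Z"), "unknown")
})

test_that("nested levels follow the parent chain", {
  evo <- clonal_evolution(
    rbind(A = c(90, 90), B = c(50, 60), C = c(20, 30), D = c(10, 10)),
    c("normal", "A", "B", "normal"))
  expect_equal(nested_level(evo, "D"), 0) # founder
  expect_equal(nested_level(evo, "C"), 2) # linear normal -> A -> B -> C
  expect_equal(nested_level(evo, "B"), 1) # child of a founder
  expect_error(nested_level(evo, "Z"), "unknown")

  lev <- nested_levels(evo)
  founders <- children_of(evo, NORMAL)
  expect_setequal(names(lev)[lev == 0], founders)
  for (c in setdiff(clone_labels(evo), founders)) {
    expect_equal(lev[[c]], lev[[evo$parents[[c]]]] + 1)
  }
})

test_that("unique_ccf subtracts children; leaves keep their row", {
  evo <- clonal_evolution(rbind(A = 80, B = 30), c("normal", "A"),
                          timepoints = 0)
  u <- unique_ccf(evo)
  expect_equal(u["A", ], 50, ignore_attr = TRUE)
  expect_equal(u["B", ], 30, ignore_attr = TRUE)
  expect_equal(u["B", ], evo$ccf["B", ]) # leaf
})

test_that("ccf_from_unique inverts unique_ccf", {
  u <- rbind(A = 50, B = 30)
  ccf <- ccf_from_unique(u, c("normal", "A"))
  expect_equal(ccf, rbind(A = 80, B = 30))
  expect_equal(ccf_from_unique(rbind(A = 0, B = 0), c("normal", "A")),
               rbind(A = 0, B = 0))
  expect_error(ccf_from_unique(rbind(A = -5, B = 3), c("normal", "A")),
               "negative")
})

test_that("round trip ccf_from_unique(unique_ccf(x)) is the identity", {
  for (seed in 1:100) {
    evo <- rand_valid_evo(seed)
    u <- unique_ccf(evo)
    back <- ccf_from_unique(u, evo$parents, tolerance = evo$tolerance)
    expect_equal(back, evo$ccf, tolerance = 1e-9)
    # defining identity re-evaluated directly
    for (c in clone_labels(evo)) {
      ch <- children_of(evo, c)
      rhs <- u[c, ] + if (length(ch)) colSums(evo$ccf[ch, , drop = FALSE]) else 0
      expect_equal(unname(evo$ccf[c, ]), unname(rhs), tolerance = 1e-9)
    }
  }
})

test_that("build_evolution accepts an input iff check_validity passes", {
  set.seed(202)
  for (i in 1:60) {
    inst <- rand_raw_instance(sample(1:5, 1), sample(2:6, 1))
    ok <- check_validity(inst$ccf, inst$parents)$passed
    built <- tryCatch(
      clonal_evolution(inst$ccf, inst$parents),
      error = function(e) e)
    if (ok) {
      expect_s3_class(built, "clonal_evolution")
    } else {
      expect_s3_class(built, "error")
    }
  }
})
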