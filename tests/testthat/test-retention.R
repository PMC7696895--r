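test_that("retention index interpolation is exact at anchors and between them", {
  lad <- default_alkane_ladder()
  # every anchor maps to 100 * carbon number
  expect_equal(as.numeric(compute_ri(lad$rt, lad)), 100 * lad$carbon)

  lad2 <- alkane_ladder(c(10, 12), c(300, 420))
  expect_equal(as.numeric(compute_ri(360, lad2)), 1100)

  # multi-carbon gap: C22@1100 s, C28@1400 s, rt 1250 s
  lad3 <- alkane_ladder(c(22, 28), c(1100, 1400))
  # hand computation: 100 * (22 + 6 * (1250-1100)/(1400-1100)) = 2500
  expect_equal(as.numeric(compute_ri(1250, lad3)), 2500)

  expect_error(compute_ri(NaN, lad), "finite")
})

test_that("extrapolation beyond the terminal anchors is linear and flagged", {
  lad <- alkane_ladder(c(10, 12), c(300, 420))
  ri <- compute_ri(c(240, 360, 480), lad)
  expect_equal(as.numeric(ri), c(900, 1100, 1300))
  expect_identical(attr(ri, "extrapolated"), c(TRUE, FALSE, TRUE))
})

test_that("rt_for_ri inverts compute_ri to 1e-9 relative and RI is monotone", {
  lad <- default_alkane_ladder()
  set.seed(21)
  x <- runif(200, 1000, 3600)
  back <- as.numeric(compute_ri(rt_for_ri(x, lad), lad))
  expect_equal(back, x, tolerance = 1e-9)
  expect_equal(rt_for_ri(1000, lad), lad$rt[1])

  rts <- sort(runif(500, min(lad$rt) - 100, max(lad$rt) + 100))
  ris <- as.numeric(compute_ri(rts, lad))
  expect_false(is.unsorted(ris))

  # the full marker set handles every gap width without special cases
  expect_equal(as.numeric(compute_ri(rt_for_ri(c(1050, 1350, 1600, 1800,
                                                 2050, 2500, 3000, 3400),
                                               lad), lad)),
               c(1050, 1350, 1600, 1800, 2050, 2500, 3000, 3400),
               tolerance = 1e-9)
})

test_that("shift reports count deltas and elution-order inversions", {
  a <- c(x = 100, y = 200, z = 300)
  r <- shift_report(a, a)
  expect_equal(r$per_compound$delta, c(0, 0, 0))
  expect_equal(nrow(r$inversions), 0)
  expect_equal(unname(r$summary["mean"]), 0)

  # two compounds with swapped order -> exactly one inversion
  b <- c(x = 210, y = 190, z = 320)
  r2 <- shift_report(a, b)
  expect_equal(nrow(r2$inversions), 1)

  expect_error(shift_report(c(p = 1), c(q = 2)), "no shared")
})

test_that("inversion counts agree with the O(n^2) oracle on noisy orderings", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(c(10, 50, 120), 1)
    a <- stats::setNames(runif(n, 1000, 3000), paste0("c", 1:n))
    b <- a + rnorm(n, 0, 40)
    r <- shift_report(a, b)
    expect_identical(nrow(r$inversions), oracle_inversions(a, b))
  }
})

test_that("histogram bins cover the deltas at the configured width", {
  a <- stats::setNames(seq(1000, 1090, by = 10), letters[1:10])
  b <- a + c(-7, -3, 0, 2, 4, 6, 8, 11, 13, 22)
  r <- shift_report(a, b, bin_width = 5)
  expect_equal(sum(r$histogram$count), 10)
  expect_true(all(diff(r$histogram$bin_start) == 5))
})

test_that("ambiguity groups chain entries within an RI tolerance", {
  lib <- table2_library()
  g10 <- ambiguity_risk(lib, 10)
  flat <- lapply(g10, function(g) vapply(g, function(n) parse_name(n)$compound,
                                         character(1)))
  # the aldohexose trio (1876/1880/1886) always travels together, while
  # fructose's main product at 1862 sits 14 RI units away and stays apart
  joint <- vapply(flat, function(g)
    all(c("Mannose", "Galactose", "Glucose") %in% g), logical(1))
  expect_true(any(joint))
  expect_false(any(vapply(flat, function(g)
    "Fructose" %in% g && "Mannose" %in% g, logical(1))))
  # no group mixes pentoses with hexoses (gap 1716 -> 1862)
  classes <- lapply(g10, function(g)
    unique(vapply(g, function(n) lib$entries[[n]]$class, character(1))))
  expect_false(any(vapply(classes, function(cl)
    all(c("Pentoses", "Hexoses") %in% cl), logical(1))))

  # with tolerance 15 all five hexose-region entries chain into one group
  g15 <- ambiguity_risk(lib, 15)
  hex_all <- vapply(lapply(g15, function(g)
    vapply(g, function(n) parse_name(n)$compound, character(1))),
    function(g) all(c("Fructose", "Mannose", "Galactose", "Glucose") %in% g),
    logical(1))
  expect_true(any(hex_all))

  # tolerance 0 groups only exact ties
  tie_lib <- compound_library(list(
    library_entry("A1", "(TMS)", ri = 1500),
    library_entry("A2", "(TMS)", ri = 1500),
    library_entry("B1", "(TMS)", ri = 1501)))
  g0 <- ambiguity_risk(tie_lib, 0)
  expect_length(g0, 1)
  expect_length(g0[[1]], 2)
})

test_that("ladder TSVs round-trip and reject invalid anchors", {
  lad <- default_alkane_ladder()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ladder_tsv(lad, path)
  lad2 <- read_ladder_tsv(path)
  expect_equal(lad2$carbon, lad$carbon)
  expect_equal(lad2$rt, lad$rt)
  expect_error(alkane_ladder(c(10, 10), c(1, 2)), "distinct")
  expect_error(alkane_ladder(c(10, 12), c(2, 1)), "increasing")
  expect_error(alkane_ladder(10, 1), ">= 2")
})
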