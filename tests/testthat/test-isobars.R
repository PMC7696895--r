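records_df <- function(mass, name = NULL, ...) {
  d <- data.frame(id = paste0("r", seq_along(mass)),
                  name = name %||% paste0("cmpd", seq_along(mass)),
                  formula = NA_character_, mass = mass,
                  status = NA_character_, pathways = NA_character_,
                  has_reaction = NA, stringsAsFactors = FALSE)
  extra <- list(...)
  for (k in names(extra)) d[[k]] <- extra[[k]]
  class(d) <- c("identmix_records", "data.frame")
  d
}

test_that("filters apply in order with an audit trail that sums up", {
  d <- records_df(c(100, 1600, 200, 300),
                  name = c("Glucose", "Heavy", "PC(16:0/18:1)", "Citrate"),
                  status = c("quantified", "detected", "detected", "expected"))
  f <- filter_records(d, list(max_mass = 1500, lipid_exclusion = TRUE,
                              status_whitelist = "quantified"))
  expect_identical(f$records$name, "Glucose")
  expect_identical(f$audit$rule,
                   c("max_mass", "lipid_exclusion", "status_whitelist"))
  expect_identical(f$audit$removed, c(1L, 1L, 1L))
  # removals plus survivors reconstruct the input count
  expect_identical(sum(f$audit$removed) + nrow(f$records), nrow(d))

  # empty rule set is the identity
  f0 <- filter_records(d, list())
  expect_identical(nrow(f0$records), nrow(d))
  expect_identical(nrow(f0$audit), 0L)

  # whitelisting an absent status warns but proceeds
  expect_warning(filter_records(d, list(status_whitelist = c("detected", "imaginary"))),
                 "imaginary")
})

test_that("formula and organic filters use the formula column", {
  d <- records_df(c(100, 110, 120), name = c("water", "salt", "glucose"))
  d$formula <- c("H2O", NA, "C6H12O6")
  f <- filter_records(d, list(require_formula = TRUE, organic_only = TRUE))
  expect_identical(f$records$name, "glucose")
  # "Co"/"Cl" style symbols do not count as carbon
  d2 <- records_df(c(50, 60), name = c("cobalt thing", "chloride"))
  d2$formula <- c("CoCl2", "NaCl")
  f2 <- filter_records(d2, list(organic_only = TRUE))
  expect_identical(nrow(f2$records), 0L)
})

test_that("the lipid text rule flags chain:double-bond names", {
  expect_true(is_lipid_name("PC(16:0/18:1)"))
  expect_false(is_lipid_name("Glucose"))
  # documented false positive: the rule is purely textual
  expect_true(is_lipid_name("Vitamin D3 1:1 complex"))
  expect_identical(is_lipid_name(c("TG(54:2)", "alanine")), c(TRUE, FALSE))
})

test_that("isobar group sizes count mass-sharing records at both resolutions", {
  five <- read_compound_records(
    system.file("extdata", "c3h7no2.tsv", package = "identmix"))
  expect_identical(isobar_group_sizes(five, "exact"), rep(5L, 5))

  # distinct at exact resolution, merged at unit resolution
  d <- records_df(c(89.0477, 89.0932))
  expect_identical(isobar_group_sizes(d, "exact"), c(1L, 1L))
  expect_identical(isobar_group_sizes(d, "unit"), c(2L, 2L))

  dm <- records_df(c(100, NA))
  expect_error(isobar_group_sizes(dm), "r2")
})

test_that("group sizes agree with the brute-force oracle and unit >= exact", {
  set.seed(31)
  mass <- round(runif(200, 50, 1500), 4)
  # seed collisions so groups exist
  mass[51:70] <- mass[1:20]
  d <- records_df(mass)
  expect_identical(isobar_group_sizes(d, "exact"), oracle_group_sizes(mass))
  unit <- isobar_group_sizes(d, "unit")
  expect_identical(unit, oracle_group_sizes(trunc(mass + 0.5), digits = 0))
  expect_true(all(unit >= isobar_group_sizes(d, "exact")))
  # group sizes over mass groups partition the records
  expect_identical(sum(1 / isobar_group_sizes(d, "exact") *
                         isobar_group_sizes(d, "exact")), 200)
})

test_that("the cumulative isobar curve starts at 100% and is non-increasing", {
  # all unique masses
  c1 <- cumulative_isobar_curve(rep(1L, 4))
  expect_equal(c1$percent[c1$threshold == 0], 100)
  expect_equal(nrow(c1), 1L)

  # one 5-group plus three singletons: 5 of 8 compounds have >= 1 partner
  gs <- c(rep(5L, 5), 1L, 1L, 1L)
  c2 <- cumulative_isobar_curve(gs)
  expect_equal(c2$percent[c2$threshold == 1], 62.5)
  expect_equal(c2$percent[c2$threshold == 0], 100)
  expect_equal(c2$percent[c2$threshold == 4], 62.5)

  set.seed(41)
  c3 <- cumulative_isobar_curve(oracle_group_sizes(sample(1:40, 100, TRUE),
                                                   digits = 0))
  expect_true(all(diff(c3$percent) <= 0))
})

test_that("window density reports the max group size per half-open 5 Da window", {
  d1 <- records_df(123.4)
  w1 <- window_density(d1)
  expect_identical(w1$window_start, 120)
  expect_identical(w1$max_count, 1L)

  five <- read_compound_records(
    system.file("extdata", "c3h7no2.tsv", package = "identmix"))
  w <- window_density(five)
  expect_gte(w$max_count[w$window_start == 85], 5L)

  # boundary mass belongs to the right-hand window
  d2 <- records_df(c(90.0, 89.9999))
  w2 <- window_density(d2)
  expect_setequal(w2$window_start, c(85, 90))
})

test_that("record reading adapts arbitrary export schemas via the column map", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tcompound\tmono_mass",
               "K1\tcitrate\t192.027",
               "K2\tisocitrate\t192.027"), path)
  rec <- read_compound_records(path, cols = list(id = "accession",
                                                 name = "compound",
                                                 mass = "mono_mass"))
  expect_identical(rec$id, c("K1", "K2"))
  expect_identical(isobar_group_sizes(rec), c(2L, 2L))
})
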