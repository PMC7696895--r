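make_runs <- function(...) {
  # helper: named list of peak lists given as ri/intensity data frames
  runs <- list(...)
  lapply(runs, function(d) {
    if (is.null(d)) data.frame(ri = numeric(), intensity = numeric())
    else d
  })
}

test_that("presence detection applies the RI window and records the most intense peak", {
  e <- library_entry("Galacturonic acid", "(MeOX)(5TMS)", ri = 1935,
                     code = c("B", "D"))
  runs <- make_runs(
    A = data.frame(ri = 1700, intensity = 100),
    B = data.frame(ri = 1934, intensity = 100),
    C = NULL,
    D = data.frame(ri = c(1934, 1990), intensity = c(80, 50)))
  p <- detect_presence(e, runs, tolerances = identify_tolerances())
  expect_identical(as.logical(p), c(FALSE, TRUE, FALSE, TRUE))

  # empty peak lists -> all absent
  p0 <- detect_presence(e, make_runs(A = NULL, B = NULL, C = NULL, D = NULL))
  expect_false(any(p0))

  # two qualifying peaks in one run: the most intense one is recorded
  runs2 <- make_runs(A = NULL, C = NULL,
                     B = data.frame(ri = c(1934, 1936), intensity = c(10, 100)),
                     D = data.frame(ri = 1935, intensity = 50))
  p2 <- detect_presence(e, runs2)
  sup <- attr(p2, "support")
  expect_equal(sup$intensity[sup$mix == "B"], 100)

  expect_error(detect_presence(e, make_runs(A = NULL, B = NULL)),
               "no run supplied")
})

test_that("peaks below the relative intensity floor do not count as present", {
  e <- library_entry("X", "(TMS)", ri = 1500, code = c("A", "B"))
  runs <- make_runs(
    A = data.frame(ri = c(1500, 1400), intensity = c(1, 1000)),
    B = data.frame(ri = 1500, intensity = 1000))
  p <- detect_presence(e, runs,
                       tolerances = identify_tolerances(intensity_min_frac = 0.05))
  expect_identical(as.logical(p), c(FALSE, TRUE))
})

test_that("pattern matching distinguishes confirmed, not_found and conflict", {
  obs <- function(on, labels = LETTERS[1:4]) {
    stats::setNames(labels %in% on, labels)
  }
  expect_identical(match_pattern(obs(c("A", "C")), c("A", "C")), "confirmed")
  expect_identical(match_pattern(obs(character()), c("B", "D")), "not_found")
  expect_identical(match_pattern(obs(c("A", "B", "C")), c("A", "C")), "conflict")
  expect_identical(match_pattern(obs("A"), c("A", "C")), "conflict")
  expect_error(match_pattern(obs("A", labels = c("A", "B")), c("A", "C")),
               "labels")
})

test_that("a zero-noise batch from the worked-example panel is fully recovered", {
  tb <- table2_batch(seed = 7)
  res <- identify_batch(tb$library, tb$design, tb$runs, ladders = tb$ladder)
  ids <- res$identifications
  expect_identical(unique(ids$status), "confirmed")
  expect_equal(ids$updated_ri, ids$expected_ri)
  # updated library re-encodes names from the confirmed RIs
  expect_identical(names(res$library$entries), names(tb$library$entries))
})

test_that("deleting a compound from the runs yields not_found, leaving the rest confirmed", {
  tb <- table2_batch(seed = 7)
  # remove ribose's peaks (RI 1672, mixes B and D) from every run
  runs <- lapply(tb$runs, function(d) d[is.na(d$truth_compound) |
                                          d$truth_compound != "Ribose", ])
  res <- identify_batch(tb$library, tb$design, runs, ladders = tb$ladder)
  ids <- res$identifications
  expect_identical(ids$status[ids$compound == "Ribose"], "not_found")
  expect_identical(unique(ids$status[ids$compound != "Ribose"]), "confirmed")
})

test_that("fully separated coeluting compounds are both confirmed via their own mixes", {
  # identical expected RI, disjoint codes: the design keeps them apart
  lib <- compound_library(list(
    library_entry("IsoA", "(TMS)", ri = 1500, code = c("A", "C")),
    library_entry("IsoB", "(TMS)", ri = 1500, code = c("B", "D"))))
  design <- mix_design(4, list(IsoA = c("A", "C"), IsoB = c("B", "D")))
  runs <- make_runs(
    A = data.frame(ri = 1500, intensity = 100),
    B = data.frame(ri = 1500, intensity = 90),
    C = data.frame(ri = 1500, intensity = 110),
    D = data.frame(ri = 1500, intensity = 95))
  res <- identify_batch(lib, design, runs)
  expect_identical(unique(res$identifications$status), "confirmed")
})

test_that("isomer claims are swapped toward the compound with the matching pattern", {
  # a peak cluster in A and D near RI 1876: mannose {A,D} wins over
  # glucose {B,D}, which lacks any supporting peak in B
  claims <- list(
    Mannose = list(code = c("A", "D"), expected = 1876,
                   candidates = data.frame(
                     mix = c("A", "D"), peak_id = c("A#1", "D#1"),
                     value = c(1876, 1876), intensity = c(100, 90))),
    Glucose = list(code = c("B", "D"), expected = 1886,
                   candidates = data.frame(
                     mix = "D", peak_id = "D#1",
                     value = 1876, intensity = 90)))
  r <- resolve_isomers(claims)
  expect_identical(r$status[["Mannose"]], "resolved")
  expect_identical(r$status[["Glucose"]], "not_found")
  expect_setequal(r$assignments$Mannose$peak_id, c("A#1", "D#1"))

  # single candidate is unchanged
  r1 <- resolve_isomers(claims["Mannose"])
  expect_identical(r1$status[["Mannose"]], "resolved")

  # identical codes competing for the same pair cannot be separated
  claims2 <- list(
    Twin1 = claims$Mannose,
    Twin2 = list(code = c("A", "D"), expected = 1877,
                 candidates = claims$Mannose$candidates))
  r2 <- resolve_isomers(claims2)
  expect_identical(unname(r2$status[c("Twin1", "Twin2")]),
                   c("ambiguous", "ambiguous"))
})

test_that("overlapping isomer windows resolve without conflicts in the worked example", {
  tb <- table2_batch(seed = 7)
  res <- identify_batch(tb$library, tb$design, tb$runs, ladders = tb$ladder)
  # hexose and sugar-derivative windows overlap heavily (1876-1935), yet
  # every entry ends on its own peaks
  conf <- res$identifications
  for (i in seq_len(nrow(conf))) {
    code <- tb$design$assignment[[conf$compound[i]]]
    expect_identical(conf$observed_pattern[i], paste(sort(code), collapse = "+"))
  }
})

test_that("decoy peaks outside every retention window change no status", {
  tb <- table2_batch(seed = 7)
  base <- identify_batch(tb$library, tb$design, tb$runs, ladders = tb$ladder)
  ris <- vapply(tb$library$entries, function(e) e$ri, numeric(1))
  runs <- lapply(tb$runs, function(d) {
    far <- data.frame(rt_seconds = rt_for_ri(c(1200, 2500, 3100), tb$ladder),
                      intensity = c(5e5, 7e5, 9e5),
                      truth_compound = NA_character_, is_decoy = TRUE)
    stopifnot(all(abs(outer(c(1200, 2500, 3100), ris, "-")) > 10))
    rbind(d, far)
  })
  withdec <- identify_batch(tb$library, tb$design, runs, ladders = tb$ladder)
  expect_identical(withdec$identifications$status,
                   base$identifications$status)
  expect_equal(withdec$identifications$updated_ri,
               base$identifications$updated_ri)
})

test_that("exclusion safety: a missing code-mix peak never produces a wrong confirmation", {
  for (seed in 1:10) {
    cfg <- sim_config(n_compounds = 20, k = 4, n_isomer_clusters = 3,
                      noise_sd = 1, seed = seed)
    truth <- generate_truth(cfg)
    batch <- generate_peaklists(truth, cfg)
    victim <- names(truth$design$assignment)[1 + seed %% 20]
    vmix <- truth$design$assignment[[victim]][1]
    runs <- batch$runs
    drop_rows <- !is.na(runs[[vmix]]$truth_compound) &
      runs[[vmix]]$truth_compound == victim
    runs[[vmix]] <- runs[[vmix]][!drop_rows, ]
    res <- identify_batch(truth$library, truth$design, runs,
                          ladders = batch$ladder)
    vstat <- res$identifications$status[res$identifications$compound == victim]
    expect_true(vstat %in% c("conflict", "not_found", "ambiguous"))
  }
})

test_that("entries without a pair-code are flagged unvalidated", {
  lib <- compound_library(list(
    library_entry("Coded", "(TMS)", ri = 1500, code = c("A", "B")),
    library_entry("Uncoded", "(TMS)", ri = 1600)))
  design <- mix_design(4, list(Coded = c("A", "B")))
  runs <- make_runs(
    A = data.frame(ri = c(1500, 1600), intensity = c(100, 100)),
    B = data.frame(ri = 1500, intensity = 100),
    C = NULL, D = NULL)
  res <- identify_batch(lib, design, runs)
  ids <- res$identifications
  expect_identical(ids$status[ids$compound == "Uncoded"], "unvalidated")
  expect_identical(ids$status[ids$compound == "Coded"], "confirmed")
  expect_true(is.na(ids$updated_ri[ids$compound == "Uncoded"]))
})

test_that("identification is reproducible and label mismatches are rejected", {
  tb <- table2_batch(seed = 9, noise_sd = 1, dropout = 0.1, decoys = 0.1)
  r1 <- identify_batch(tb$library, tb$design, tb$runs, ladders = tb$ladder)
  r2 <- identify_batch(tb$library, tb$design, tb$runs, ladders = tb$ladder)
  expect_identical(r1$identifications, r2$identifications)

  expect_error(identify_batch(tb$library, tb$design, tb$runs[c("A", "B")],
                              ladders = tb$ladder), "labels")
})

test_that("gap-filled peaks are excluded from presence by default", {
  e <- library_entry("X", "(TMS)", ri = 1500, code = c("A", "B"))
  runs <- list(
    A = data.frame(ri = 1500, intensity = 100, gap_filled = TRUE),
    B = data.frame(ri = 1500, intensity = 100, gap_filled = FALSE))
  p <- detect_presence(e, runs)
  expect_identical(as.logical(p), c(FALSE, TRUE))
  p2 <- detect_presence(e, runs,
                        tolerances = identify_tolerances(include_gap_filled = TRUE))
  expect_identical(as.logical(p2), c(TRUE, TRUE))
})
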