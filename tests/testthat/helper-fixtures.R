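# Fixture generators shared across the test files. Everything is built in
# code under fixed seeds; no binary data.

# A random valid library entry with an integer RI (the codec renders RI as
# an integer, so integer RIs round-trip losslessly).
random_entry <- function(i) {
  library_entry(
    compound = paste0("Compound ", i),
    derivatisation = sample(c("(2TMS)", "(3TMS)", "(MeOX)(5TMS)"), 1),
    rank = sample(c("MP", "BP", NA_character_), 1),
    ri = sample(900:3600, 1),
    code = if (stats::runif(1) < 0.7) sample(LETTERS[1:4], 2) else NULL
  )
}

# Sparse random EI-like spectrum on integer m/z.
random_spectrum <- function(n_peaks = 8, mz_range = c(60, 600)) {
  mz <- sort(sample(seq(mz_range[1], mz_range[2]), n_peaks))
  spectrum(mz, stats::runif(n_peaks, 1, 999))
}

# Zero-noise synthetic batch from the bundled worked-example panel.
table2_batch <- function(noise_sd = 0, dropout = 0, decoys = 0, seed = 7) {
  lib <- table2_library()
  design <- table2_design()
  cfg <- sim_config(n_compounds = length(lib$entries), k = design$k,
                    n_isomer_clusters = 0, noise_sd = noise_sd,
                    dropout_rate = dropout, decoy_rate = decoys, seed = seed)
  batch <- generate_peaklists(list(library = lib, design = design), cfg)
  list(library = lib, design = design, runs = batch$runs,
       ladder = batch$ladder, config = cfg)
}

# Brute-force Kendall-style disagreement count: O(n^2) double loop, kept
# deliberately naive as the oracle for inversion counting.
oracle_inversions <- function(a, b) {
  shared <- intersect(names(a), names(b))
  n <- 0L
  for (i in seq_along(shared)) {
    for (j in seq_along(shared)) {
      if (i < j) {
        da <- a[[shared[i]]] - a[[shared[j]]]
        db <- b[[shared[i]]] - b[[shared[j]]]
        if (da * db < 0) n <- n + 1L
      }
    }
  }
  n
}

# Brute-force isobar group size: count pairwise mass matches per record.
oracle_group_sizes <- function(mass, digits = 4) {
  key <- round(mass, digits)
  vapply(seq_along(key), function(i) sum(key == key[i]), integer(1))
}

# Weighted-cosine match factor recomputed from first principles (plain
# arithmetic, no shared code path with match_factor()).
oracle_match_factor <- function(q_mz, q_int, r_mz, r_int, a = 0.6, b = 3,
                                reverse = FALSE) {
  bins <- if (reverse) unique(round(r_mz)) else
    sort(union(round(q_mz), round(r_mz)))
  wq <- wr <- numeric(length(bins))
  for (k in seq_along(bins)) {
    qi <- sum(q_int[round(q_mz) == bins[k]])
    ri <- sum(r_int[round(r_mz) == bins[k]])
    wq[k] <- if (qi > 0) qi^a * bins[k]^b else 0
    wr[k] <- if (ri > 0) ri^a * bins[k]^b else 0
  }
  den <- sum(wq^2) * sum(wr^2)
  if (den == 0) return(0)
  round(1000 * sum(wq * wr)^2 / den)
}
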