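#' Simulation configuration for synthetic Ident-Mix batches
#'
#' Parameters of the synthetic-batch generator, the in-silico stand-in for
#' physically prepared mixtures. Defaults describe a typical routine GC
#' batch: 50 compounds over four mixtures, expected RIs spread over the
#' C11-C34 region, within-batch RI reproducibility of 2 RI units (1 sd),
#' and log-normal MS responses around 1e6 counts with a 0.5 sdlog spread.
#'
#' @param n_compounds number of ground-truth compounds.
#' @param k number of mixtures.
#' @param ri_range numeric length 2, RI range for expected RIs.
#' @param n_isomer_clusters number of isomer clusters — groups of compounds
#'   with near-identical retention that receive pairwise DISTINCT
#'   constraints and hence pattern-distinct codes.
#' @param cluster_size compounds per cluster (must not exceed
#'   [code_capacity()]).
#' @param cluster_spread RI spread within a cluster (members are laid out
#'   within this many RI units).
#' @param noise_sd sd of the per-peak RI measurement noise, RI units.
#' @param dropout_rate probability that a true peak is missing from a run.
#' @param decoy_rate expected decoy peaks per run, as a fraction of
#'   `n_compounds` (Poisson counts).
#' @param intensity_meanlog,intensity_sdlog log-normal intensity parameters.
#' @param clean_decoys if `TRUE`, decoys are re-drawn until at least
#'   `2 * noise_sd` away from every true RI, so dropout effects and
#'   collision effects can be separated in tests.
#' @param seed integer seed; all generation is reproducible given it.
#' @return A list of class `identmix_simconfig`.
#' @export
sim_config <- function(n_compounds = 50, k = 4, ri_range = c(1100, 3400),
                       n_isomer_clusters = 5, cluster_size = 3,
                       cluster_spread = 8, noise_sd = 2, dropout_rate = 0,
                       decoy_rate = 0, intensity_meanlog = log(1e6),
                       intensity_sdlog = 0.5, clean_decoys = TRUE,
                       seed = 1) {
  stopifnot(n_compounds >= 1, k >= 2, length(ri_range) == 2,
            ri_range[1] < ri_range[2], n_isomer_clusters >= 0,
            cluster_size >= 1, cluster_spread >= 0, noise_sd >= 0,
            dropout_rate >= 0, dropout_rate <= 1, decoy_rate >= 0)
  if (n_isomer_clusters * cluster_size > n_compounds) {
    stop("isomer clusters would need more compounds than n_compounds")
  }
  if (cluster_size > code_capacity(k)) {
    stop("cluster_size ", cluster_size, " exceeds the code capacity ",
         code_capacity(k), " of k = ", k)
  }
  structure(list(n_compounds = n_compounds, k = k, ri_range = ri_range,
                 n_isomer_clusters = n_isomer_clusters,
                 cluster_size = cluster_size, cluster_spread = cluster_spread,
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 decoy_rate = decoy_rate,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 clean_decoys = clean_decoys, seed = as.integer(seed)),
            class = "identmix_simconfig")
}

#' Generate a ground-truth library, constraints and design
#'
#' Draws compound expected RIs (isomer-cluster members tightly spaced,
#' the rest uniform over the RI range), builds pairwise DISTINCT
#' constraints within each cluster, and assigns pair-codes with
#' [assign_codes()]. Deterministic given the config seed.
#'
#' @param config an [sim_config()].
#' @return A list with `library` (`identmix_library`), `design`
#'   (`identmix_design`) and `constraints` ([constraint_graph()]).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "identmix_simconfig"))
  set.seed(config$seed)
  n <- config$n_compounds
  ids <- sprintf("Cmpd%03d", seq_len(n))
  ris <- numeric(n)
  distinct_pairs <- NULL
  idx <- 1L
  if (config$n_isomer_clusters > 0) {
    # cluster centers kept well apart so clusters never merge
    min_sep <- max(50, 3 * config$cluster_spread)
    centers <- numeric(0)
    tries <- 0L
    while (length(centers) < config$n_isomer_clusters && tries < 10000L) {
      cand <- stats::runif(1, config$ri_range[1] + config$cluster_spread,
                           config$ri_range[2] - config$cluster_spread)
      if (!length(centers) || all(abs(centers - cand) >= min_sep)) {
        centers <- c(centers, cand)
      }
      tries <- tries + 1L
    }
    if (length(centers) < config$n_isomer_clusters) {
      stop("could not place ", config$n_isomer_clusters,
           " isomer clusters with separation ", min_sep,
           " inside the RI range")
    }
    centers <- sort(centers)
    for (ci in seq_len(config$n_isomer_clusters)) {
      members <- idx:(idx + config$cluster_size - 1L)
      offs <- sort(stats::runif(config$cluster_size, 0, config$cluster_spread))
      ris[members] <- centers[ci] + offs
      if (length(members) > 1) {
        distinct_pairs <- rbind(distinct_pairs,
                                t(utils::combn(ids[members], 2)))
      }
      idx <- idx + config$cluster_size
    }
  }
  if (idx <= n) {
    ris[idx:n] <- stats::runif(n - idx + 1L, config$ri_range[1],
                               config$ri_range[2])
  }
  constraints <- constraint_graph(distinct = distinct_pairs)
  design <- assign_codes(ids, constraints, k = config$k, seed = config$seed)
  entries <- lapply(seq_len(n), function(i) {
    library_entry(ids[i], "(TMS)", rank = "MP", ri = ris[i],
                  code = design$assignment[[ids[i]]],
                  class = if (i < idx) "isomer-cluster" else "singleton")
  })
  list(library = compound_library(entries,
                                  metadata = list(generator = "identmix synthetic",
                                                  seed = config$seed)),
       design = design, constraints = constraints)
}

#' Generate per-mixture peak lists and alkane ladders
#'
#' Emulates measuring the k Ident-Mixes: every compound produces one peak
#' in each of its two code mixtures at `RI ~ Normal(expected, noise_sd)`
#' (dropped with probability `dropout_rate` per mixture), decoy peaks are
#' drawn uniformly over the RI range, and all RIs are converted to
#' retention times through a shared alkane ladder so the peak lists carry
#' only what an instrument would report (`rt_seconds`, `intensity`).
#' Ground-truth annotation columns (`truth_compound`, `is_decoy`) ride
#' along for test bookkeeping; file export drops them.
#'
#' @param truth output of [generate_truth()] (or a list with `library` and
#'   `design`).
#' @param config the same [sim_config()].
#' @param ladder alkane ladder used for the RI -> RT conversion.
#' @return A list with `runs` (named list of peak-list data frames),
#'   `ladders` (named list, the same ladder per run) and `ladder`.
#' @export
generate_peaklists <- function(truth, config,
                               ladder = default_alkane_ladder()) {
  stopifnot(inherits(config, "identmix_simconfig"))
  set.seed(config$seed + 1L)
  design <- truth$design
  entries <- truth$library$entries
  labels <- design$labels
  true_ri <- vapply(entries, function(e) e$ri, numeric(1))
  runs <- stats::setNames(vector("list", length(labels)), labels)
  for (lab in labels) runs[[lab]] <- list()
  for (e in entries) {
    for (lab in e$code) {
      if (stats::runif(1) < config$dropout_rate) next
      ri_obs <- e$ri + stats::rnorm(1, 0, config$noise_sd)
      runs[[lab]][[length(runs[[lab]]) + 1L]] <- data.frame(
        ri = ri_obs,
        intensity = stats::rlnorm(1, config$intensity_meanlog,
                                  config$intensity_sdlog),
        truth_compound = e$compound, is_decoy = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  margin <- 2 * config$noise_sd
  for (lab in labels) {
    n_dec <- stats::rpois(1, config$decoy_rate * config$n_compounds)
    d <- 0L
    while (d < n_dec) {
      ri_d <- stats::runif(1, config$ri_range[1], config$ri_range[2])
      if (config$clean_decoys && margin > 0 &&
          any(abs(true_ri - ri_d) < margin)) next
      runs[[lab]][[length(runs[[lab]]) + 1L]] <- data.frame(
        ri = ri_d,
        intensity = stats::rlnorm(1, config$intensity_meanlog,
                                  config$intensity_sdlog),
        truth_compound = NA_character_, is_decoy = TRUE,
        stringsAsFactors = FALSE)
      d <- d + 1L
    }
  }
  runs <- lapply(runs, function(pk) {
    if (!length(pk)) {
      return(data.frame(rt_seconds = numeric(), intensity = numeric(),
                        truth_compound = character(), is_decoy = logical(),
                        stringsAsFactors = FALSE))
    }
    d <- do.call(rbind, pk)
    d$rt_seconds <- rt_for_ri(d$ri, ladder)
    d <- d[order(d$rt_seconds),
           c("rt_seconds", "intensity", "truth_compound", "is_decoy")]
    rownames(d) <- NULL
    d
  })
  list(runs = runs,
       ladders = stats::setNames(rep(list(ladder), length(labels)), labels),
       ladder = ladder)
}

#' The worked-example standard panel ("table2" preset)
#'
#' A 13-compound excerpt of a routine Ident-Mix panel — pentoses, hexoses
#' and sugar derivatives with closely spaced retention indices — together
#' with its printed pair-code assignment over mixtures A-D and the
#' constraints that assignment satisfies (all hexoses pairwise DISTINCT,
#' fructose/mannose DISJOINT, mannose/galactose OVERLAP_ONE). Fructose is
#' carried at the RI of its main derivatisation product (1862).
#'
#' @return `table2_library()`: an `identmix_library`; `table2_design()`: an
#'   `identmix_design`; `table2_constraints()`: a [constraint_graph()].
#' @export
table2_library <- function() {
  t2 <- table2_rows()
  entries <- lapply(seq_len(nrow(t2)), function(i) {
    library_entry(t2$compound[i], t2$derivatisation[i], rank = "MP",
                  ri = t2$ri[i], code = c(t2$mix1[i], t2$mix2[i]),
                  class = t2$class[i])
  })
  compound_library(entries, metadata = list(preset = "table2"))
}

#' @rdname table2_library
#' @export
table2_design <- function() {
  t2 <- table2_rows()
  assignment <- lapply(seq_len(nrow(t2)), function(i) c(t2$mix1[i], t2$mix2[i]))
  names(assignment) <- t2$compound
  mix_design(4, assignment)
}

#' @rdname table2_library
#' @export
table2_constraints <- function() {
  hex <- c("Fructose", "Mannose", "Galactose", "Glucose")
  pairs <- t(utils::combn(hex, 2))
  special <- pairs[, 1] == "Fructose" & pairs[, 2] == "Mannose" |
             pairs[, 1] == "Mannose" & pairs[, 2] == "Galactose"
  constraint_graph(
    distinct = pairs[!special, , drop = FALSE],
    disjoint = matrix(c("Fructose", "Mannose"), ncol = 2),
    overlap_one = matrix(c("Mannose", "Galactose"), ncol = 2))
}

table2_rows <- function() {
  data.frame(
    class = rep(c("Pentoses", "Hexoses", "Sugar Derivatives"), c(4, 4, 5)),
    compound = c("Xylose", "Ribose", "Arabitol", "Ribitol",
                 "Fructose", "Mannose", "Galactose", "Glucose",
                 "Sorbitol", "Glucuronic acid", "Glucosamine",
                 "Galacturonic acid", "Gluconic acid"),
    derivatisation = c("(MeOX)(4TMS)", "(MeOX)(4TMS)", "(5TMS)", "(5TMS)",
                       "(MeOX)(5TMS)", "(MeOX)(5TMS)", "(MeOX)(5TMS)",
                       "(MeOX)(5TMS)", "(6TMS)", "(MeOX)(5TMS)",
                       "(MeOX)(5TMS)", "(MeOX)(5TMS)", "(6TMS)"),
    ri = c(1651, 1672, 1711, 1716, 1862, 1876, 1880, 1886,
           1926, 1927, 1932, 1935, 1996),
    mix1 = c("A", "B", "C", "A", "B", "A", "A", "B", "A", "A", "A", "B", "B"),
    mix2 = c("C", "D", "D", "B", "C", "D", "C", "D", "D", "C", "B", "D", "C"),
    stringsAsFactors = FALSE)
}

#' Read / write a peak-list TSV
#'
#' Columns `rt_seconds`, `intensity` and optionally `mz`, `spectrum_id`,
#' `gap_filled`; tab-separated with a header row. Ground-truth annotation
#' columns from the simulator are dropped on write.
#'
#' @param path file path.
#' @param peaks a peak-list data frame.
#' @return `read_peaklist_tsv()` returns a data frame;
#'   `write_peaklist_tsv()` returns `path` invisibly.
#' @export
read_peaklist_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("rt_seconds", "intensity") %in% names(d))) {
    stop("peak list TSV needs columns rt_seconds, intensity: ", path)
  }
  d
}

#' @rdname read_peaklist_tsv
#' @export
write_peaklist_tsv <- function(peaks, path) {
  keep <- intersect(c("rt_seconds", "intensity", "mz", "spectrum_id",
                      "gap_filled"), names(peaks))
  utils::write.table(peaks[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
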