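#' Matching tolerances for pattern-guided identification
#'
#' Bundle of thresholds used by [detect_presence()] and [identify_batch()].
#' The positive signal of a spiked standard is by design strong, so the
#' detection thresholds can be set high: false positives are excluded at the
#' price of occasionally missing a genuinely present compound, which the
#' pattern readout then reports as `not_found` rather than misassigning it.
#'
#' @param ri_window half-width of the expected-RI search window, RI units
#'   (GC mode).
#' @param rt_window half-width of the expected-RT window, seconds (LC mode,
#'   where run-to-run shifts of 20-30 s are routine).
#' @param spectral_min minimum reverse match factor (0-1000) when both the
#'   entry and the peak carry spectra; ignored otherwise.
#' @param intensity_min_frac a peak must reach this fraction of its run's
#'   base-peak intensity to count as present.
#' @param pair_tol maximum retention disagreement (same units as the active
#'   window) between the two peaks supporting one compound in its two code
#'   mixes; the duplicate measurement must agree for a confirmation.
#' @param mode `"ri"` (GC, retention-index axis) or `"rt"` (LC, raw
#'   retention time).
#' @param include_gap_filled whether peaks flagged `gap_filled` in a peak
#'   list count as present (default `FALSE`: software-imputed peaks carry no
#'   evidential weight for the pattern readout).
#' @return A list of class `identmix_tolerances`.
#' @export
identify_tolerances <- function(ri_window = 10, rt_window = 30,
                                spectral_min = 650,
                                intensity_min_frac = 0.05, pair_tol = 5,
                                mode = c("ri", "rt"),
                                include_gap_filled = FALSE) {
  mode <- match.arg(mode)
  stopifnot(ri_window >= 0, rt_window >= 0, pair_tol >= 0,
            intensity_min_frac >= 0, intensity_min_frac <= 1,
            spectral_min >= 0, spectral_min <= 1000)
  structure(list(ri_window = ri_window, rt_window = rt_window,
                 spectral_min = spectral_min,
                 intensity_min_frac = intensity_min_frac,
                 pair_tol = pair_tol, mode = mode,
                 include_gap_filled = include_gap_filled),
            class = "identmix_tolerances")
}

# Pool all runs into one annotated peak table on the active retention axis.
# runs: named list (mix label -> data.frame with rt_seconds, intensity,
# optional ri / spectrum_id / gap_filled). ladders: NULL, one ladder, or a
# named list per mix.
build_peak_table <- function(runs, ladders, tol) {
  if (is.null(names(runs)) || any(!nzchar(names(runs)))) {
    stop("runs must be a named list (mixture label -> peak list)")
  }
  out <- lapply(names(runs), function(mix) {
    d <- runs[[mix]]
    if (!is.data.frame(d)) stop("run '", mix, "' is not a data frame")
    if (nrow(d) == 0L) {
      return(data.frame(mix = character(), peak_id = character(),
                        value = numeric(), rt = numeric(),
                        intensity = numeric(), spectrum_id = character(),
                        stringsAsFactors = FALSE))
    }
    if (!"intensity" %in% names(d)) stop("run '", mix, "' lacks an intensity column")
    value <- if (tol$mode == "rt") {
      if (!"rt_seconds" %in% names(d)) stop("run '", mix, "' lacks rt_seconds")
      d$rt_seconds
    } else if ("ri" %in% names(d)) {
      d$ri
    } else {
      if (!"rt_seconds" %in% names(d)) stop("run '", mix, "' lacks rt_seconds")
      lad <- if (inherits(ladders, "identmix_ladder")) ladders else ladders[[mix]]
      if (is.null(lad)) stop("no alkane ladder for run '", mix,
                             "' and no precomputed ri column")
      as.numeric(compute_ri(d$rt_seconds, lad))
    }
    keep <- rep(TRUE, nrow(d))
    if (!tol$include_gap_filled && "gap_filled" %in% names(d)) {
      keep <- keep & !d$gap_filled
    }
    data.frame(mix = mix, peak_id = paste0(mix, "#", seq_len(nrow(d))),
               value = value,
               rt = if ("rt_seconds" %in% names(d)) d$rt_seconds else NA_real_,
               intensity = d$intensity,
               spectrum_id = if ("spectrum_id" %in% names(d))
                 as.character(d$spectrum_id) else NA_character_,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  })
  pt <- do.call(rbind, out)
  # per-run relative intensity threshold
  thr <- vapply(names(runs), function(mix) {
    v <- pt$intensity[pt$mix == mix]
    if (length(v)) tol$intensity_min_frac * max(v) else 0
  }, numeric(1))
  pt$passes_intensity <- pt$intensity >= thr[pt$mix]
  pt
}

# Qualifying peaks for one entry: retention window + intensity gate +
# optional spectral gate (reverse match factor vs the entry's spectrum).
qualifying_peaks <- function(entry, pt, tol, spectra = NULL) {
  expected <- if (tol$mode == "rt") entry$rt else entry$ri
  window <- if (tol$mode == "rt") tol$rt_window else tol$ri_window
  if (is.na(expected)) {
    return(pt[0, , drop = FALSE])
  }
  q <- pt[abs(pt$value - expected) <= window & pt$passes_intensity, , drop = FALSE]
  if (!is.null(entry$spectrum) && nrow(q) > 0L && !is.null(spectra)) {
    ok <- vapply(seq_len(nrow(q)), function(i) {
      sid <- q$spectrum_id[i]
      if (is.na(sid) || is.null(spectra[[sid]])) return(TRUE)
      match_factor(spectra[[sid]], entry$spectrum, "reverse") >= tol$spectral_min
    }, logical(1))
    q <- q[ok, , drop = FALSE]
  }
  q
}

#' Presence/absence pattern of one compound across the mixture runs
#'
#' A mixture counts as "present" when at least one of its peaks falls within
#' the retention window around the entry's expected RI (or RT in LC mode),
#' reaches the relative intensity threshold, and — when both entry and peak
#' carry spectra — passes the reverse-match-factor gate. The most intense
#' qualifying peak per present mixture is recorded as the supporting peak.
#'
#' @param entry a [library_entry()].
#' @param runs named list of peak-list data frames, one per mixture label.
#' @param ladders an [alkane_ladder()], a named list of ladders (one per
#'   run), or `NULL` when the peak lists already carry an `ri` column.
#' @param tolerances an [identify_tolerances()].
#' @param spectra optional named list mapping `spectrum_id` to
#'   [spectrum()] objects for the spectral gate.
#' @return A named logical vector (class `identmix_presence`) over the run
#'   labels, with the supporting peaks in attribute `"support"`.
#' @export
detect_presence <- function(entry, runs, ladders = NULL,
                            tolerances = identify_tolerances(),
                            spectra = NULL) {
  stopifnot(inherits(entry, "identmix_entry"))
  if (!is.null(entry$code)) {
    missing <- setdiff(entry$code, names(runs))
    if (length(missing)) {
      stop("no run supplied for mixture label(s): ",
           paste(missing, collapse = ", "))
    }
  }
  pt <- build_peak_table(runs, ladders, tolerances)
  q <- qualifying_peaks(entry, pt, tolerances, spectra)
  labels <- names(runs)
  present <- stats::setNames(labels %in% q$mix, labels)
  support <- q[order(q$mix, -q$intensity), , drop = FALSE]
  support <- support[!duplicated(support$mix), , drop = FALSE]
  structure(present, support = support, class = "identmix_presence")
}

#' @export
print.identmix_presence <- function(x, ...) {
  on <- names(x)[as.logical(x)]
  cat("<presence: {", paste(on, collapse = ","), "}>\n", sep = "")
  invisible(x)
}

#' Match an observed presence pattern against a pair-code
#'
#' `confirmed` when the observed pattern equals the code exactly (present in
#' both code mixtures, absent everywhere else); `not_found` when the
#' compound is absent from every mixture; `conflict` for anything in
#' between — a presence in a non-code mixture, or presence in only one of
#' the two code mixtures. Conflict is a distinct, reportable state, not a
#' silent not-found: it flags either a coeluting interference or a stale
#' library entry.
#'
#' @param observed named logical vector (or [detect_presence()] result).
#' @param code character vector of the two code mixture labels.
#' @return One of `"confirmed"`, `"conflict"`, `"not_found"`.
#' @export
match_pattern <- function(observed, code) {
  code <- validate_pair_code(code)
  if (!all(code %in% names(observed))) {
    stop("observed pattern does not cover the code's labels")
  }
  on <- names(observed)[as.logical(observed)]
  if (setequal(on, code)) return("confirmed")
  if (length(on) == 0L) return("not_found")
  "conflict"
}

#' Resolve competing isomer claims on overlapping peaks
#'
#' When several library entries' retention windows overlap, the same peaks
#' qualify for more than one entry and patterns computed per entry in
#' isolation conflict. This solver assigns peaks to entries jointly: an
#' entry is supported by a pair of peaks, one in each of its code mixtures,
#' whose retention values agree within `pair_tol`; entries are processed
#' most-constrained-first (fewest available pairs), each taking the pair
#' closest to its expected retention (ties to the most intense), and every
#' peak supports at most one entry. An identification initially pointing at
#' another compound's peaks is thereby swapped toward the compound whose
#' code matches the peaks' across-mixture occurrence. Entries left without a
#' consistent pair become `not_found`; two entries with identical codes
#' competing for the same pair cannot be separated by pattern and are
#' `ambiguous`.
#'
#' @param claims named list, one element per competing entry:
#'   `list(code = <character(2)>, expected = <numeric>, candidates =
#'   <data.frame mix/peak_id/value/intensity>)`.
#' @param pair_tol maximum retention disagreement within a supporting pair.
#' @return A list with `assignments` (named list of two-row candidate data
#'   frames for resolved entries), `status` (named: `"resolved"`,
#'   `"not_found"` or `"ambiguous"`) and `swaps` (character vector of log
#'   lines describing swap events).
#' @export
resolve_isomers <- function(claims, pair_tol = 5) {
  stopifnot(is.list(claims), length(claims) > 0, !is.null(names(claims)))
  placements <- lapply(claims, function(cl) {
    cd <- validate_pair_code(cl$code)
    c1 <- cl$candidates[cl$candidates$mix == cd[1], , drop = FALSE]
    c2 <- cl$candidates[cl$candidates$mix == cd[2], , drop = FALSE]
    if (!nrow(c1) || !nrow(c2)) return(NULL)
    g <- expand.grid(i = seq_len(nrow(c1)), j = seq_len(nrow(c2)))
    ok <- abs(c1$value[g$i] - c2$value[g$j]) <= pair_tol
    g <- g[ok, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    data.frame(p1 = c1$peak_id[g$i], p2 = c2$peak_id[g$j],
               v1 = c1$value[g$i], v2 = c2$value[g$j],
               int = c1$intensity[g$i] + c2$intensity[g$j],
               stringsAsFactors = FALSE)
  })
  n_opts <- vapply(placements, NROW, integer(1))
  ord <- names(claims)[order(n_opts, names(claims))]

  used <- character()
  owner <- list()   # peak_id -> entry that took it
  assignments <- list()
  status <- stats::setNames(rep("not_found", length(claims)), names(claims))
  swaps <- character()

  for (nm in ord) {
    pl <- placements[[nm]]
    if (is.null(pl)) next
    avail <- !(pl$p1 %in% used) & !(pl$p2 %in% used)
    if (!any(avail)) {
      # all consistent pairs taken; by an identical code -> pattern cannot
      # separate the two entries
      takers <- unique(unlist(owner[c(pl$p1, pl$p2)]))
      same_code <- any(vapply(takers, function(tk)
        identical(validate_pair_code(claims[[tk]]$code),
                  validate_pair_code(claims[[nm]]$code)), logical(1)))
      status[nm] <- if (same_code) "ambiguous" else "not_found"
      if (same_code) {
        for (tk in takers) {
          if (identical(validate_pair_code(claims[[tk]]$code),
                        validate_pair_code(claims[[nm]]$code))) {
            status[tk] <- "ambiguous"
            assignments[[tk]] <- NULL
          }
        }
      }
      next
    }
    pl <- pl[avail, , drop = FALSE]
    dist <- abs((pl$v1 + pl$v2) / 2 - claims[[nm]]$expected)
    pl <- pl[order(dist, -pl$int), , drop = FALSE]
    pick <- pl[1, ]
    cand <- claims[[nm]]$candidates
    assignments[[nm]] <- cand[cand$peak_id %in% c(pick$p1, pick$p2), , drop = FALSE]
    used <- c(used, pick$p1, pick$p2)
    owner[[pick$p1]] <- nm
    owner[[pick$p2]] <- nm
    status[nm] <- "resolved"
    # swap log: the raw most-intense candidate was not the one kept
    top <- cand[order(-cand$intensity), , drop = FALSE][1, ]
    if (!top$peak_id %in% c(pick$p1, pick$p2)) {
      swaps <- c(swaps, sprintf(
        "%s: most intense candidate %s (value %.1f) left to a pattern-matching competitor; kept %s/%s",
        nm, top$peak_id, top$value, pick$p1, pick$p2))
    }
  }
  list(assignments = assignments, status = status, swaps = swaps)
}

#' Identify a whole Ident-Mix batch against a library
#'
#' The full pattern-guided identification: every library entry carrying a
#' pair-code is searched for in the k mixture runs; overlapping claims are
#' resolved jointly by [resolve_isomers()]; each resolved entry's observed
#' pattern (its assigned peaks plus any residual unexplained peaks inside
#' its retention window) is matched against its code by [match_pattern()].
#' For confirmed entries the retention information is updated to the
#' intensity-weighted mean of the two supporting peaks — the two replicate
#' measurements the design provides — and a new library with refreshed
#' encoded names is returned, ready to identify the samples of the same
#' batch. Entries without a pair-code are matched by retention (and
#' spectrum) only and flagged `unvalidated`.
#'
#' @param library an `identmix_library`.
#' @param design an `identmix_design`; every coded entry's labels must be in
#'   the design and every design label must have a run.
#' @param runs named list of peak-list data frames (one per mixture label).
#' @param ladders ladder(s) as in [detect_presence()].
#' @param tolerances an [identify_tolerances()].
#' @param spectra optional named list of [spectrum()] objects keyed by
#'   `spectrum_id`.
#' @return A list of class `identmix_result`: `identifications` (data frame
#'   with name, compound, status, expected/updated retention, observed
#'   pattern, notes), `library` (updated `identmix_library`), `support`
#'   (named list of supporting-peak data frames) and `swaps`.
#' @export
identify_batch <- function(library, design, runs, ladders = NULL,
                           tolerances = identify_tolerances(),
                           spectra = NULL) {
  stopifnot(inherits(library, "identmix_library"),
            inherits(design, "identmix_design"))
  if (!setequal(names(runs), design$labels)) {
    stop("run labels {", paste(names(runs), collapse = ","),
         "} do not match the design labels {",
         paste(design$labels, collapse = ","), "}")
  }
  coded <- vapply(library$entries, function(e) !is.null(e$code), logical(1))
  bad <- vapply(library$entries[coded], function(e)
    !all(e$code %in% design$labels), logical(1))
  if (any(bad)) {
    stop("entries with pair-codes outside the design: ",
         paste(names(library$entries[coded])[bad], collapse = ", "))
  }

  pt <- build_peak_table(runs, ladders, tolerances)
  cand <- lapply(library$entries, qualifying_peaks, pt = pt,
                 tol = tolerances, spectra = spectra)
  names(cand) <- names(library$entries)

  coded_nms <- names(library$entries)[coded]
  # connected components of entries sharing candidate peaks
  comp_id <- overlap_components(cand[coded_nms])

  assignments <- list()
  res_status <- stats::setNames(rep(NA_character_, length(coded_nms)), coded_nms)
  swaps <- character()
  for (cc in split(coded_nms, comp_id)) {
    claims <- lapply(cc, function(nm) list(
      code = library$entries[[nm]]$code,
      expected = if (tolerances$mode == "rt") library$entries[[nm]]$rt
                 else library$entries[[nm]]$ri,
      candidates = cand[[nm]]))
    names(claims) <- cc
    r <- resolve_isomers(claims, pair_tol = tolerances$pair_tol)
    assignments <- c(assignments, r$assignments)
    res_status[cc] <- r$status[cc]
    swaps <- c(swaps, r$swaps)
  }

  assigned_ids <- unlist(lapply(assignments, function(a) a$peak_id))
  entries_new <- library$entries
  rows <- vector("list", length(library$entries))
  support <- list()

  for (i in seq_along(library$entries)) {
    nm <- names(library$entries)[i]
    e <- library$entries[[i]]
    q <- cand[[nm]]
    notes <- character()
    updated <- NA_real_
    if (is.null(e$code)) {
      status <- if (nrow(q)) "unvalidated" else "not_found"
      obs_mixes <- unique(q$mix)
      if (status == "unvalidated") notes <- "no pair-code; retention/spectrum match only"
    } else {
      own <- assignments[[nm]]
      resid <- q[!(q$peak_id %in% assigned_ids), , drop = FALSE]
      obs_mixes <- unique(c(if (!is.null(own)) own$mix, resid$mix))
      observed <- stats::setNames(design$labels %in% obs_mixes, design$labels)
      if (identical(res_status[nm], "ambiguous")) {
        status <- "ambiguous"
        notes <- "identical pair-code competitor claims the same peaks"
      } else if (!is.null(own)) {
        status <- match_pattern(observed, e$code)
        if (status == "confirmed") {
          updated <- stats::weighted.mean(own$value, own$intensity)
          if (tolerances$mode == "rt") entries_new[[i]]$rt <- updated
          else entries_new[[i]]$ri <- updated
          support[[nm]] <- own
        } else {
          notes <- "unexplained peak(s) in a non-code mixture"
        }
      } else {
        status <- if (length(obs_mixes) == 0L) "not_found" else "conflict"
        if (status == "conflict") {
          notes <- "no retention-consistent peak pair in the code mixtures"
        }
      }
    }
    rows[[i]] <- data.frame(
      name = nm, compound = e$compound, class = e$class, status = status,
      expected = if (tolerances$mode == "rt") e$rt else e$ri,
      observed_pattern = paste(sort(obs_mixes), collapse = "+"),
      updated = updated,
      n_candidates = nrow(q),
      notes = paste(notes, collapse = "; "),
      stringsAsFactors = FALSE)
  }

  ids <- do.call(rbind, rows)
  value_name <- if (tolerances$mode == "rt") "rt" else "ri"
  names(ids)[names(ids) == "expected"] <- paste0("expected_", value_name)
  names(ids)[names(ids) == "updated"] <- paste0("updated_", value_name)
  structure(list(identifications = ids,
                 library = compound_library(entries_new, library$metadata),
                 support = support, swaps = swaps,
                 tolerances = tolerances),
            class = "identmix_result")
}

# Component labels for entries sharing at least one candidate peak.
overlap_components <- function(cand) {
  nms <- names(cand)
  if (!length(nms)) return(integer())
  comp <- seq_along(nms)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  peak_owner <- list()
  for (i in seq_along(nms)) {
    for (p in cand[[i]]$peak_id) {
      j <- peak_owner[[p]]
      if (is.null(j)) peak_owner[[p]] <- i
      else { ri_ <- find(i); rj <- find(j); if (ri_ != rj) comp[ri_] <- rj }
    }
  }
  vapply(seq_along(nms), find, integer(1))
}

#' @export
print.identmix_result <- function(x, ...) {
  tab <- table(x$identifications$status)
  cat("<identification result: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Write an identification report (TSV + optional JSON summary)
#'
#' @param result an `identmix_result` from [identify_batch()].
#' @param tsv_path output table path.
#' @param json_path optional JSON summary path.
#' @return `tsv_path`, invisibly.
#' @export
write_identification_report <- function(result, tsv_path, json_path = NULL) {
  stopifnot(inherits(result, "identmix_result"))
  utils::write.table(result$identifications, tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(json_path)) {
    tab <- as.list(table(result$identifications$status))
    jsonlite::write_json(list(status_counts = tab, n_swaps = length(result$swaps)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
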