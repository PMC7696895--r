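#' n-alkane retention ladder
#'
#' The set of (carbon number, retention time) anchors measured in-run, used
#' to convert retention times to retention indices. Carbon numbers and
#' retention times must both be strictly increasing and at least two anchors
#' are required.
#'
#' @param carbon integer carbon numbers, e.g. `c(10, 12, 15, ...)`.
#' @param rt retention times in seconds, same length.
#' @return An object of class `identmix_ladder`.
#' @export
alkane_ladder <- function(carbon, rt) {
  carbon <- as.numeric(carbon)
  rt <- as.numeric(rt)
  if (length(carbon) < 2L || length(carbon) != length(rt)) {
    stop("a ladder needs >= 2 (carbon, rt) anchors of equal length")
  }
  o <- order(carbon)
  carbon <- carbon[o]; rt <- rt[o]
  if (any(diff(carbon) <= 0)) stop("carbon numbers must be distinct")
  if (any(diff(rt) <= 0)) stop("retention times must be strictly increasing with carbon number")
  structure(list(carbon = carbon, rt = rt), class = "identmix_ladder")
}

#' Default alkane ladder (C10-C36)
#'
#' The marker set used throughout this package's simulations: C10, C12,
#' C15, C17, C19, C22, C28, C32 and C36 (C17 rather than C18, keeping the
#' RI 1800 region free for analyte peaks), with retention times from a
#' simple linear elution model (60 s per carbon).
#'
#' @param carbons carbon numbers of the markers.
#' @param rt retention times in seconds; defaults to `60 * carbons`.
#' @return An `identmix_ladder`.
#' @export
default_alkane_ladder <- function(carbons = c(10, 12, 15, 17, 19, 22, 28, 32, 36),
                                  rt = 60 * carbons) {
  alkane_ladder(carbons, rt)
}

#' @export
print.identmix_ladder <- function(x, ...) {
  cat(sprintf("<alkane ladder: C%s, rt %.0f-%.0f s>\n",
              paste(x$carbon, collapse = "/C"), min(x$rt), max(x$rt)), sep = "")
  invisible(x)
}

#' Retention index from retention time (van den Dool-Kratz)
#'
#' Linear interpolation between the bracketing alkane anchors, as
#' appropriate for temperature-programmed GC:
#' `RI = 100 * (n_i + (n_{i+1} - n_i) * (rt - rt_i) / (rt_{i+1} - rt_i))`.
#' Every anchor maps exactly to 100 times its carbon number, and the
#' mapping is monotone in rt. Beyond the first/last anchor the terminal
#' segment is continued linearly; such values are flagged in the
#' `"extrapolated"` attribute.
#'
#' @param rt numeric vector of retention times (seconds).
#' @param ladder an [alkane_ladder()].
#' @return Numeric vector of retention indices with a logical attribute
#'   `extrapolated`.
#' @examples
#' lad <- alkane_ladder(c(10, 12), c(300, 420))
#' compute_ri(360, lad)  # 1100
#' @export
compute_ri <- function(rt, ladder) {
  stopifnot(inherits(ladder, "identmix_ladder"))
  if (any(!is.finite(rt))) stop("retention times must be finite")
  i <- findInterval(rt, ladder$rt, all.inside = TRUE)
  c0 <- ladder$carbon[i]; c1 <- ladder$carbon[i + 1L]
  t0 <- ladder$rt[i]; t1 <- ladder$rt[i + 1L]
  ri <- 100 * (c0 + (c1 - c0) * (rt - t0) / (t1 - t0))
  attr(ri, "extrapolated") <- rt < ladder$rt[1L] | rt > ladder$rt[length(ladder$rt)]
  ri
}

#' Retention time for a retention index (inverse mapping)
#'
#' Exact inverse of [compute_ri()] on the piecewise-linear ladder map; used
#' to place expected-RI search windows on the time axis.
#'
#' @param ri numeric vector of retention indices.
#' @param ladder an [alkane_ladder()].
#' @return Numeric vector of retention times (seconds).
#' @export
rt_for_ri <- function(ri, ladder) {
  stopifnot(inherits(ladder, "identmix_ladder"))
  if (any(!is.finite(ri))) stop("retention indices must be finite")
  cn <- ri / 100
  i <- findInterval(cn, ladder$carbon, all.inside = TRUE)
  c0 <- ladder$carbon[i]; c1 <- ladder$carbon[i + 1L]
  t0 <- ladder$rt[i]; t1 <- ladder$rt[i + 1L]
  t0 + (cn - c0) / (c1 - c0) * (t1 - t0)
}

#' Read / write an alkane ladder TSV
#'
#' Two tab-separated columns `carbon_number` and `rt_seconds`, header row.
#'
#' @param path file path.
#' @param ladder an `identmix_ladder`.
#' @return `read_ladder_tsv()` returns an `identmix_ladder`;
#'   `write_ladder_tsv()` returns `path` invisibly.
#' @export
read_ladder_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t")
  if (!all(c("carbon_number", "rt_seconds") %in% names(d))) {
    stop("ladder TSV needs columns carbon_number, rt_seconds")
  }
  alkane_ladder(d$carbon_number, d$rt_seconds)
}

#' @rdname read_ladder_tsv
#' @export
write_ladder_tsv <- function(ladder, path) {
  stopifnot(inherits(ladder, "identmix_ladder"))
  utils::write.table(
    data.frame(carbon_number = ladder$carbon, rt_seconds = ladder$rt),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-setup retention shift report
#'
#' Compares retention values (RI or RT) of the compounds shared by two
#' setups: per-compound deltas (`b - a`), summary statistics, a fixed-width
#' histogram, and the list of elution-order inversions — compound pairs
#' whose retention order differs between the setups, the situation that
#' defeats identification by stored retention alone.
#'
#' @param a,b named numeric vectors (compound -> retention value) for the
#'   two setups; only the shared names are compared.
#' @param bin_width histogram bin width (default 5: RI units for GC,
#'   seconds for LC).
#' @return A list of class `identmix_shift_report`: `per_compound` (data
#'   frame compound/value_a/value_b/delta), `summary` (mean, median, sd),
#'   `histogram` (bin_start, count) and `inversions` (data frame of
#'   disagreeing pairs).
#' @export
shift_report <- function(a, b, bin_width = 5) {
  if (is.null(names(a)) || is.null(names(b))) stop("a and b must be named")
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("no shared compounds between the two setups")
  va <- a[shared]; vb <- b[shared]
  delta <- unname(vb - va)
  per <- data.frame(compound = shared, value_a = unname(va),
                    value_b = unname(vb), delta = delta,
                    stringsAsFactors = FALSE)
  smry <- c(mean = mean(delta), median = stats::median(delta),
            sd = if (length(delta) > 1) stats::sd(delta) else NA_real_)
  lo <- floor(min(delta) / bin_width) * bin_width
  hi <- ceiling(max(delta) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cnt <- table(cut(delta, breaks = breaks, right = FALSE,
                   include.lowest = TRUE))
  hist <- data.frame(bin_start = breaks[-length(breaks)],
                     count = as.integer(cnt))
  inv <- inversion_pairs(va, vb)
  structure(list(per_compound = per, summary = smry, histogram = hist,
                 inversions = inv),
            class = "identmix_shift_report")
}

# All pairs whose retention order strictly disagrees between the setups.
inversion_pairs <- function(va, vb) {
  n <- length(va)
  if (n < 2L) {
    return(data.frame(compound_1 = character(), compound_2 = character()))
  }
  da <- outer(va, va, `-`)
  db <- outer(vb, vb, `-`)
  bad <- which(da * db < 0 & upper.tri(da), arr.ind = TRUE)
  data.frame(compound_1 = names(va)[bad[, 1]],
             compound_2 = names(va)[bad[, 2]],
             stringsAsFactors = FALSE)
}

#' @export
print.identmix_shift_report <- function(x, ...) {
  cat(sprintf("<shift report: %d shared compounds, mean delta %.2f, %d inversion(s)>\n",
              nrow(x$per_compound), x$summary["mean"], nrow(x$inversions)))
  invisible(x)
}

#' Write a shift report (TSV table + JSON summary)
#'
#' @param report an `identmix_shift_report`.
#' @param tsv_path path for the per-compound table.
#' @param json_path optional path for the JSON summary.
#' @return `tsv_path`, invisibly.
#' @export
write_shift_report <- function(report, tsv_path, json_path = NULL) {
  stopifnot(inherits(report, "identmix_shift_report"))
  utils::write.table(report$per_compound, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = as.list(report$summary),
           n_shared = nrow(report$per_compound),
           n_inversions = nrow(report$inversions)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Groups of library entries within an RI tolerance
#'
#' Single-linkage grouping on the RI axis: entries are chained into one
#' group whenever consecutive expected RIs are no more than `tolerance`
#' apart. These groups are the ambiguity-risk sets — the entries a retention
#' shift of the tolerance's magnitude could confuse, and hence the natural
#' candidates for DISTINCT constraints in [assign_codes()].
#'
#' @param library an `identmix_library` whose entries have expected RIs.
#' @param tolerance RI units; `0` groups only exact ties.
#' @return List of character vectors (encoded entry names), one per group
#'   with two or more members.
#' @export
ambiguity_risk <- function(library, tolerance) {
  stopifnot(inherits(library, "identmix_library"), tolerance >= 0)
  ris <- vapply(library$entries, function(e) e$ri, numeric(1))
  if (any(is.na(ris))) {
    stop("entries without expected RI: ",
         paste(names(ris)[is.na(ris)], collapse = ", "))
  }
  o <- order(ris)
  ris <- ris[o]
  grp <- cumsum(c(1, diff(ris) > tolerance))
  groups <- split(names(ris), grp)
  unname(groups[lengths(groups) >= 2L])
}
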