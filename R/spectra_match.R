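#' Spectral match factor (weighted cosine, 0-1000)
#'
#' Stein-Scott weighted dot product between two spectra. Peaks are first
#' binned on the m/z axis (unit bins by default, intensities summed within a
#' bin), each bin is weighted as `intensity^a * mz^b` with the standard
#' defaults a = 0.6 and b = 3, and the score is
#' `1000 * (sum(wq * wr))^2 / (sum(wq^2) * sum(wr^2))` over the bin union,
#' rounded to the nearest integer. Identical spectra score 1000; spectra
#' with no shared bins score 0.
#'
#' In `"reverse"` mode (the reverse match factor, RMF) the comparison is
#' restricted to bins occupied by the reference, so extra peaks in the query
#' — impurities, coeluting material — do not penalise the score. This is the
#' score of choice when matching a measured, possibly contaminated spectrum
#' against a clean library reference.
#'
#' @param query,reference [spectrum()] objects.
#' @param mode `"forward"` or `"reverse"`.
#' @param intensity_exponent weight exponent a on intensity (default 0.6).
#' @param mz_exponent weight exponent b on m/z (default 3).
#' @param bin_width m/z bin width in Th (default 1).
#' @return Integer score in `[0, 1000]`.
#' @examples
#' q <- spectrum(c(73, 147, 205), c(100, 50, 10))
#' r <- spectrum(c(73, 147), c(100, 50))
#' match_factor(q, r, "reverse")  # 1000: query-only m/z 205 is ignored
#' match_factor(q, r, "forward") < 1000
#' @export
match_factor <- function(query, reference, mode = c("forward", "reverse"),
                         intensity_exponent = 0.6, mz_exponent = 3,
                         bin_width = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(query, "identmix_spectrum"),
            inherits(reference, "identmix_spectrum"))
  q <- bin_spectrum(query, bin_width)
  r <- bin_spectrum(reference, bin_width)
  bins <- if (mode == "reverse") r$bin else sort(union(q$bin, r$bin))
  wq <- weight_vec(q, bins, intensity_exponent, mz_exponent, bin_width)
  wr <- weight_vec(r, bins, intensity_exponent, mz_exponent, bin_width)
  num <- sum(wq * wr)^2
  den <- sum(wq^2) * sum(wr^2)
  if (den == 0) return(0L)
  as.integer(round(1000 * num / den))
}

# Sum intensities into m/z bins; bin index = round(mz / bin_width).
bin_spectrum <- function(sp, bin_width) {
  bin <- as.integer(round(sp$mz / bin_width))
  it <- as.numeric(tapply(sp$intensity, factor(bin, levels = unique(bin)), sum))
  list(bin = unique(bin), intensity = it)
}

weight_vec <- function(binned, bins, a, b, bin_width) {
  it <- stats::setNames(binned$intensity, binned$bin)[as.character(bins)]
  it[is.na(it)] <- 0
  unname(it^a * (bins * bin_width)^b)
}

#' Forward and reverse match in one call
#'
#' @inheritParams match_factor
#' @return A list of class `identmix_match` with `forward`, `reverse`
#'   and `shared_peaks` (number of shared m/z bins).
#' @export
match_result <- function(query, reference, intensity_exponent = 0.6,
                         mz_exponent = 3, bin_width = 1) {
  q <- bin_spectrum(query, bin_width)
  r <- bin_spectrum(reference, bin_width)
  structure(
    list(forward = match_factor(query, reference, "forward",
                                intensity_exponent, mz_exponent, bin_width),
         reverse = match_factor(query, reference, "reverse",
                                intensity_exponent, mz_exponent, bin_width),
         shared_peaks = length(intersect(q$bin, r$bin))),
    class = "identmix_match")
}

#' @export
print.identmix_match <- function(x, ...) {
  cat(sprintf("<match: forward %d, reverse %d, %d shared peak bin(s)>\n",
              x$forward, x$reverse, x$shared_peaks))
  invisible(x)
}

#' Pairwise match-factor matrix over a library
#'
#' Entry `[i, j]` scores entry i as the query against entry j as the
#' reference. In forward mode the matrix is symmetric (cosine); in reverse
#' mode it is directional — the direction of comparison matters, since only
#' the reference's peaks enter the score.
#'
#' @param library an `identmix_library`; every entry must carry a spectrum.
#' @param mode `"forward"` or `"reverse"`.
#' @param ... passed to [match_factor()].
#' @return An integer matrix with encoded entry names as dimnames.
#' @export
pairwise_matrix <- function(library, mode = c("forward", "reverse"), ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "identmix_library"))
  missing_sp <- vapply(library$entries, function(e) is.null(e$spectrum), logical(1))
  if (any(missing_sp)) {
    stop("entries without spectra: ",
         paste(names(library$entries)[missing_sp], collapse = ", "))
  }
  n <- length(library$entries)
  nms <- names(library$entries)
  m <- matrix(0L, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- match_factor(library$entries[[i]]$spectrum,
                              library$entries[[j]]$spectrum, mode, ...)
    }
  }
  m
}

#' Write a score matrix as TSV with entry-name headers
#'
#' @param m matrix from [pairwise_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(name = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
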