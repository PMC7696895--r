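#' Construct a mass spectrum
#'
#' A spectrum is a set of (m/z, intensity) peaks. Peaks are sorted by m/z on
#' construction and duplicate m/z values are summed, so the stored form always
#' has strictly increasing m/z. Intensities must be non-negative and at least
#' one peak is required.
#'
#' @param mz numeric vector of mass-to-charge values (Th).
#' @param intensity numeric vector of abundances, same length as `mz`.
#' @return An object of class `identmix_spectrum` with elements `mz` and
#'   `intensity`.
#' @examples
#' sp <- spectrum(c(147, 73), c(50, 100))
#' sp$mz  # sorted: 73 147
#' @export
spectrum <- function(mz, intensity) {
  if (!is.numeric(mz) || !is.numeric(intensity)) {
    stop("mz and intensity must be numeric")
  }
  if (length(mz) == 0L) stop("a spectrum needs at least one peak")
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("mz and intensity must be finite")
  }
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(mz = mz, intensity = intensity), class = "identmix_spectrum")
}

#' Normalize a spectrum to the msp base-peak convention
#'
#' Scales intensities so the base (most intense) peak equals `base`
#' (999 by msp convention).
#'
#' @param x an `identmix_spectrum`.
#' @param base intensity assigned to the base peak.
#' @return A normalized `identmix_spectrum`.
#' @export
normalize_spectrum <- function(x, base = 999) {
  stopifnot(inherits(x, "identmix_spectrum"))
  spectrum(x$mz, x$intensity / max(x$intensity) * base)
}

#' @export
print.identmix_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d peaks, m/z %.4g-%.4g, base %.4g>\n",
              length(x$mz), min(x$mz), max(x$mz), max(x$intensity)))
  invisible(x)
}
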