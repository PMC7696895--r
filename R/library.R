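#' Construct a compound library entry
#'
#' One library entry is one chromatographic peak of one derivatisation
#' product of one compound. A compound that yields several derivatisation
#' products (a common situation with MeOX/TMS chemistry) therefore owns
#' several entries, distinguished by the derivatisation state and the
#' product rank ("MP" marks the main product, "BP" a by-product).
#'
#' Entry identity is carried in a single machine-readable encoded name,
#' `Compound_Derivatisationstate_Rank_RI:<int>_IDENT:<labels>` (see
#' [encode_name()]); for that convention to stay parseable the compound name
#' and derivatisation state must not contain an underscore.
#'
#' @param compound compound name, e.g. `"Alanine"`. No underscores.
#' @param derivatisation derivatisation state, e.g. `"(3TMS)"` or
#'   `"(MeOX)(5TMS)"`. No underscores.
#' @param rank derivatisation-product rank: `"MP"` (main product), `"BP"`
#'   (by-product) or `NA`.
#' @param ri expected retention index (RI units), or `NA`.
#' @param rt expected retention time (seconds), or `NA`.
#' @param code Ident-Mix pair-code: character vector of exactly two distinct
#'   mixture labels, or `NULL` when the entry is not part of a design.
#' @param spectrum optional [spectrum()].
#' @param class optional compound-class label (e.g. `"Hexoses"`).
#' @return An object of class `identmix_entry`.
#' @examples
#' library_entry("Alanine", "(3TMS)", rank = "MP", ri = 1367, code = c("B", "C"))
#' @export
library_entry <- function(compound, derivatisation, rank = NA_character_,
                          ri = NA_real_, rt = NA_real_, code = NULL,
                          spectrum = NULL, class = NA_character_) {
  if (!is.character(compound) || length(compound) != 1L || !nzchar(compound)) {
    stop("compound must be a non-empty string")
  }
  if (grepl("_", compound, fixed = TRUE)) {
    stop("compound name must not contain '_' (reserved as the name-field separator): ",
         compound)
  }
  if (!is.character(derivatisation) || length(derivatisation) != 1L ||
      !nzchar(derivatisation)) {
    stop("derivatisation state must be a non-empty string")
  }
  if (grepl("_", derivatisation, fixed = TRUE)) {
    stop("derivatisation state must not contain '_': ", derivatisation)
  }
  rank <- as.character(rank)
  if (!is.na(rank) && !rank %in% c("MP", "BP")) {
    stop("rank must be 'MP', 'BP' or NA")
  }
  if (!is.null(code)) {
    code <- validate_pair_code(code)
  }
  ri <- as.numeric(ri)
  rt <- as.numeric(rt)
  if (is.na(ri) && is.na(rt) && is.null(spectrum)) {
    stop("an entry needs at least one of: expected RI, expected RT, a spectrum")
  }
  if (!is.null(spectrum) && !inherits(spectrum, "identmix_spectrum")) {
    stop("spectrum must be an identmix_spectrum")
  }
  structure(
    list(compound = compound, derivatisation = derivatisation, rank = rank,
         ri = ri, rt = rt, code = code, spectrum = spectrum,
         class = as.character(class), extra = character()),
    class = "identmix_entry"
  )
}

# Pair-code sanity shared by library_entry() and mix_design().
validate_pair_code <- function(code) {
  code <- as.character(code)
  if (length(code) != 2L || anyDuplicated(code)) {
    stop("a pair-code is exactly two distinct mixture labels")
  }
  if (any(grepl("[+_]", code)) || any(!nzchar(code))) {
    stop("mixture labels must be non-empty and free of '+' and '_'")
  }
  sort(code)
}

#' @export
print.identmix_entry <- function(x, ...) {
  cat("<entry> ", encode_name(x), "\n", sep = "")
  invisible(x)
}

#' Encode a library entry name
#'
#' Joins the entry fields with underscores in the fixed order
#' compound, derivatisation state, product rank, `RI:<int>` (and/or
#' `RT:<int>` seconds when only a retention time is known), and
#' `IDENT:<label>+<label>`. Unset fields are omitted, so e.g. an entry
#' without a pair-code encodes as `"X_(2TMS)_RI:1000"`. The RI is rendered
#' as the nearest integer; internally it stays a float.
#'
#' @param entry an `identmix_entry`.
#' @return The encoded name, a single string.
#' @examples
#' e <- library_entry("Alanine", "(3TMS)", "MP", ri = 1367, code = c("B", "C"))
#' encode_name(e)  # "Alanine_(3TMS)_MP_RI:1367_IDENT:B+C"
#' @seealso [parse_name()] for the inverse.
#' @export
encode_name <- function(entry) {
  stopifnot(inherits(entry, "identmix_entry"))
  parts <- c(entry$compound, entry$derivatisation)
  if (!is.na(entry$rank)) parts <- c(parts, entry$rank)
  if (!is.na(entry$ri)) parts <- c(parts, sprintf("RI:%d", as.integer(round(entry$ri))))
  if (is.na(entry$ri) && !is.na(entry$rt)) {
    parts <- c(parts, sprintf("RT:%d", as.integer(round(entry$rt))))
  }
  if (!is.null(entry$code)) {
    parts <- c(parts, paste0("IDENT:", paste(entry$code, collapse = "+")))
  }
  paste(parts, collapse = "_")
}

#' Parse an encoded library-entry name
#'
#' Splits on underscores: the first two fields are always the compound name
#' and the derivatisation state (their concatenation, split after the second
#' underscore, is the compound display identity used in figures). Every later
#' field is recognised by its form — `MP`/`BP` as the product rank,
#' `RI:<int>` / `RT:<int>` as expected retention, `IDENT:A+B` as the
#' pair-code — regardless of position; unrecognised trailing fields are kept
#' verbatim in `$extra`.
#'
#' @param name an encoded name, e.g. `"Alanine_(3TMS)_MP_RI:1367_IDENT:B+C"`.
#' @return A list with elements `compound`, `derivatisation`, `rank`, `ri`,
#'   `rt`, `code`, `extra` and `display` (the display identity).
#' @export
parse_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3L) {
    stop("cannot parse '", name,
         "': expected at least compound, derivatisation state and one more field")
  }
  out <- list(compound = parts[1], derivatisation = parts[2],
              rank = NA_character_, ri = NA_real_, rt = NA_real_,
              code = NULL, extra = character(),
              display = paste(parts[1:2], collapse = "_"))
  for (p in parts[-(1:2)]) {
    if (p %in% c("MP", "BP")) {
      out$rank <- p
    } else if (startsWith(p, "RI:")) {
      v <- substring(p, 4)
      if (!grepl("^-?[0-9]+$", v)) {
        stop("malformed RI segment '", p, "' in name '", name, "'")
      }
      out$ri <- as.numeric(v)
    } else if (startsWith(p, "RT:")) {
      v <- substring(p, 4)
      if (!grepl("^-?[0-9]+$", v)) {
        stop("malformed RT segment '", p, "' in name '", name, "'")
      }
      out$rt <- as.numeric(v)
    } else if (startsWith(p, "IDENT:")) {
      out$code <- validate_pair_code(strsplit(substring(p, 7), "+", fixed = TRUE)[[1]])
    } else {
      out$extra <- c(out$extra, p)
    }
  }
  out
}

# Rebuild an identmix_entry from parsed name fields (+ optional spectrum).
entry_from_parsed <- function(p, spectrum = NULL, class = NA_character_) {
  e <- library_entry(p$compound, p$derivatisation, rank = p$rank,
                     ri = p$ri, rt = p$rt, code = p$code,
                     spectrum = spectrum, class = class)
  e$extra <- p$extra
  e
}

#' Construct a compound library
#'
#' An ordered collection of [library_entry()] objects plus free-form
#' provenance metadata (batch date, column, setup id, ...). Encoded names
#' must be unique; several entries per compound are expected when a compound
#' yields several derivatisation products.
#'
#' @param entries list of `identmix_entry` objects.
#' @param metadata named list of provenance fields.
#' @return An object of class `identmix_library`.
#' @export
compound_library <- function(entries, metadata = list()) {
  if (!is.list(entries) || length(entries) == 0L ||
      !all(vapply(entries, inherits, logical(1), "identmix_entry"))) {
    stop("entries must be a non-empty list of identmix_entry objects")
  }
  nms <- vapply(entries, encode_name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate encoded names in library: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(entries) <- nms
  structure(list(entries = entries, metadata = metadata),
            class = "identmix_library")
}

#' @export
print.identmix_library <- function(x, ...) {
  cat(sprintf("<compound library: %d entries>\n", length(x$entries)))
  nms <- utils::head(vapply(x$entries, encode_name, character(1)), 5)
  cat(paste0("  ", nms), sep = "\n")
  if (length(x$entries) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
length.identmix_library <- function(x) length(x$entries)

#' Read / write a NIST-flavour msp spectral library
#'
#' `read_msp()` parses the plain-text NIST msp dialect: records separated by
#' blank lines, `Name:` / `Comment:` / `Num Peaks:` headers, then peak lines
#' of `mz intensity;` pairs. Unrecognised headers (`Synon:`, `CAS#:`, ...)
#' are preserved verbatim per entry and written back by `write_msp()`.
#' Entry names are expected to follow the encoded-name convention; names
#' that do not parse are kept as compound = full name with derivatisation
#' state `"(?)"`.
#'
#' @param path file path.
#' @param library an `identmix_library` whose entries carry spectra.
#' @return `read_msp()` returns an `identmix_library`; `write_msp()` returns
#'   `path` invisibly.
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1]))
  grp[blank] <- NA
  entries <- list()
  for (g in unique(stats::na.omit(grp))) {
    block <- lines[which(grp == g)]
    if (!length(block)) next
    entries[[length(entries) + 1L]] <- parse_msp_block(block)
  }
  if (!length(entries)) stop("no entries found in msp file: ", path)
  compound_library(entries, metadata = list(source = path))
}

parse_msp_block <- function(block) {
  is_header <- grepl("^[A-Za-z][A-Za-z0-9 #_.-]*:", block)
  headers <- block[is_header]
  key <- sub(":.*$", "", headers)
  val <- trimws(sub("^[^:]*:", "", headers))
  nm <- val[match("Name", key)]
  if (is.na(nm)) stop("msp entry without a Name: header")
  npk_raw <- val[match("Num Peaks", key)]
  if (is.na(npk_raw)) stop("msp entry '", nm, "' lacks a 'Num Peaks:' header")
  npk <- as.integer(npk_raw)
  peak_lines <- block[!is_header]
  toks <- unlist(strsplit(paste(peak_lines, collapse = " "), "[;,]"))
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  pairs <- strsplit(toks, "[[:space:]]+")
  ok <- lengths(pairs) == 2L
  mz <- as.numeric(vapply(pairs[ok], `[`, character(1), 1))
  it <- as.numeric(vapply(pairs[ok], `[`, character(1), 2))
  if (length(mz) != npk || any(is.na(mz)) || any(is.na(it))) {
    stop("msp entry '", nm, "': Num Peaks (", npk,
         ") does not match the ", length(mz), " peaks listed")
  }
  sp <- spectrum(mz, it)
  p <- tryCatch(parse_name(nm), error = function(e) NULL)
  e <- if (is.null(p)) {
    library_entry(gsub("_", " ", nm), "(?)", spectrum = sp)
  } else {
    entry_from_parsed(p, spectrum = sp)
  }
  keep <- !key %in% c("Name", "Num Peaks")
  e$extra_headers <- stats::setNames(val[keep], key[keep])
  e
}

#' @rdname read_msp
#' @export
write_msp <- function(library, path) {
  stopifnot(inherits(library, "identmix_library"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (e in library$entries) {
    if (is.null(e$spectrum)) {
      stop("entry without spectrum cannot be written to msp: ", encode_name(e))
    }
    writeLines(paste0("Name: ", encode_name(e)), con)
    for (k in names(e$extra_headers %||% character())) {
      writeLines(paste0(k, ": ", e$extra_headers[[k]]), con)
    }
    sp <- e$spectrum
    writeLines(sprintf("Num Peaks: %d", length(sp$mz)), con)
    pairs <- sprintf("%.6g %.6g;", sp$mz, sp$intensity)
    idx <- split(pairs, (seq_along(pairs) - 1L) %/% 5L)
    writeLines(vapply(idx, paste, character(1), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a compound library as TSV
#'
#' Tab-separated, UTF-8, header row with columns `name` (compound),
#' `derivatisation`, `rank`, `ri`, `rt`, `ident_code` (labels joined by
#' `+`), `class`. Spectra are not carried by the TSV form; pair them via
#' [read_msp()] when needed.
#'
#' @param path file path.
#' @param library an `identmix_library`.
#' @return `read_library_tsv()` returns an `identmix_library`;
#'   `write_library_tsv()` returns `path` invisibly.
#' @export
read_library_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), check.names = FALSE)
  need <- c("name", "derivatisation")
  if (!all(need %in% names(d))) {
    stop("library TSV needs at least columns: ", paste(need, collapse = ", "))
  }
  entries <- lapply(seq_len(nrow(d)), function(i) {
    code <- d$ident_code[i]
    code <- if (is.null(code) || is.na(code)) NULL else
      strsplit(code, "+", fixed = TRUE)[[1]]
    library_entry(
      d$name[i], d$derivatisation[i],
      rank = if ("rank" %in% names(d)) d$rank[i] else NA_character_,
      ri = if ("ri" %in% names(d)) d$ri[i] else NA_real_,
      rt = if ("rt" %in% names(d)) d$rt[i] else NA_real_,
      code = code,
      class = if ("class" %in% names(d)) d$class[i] else NA_character_
    )
  })
  compound_library(entries, metadata = list(source = path))
}

#' @rdname read_library_tsv
#' @export
write_library_tsv <- function(library, path) {
  stopifnot(inherits(library, "identmix_library"))
  rows <- lapply(library$entries, function(e) {
    data.frame(name = e$compound, derivatisation = e$derivatisation,
               rank = e$rank, ri = e$ri, rt = e$rt,
               ident_code = if (is.null(e$code)) NA_character_ else
                 paste(e$code, collapse = "+"),
               class = e$class, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
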