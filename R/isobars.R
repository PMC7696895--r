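#' Read a metabolite-database export as compound records
#'
#' Operates on flat TSV exports of compound tables (one row per compound)
#' rather than live database APIs. A column-mapping list adapts arbitrary
#' export schemas to the canonical record fields `id`, `name`, `formula`,
#' `mass`, `status`, `pathways` (a `;`-separated label set) and
#' `has_reaction`.
#'
#' @param path TSV file path.
#' @param cols named list mapping canonical field -> column name in the
#'   file. Only `id`, `name` and `mass` are required to exist.
#' @return A data frame of class `identmix_records` with the canonical
#'   columns.
#' @export
read_compound_records <- function(path,
                                  cols = list(id = "id", name = "name",
                                              formula = "formula",
                                              mass = "mass", status = "status",
                                              pathways = "pathways",
                                              has_reaction = "has_reaction")) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), check.names = FALSE)
  get <- function(field, default) {
    cn <- cols[[field]]
    if (!is.null(cn) && cn %in% names(d)) d[[cn]] else default
  }
  n <- nrow(d)
  out <- data.frame(
    id = as.character(get("id", seq_len(n))),
    name = as.character(get("name", NA_character_)),
    formula = as.character(get("formula", NA_character_)),
    mass = as.numeric(get("mass", NA_real_)),
    status = as.character(get("status", NA_character_)),
    pathways = as.character(get("pathways", NA_character_)),
    has_reaction = as.logical(get("has_reaction", NA)),
    stringsAsFactors = FALSE)
  if (any(!is.na(out$mass) & out$mass <= 0)) stop("masses must be > 0")
  class(out) <- c("identmix_records", "data.frame")
  out
}

#' Lipid text rule: two numbers separated by a colon
#'
#' Flags names containing a `digits:digits` substring, the chain-length /
#' double-bond notation carried by the majority of lipid names (e.g.
#' `PC(16:0/18:1)`). Being purely textual, the rule has documented false
#' positives (any name containing a ratio also matches).
#'
#' @param name character vector of compound names.
#' @return Logical vector.
#' @examples
#' is_lipid_name(c("PC(16:0/18:1)", "Glucose"))  # TRUE FALSE
#' @export
is_lipid_name <- function(name) {
  grepl("[0-9]+:[0-9]+", name)
}

#' Filter compound records with an audited rule chain
#'
#' Applies the standard database pre-filters in a fixed declared order,
#' recording how many records each rule removed:
#' `require_formula`, `require_reaction`, `organic_only` (formula contains
#' carbon), `max_mass` (e.g. 1500 Da), `lipid_exclusion`
#' ([is_lipid_name()]), `status_whitelist` (e.g. detected/quantified),
#' `pathway_whitelist`. Rules set to `NULL`/`FALSE` are skipped.
#'
#' @param records an `identmix_records` data frame.
#' @param rules named list; see Details above. `status_whitelist` and
#'   `pathway_whitelist` are character vectors, `max_mass` a number, the
#'   rest logical flags.
#' @return A list of class `identmix_filter` with `records` (the
#'   survivors) and `audit` (data frame rule/removed/remaining).
#' @export
filter_records <- function(records, rules = list()) {
  stopifnot(is.data.frame(records))
  audit <- data.frame(rule = character(), removed = integer(),
                      remaining = integer(), stringsAsFactors = FALSE)
  log_rule <- function(rule, keep) {
    audit <<- rbind(audit, data.frame(rule = rule, removed = sum(!keep),
                                      remaining = sum(keep)))
    records <<- records[keep, , drop = FALSE]
  }
  if (isTRUE(rules$require_formula)) {
    log_rule("require_formula", !is.na(records$formula) & nzchar(records$formula))
  }
  if (isTRUE(rules$require_reaction)) {
    log_rule("require_reaction", !is.na(records$has_reaction) & records$has_reaction)
  }
  if (isTRUE(rules$organic_only)) {
    log_rule("organic_only",
             !is.na(records$formula) & grepl("C(?![a-z])", records$formula, perl = TRUE))
  }
  if (!is.null(rules$max_mass)) {
    log_rule("max_mass", !is.na(records$mass) & records$mass <= rules$max_mass)
  }
  if (isTRUE(rules$lipid_exclusion)) {
    log_rule("lipid_exclusion", !is_lipid_name(records$name))
  }
  if (!is.null(rules$status_whitelist)) {
    known <- unique(records$status[!is.na(records$status)])
    unknown <- setdiff(rules$status_whitelist, known)
    if (length(unknown)) {
      warning("status value(s) not present in the records: ",
              paste(unknown, collapse = ", "))
    }
    log_rule("status_whitelist",
             !is.na(records$status) & records$status %in% rules$status_whitelist)
  }
  if (!is.null(rules$pathway_whitelist)) {
    pw <- strsplit(ifelse(is.na(records$pathways), "", records$pathways), ";",
                   fixed = TRUE)
    keep <- vapply(pw, function(p) any(trimws(p) %in% rules$pathway_whitelist),
                   logical(1))
    log_rule("pathway_whitelist", keep)
  }
  structure(list(records = records, audit = audit), class = "identmix_filter")
}

#' @export
print.identmix_filter <- function(x, ...) {
  cat(sprintf("<filtered records: %d surviving>\n", nrow(x$records)))
  print(x$audit)
  invisible(x)
}

# round half away from zero (so 0.5 -> 1, -0.5 -> -1), the documented
# integer-rounding rule for unit-resolution masses
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Isobar group size per compound
#'
#' For each record, the number of records (itself included) sharing its
#' molecular mass. `"exact"` resolution groups by stored mass rounded to 4
#' decimals (databases store fixed-precision values); `"unit"` resolution
#' first rounds masses to the nearest integer (half away from zero), the
#' low-resolution view of a unit-resolution mass spectrometer. Unit group
#' sizes are therefore always >= exact group sizes.
#'
#' @param records an `identmix_records` data frame (or any data frame with a
#'   numeric `mass` column).
#' @param resolution `"exact"` or `"unit"`.
#' @return Integer vector of group sizes, one per record, in input order.
#' @export
isobar_group_sizes <- function(records, resolution = c("exact", "unit")) {
  resolution <- match.arg(resolution)
  mass <- records$mass
  if (any(is.na(mass))) {
    stop("records without mass: ",
         paste(records$id[is.na(mass)], collapse = ", "))
  }
  key <- if (resolution == "unit") round_half_away(mass) else round(mass, 4)
  cnt <- table(key)
  as.integer(cnt[as.character(key)])
}

#' Cumulative isobar curve
#'
#' For each threshold t >= 0, the percentage of compounds having at least t
#' isobaric partners (group size minus one >= t). By construction the curve
#' starts at 100% for t = 0 and is non-increasing; the value at t = 1 is the
#' complement of the fraction of compounds with a unique mass.
#'
#' @param group_sizes integer vector from [isobar_group_sizes()].
#' @return Data frame with columns `threshold` and `percent`.
#' @export
cumulative_isobar_curve <- function(group_sizes) {
  if (!length(group_sizes)) stop("no group sizes supplied")
  partners <- group_sizes - 1L
  thresholds <- 0:max(partners)
  percent <- vapply(thresholds, function(t) 100 * mean(partners >= t),
                    numeric(1))
  data.frame(threshold = thresholds, percent = percent)
}

#' Maximum isobar group size per mass window
#'
#' Splits the mass axis into half-open windows `[w, w + width)` starting at
#' 0 and reports, for each window containing at least one record, the
#' maximum exact-resolution isobar group size among the records falling in
#' it — the view that shows where on the mass axis the isobar density
#' concentrates.
#'
#' @param records an `identmix_records` data frame.
#' @param window_width window width in Da (default 5).
#' @return Data frame with columns `window_start` and `max_count`.
#' @export
window_density <- function(records, window_width = 5) {
  stopifnot(window_width > 0)
  gs <- isobar_group_sizes(records, "exact")
  win <- floor(records$mass / window_width) * window_width
  agg <- tapply(gs, win, max)
  data.frame(window_start = as.numeric(names(agg)),
             max_count = as.integer(agg), row.names = NULL)
}

#' Write isobar statistics (sizes, curve, windows) as TSVs
#'
#' @param records an `identmix_records` data frame.
#' @param prefix output path prefix; writes `<prefix>_sizes.tsv`,
#'   `<prefix>_curve_exact.tsv`, `<prefix>_curve_unit.tsv`,
#'   `<prefix>_windows.tsv`.
#' @return The paths written, invisibly.
#' @export
write_isobar_stats <- function(records, prefix) {
  exact <- isobar_group_sizes(records, "exact")
  unit <- isobar_group_sizes(records, "unit")
  paths <- paste0(prefix, c("_sizes.tsv", "_curve_exact.tsv",
                            "_curve_unit.tsv", "_windows.tsv"))
  utils::write.table(
    data.frame(id = records$id, mass = records$mass,
               group_size_exact = exact, group_size_unit = unit),
    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cumulative_isobar_curve(exact), paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cumulative_isobar_curve(unit), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(window_density(records), paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
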