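#' Number of distinct pair-codes for k mixtures
#'
#' Each compound is spiked into exactly two of the k pooled mixtures, so the
#' number of distinguishable presence/absence patterns is the number of
#' unordered pairs, k(k-1)/2: 6 codes for four mixtures, 10 for five, 15 for
#' six. This bounds how many mutually similar compounds one design can
#' discriminate by pattern alone.
#'
#' @param k number of mixtures, integer >= 2.
#' @return Integer count of distinct pair-codes.
#' @examples
#' code_capacity(4)  # 6
#' @export
code_capacity <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 2) {
    stop("k must be a single integer >= 2")
  }
  as.integer(k * (k - 1) / 2)
}

#' Constraint graph over compounds for code assignment
#'
#' Three typed, mutually exclusive pairwise constraints steer [assign_codes()]:
#' \describe{
#'   \item{DISTINCT}{chemically similar compounds — their pair-codes must
#'     differ, so their presence patterns discriminate them.}
#'   \item{DISJOINT}{codes must share no mixture; the pair is never
#'     co-injected (e.g. keeping two potentially coeluting hexoses fully
#'     separated).}
#'   \item{OVERLAP_ONE}{codes share exactly one mixture, so one run shows
#'     whether the pair can still be separated when simultaneously present.}
#' }
#' DISJOINT and OVERLAP_ONE each imply DISTINCT.
#'
#' @param distinct,disjoint,overlap_one each a 2-column matrix or data frame
#'   of compound-id pairs (or `NULL`).
#' @return A data frame of class `identmix_constraints` with columns
#'   `a`, `b`, `type`.
#' @export
constraint_graph <- function(distinct = NULL, disjoint = NULL,
                             overlap_one = NULL) {
  pack <- function(x, type) {
    if (is.null(x) || NROW(x) == 0L) return(NULL)
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop(type, " constraints must have two columns")
    data.frame(a = as.character(x[, 1]), b = as.character(x[, 2]),
               type = type, stringsAsFactors = FALSE)
  }
  g <- rbind(pack(distinct, "DISTINCT"), pack(disjoint, "DISJOINT"),
             pack(overlap_one, "OVERLAP_ONE"))
  if (is.null(g)) {
    g <- data.frame(a = character(), b = character(), type = character(),
                    stringsAsFactors = FALSE)
  }
  if (any(g$a == g$b)) stop("self-constraints are not allowed")
  key <- paste(pmin(g$a, g$b), pmax(g$a, g$b))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("conflicting/duplicate constraints for pair(s): ",
         paste(unique(dup), collapse = "; "))
  }
  class(g) <- c("identmix_constraints", "data.frame")
  g
}

empty_constraints <- function() constraint_graph()

#' Construct a mix design
#'
#' @param k number of mixtures.
#' @param assignment named list: compound id -> character(2) pair of labels.
#' @param labels mixture labels, default `LETTERS[1:k]`.
#' @return An object of class `identmix_design`.
#' @export
mix_design <- function(k, assignment, labels = LETTERS[seq_len(k)]) {
  k <- as.integer(k)
  if (length(labels) != k || anyDuplicated(labels)) {
    stop("labels must be k distinct mixture labels")
  }
  if (any(grepl("[+_]", labels))) stop("mixture labels must not contain '+' or '_'")
  assignment <- lapply(assignment, validate_pair_code)
  bad <- vapply(assignment, function(cd) !all(cd %in% labels), logical(1))
  if (any(bad)) {
    stop("pair-codes outside the label set for: ",
         paste(names(assignment)[bad], collapse = ", "))
  }
  structure(list(k = k, labels = as.character(labels), assignment = assignment),
            class = "identmix_design")
}

#' @export
print.identmix_design <- function(x, ...) {
  cat(sprintf("<Ident-Mix design: k=%d (%s), %d compounds>\n", x$k,
              paste(x$labels, collapse = ""), length(x$assignment)))
  invisible(x)
}

#' Fraction of compounds present in each mixture
#'
#' With every compound in exactly two of k mixtures, a balanced design puts
#' 2/k of all compounds into each mixture — a 50% complexity reduction per
#' run at k = 4 — while retaining a duplicate measurement of each compound.
#'
#' @param design an `identmix_design`.
#' @return List with `theoretical` (2/k) and `per_mix`, the realised
#'   fraction for each mixture label.
#' @export
per_mix_fraction <- function(design) {
  stopifnot(inherits(design, "identmix_design"))
  n <- length(design$assignment)
  if (n == 0L) stop("design has no compounds")
  loads <- mix_loads(design)
  list(theoretical = 2 / design$k, per_mix = loads / n)
}

mix_loads <- function(design) {
  tab <- table(factor(unlist(design$assignment), levels = design$labels))
  stats::setNames(as.integer(tab), design$labels)
}

# Does `code` satisfy the typed constraint against `other` (a fixed code)?
code_ok <- function(code, other, type) {
  shared <- length(intersect(code, other))
  switch(type,
    DISTINCT = shared < 2L,
    DISJOINT = shared == 0L,
    OVERLAP_ONE = shared == 1L,
    stop("unknown constraint type: ", type)
  )
}

#' Assign pair-codes to compounds under constraints
#'
#' Backtracking search: compounds are ordered most-constrained-first (by
#' constraint degree, ties broken by a seeded shuffle) and candidate codes
#' are tried in order of current mixture load (so the design stays
#' balanced), ties again broken by the seeded order. The result is
#' deterministic given the seed. Infeasible inputs — a clique of mutually
#' DISTINCT compounds larger than [code_capacity()], or DISJOINT pairs with
#' fewer than four mixtures — are rejected with the offending clique/pair
#' named.
#'
#' @param compounds character vector of compound ids.
#' @param constraints a [constraint_graph()] (or `NULL` for none).
#' @param k number of mixtures.
#' @param labels mixture labels.
#' @param seed integer seed controlling tie-breaking.
#' @return An `identmix_design`.
#' @examples
#' d <- assign_codes(paste0("c", 1:6), k = 4, seed = 1)
#' mix_loads <- table(unlist(d$assignment))
#' @export
assign_codes <- function(compounds, constraints = NULL, k = 4,
                         labels = LETTERS[seq_len(k)], seed = 1) {
  compounds <- as.character(compounds)
  if (!length(compounds)) stop("no compounds to assign")
  if (anyDuplicated(compounds)) stop("duplicate compound ids")
  if (is.null(constraints)) constraints <- empty_constraints()
  cap <- code_capacity(k)

  cids <- unique(c(constraints$a, constraints$b))
  if (!all(cids %in% compounds)) {
    stop("constraints mention unknown compounds: ",
         paste(setdiff(cids, compounds), collapse = ", "))
  }
  if (k < 4 && any(constraints$type == "DISJOINT")) {
    i <- which(constraints$type == "DISJOINT")[1]
    stop("DISJOINT constraint (", constraints$a[i], ", ", constraints$b[i],
         ") is infeasible with k < 4")
  }
  # All three types imply the codes differ; a clique of such edges larger
  # than the code capacity cannot be coded.
  if (nrow(constraints) > 0) {
    g <- igraph::graph_from_data_frame(constraints[, c("a", "b")],
                                       directed = FALSE)
    if (igraph::clique_num(g) > cap) {
      cl <- igraph::largest_cliques(g)[[1]]
      stop("infeasible: ", length(cl), " mutually distinct compounds (",
           paste(names(cl), collapse = ", "), ") exceed the ", cap,
           " available pair-codes for k = ", k)
    }
  }

  all_codes <- utils::combn(labels, 2, simplify = FALSE)
  all_codes <- lapply(all_codes, sort)

  # adjacency: per compound, data frame of (other, type)
  adj <- stats::setNames(vector("list", length(compounds)), compounds)
  for (i in seq_len(nrow(constraints))) {
    a <- constraints$a[i]; b <- constraints$b[i]; ty <- constraints$type[i]
    adj[[a]] <- rbind(adj[[a]], data.frame(other = b, type = ty))
    adj[[b]] <- rbind(adj[[b]], data.frame(other = a, type = ty))
  }
  degree <- vapply(adj, NROW, integer(1))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  shuffle <- sample.int(length(compounds))
  code_tiebreak <- sample.int(length(all_codes))
  # backtracking is only needed where constraints bite; unconstrained
  # compounds are load-balanced greedily afterwards
  constrained <- compounds[degree > 0]
  free <- compounds[degree == 0]
  ord <- constrained[order(-degree[constrained],
                           shuffle[match(constrained, compounds)])]
  free <- free[order(shuffle[match(free, compounds)])]

  assignment <- list()
  load <- stats::setNames(integer(length(labels)), labels)

  try_assign <- function(idx) {
    if (idx > length(ord)) return(TRUE)
    cid <- ord[idx]
    nbr <- adj[[cid]]
    cand <- seq_along(all_codes)
    if (NROW(nbr)) {
      fixed <- nbr[nbr$other %in% names(assignment), , drop = FALSE]
      for (j in seq_len(NROW(fixed))) {
        other_code <- assignment[[fixed$other[j]]]
        cand <- cand[vapply(all_codes[cand], code_ok, logical(1),
                            other = other_code, type = fixed$type[j])]
      }
    }
    if (!length(cand)) return(FALSE)
    load_sum <- vapply(all_codes[cand], function(cd) sum(load[cd]), numeric(1))
    cand <- cand[order(load_sum, code_tiebreak[cand])]
    for (ci in cand) {
      cd <- all_codes[[ci]]
      assignment[[cid]] <<- cd
      load[cd] <<- load[cd] + 1L
      if (try_assign(idx + 1L)) return(TRUE)
      load[cd] <<- load[cd] - 1L
      assignment[[cid]] <<- NULL
    }
    FALSE
  }
  if (!try_assign(1L)) {
    stop("infeasible constraint set: backtracking found no valid assignment")
  }
  for (cid in free) {
    load_sum <- vapply(all_codes, function(cd) sum(load[cd]), numeric(1))
    ci <- order(load_sum, code_tiebreak)[1]
    assignment[[cid]] <- all_codes[[ci]]
    load[all_codes[[ci]]] <- load[all_codes[[ci]]] + 1L
  }
  mix_design(k, assignment[compounds], labels)
}

#' Validate a mix design against its constraints
#'
#' Report-only check: lists every violated constraint, every compound whose
#' code is not exactly two in-design mixtures, and the per-mix loads. The
#' design is valid iff the violation table is empty.
#'
#' @param design an `identmix_design`.
#' @param constraints a [constraint_graph()] (or `NULL`).
#' @return A list of class `identmix_validation` with elements `valid`,
#'   `violations` (data frame: `type`, `a`, `b`, `detail`) and `loads`.
#' @export
validate_design <- function(design, constraints = NULL) {
  stopifnot(inherits(design, "identmix_design"))
  if (is.null(constraints)) constraints <- empty_constraints()
  v <- data.frame(type = character(), a = character(), b = character(),
                  detail = character(), stringsAsFactors = FALSE)
  for (cid in names(design$assignment)) {
    cd <- design$assignment[[cid]]
    if (length(cd) != 2L || anyDuplicated(cd) || !all(cd %in% design$labels)) {
      v <- rbind(v, data.frame(type = "BAD_CODE", a = cid, b = NA_character_,
                               detail = paste(cd, collapse = "+")))
    }
  }
  for (i in seq_len(nrow(constraints))) {
    a <- constraints$a[i]; b <- constraints$b[i]; ty <- constraints$type[i]
    ca <- design$assignment[[a]]; cb <- design$assignment[[b]]
    if (is.null(ca) || is.null(cb)) {
      v <- rbind(v, data.frame(type = "MISSING_COMPOUND", a = a, b = b,
                               detail = "constraint references unassigned compound"))
      next
    }
    if (!code_ok(ca, cb, ty)) {
      v <- rbind(v, data.frame(
        type = ty, a = a, b = b,
        detail = sprintf("%s=%s vs %s=%s share %d mix(es)", a,
                         paste(ca, collapse = "+"), b, paste(cb, collapse = "+"),
                         length(intersect(ca, cb)))))
    }
  }
  structure(list(valid = nrow(v) == 0L, violations = v,
                 loads = mix_loads(design)),
            class = "identmix_validation")
}

#' @export
print.identmix_validation <- function(x, ...) {
  cat(if (x$valid) "design valid" else
    sprintf("design INVALID: %d violation(s)", nrow(x$violations)), "\n")
  cat("per-mix loads:", paste(names(x$loads), x$loads, sep = "=",
                              collapse = " "), "\n")
  if (!x$valid) print(x$violations)
  invisible(x)
}

#' Find compounds whose pair-code matches an observed pattern
#'
#' The lookup half of the principle of exclusion: given the pair of mixtures
#' in which a peak was observed, return the compound(s) the design assigned
#' that code, optionally restricted to a candidate subset (e.g. one compound
#' class).
#'
#' @param design an `identmix_design`.
#' @param mixes character vector of the two mixture labels observed.
#' @param among optional character vector restricting the candidate ids.
#' @return Character vector of matching compound ids (possibly empty).
#' @examples
#' d <- table2_design()
#' lookup_code(d, c("B", "C"))  # Fructose and Gluconic acid
#' @export
lookup_code <- function(design, mixes, among = NULL) {
  stopifnot(inherits(design, "identmix_design"))
  mixes <- validate_pair_code(mixes)
  ids <- names(design$assignment)
  if (!is.null(among)) ids <- intersect(ids, among)
  hit <- vapply(ids, function(i) identical(design$assignment[[i]], mixes),
                logical(1))
  ids[hit]
}

#' Read / write a mix design as JSON
#'
#' JSON object with fields `k`, `labels`, `assignment` (compound ->
#' two-label array) and optionally `constraints` (array of `{a, b, type}`).
#'
#' @param path file path.
#' @param design an `identmix_design`.
#' @param constraints optional [constraint_graph()] stored alongside.
#' @return `read_design_json()` returns a list with `design` and
#'   `constraints`; `write_design_json()` returns `path` invisibly.
#' @export
write_design_json <- function(design, path, constraints = NULL) {
  stopifnot(inherits(design, "identmix_design"))
  obj <- list(k = design$k, labels = design$labels,
              assignment = design$assignment)
  if (!is.null(constraints) && nrow(constraints) > 0) {
    obj$constraints <- as.data.frame(constraints)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignment <- lapply(obj$assignment, unlist)
  design <- mix_design(obj$k, assignment, labels = unlist(obj$labels))
  cons <- if (!is.null(obj$constraints)) {
    cg <- as.data.frame(obj$constraints, stringsAsFactors = FALSE)
    constraint_graph(
      distinct = cg[cg$type == "DISTINCT", c("a", "b")],
      disjoint = cg[cg$type == "DISJOINT", c("a", "b")],
      overlap_one = cg[cg$type == "OVERLAP_ONE", c("a", "b")]
    )
  } else {
    empty_constraints()
  }
  list(design = design, constraints = cons)
}

#' Export a design as a composition table (TSV)
#'
#' One row per compound with its class and expected RI when a library is
#' supplied, and one column per mixture marked with the mixture label where
#' the compound is present — the layout used for bench sheets.
#'
#' @param design an `identmix_design`.
#' @param path output file.
#' @param library optional `identmix_library` supplying class/expected RI.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path, library = NULL) {
  stopifnot(inherits(design, "identmix_design"))
  ids <- names(design$assignment)
  cls <- ri <- rep(NA, length(ids))
  if (!is.null(library)) {
    by_compound <- vapply(library$entries, function(e) e$compound, character(1))
    m <- match(ids, by_compound)
    cls <- vapply(seq_along(ids), function(i)
      if (is.na(m[i])) NA_character_ else library$entries[[m[i]]]$class, character(1))
    ri <- vapply(seq_along(ids), function(i)
      if (is.na(m[i])) NA_real_ else library$entries[[m[i]]]$ri, numeric(1))
  }
  occ <- sapply(design$labels, function(l)
    ifelse(vapply(design$assignment, function(cd) l %in% cd, logical(1)), l, ""))
  d <- data.frame(class = cls, compound = ids, expected_ri = ri,
                  occ, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}
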