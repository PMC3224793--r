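# GO DAG container, ancestor closures, binary term vectors and the cosine
# term similarity.  Terms are indexed lexicographically by id so that the
# vector layout is deterministic across runs.

#' Construct an ontology from a parent map
#'
#' Low-level constructor used by [load_obo()], [toy_ontology()] and
#' [generate_ontology()].  The parent relation must be acyclic; reflexive
#' transitive ancestor closures are precomputed for every term.
#'
#' @param parents Named list: term id -> character vector of parent term
#'   ids (empty vector for roots).  Every parent must itself be a name of
#'   the list, and no term may list itself as a parent.
#' @param names Optional named character vector of human-readable term
#'   names.
#' @param namespace Ontology namespace label (one of
#'   `"biological_process"`, `"molecular_function"`,
#'   `"cellular_component"`).
#' @return An object of class `"Ontology"`: a list with elements `ids`
#'   (term ids in lexicographic order), `index` (named integer vector of
#'   1-based vector positions), `parents`, `anc` (named list of reflexive
#'   transitive ancestor closures), `roots` (ids with no parents),
#'   `names`, and `namespace`.
#' @export
build_ontology <- function(parents, names = NULL,
                           namespace = "biological_process") {
  ids <- sort(base::names(parents))
  if (anyDuplicated(ids)) stop("duplicate term ids in ontology")
  parents <- lapply(parents[ids], function(p) unique(as.character(p)))
  for (id in ids) {
    if (id %in% parents[[id]])
      stop("term ", id, " lists itself as a parent")
    missing <- setdiff(parents[[id]], ids)
    if (length(missing))
      stop("unknown parent term(s) referenced by ", id, ": ",
           paste(missing, collapse = ", "))
  }
  cyc <- .find_cycle_edge(parents)
  if (!is.null(cyc))
    stop("ontology parent relation contains a cycle (e.g. edge ",
         cyc[1], " -> ", cyc[2], ")")
  anc <- .ancestor_closures(parents)
  structure(list(
    ids       = ids,
    index     = setNames(seq_along(ids), ids),
    parents   = parents,
    anc       = anc,
    roots     = ids[lengths(parents) == 0L],
    names     = names,
    namespace = namespace
  ), class = "Ontology")
}

# DFS for a back edge; returns c(child, parent) on a cycle, or NULL.
.find_cycle_edge <- function(parents) {
  state <- setNames(integer(length(parents)), names(parents)) # 0/1/2
  found <- NULL
  visit <- function(id) {
    if (!is.null(found)) return()
    state[[id]] <<- 1L
    for (p in parents[[id]]) {
      if (state[[p]] == 1L) { found <<- c(id, p); return() }
      if (state[[p]] == 0L) visit(p)
      if (!is.null(found)) return()
    }
    state[[id]] <<- 2L
  }
  for (id in names(parents)) if (state[[id]] == 0L) visit(id)
  found
}

# Reflexive transitive closures, memoised in reverse topological order.
.ancestor_closures <- function(parents) {
  anc <- vector("list", length(parents))
  names(anc) <- names(parents)
  get_anc <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    out <- id
    for (p in parents[[id]]) out <- c(out, get_anc(p))
    out <- sort(unique(out))
    anc[[id]] <<- out
    out
  }
  for (id in names(parents)) get_anc(id)
  anc
}

#' @export
print.Ontology <- function(x, ...) {
  cat("Ontology <", x$namespace, ">: ", length(x$ids), " terms, ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' Number of terms in an ontology
#' @param ontology An [build_ontology()] object.
#' @return Integer count of terms (the dimension of the term vectors).
#' @export
n_terms <- function(ontology) length(ontology$ids)

.check_term <- function(ontology, term) {
  if (!term %in% ontology$ids)
    stop("unknown term: ", term, call. = FALSE)
}

#' Reflexive ancestor closure of a term
#'
#' Returns the term itself plus every term reachable through parent links
#' (`is_a`, and `part_of` when the ontology was loaded with it).
#'
#' @inheritParams n_terms
#' @param term A term id present in the ontology.
#' @return Character vector of term ids (sorted), always containing
#'   `term`.
#' @export
ancestors <- function(ontology, term) {
  .check_term(ontology, term)
  ontology$anc[[term]]
}

#' Binary ancestor vector of a term
#'
#' Represents a function as a binary vector over all ontology terms: the
#' positions of the term's ancestors are 1, all others 0.  The sparse set
#' of 1-positions is returned.
#'
#' @inheritParams ancestors
#' @param closure_mode `"transitive"` (default) uses the full reflexive
#'   transitive closure; `"parents_only"` marks only the term itself and
#'   its direct parents.
#' @param include_roots If `FALSE`, root terms (no parents) are dropped
#'   from the closure -- they contribute a dimension shared by every term
#'   and so inflate all similarities.  A root term always keeps its own
#'   position so the vector is never empty.
#' @return Object of class `"term_vector"`: list with `positions`
#'   (sorted 1-based integer positions under the lexicographic term
#'   index) and `n_terms` (the vector dimension).
#' @export
term_vector <- function(ontology, term,
                        closure_mode = c("transitive", "parents_only"),
                        include_roots = TRUE) {
  closure_mode <- match.arg(closure_mode)
  .check_term(ontology, term)
  ids <- if (closure_mode == "transitive") ontology$anc[[term]]
         else unique(c(term, ontology$parents[[term]]))
  if (!include_roots) {
    kept <- setdiff(ids, ontology$roots)
    ids <- if (length(kept)) unique(c(term, kept)) else term
  }
  structure(list(positions = sort(unname(ontology$index[ids])),
                 n_terms = length(ontology$ids)),
            class = "term_vector")
}

#' @export
print.term_vector <- function(x, ...) {
  v <- integer(x$n_terms)
  v[x$positions] <- 1L
  cat("term_vector (", x$n_terms, " terms): (",
      paste(v, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Convert a term vector to a dense 0/1 numeric vector
#' @param v A [term_vector()] object.
#' @return Numeric vector of length `n_terms` with 1 at the ancestor
#'   positions.
#' @export
as_dense <- function(v) {
  out <- numeric(v$n_terms)
  out[v$positions] <- 1
  out
}

.positions <- function(v) {
  if (inherits(v, "term_vector")) v$positions else as.integer(v)
}

#' Cosine similarity of two binary term vectors
#'
#' `fsim(f, f') = f.f' / (||f|| ||f'||)`.  For binary vectors this is
#' `|A n B| / sqrt(|A| |B|)` where A, B are the 1-position sets; the value
#' always lies in \[0, 1\].
#'
#' @param v1,v2 [term_vector()] objects (or bare integer position
#'   vectors).  Both must be non-empty.
#' @return Similarity in \[0, 1\]; 1 for identical vectors, 0 for
#'   orthogonal ones.
#' @examples
#' ont <- toy_ontology()
#' f1 <- term_vector(ont, "GO:0000004", closure_mode = "parents_only")
#' f2 <- term_vector(ont, "GO:0000005", closure_mode = "parents_only")
#' function_similarity(f1, f2)  # 2/3
#' @export
function_similarity <- function(v1, v2) {
  p1 <- .positions(v1); p2 <- .positions(v2)
  if (!length(p1) || !length(p2))
    stop("function_similarity: empty term vector")
  length(intersect(p1, p2)) / sqrt(length(p1) * length(p2))
}

#' Cosine similarity between two ontology terms
#'
#' Convenience wrapper building the two ancestor vectors and applying
#' [function_similarity()].
#'
#' @inheritParams term_vector
#' @param t1,t2 Term ids.
#' @return Similarity in \[0, 1\].
#' @export
term_similarity <- function(ontology, t1, t2,
                            closure_mode = c("transitive", "parents_only"),
                            include_roots = TRUE) {
  closure_mode <- match.arg(closure_mode)
  function_similarity(
    term_vector(ontology, t1, closure_mode, include_roots),
    term_vector(ontology, t2, closure_mode, include_roots))
}

# Pairwise fsim matrix between two term id vectors; rows = ta, cols = tb.
# Shared by scoring and the semantic metrics.
.fsim_matrix <- function(ontology, ta, tb,
                         closure_mode = "transitive",
                         include_roots = TRUE) {
  anc_of <- function(t) term_vector(ontology, t, closure_mode,
                                    include_roots)$positions
  pa <- lapply(ta, anc_of)
  pb <- lapply(tb, anc_of)
  m <- matrix(0, length(ta), length(tb), dimnames = list(ta, tb))
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      m[i, j] <- length(intersect(pa[[i]], pb[[j]])) /
        sqrt(length(pa[[i]]) * length(pb[[j]]))
    }
  }
  m
}

#' Read an ontology from an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file.  `is_a` edges are
#' always kept; `relationship: part_of` edges are kept when
#' `include_part_of = TRUE`.  Obsolete terms are dropped, `alt_id`s are
#' mapped to their canonical id, and only the requested namespace is
#' retained (parents outside the namespace are dropped).
#'
#' @param path Path to the OBO file.
#' @param namespace Namespace to keep; terms in a single-namespace file
#'   with no `namespace:` tag are assumed to belong to it.
#' @param include_part_of Keep `part_of` relationships as parent edges.
#' @return An `"Ontology"` object; its `alt` element maps alternate ids
#'   to canonical ids (used by [read_gaf()]).
#' @export
load_obo <- function(path, namespace = "biological_process",
                     include_part_of = TRUE) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  # split into stanzas
  starts <- grep("^\\[", lines)
  terms <- list(); term_names <- character(); alt <- character()
  if (length(starts)) {
    bounds <- c(starts, length(lines) + 1L)
    for (s in seq_along(starts)) {
      block <- lines[starts[s]:(bounds[s + 1L] - 1L)]
      if (!identical(block[1L], "[Term]")) next
      tag <- sub("^([a-zA-Z_]+):.*$", "\\1", block)
      val <- sub("^[a-zA-Z_]+:\\s*", "", block)
      get <- function(t) val[tag == t]
      id <- get("id")[1]
      if (is.na(id) || !nzchar(id)) next
      if (any(tolower(get("is_obsolete")) == "true")) next
      ns <- get("namespace")
      if (length(ns) && ns[1] != namespace) next
      pars <- sub("\\s*!.*$", "", get("is_a"))
      if (include_part_of) {
        rel <- sub("\\s*!.*$", "", get("relationship"))
        po <- rel[grepl("^part_of\\s", rel)]
        pars <- c(pars, sub("^part_of\\s+", "", po))
      }
      terms[[id]] <- unique(trimws(pars))
      nm <- get("name")
      term_names[id] <- if (length(nm)) nm[1] else id
      for (a in get("alt_id")) alt[trimws(a)] <- id
    }
  }
  # drop parent references outside the kept namespace / file
  ids <- names(terms)
  terms <- lapply(terms, function(p) {
    p <- ifelse(p %in% names(alt), alt[p], p)
    intersect(unique(p), ids)
  })
  ont <- build_ontology(terms, names = term_names, namespace = namespace)
  ont$alt <- alt
  ont
}

#' Canonicalize a vector of term ids through an ontology's alt_id map
#' @inheritParams n_terms
#' @param ids Character vector of term ids (canonical or alternate).
#' @return Character vector with alternate ids replaced by canonical ones.
#' @export
canonical_ids <- function(ontology, ids) {
  alt <- ontology$alt
  if (is.null(alt) || !length(alt)) return(ids)
  ifelse(ids %in% names(alt), alt[ids], ids)
}
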