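# Candidate-function scoring: function-overlap protein similarity, the
# IDF-style global influence weight log(N / n_f), and the weighted kNN
# score over the target's direct neighbourhood.

#' Function-overlap similarity between two proteins
#'
#' `sim(p, p') = |F(p) n F(p')| / max(|F(p)|, |F(p')|)`: the double sum of
#' the exact-match indicator over the two annotation sets, normalised by
#' the larger set size.  Symmetric; 1 iff the sets are equal; 0 iff they
#' are disjoint.
#'
#' @param fa,fb Non-empty character vectors (sets) of term ids.
#' @return Similarity in \[0, 1\].
#' @export
protein_similarity <- function(fa, fb) {
  fa <- unique(fa); fb <- unique(fb)
  if (!length(fa) || !length(fb))
    stop("protein_similarity: empty annotation set")
  length(intersect(fa, fb)) / max(length(fa), length(fb))
}

#' Global influence weights of annotation terms
#'
#' For each term f directly annotated in the map, computes the IDF-style
#' weight `log(N / n_f)` (natural log), where N is the number of proteins
#' in the dataset and n_f the number of proteins carrying f.  A function
#' common to almost all proteins carries little information and gets a
#' weight near 0; a rare function gets a large weight.
#'
#' @param annotations Non-empty annotation map (named list, protein ->
#'   direct term ids).
#' @param n_total Dataset size N; defaults to the number of proteins in
#'   the map.  Pass the full dataset size when the map has annotations
#'   hidden (e.g. cross-validation): hidden proteins are still part of
#'   the dataset.
#' @return Object of class `"FunctionInfluence"`: list with
#'   `total_proteins` (N), `per_term_count` (named integer n_f) and
#'   `weight` (named numeric log(N/n_f)).
#' @export
compute_influence <- function(annotations, n_total = NULL) {
  if (!length(annotations)) stop("compute_influence: empty annotation map")
  N <- if (is.null(n_total)) length(annotations) else as.integer(n_total)
  counts <- table(unlist(lapply(annotations, unique)))
  nf <- setNames(as.integer(counts), names(counts))
  nf <- nf[order(names(nf))]
  structure(list(total_proteins = N,
                 per_term_count = nf,
                 weight = log(N / nf)),
            class = "FunctionInfluence")
}

#' @export
print.FunctionInfluence <- function(x, ...) {
  cat("FunctionInfluence: N =", x$total_proteins, "proteins,",
      length(x$per_term_count), "terms\n")
  invisible(x)
}

.influence_weight <- function(influence, terms) {
  w <- influence$weight[terms]
  if (anyNA(w))
    stop("no influence weight for term(s): ",
         paste(terms[is.na(w)], collapse = ", "))
  w
}

.score_table <- function(target, scores, threshold = NULL) {
  structure(list(target = target,
                 scores = scores[order(names(scores))],
                 threshold = threshold),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat("ScoreTable for ", x$target, ": ", length(x$scores),
      " candidate function(s)", sep = "")
  if (!is.null(x$threshold))
    cat(", threshold =", format(x$threshold))
  cat("\n")
  if (length(x$scores)) print(sort(x$scores, decreasing = TRUE))
  invisible(x)
}

# Shared engine for the weighted scores.  For every candidate f in FN(p):
#   score(p, f) = sum_{p' in N(p)} sim_{p'} * sum_{f' in F(p')}
#                 fsim(f, f') * log(N / n_{f'})
# with sim_{p'} either the Eq.-(1) protein similarity against
# `predicted_fp` or fixed to 1 (initial scores).  Unannotated neighbours
# contribute nothing and are skipped.
.weighted_scores <- function(p, predicted_fp, network, annotations,
                             ontology, influence, closure_mode,
                             fixed_sim = FALSE) {
  nb <- protein_neighbors(network, p)
  nb <- nb[nb %in% names(annotations)]
  nb <- nb[lengths(annotations[nb]) > 0L]
  cand <- sort(unique(unlist(annotations[nb])))
  if (!length(cand)) return(.score_table(p, setNames(numeric(0), character(0))))
  fs <- .fsim_matrix(ontology, cand, cand, closure_mode = closure_mode)
  w <- .influence_weight(influence, cand)
  # neighbour-independent inner sums: influence(f | F(p')) for each f
  scores <- setNames(numeric(length(cand)), cand)
  use_sim <- !fixed_sim && length(predicted_fp) > 0L
  for (q in nb) {
    fq <- annotations[[q]]
    inner <- fs[, fq, drop = FALSE] %*% w[fq]
    s <- if (use_sim) protein_similarity(predicted_fp, fq) else 1
    scores <- scores + s * inner[, 1]
  }
  .score_table(p, scores)
}

#' Candidate-function scores for a target protein
#'
#' Scores every candidate function f in FN(p) (union of the neighbours'
#' direct annotation sets) by
#' `score(p,f) = sum_{p' in N(p)} [ sim(p,p') * sum_{f' in F(p')}
#' fsim(f,f') * log(N/n_f') ]`,
#' where `sim(p,p')` is [protein_similarity()] between the current
#' predicted set of p and F(p').  If `predicted_fp` is empty the protein
#' similarity falls back to 1 (the initial-score behaviour), keeping the
#' iteration total.
#'
#' @param p Target protein id (present in the network; its own
#'   annotations, if any, are never consulted).
#' @param predicted_fp Character vector: p's currently predicted term set.
#' @inheritParams preprocess
#' @param ontology An `"Ontology"` object.
#' @param influence A [compute_influence()] object covering every term
#'   annotated to the neighbours.
#' @param closure_mode Passed to the term-vector construction; see
#'   [term_vector()].
#' @return A `"ScoreTable"`; empty when p has no annotated neighbours.
#' @export
candidate_scores <- function(p, predicted_fp, network, annotations,
                             ontology, influence,
                             closure_mode = c("transitive", "parents_only")) {
  closure_mode <- match.arg(closure_mode)
  .weighted_scores(p, predicted_fp, network, annotations, ontology,
                   influence, closure_mode, fixed_sim = FALSE)
}

#' Initial candidate scores (protein similarity fixed to 1)
#'
#' The bootstrap scores used before any predicted set exists:
#' `score0(p,f) = sum_{p' in N(p)} sum_{f' in F(p')} fsim(f,f') *
#' log(N/n_f')`, i.e. [candidate_scores()] with every protein similarity
#' set to 1.
#'
#' @inheritParams candidate_scores
#' @return A `"ScoreTable"`.
#' @export
initial_scores <- function(p, network, annotations, ontology, influence,
                           closure_mode = c("transitive", "parents_only")) {
  closure_mode <- match.arg(closure_mode)
  .weighted_scores(p, character(), network, annotations, ontology,
                   influence, closure_mode, fixed_sim = TRUE)
}

#' Initial-selection threshold
#'
#' The mean of the initial scores over FN(p); candidates scoring strictly
#' above it form the initial predicted set.
#'
#' @param table A non-empty `"ScoreTable"`.
#' @return The threshold value (arithmetic mean of the scores).
#' @export
initial_threshold <- function(table) {
  if (!length(table$scores)) stop("initial_threshold: empty score table")
  mean(table$scores)
}

#' Export a score table as a data frame
#' @inheritParams initial_threshold
#' @return Data frame with columns `protein`, `term`, `score`, `rank`
#'   (rank 1 = highest score; ties broken by term id).
#' @export
score_table_df <- function(table) {
  s <- table$scores
  ord <- order(-s, names(s))
  data.frame(protein = rep(table$target, length(s)),
             term = names(s)[ord],
             score = unname(s[ord]),
             rank = seq_along(s),
             stringsAsFactors = FALSE)
}
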