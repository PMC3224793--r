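# The iterative predictor (CIA) and the Neighbour Counting baselines.
# Each target is predicted independently; the target's own annotations are
# never consulted.

#' Estimate the prediction size k
#'
#' k is the average number of directly annotated functions per protein in
#' the dataset, rounded half-up, with a minimum of 1.
#'
#' @param annotations Non-empty annotation map.
#' @return Positive integer k.
#' @export
estimate_k <- function(annotations) {
  if (!length(annotations)) stop("estimate_k: empty annotation map")
  max(1L, as.integer(floor(mean(lengths(annotations)) + 0.5)))
}

#' Select the k highest-scoring candidate functions
#'
#' Sorts by score descending, ties broken by term id ascending (so runs
#' are deterministic), and returns at most k terms.
#'
#' @param table A `"ScoreTable"`.
#' @param k Positive integer.
#' @return Character vector of term ids in rank order (length <= k).
#' @export
select_top_k <- function(table, k) {
  s <- table$scores
  if (!length(s)) return(character())
  ord <- order(-s, names(s))
  names(s)[ord][seq_len(min(k, length(s)))]
}

.prediction_result <- function(target, predicted, iterations, converged,
                               trajectory, initial_set,
                               scores = setNames(numeric(0), character())) {
  structure(list(target = target,
                 predicted = predicted,
                 iterations = iterations,
                 converged = converged,
                 trajectory = trajectory,
                 initial_set = initial_set,
                 scores = scores),
            class = "PredictionResult")
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat("PredictionResult for ", x$target, ": ",
      length(x$predicted), " term(s) [",
      paste(x$predicted, collapse = ", "), "]\n",
      "  iterations = ", x$iterations,
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

# Shared fixed-point loop.  `score_fun(predicted_set)` must return a
# ScoreTable; `initial_table` provides the bootstrap scores whose mean is
# the initial-selection threshold (strict inequality: candidates equal to
# the mean are excluded).  Convergence is set equality of consecutive
# predicted sets; a recurrence of any earlier (non-adjacent) set stops the
# loop without convergence, and `max_iterations` is a hard cap.
.iterate_prediction <- function(p, initial_table, score_fun, k,
                                max_iterations) {
  if (!length(initial_table$scores))
    return(.prediction_result(p, character(), 0L, TRUE, list(),
                              character()))
  eps <- initial_threshold(initial_table)
  init <- sort(names(initial_table$scores)[initial_table$scores > eps])
  current <- init
  seen <- list(init)
  trajectory <- list()
  iterations <- 0L
  converged <- FALSE
  last_table <- initial_table
  while (iterations < max_iterations) {
    last_table <- score_fun(current)
    new <- select_top_k(last_table, k)
    iterations <- iterations + 1L
    trajectory[[iterations]] <- new
    if (setequal(new, current)) { converged <- TRUE; current <- new; break }
    recurred <- any(vapply(seen[-length(seen)], setequal, logical(1),
                           y = new))
    current <- new
    seen[[length(seen) + 1L]] <- new
    if (recurred) break
  }
  .prediction_result(p, current, iterations, converged, trajectory, init,
                     last_table$scores)
}

#' Predict protein functions with the Cosine Iterative Algorithm
#'
#' Bootstraps a predicted set from the [initial_scores()] mean threshold,
#' then alternates between recomputing the candidate scores (the
#' target-neighbour protein similarities now coming from the current
#' predicted set) and reselecting the top k, until the predicted set is
#' stable.  Because a fixed predicted set fixes every `sim(p, p')`, set
#' stability is exactly similarity stability.
#'
#' @inheritParams candidate_scores
#' @param influence Optional precomputed [compute_influence()]; by
#'   default it is computed from `annotations` with the target's own
#'   entry removed but still counted in N (the target is part of the
#'   dataset even though its annotations are hidden).
#' @param k Number of functions to predict; default [estimate_k()].
#' @param max_iterations Hard iteration cap; default `k + 5` (the fixed
#'   point is typically reached in two or three rounds).
#' @return A `"PredictionResult"` with the ranked predicted terms, the
#'   iteration trajectory, the threshold-selected initial set, the final
#'   score table and a convergence flag.  A target without annotated
#'   neighbours yields an empty prediction with `converged = TRUE`.
#' @export
predict_cia <- function(p, network, annotations, ontology,
                        influence = NULL, k = NULL, max_iterations = NULL,
                        closure_mode = c("transitive", "parents_only")) {
  closure_mode <- match.arg(closure_mode)
  n_all <- length(annotations) + !(p %in% names(annotations))
  annotations[[p]] <- NULL   # the target's own annotations are never read
  if (is.null(influence)) {
    if (!length(annotations))
      return(.prediction_result(p, character(), 0L, TRUE, list(),
                                character()))
    influence <- compute_influence(annotations, n_total = n_all)
  }
  if (is.null(k)) k <- estimate_k(annotations)
  if (is.null(max_iterations)) max_iterations <- k + 5L
  init <- initial_scores(p, network, annotations, ontology, influence,
                         closure_mode)
  .iterate_prediction(
    p, init,
    function(current) candidate_scores(p, current, network, annotations,
                                       ontology, influence, closure_mode),
    k, max_iterations)
}

# Frequency scores: number of annotated neighbours carrying each term.
.frequency_scores <- function(p, network, annotations) {
  nb <- protein_neighbors(network, p)
  nb <- nb[nb %in% names(annotations)]
  nb <- nb[lengths(annotations[nb]) > 0L]
  if (!length(nb))
    return(.score_table(p, setNames(numeric(0), character(0))))
  counts <- table(unlist(lapply(annotations[nb], unique)))
  .score_table(p, setNames(as.numeric(counts), names(counts)))
}

#' Neighbour Counting prediction
#'
#' The classic non-iterative baseline: each candidate function is scored
#' by the number of direct neighbours annotated with it.
#'
#' @inheritParams predict_cia
#' @param nc_mode `"frequency"` (default) ranks all candidates by
#'   neighbour frequency and takes the top k; `"threshold"` first keeps
#'   only candidates scoring strictly above the mean frequency (the same
#'   bootstrap selection the iterative predictors use) and then takes the
#'   top k of those.
#' @return A `"PredictionResult"` with `iterations = 0` and
#'   `converged = TRUE`.
#' @export
predict_nc <- function(p, network, annotations, k = NULL,
                       nc_mode = c("frequency", "threshold")) {
  nc_mode <- match.arg(nc_mode)
  annotations[[p]] <- NULL
  if (is.null(k)) k <- estimate_k(annotations)
  tbl <- .frequency_scores(p, network, annotations)
  if (!length(tbl$scores))
    return(.prediction_result(p, character(), 0L, TRUE, list(),
                              character()))
  if (nc_mode == "threshold") {
    eps <- initial_threshold(tbl)
    tbl <- .score_table(p, tbl$scores[tbl$scores > eps], threshold = eps)
  }
  pred <- select_top_k(tbl, k)
  .prediction_result(p, pred, 0L, TRUE, list(), pred, tbl$scores)
}

#' Iterative Neighbour Counting prediction
#'
#' Same fixed-point loop as [predict_cia()], but the per-neighbour inner
#' sum is replaced by the plain membership indicator:
#' `score(p,f) = sum_{p' in N(p)} sim(p,p') * I[f in F(p')]`, with
#' initial scores equal to the neighbour frequencies and the same
#' mean-threshold bootstrap selection.
#'
#' @inheritParams predict_cia
#' @return A `"PredictionResult"`.
#' @export
predict_inc <- function(p, network, annotations, k = NULL,
                        max_iterations = NULL) {
  annotations[[p]] <- NULL
  if (is.null(k)) {
    if (!length(annotations))
      return(.prediction_result(p, character(), 0L, TRUE, list(),
                                character()))
    k <- estimate_k(annotations)
  }
  if (is.null(max_iterations)) max_iterations <- k + 5L
  nb <- protein_neighbors(network, p)
  nb <- nb[nb %in% names(annotations)]
  nb <- nb[lengths(annotations[nb]) > 0L]
  init <- .frequency_scores(p, network, annotations)
  score_fun <- function(current) {
    cand <- names(init$scores)
    scores <- setNames(numeric(length(cand)), cand)
    for (q in nb) {
      fq <- annotations[[q]]
      s <- if (length(current)) protein_similarity(current, fq) else 1
      scores[cand %in% fq] <- scores[cand %in% fq] + s
    }
    .score_table(p, scores)
  }
  .iterate_prediction(p, init, score_fun, k, max_iterations)
}

#' Export prediction results as a data frame
#'
#' @param results A single `"PredictionResult"` or a list of them.
#' @return Data frame with columns `protein`, `rank`, `term`, `score`,
#'   `iterations`, `converged` -- one row per predicted term (proteins
#'   with empty predictions contribute no rows).
#' @export
prediction_df <- function(results) {
  if (inherits(results, "PredictionResult")) results <- list(results)
  rows <- lapply(results, function(r) {
    if (!length(r$predicted)) return(NULL)
    data.frame(protein = r$target,
               rank = seq_along(r$predicted),
               term = r$predicted,
               score = unname(r$scores[r$predicted]),
               iterations = r$iterations,
               converged = r$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(), rank = integer(),
                      term = character(), score = numeric(),
                      iterations = integer(), converged = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
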