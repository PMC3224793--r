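# Exact-match and semantic precision/recall/F metrics, plus holdout and
# k-fold cross-validation harnesses with strict annotation hiding.

.f_value <- function(precision, recall) {
  if (precision + recall > 0) 2 * precision * recall / (precision + recall)
  else 0
}

.eval_report <- function(precision, recall, mode, n_targets,
                         per_target = NULL, n_skipped = 0L) {
  structure(list(precision = precision,
                 recall = recall,
                 f_value = .f_value(precision, recall),
                 mode = mode,
                 n_targets = n_targets,
                 n_skipped = n_skipped,
                 per_target = per_target),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport [%s] over %d target(s): P = %.4f, R = %.4f, F = %.4f\n",
              x$mode, x$n_targets, x$precision, x$recall, x$f_value))
  if (x$n_skipped > 0)
    cat("  (", x$n_skipped, " target(s) skipped: no annotated neighbour)\n",
        sep = "")
  invisible(x)
}

#' Exact-match precision, recall and F-value for one protein
#'
#' `Precision = N_P / N_A`, `Recall = N_P / N_R`, with N_P the number of
#' predicted functions exactly matching a real function, N_A the number
#' of predictions and N_R the number of real functions.  F is the
#' harmonic mean (0 when both are 0).
#'
#' @param real Non-empty character vector: the protein's real functions.
#' @param predicted Character vector of predicted functions (may be
#'   empty, giving precision = recall = 0).
#' @return An `"EvalReport"` with `mode = "exact"` and `n_targets = 1`.
#' @export
exact_metrics <- function(real, predicted) {
  real <- unique(real); predicted <- unique(predicted)
  if (!length(real)) stop("exact_metrics: empty set of real functions")
  np <- length(intersect(real, predicted))
  precision <- if (length(predicted)) np / length(predicted) else 0
  recall <- np / length(real)
  .eval_report(precision, recall, "exact", 1L)
}

#' Semantic precision, recall and F-value for one protein
#'
#' Credits near-misses through the ontology: each real function scores
#' its best cosine similarity to any predicted function
#' (`RecallSuccess(f_o) = max_j fsim(f_o, f_pj)`) and vice versa
#' (`PrecisionSuccess(f_p) = max_i fsim(f_oi, f_p)`).  These successes
#' are summed and normalised by the sums of the self-similarities
#' `fsim(f, f)` of the respective sets (computed literally, so a
#' non-cosine similarity would plug in unchanged).
#'
#' @inheritParams exact_metrics
#' @param ontology Ontology containing every term in either set.
#' @inheritParams term_vector
#' @return An `"EvalReport"` with `mode = "semantic"`.  An empty
#'   prediction gives precision = recall = 0.
#' @export
semantic_metrics <- function(real, predicted, ontology,
                             closure_mode = c("transitive", "parents_only"),
                             include_roots = TRUE) {
  closure_mode <- match.arg(closure_mode)
  real <- unique(real); predicted <- unique(predicted)
  if (!length(real)) stop("semantic_metrics: empty set of real functions")
  if (!length(predicted))
    return(.eval_report(0, 0, "semantic", 1L))
  fs <- .fsim_matrix(ontology, real, predicted,
                     closure_mode = closure_mode,
                     include_roots = include_roots)
  self_sim <- function(ts)
    sum(vapply(ts, function(t)
      term_similarity(ontology, t, t, closure_mode, include_roots),
      numeric(1)))
  recall <- sum(apply(fs, 1, max)) / self_sim(real)
  precision <- sum(apply(fs, 2, max)) / self_sim(predicted)
  .eval_report(precision, recall, "semantic", 1L)
}

# Resolve the `algorithm` argument to function(p, network, train_ann,
# influence, k) -> character vector of predicted terms.  A user-supplied
# function may accept (p, network, annotations, k).
.resolve_predictor <- function(algorithm, ontology, max_iterations = NULL,
                               closure_mode = "transitive") {
  if (is.function(algorithm))
    return(function(p, network, ann, influence, k)
      algorithm(p, network, ann, k))
  switch(match.arg(algorithm, c("cia", "inc", "nc")),
    cia = function(p, network, ann, influence, k)
      predict_cia(p, network, ann, ontology, influence = influence, k = k,
                  max_iterations = max_iterations,
                  closure_mode = closure_mode)$predicted,
    inc = function(p, network, ann, influence, k)
      predict_inc(p, network, ann, k = k,
                  max_iterations = max_iterations)$predicted,
    nc = function(p, network, ann, influence, k)
      predict_nc(p, network, ann, k = k)$predicted)
}

# Evaluate one batch of targets whose annotations have been hidden.
# Returns macro-averaged exact and semantic reports over the targets that
# have at least one annotated neighbour.
.evaluate_targets <- function(targets, network, train_ann, full_ann,
                              ontology, predictor, influence, k,
                              closure_mode) {
  per <- list()
  skipped <- 0L
  for (p in targets) {
    nb <- protein_neighbors(network, p)
    nb <- nb[nb %in% names(train_ann)]
    if (!length(nb)) { skipped <- skipped + 1L; next }
    pred <- predictor(p, network, train_ann, influence, k)
    ex <- exact_metrics(full_ann[[p]], pred)
    se <- semantic_metrics(full_ann[[p]], pred, ontology,
                           closure_mode = closure_mode)
    per[[p]] <- data.frame(
      protein = p, n_predicted = length(pred),
      exact_precision = ex$precision, exact_recall = ex$recall,
      exact_f = ex$f_value,
      semantic_precision = se$precision, semantic_recall = se$recall,
      semantic_f = se$f_value, stringsAsFactors = FALSE)
  }
  per_target <- do.call(rbind, per)
  n <- length(per)
  mean0 <- function(col) if (n) mean(per_target[[col]]) else 0
  list(
    exact = .eval_report(mean0("exact_precision"), mean0("exact_recall"),
                         "exact", n, per_target, skipped),
    semantic = .eval_report(mean0("semantic_precision"),
                            mean0("semantic_recall"),
                            "semantic", n, per_target, skipped))
}

#' k-fold cross-validation of a predictor
#'
#' Annotated proteins are randomly partitioned into `folds` parts.  For
#' each fold the test proteins' annotations are hidden -- removed from
#' the annotation map used for scoring, protein similarity and the
#' influence weights (which are recomputed from the training map, with N
#' still counting the hidden proteins as dataset members) -- while the
#' proteins themselves stay in the network.  Every test protein with at
#' least one annotated neighbour is predicted and scored against its real
#' annotations; metrics are macro-averaged over targets within a fold,
#' then averaged over folds.
#'
#' @inheritParams candidate_scores
#' @param algorithm `"cia"`, `"inc"`, `"nc"`, or a function
#'   `(p, network, annotations, k) -> character vector` (e.g. a stub for
#'   testing harness behaviour).
#' @param folds Number of folds (>= 2, <= number of annotated proteins).
#' @param seed Integer seed driving the partition.
#' @param k Prediction size; default: estimated from each fold's training
#'   annotations.
#' @param max_iterations Passed to the iterative predictors.
#' @return List with elements `exact` and `semantic` (`"EvalReport"`s
#'   averaged over folds, with the pooled per-target table attached) and
#'   `folds` (per-fold summaries).
#' @export
cross_validate <- function(network, annotations, ontology,
                           algorithm = "cia", folds = 10, seed = 1,
                           k = NULL, max_iterations = NULL,
                           closure_mode = c("transitive", "parents_only")) {
  closure_mode <- match.arg(closure_mode)
  targets_all <- intersect(proteins(network), names(annotations))
  if (folds < 2) stop("cross_validate: folds must be >= 2")
  if (folds > length(targets_all))
    stop("cross_validate: more folds than annotated proteins")
  predictor <- .resolve_predictor(algorithm, ontology, max_iterations,
                                  closure_mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assignment <- sample(rep_len(seq_len(folds), length(targets_all)))
  fold_res <- vector("list", folds)
  for (i in seq_len(folds)) {
    test <- targets_all[assignment == i]
    train_ann <- annotations[setdiff(names(annotations), test)]
    influence <- compute_influence(train_ann,
                                   n_total = length(targets_all))
    kf <- if (is.null(k)) estimate_k(train_ann) else k
    fold_res[[i]] <- .evaluate_targets(test, network, train_ann,
                                       annotations, ontology, predictor,
                                       influence, kf, closure_mode)
  }
  avg <- function(mode, field)
    mean(vapply(fold_res, function(fr) fr[[mode]][[field]], numeric(1)))
  per_target <- do.call(rbind, lapply(fold_res,
                                      function(fr) fr$exact$per_target))
  n_eval <- sum(vapply(fold_res, function(fr) fr$exact$n_targets,
                       numeric(1)))
  n_skip <- sum(vapply(fold_res, function(fr) fr$exact$n_skipped,
                       numeric(1)))
  list(
    exact = .eval_report(avg("exact", "precision"), avg("exact", "recall"),
                         "exact", n_eval, per_target, n_skip),
    semantic = .eval_report(avg("semantic", "precision"),
                            avg("semantic", "recall"),
                            "semantic", n_eval, per_target, n_skip),
    folds = fold_res)
}

#' Holdout evaluation at one or more test-set sizes
#'
#' For each requested size, draws that many annotated proteins as test
#' targets, hides their annotations jointly (the influence weights are
#' recomputed from the remaining training annotations), predicts each
#' target that still has an annotated neighbour, and macro-averages the
#' metrics.
#'
#' @inheritParams cross_validate
#' @param sample_sizes Integer vector of test-set sizes, each <= number
#'   of annotated proteins.
#' @return List with one element per size: list(`size`, `exact`,
#'   `semantic`).
#' @export
holdout_evaluate <- function(network, annotations, ontology,
                             algorithm = "cia", sample_sizes = 20,
                             seed = 1, k = NULL, max_iterations = NULL,
                             closure_mode = c("transitive", "parents_only")) {
  closure_mode <- match.arg(closure_mode)
  targets_all <- intersect(proteins(network), names(annotations))
  if (any(sample_sizes > length(targets_all)))
    stop("holdout_evaluate: sample size exceeds annotated proteins")
  predictor <- .resolve_predictor(algorithm, ontology, max_iterations,
                                  closure_mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- vector("list", length(sample_sizes))
  for (j in seq_along(sample_sizes)) {
    size <- sample_sizes[j]
    set.seed(seed + j - 1L)
    test <- sample(targets_all, size)
    train_ann <- annotations[setdiff(names(annotations), test)]
    influence <- compute_influence(train_ann,
                                   n_total = length(targets_all))
    kh <- if (is.null(k)) estimate_k(train_ann) else k
    res <- .evaluate_targets(test, network, train_ann, annotations,
                             ontology, predictor, influence, kh,
                             closure_mode)
    out[[j]] <- list(size = size, exact = res$exact,
                     semantic = res$semantic)
  }
  out
}

#' Precision-recall curve points over the prediction size k
#'
#' Runs a holdout evaluation for each k in `1:k_max` and collects the
#' averaged exact and semantic metrics, yielding plot-ready
#' precision-recall points.
#'
#' @inheritParams holdout_evaluate
#' @param k_max Largest prediction size to evaluate.
#' @param size Holdout test-set size.
#' @return Data frame with columns `k`, `mode`, `precision`, `recall`,
#'   `f_value`.
#' @export
pr_curve <- function(network, annotations, ontology, algorithm = "cia",
                     k_max = 5, size = 20, seed = 1,
                     closure_mode = c("transitive", "parents_only")) {
  closure_mode <- match.arg(closure_mode)
  rows <- list()
  for (kk in seq_len(k_max)) {
    rep1 <- holdout_evaluate(network, annotations, ontology, algorithm,
                             sample_sizes = size, seed = seed, k = kk,
                             closure_mode = closure_mode)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      k = kk, mode = "exact", precision = rep1$exact$precision,
      recall = rep1$exact$recall, f_value = rep1$exact$f_value)
    rows[[length(rows) + 1L]] <- data.frame(
      k = kk, mode = "semantic", precision = rep1$semantic$precision,
      recall = rep1$semantic$recall, f_value = rep1$semantic$f_value)
  }
  do.call(rbind, rows)
}

# Save/restore the global RNG state so evaluation seeding does not
# disturb a caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
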