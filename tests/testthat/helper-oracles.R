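# Independent brute-force transcriptions of the model's formulas, kept as
# literal nested loops so they share no code path with the implementation.

# Reflexive transitive ancestor set by brute-force reachability: repeat
# "add all parents of everything collected so far" until no change.
oracle_ancestors <- function(parents, term) {
  out <- term
  repeat {
    grown <- unique(c(out, unlist(parents[out])))
    if (setequal(grown, out)) return(sort(out))
    out <- grown
  }
}

# Dense-vector cosine over full 0/1 vectors.
oracle_cosine <- function(dense1, dense2) {
  sum(dense1 * dense2) / (sqrt(sum(dense1^2)) * sqrt(sum(dense2^2)))
}

# Dense ancestor vector for a term (transitive closure, all terms in
# lexicographic id order).
oracle_dense_vector <- function(parents, term) {
  ids <- sort(names(parents))
  as.numeric(ids %in% oracle_ancestors(parents, term))
}

oracle_fsim <- function(parents, t1, t2) {
  oracle_cosine(oracle_dense_vector(parents, t1),
                oracle_dense_vector(parents, t2))
}

# Protein similarity as the literal double sum of the exact-match
# indicator, normalised by the larger set size.
oracle_protein_sim <- function(fa, fb) {
  acc <- 0
  for (f in fa) for (g in fb) acc <- acc + as.numeric(identical(f, g))
  acc / max(length(fa), length(fb))
}

# Weighted candidate scores: quadruple-nested literal loop over
# neighbours and their functions.  `adj` is a named list of neighbour
# sets, `ann` the annotation map, `parents` the ontology parent map,
# `weight` the per-term influence weights.  sim_sets[[q]] gives the set
# used for the protein similarity with neighbour q (or NULL for sim = 1).
oracle_weighted_scores <- function(p, predicted, adj, ann, parents,
                                   weight, fixed_sim = FALSE) {
  nb <- adj[[p]]
  nb <- nb[nb %in% names(ann)]
  nb <- nb[vapply(ann[nb], length, 1L) > 0]
  cand <- sort(unique(as.character(unlist(ann[nb]))))
  scores <- setNames(numeric(length(cand)), cand)
  for (f in cand) {
    total <- 0
    for (q in nb) {
      s <- if (fixed_sim || length(predicted) == 0) 1
           else oracle_protein_sim(predicted, ann[[q]])
      inner <- 0
      for (g in ann[[q]])
        inner <- inner + oracle_fsim(parents, f, g) * weight[[g]]
      total <- total + s * inner
    }
    scores[[f]] <- total
  }
  scores
}

# Literal INC predictor: frequency bootstrap, strict mean threshold,
# indicator scoring, top-k with lexicographic ties, set-equality stop.
oracle_inc <- function(p, adj, ann, k, max_iter) {
  nb <- adj[[p]]
  nb <- nb[nb %in% names(ann)]
  nb <- nb[vapply(ann[nb], length, 1L) > 0]
  cand <- sort(unique(unlist(ann[nb])))
  if (!length(cand))
    return(list(predicted = character(), iterations = 0L,
                converged = TRUE))
  freq <- setNames(numeric(length(cand)), cand)
  for (f in cand) for (q in nb) freq[[f]] <- freq[[f]] + (f %in% ann[[q]])
  eps <- mean(freq)
  current <- sort(cand[freq > eps])
  topk <- function(scores) {
    ord <- order(-scores, names(scores))
    names(scores)[ord][seq_len(min(k, length(scores)))]
  }
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    scores <- setNames(numeric(length(cand)), cand)
    for (f in cand) for (q in nb) {
      s <- if (length(current)) oracle_protein_sim(current, ann[[q]]) else 1
      scores[[f]] <- scores[[f]] + s * (f %in% ann[[q]])
    }
    new <- topk(scores)
    it <- it + 1L
    if (setequal(new, current)) { converged <- TRUE; current <- new; break }
    current <- new
  }
  list(predicted = current, iterations = it, converged = converged)
}

# Semantic metrics by literal nested maxima and self-similarity sums.
oracle_semantic <- function(real, predicted, parents) {
  rec_num <- 0
  for (fo in real) {
    best <- 0
    for (fp in predicted) best <- max(best, oracle_fsim(parents, fo, fp))
    rec_num <- rec_num + best
  }
  prec_num <- 0
  for (fp in predicted) {
    best <- 0
    for (fo in real) best <- max(best, oracle_fsim(parents, fo, fp))
    prec_num <- prec_num + best
  }
  rec_den <- sum(vapply(real, function(f) oracle_fsim(parents, f, f),
                        numeric(1)))
  prec_den <- sum(vapply(predicted, function(f) oracle_fsim(parents, f, f),
                         numeric(1)))
  recall <- rec_num / rec_den
  precision <- if (length(predicted)) prec_num / prec_den else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f_value = f)
}

# Neighbour-frequency counts by hand.
oracle_nc_scores <- function(p, adj, ann) {
  nb <- adj[[p]]
  nb <- nb[nb %in% names(ann)]
  nb <- nb[vapply(ann[nb], length, 1L) > 0]
  cand <- sort(unique(unlist(ann[nb])))
  scores <- setNames(numeric(length(cand)), cand)
  for (f in cand) for (q in nb) scores[[f]] <- scores[[f]] + (f %in% ann[[q]])
  scores
}
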