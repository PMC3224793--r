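# Self-contained fixtures: the five-term demonstration DAG, random
# ontologies, and annotated PPI networks with planted functional
# homophily.  Everything is deterministic under the config seed, so the
# whole pipeline is testable without any download.

#' Configuration for the synthetic generators
#'
#' The defaults describe the benchmark regime the predictors are studied
#' under: 100 proteins carrying on average five direct annotations each,
#' drawn from a 66-term DAG -- both scaled from the composition of a
#' curated yeast biological-process dataset (about five direct terms per
#' protein, and roughly two distinct GO terms for every three proteins)
#' -- with interaction probability driven mostly by functional overlap
#' (strong homophily, little noise).
#'
#' @param n_terms Number of ontology terms.
#' @param max_parents Maximum parents drawn per non-root term.
#' @param n_proteins Number of proteins.
#' @param annotations_per_protein Mean direct annotations per protein
#'   (shifted-Poisson, minimum 1).
#' @param homophily Strength in \[0, 1\] with which the function-overlap
#'   [protein_similarity()] of a pair raises its edge probability.
#' @param base_edge_prob Baseline edge probability for any pair.
#' @param noise_edge_prob Probability of an additional random
#'   (function-independent) edge per pair.
#' @param seed Integer seed; identical configs generate identical data.
#' @return A list of class `"SynthConfig"`.
#' @export
synth_config <- function(n_terms = 66, max_parents = 2, n_proteins = 100,
                         annotations_per_protein = 5, homophily = 0.8,
                         base_edge_prob = 0.05, noise_edge_prob = 0.02,
                         seed = 1) {
  stopifnot(n_terms >= 1, max_parents >= 1, n_proteins >= 1,
            annotations_per_protein >= 1,
            homophily >= 0, homophily <= 1,
            base_edge_prob >= 0, base_edge_prob <= 1,
            noise_edge_prob >= 0, noise_edge_prob <= 1)
  structure(list(n_terms = as.integer(n_terms),
                 max_parents = as.integer(max_parents),
                 n_proteins = as.integer(n_proteins),
                 annotations_per_protein = annotations_per_protein,
                 homophily = homophily,
                 base_edge_prob = base_edge_prob,
                 noise_edge_prob = noise_edge_prob,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' The five-term demonstration ontology
#'
#' A minimal GO-like DAG of five biological-process terms: terms 1-3 are
#' roots, term 4 has parents 2 and 3, and term 5 has parents 3 and 4.
#' Under `closure_mode = "parents_only"` the ancestor vectors of terms 4
#' and 5 are (0,1,1,1,0) and (0,0,1,1,1), whose cosine similarity is 2/3.
#'
#' @return An `"Ontology"` with term ids `GO:0000001` .. `GO:0000005`.
#' @export
toy_ontology <- function() {
  ids <- sprintf("GO:%07d", 1:5)
  parents <- list(character(), character(), character(),
                  ids[c(2, 3)], ids[c(3, 4)])
  names(parents) <- ids
  build_ontology(parents,
                 names = setNames(paste("toy term", 1:5), ids))
}

#' Generate a random ontology DAG
#'
#' Terms are created in id order; each term after the first draws between
#' 1 and `max_parents` parents uniformly from the earlier terms, so the
#' graph is acyclic by construction with a single root.
#'
#' @param config A [synth_config()].
#' @return An `"Ontology"` with ids `GO:0000001` ...
#' @export
generate_ontology <- function(config) {
  n <- config$n_terms
  ids <- sprintf("GO:%07d", seq_len(n))
  parents <- .with_seed(config$seed, {
    out <- rep(list(character()), n)
    for (i in seq_len(n)[-1]) {
      np <- sample.int(min(config$max_parents, i - 1L), 1L)
      out[[i]] <- ids[sample.int(i - 1L, np)]
    }
    out
  })
  names(parents) <- ids
  build_ontology(parents, names = setNames(paste("synthetic term",
                                                 seq_len(n)), ids))
}

#' Generate an annotated PPI network with planted functional homophily
#'
#' Each protein receives a shifted-Poisson number (minimum 1, mean
#' `annotations_per_protein`) of distinct terms drawn uniformly from the
#' ontology.  Each unordered protein pair is connected with probability
#' `min(1, base_edge_prob + homophily * sim)` -- where `sim` is the
#' function-overlap [protein_similarity()] of the pair, i.e. the planted
#' signal is exactly the quantity the iterative predictor exploits -- and
#' independently with probability `noise_edge_prob` regardless of
#' function.  The output has no self-loops or duplicate edges and every
#' protein is annotated, so it passes [preprocess()] unchanged.
#'
#' @inheritParams generate_ontology
#' @param ontology A non-empty `"Ontology"` the annotations are drawn
#'   from.
#' @return List with elements `network` (an `"InteractionNetwork"`) and
#'   `annotations` (named list, protein -> direct term ids).
#' @export
generate_annotated_network <- function(config, ontology) {
  if (!length(ontology$ids))
    stop("generate_annotated_network: empty ontology")
  n <- config$n_proteins
  prots <- sprintf("P%04d", seq_len(n))
  .with_seed(config$seed + 1L, {
    counts <- 1L + rpois(n, config$annotations_per_protein - 1)
    counts <- pmin(counts, length(ontology$ids))
    ann <- lapply(counts, function(m)
      sort(sample(ontology$ids, m)))
    names(ann) <- prots
    edges <- list()
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in seq.int(i + 1L, n)) {
          s <- protein_similarity(ann[[i]], ann[[j]])
          pr <- min(1, config$base_edge_prob + config$homophily * s)
          hit <- runif(1) < pr
          noise <- config$noise_edge_prob > 0 &&
            runif(1) < config$noise_edge_prob
          if (hit || noise)
            edges[[length(edges) + 1L]] <- c(prots[i], prots[j])
        }
      }
    }
    em <- if (length(edges)) do.call(rbind, edges)
          else matrix(character(), ncol = 2)
    list(network = ppi_network(em, proteins = prots),
         annotations = ann)
  })
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG.
.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Write an ontology as an OBO flat file
#'
#' Emits a minimal OBO 1.2 document ([load_obo()] reads it back
#' identically); all parent edges are written as `is_a`.
#'
#' @inheritParams n_terms
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  lines <- c("format-version: 1.2",
             paste0("default-namespace: ", ontology$namespace), "")
  for (id in ontology$ids) {
    nm <- if (!is.null(ontology$names) && id %in% names(ontology$names))
      ontology$names[[id]] else id
    lines <- c(lines, "[Term]",
               paste0("id: ", id),
               paste0("name: ", nm),
               paste0("namespace: ", ontology$namespace),
               paste0("is_a: ", ontology$parents[[id]]),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotation map as a GAF 2.2 file
#'
#' One row per (protein, term) pair with the protein id in the DB object
#' symbol column; round-trips through [read_gaf()].
#'
#' @param annotations Annotation map.
#' @param path Output path.
#' @param aspect GO aspect code (`"P"`, `"F"` or `"C"`).
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, aspect = "P") {
  rows <- character()
  for (p in names(annotations)) {
    for (t in annotations[[p]]) {
      rows <- c(rows, paste(c("SYNTH", p, p, "", t, "SYNTH:0001", "IEA",
                              "", aspect, p, "", "protein", "taxon:0000",
                              "20260101", "SYNTH", "", ""),
                            collapse = "\t"))
    }
  }
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Write a network as a two-column edge-list TSV
#'
#' Header `protein_a<TAB>protein_b`; round-trips through
#' [read_edge_list()] (isolated proteins are not representable in an
#' edge list and are dropped).
#'
#' @inheritParams proteins
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  em <- interactions(network)
  lines <- c("protein_a\tprotein_b",
             if (nrow(em)) paste(em[, 1], em[, 2], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
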