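# Fixtures built in code: random small instances for fuzzing, adjacency
# extraction for the oracles, and a reusable 3-protein toy instance on
# the five-term DAG.

toy_ids <- sprintf("GO:%07d", 1:5)

# Adjacency list of an InteractionNetwork, for the oracle loops.
adjacency_of <- function(network) {
  setNames(lapply(proteins(network), function(p)
    protein_neighbors(network, p)), proteins(network))
}

# Random small instance: DAG ontology + network + annotations, all plain
# structures alongside the package objects.
random_instance <- function(seed, max_proteins = 10, max_terms = 20) {
  set.seed(seed)
  nt <- sample(3:max_terms, 1)
  np <- sample(3:max_proteins, 1)
  ids <- sprintf("GO:%07d", seq_len(nt))
  parents <- rep(list(character()), nt)
  names(parents) <- ids
  for (i in seq_len(nt)[-1]) {
    npar <- sample.int(min(2L, i - 1L), 1)
    parents[[i]] <- ids[sample.int(i - 1L, npar)]
  }
  ont <- build_ontology(parents)
  prots <- sprintf("P%02d", seq_len(np))
  ann <- setNames(lapply(seq_len(np), function(i)
    sort(sample(ids, sample.int(min(4L, nt), 1)))), prots)
  pairs <- t(combn(prots, 2))
  keep <- runif(nrow(pairs)) < 0.45
  net <- ppi_network(pairs[keep, , drop = FALSE], proteins = prots)
  list(ontology = ont, parents = parents, network = net,
       annotations = ann, proteins = prots)
}

# The 3-protein toy instance on the 5-term demonstration DAG: target p
# with neighbours p1 (annotated with term 4) and p2 (annotated with
# term 5).
toy_instance <- function() {
  ont <- toy_ontology()
  net <- ppi_network(rbind(c("p", "p1"), c("p", "p2")))
  ann <- list(p1 = toy_ids[4], p2 = toy_ids[5])
  list(ontology = ont, parents = ont$parents, network = net,
       annotations = ann)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal OBO text for the five-term DAG (with assorted format features
# exercised by the reader tests).
toy_obo_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: t1",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: t2",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000003", "name: t3",
    "namespace: biological_process", "alt_id: GO:0000033", "",
    "[Term]", "id: GO:0000004", "name: t4",
    "namespace: biological_process",
    "is_a: GO:0000002 ! t2", "is_a: GO:0000003 ! t3", "",
    "[Term]", "id: GO:0000005", "name: t5",
    "namespace: biological_process",
    "is_a: GO:0000003", "relationship: part_of GO:0000004", "")
}

gaf_line <- function(symbol, term, qualifier = "") {
  paste(c("SGD", symbol, symbol, qualifier, term, "REF:1", "IEA", "",
          "P", symbol, "", "protein", "taxon:4932", "20110101", "SGD",
          "", ""), collapse = "\t")
}
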