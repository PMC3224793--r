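# PPI network container (undirected, backed by igraph), readers for
# edge-list and BioGRID tab-delimited exports, GAF annotation reading, and
# the duplicate/self-interaction/unannotated-protein preprocessing filter.

#' Construct a protein interaction network
#'
#' @param edges Two-column character matrix or data frame of interacting
#'   protein pairs (undirected; orientation and duplicates are collapsed,
#'   self-loops are kept -- [preprocess()] removes them).
#' @param proteins Optional character vector of protein ids; defaults to
#'   the union of the edge endpoints.  Extra ids become isolated nodes.
#' @return Object of class `"InteractionNetwork"` wrapping an undirected
#'   `igraph` graph with named vertices.
#' @export
ppi_network <- function(edges = NULL, proteins = character()) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    # collapse orientation, then exact duplicates
    em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    em <- em[!duplicated(em), , drop = FALSE]
  }
  proteins <- sort(unique(c(as.character(proteins), as.vector(em))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = proteins, stringsAsFactors = FALSE))
  structure(list(graph = g), class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork: ", igraph::vcount(x$graph), " proteins, ",
      igraph::ecount(x$graph), " interactions\n", sep = "")
  invisible(x)
}

#' Protein ids of a network
#' @param network An [ppi_network()] object.
#' @return Character vector of protein identifiers (sorted).
#' @export
proteins <- function(network) sort(igraph::V(network$graph)$name)

#' Edge list of a network
#' @inheritParams proteins
#' @return Two-column character matrix of unordered interaction pairs.
#' @export
interactions <- function(network) {
  em <- igraph::as_edgelist(network$graph)
  if (nrow(em)) em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  colnames(em) <- c("protein_a", "protein_b")
  em
}

#' Direct interaction neighbours of a protein
#'
#' Only direct interaction partners count as neighbours; the protein
#' itself is never included (self-interactions are removed by
#' [preprocess()]).
#'
#' @inheritParams proteins
#' @param p A protein id present in the network.
#' @return Character vector of neighbour protein ids (sorted).
#' @export
protein_neighbors <- function(network, p) {
  if (!p %in% igraph::V(network$graph)$name)
    stop("unknown protein: ", p)
  nb <- igraph::neighbors(network$graph, p)$name
  sort(setdiff(unique(nb), p))
}

#' Read a two-column edge-list TSV
#'
#' Whitespace- or tab-separated, two protein ids per line.  A header row
#' is auto-detected (first line whose two fields match common column
#' names such as `protein_a`, `source`, `interactor_a`, `from`, `node1`).
#' Orientation and exact duplicates are collapsed; self-loops are kept at
#' read time and removed by [preprocess()].
#'
#' @param path Path to the file.
#' @return An `"InteractionNetwork"`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ppi_network())
  fields <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed edge-list line ", bad[1], ": expected 2 fields, got ",
         lengths(fields)[bad[1]])
  header_words <- c("protein_a", "protein_b", "proteina", "proteinb",
                    "protein1", "protein2", "source", "target", "from",
                    "to", "node1", "node2", "interactor_a", "interactor_b")
  first <- tolower(fields[[1]])
  if (all(first %in% header_words)) fields <- fields[-1]
  if (!length(fields)) return(ppi_network())
  ppi_network(do.call(rbind, fields))
}

#' Read a BioGRID tab-delimited interaction export
#'
#' Builds the network from the systematic-name columns of a TAB2-style
#' export (header row required).  Rows whose systematic names are empty
#' or `"-"` are skipped with a warning.  Optionally restricts to one
#' experimental system (e.g. `"Two-hybrid"` or `"Affinity Capture-MS"`).
#'
#' @param path Path to the BioGRID file.
#' @param experimental_system If non-`NULL`, keep only rows whose
#'   `Experimental System` column equals this value.
#' @return An `"InteractionNetwork"`.  Interaction scores/weights in the
#'   export are ignored: the model is unweighted.
#' @export
read_biogrid_tab <- function(path, experimental_system = NULL) {
  if (!file.exists(path)) stop("cannot read BioGRID file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "", quote = "")
  cols <- names(df)
  find_col <- function(pat) {
    hit <- grep(pat, cols, ignore.case = TRUE, value = TRUE)
    if (!length(hit))
      stop("BioGRID file missing required column matching '", pat, "'")
    hit[1]
  }
  ca <- find_col("Systematic Name.*(Interactor )?A")
  cb <- find_col("Systematic Name.*(Interactor )?B")
  if (!is.null(experimental_system)) {
    ce <- find_col("Experimental System")
    df <- df[df[[ce]] == experimental_system, , drop = FALSE]
  }
  a <- trimws(as.character(df[[ca]]))
  b <- trimws(as.character(df[[cb]]))
  ok <- nzchar(a) & nzchar(b) & a != "-" & b != "-"
  if (any(!ok))
    warning(sum(!ok), " BioGRID row(s) skipped: empty systematic name")
  ppi_network(cbind(a[ok], b[ok]))
}

#' Read protein annotations from a GAF 2.x file
#'
#' Maps the DB object symbol (column 3) to its set of directly annotated
#' term ids.  Rows whose qualifier contains `NOT` are excluded, alternate
#' ids are canonicalized through the ontology, and terms absent from the
#' ontology (other namespaces, obsolete ids) are dropped.
#'
#' @param path Path to the GAF file (`!` comment lines are skipped).
#' @param ontology Ontology used for namespace restriction and alt-id
#'   canonicalization.
#' @return An annotation map: named list, protein id -> character vector
#'   of directly annotated term ids.  Proteins whose annotations are all
#'   dropped do not appear.
#' @export
read_gaf <- function(path, ontology) {
  if (!file.exists(path)) stop("cannot read GAF file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^!", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(structure(list(), names = character()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 15L)
  if (length(bad))
    stop("malformed GAF line ", idx[bad[1]], ": expected >= 15 columns, got ",
         lengths(fields)[bad[1]])
  sym  <- vapply(fields, `[[`, "", 3L)
  qual <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  ok <- !grepl("(^|\\|)NOT($|\\|)", qual)
  term <- canonical_ids(ontology, term)
  ok <- ok & term %in% ontology$ids
  ann <- split(term[ok], sym[ok])
  ann <- lapply(ann, function(x) sort(unique(x)))
  ann[order(names(ann))]
}

#' Read annotations from a simple two-column TSV
#'
#' One `protein<TAB>term` pair per line (header auto-detected as in
#' [read_edge_list()]).  Terms are canonicalized and restricted to the
#' ontology as in [read_gaf()].
#'
#' @inheritParams read_gaf
#' @return An annotation map (named list of term-id character vectors).
#' @export
read_annotation_tsv <- function(path, ontology) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  fields <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed annotation line ", bad[1], ": expected 2 fields")
  if (tolower(fields[[1]][1]) %in% c("protein", "gene", "id"))
    fields <- fields[-1]
  if (!length(fields)) return(structure(list(), names = character()))
  prot <- vapply(fields, `[[`, "", 1L)
  term <- canonical_ids(ontology, vapply(fields, `[[`, "", 2L))
  ok <- term %in% ontology$ids
  ann <- split(term[ok], prot[ok])
  ann <- lapply(ann, function(x) sort(unique(x)))
  ann[order(names(ann))]
}

#' Filter a network and its annotations for prediction
#'
#' Applies the standard noise filters: duplicated interactions and
#' self-interactions are removed, and proteins without any GO annotation
#' are dropped from the network together with their incident edges.
#' Annotated proteins left without edges are retained -- they still count
#' towards the dataset size N and the per-term counts of the IDF weight.
#'
#' @inheritParams proteins
#' @param annotations Annotation map (named list, protein -> term ids).
#' @param keep Protein ids to retain even without annotation (e.g.
#'   prediction targets whose annotations are deliberately unknown).
#' @return List with elements `network` and `annotations` (entries for
#'   proteins absent from the network are kept -- the map is restricted
#'   only by dropping empty sets).  Inputs are not modified.
#' @export
preprocess <- function(network, annotations, keep = character()) {
  ann <- annotations[lengths(annotations) > 0L]
  g <- igraph::simplify(network$graph, remove.multiple = TRUE,
                        remove.loops = TRUE)
  retain <- igraph::V(g)$name[igraph::V(g)$name %in% c(names(ann), keep)]
  g <- igraph::induced_subgraph(g, retain)
  em <- igraph::as_edgelist(g)
  list(network = ppi_network(em, proteins = igraph::V(g)$name),
       annotations = ann)
}

#' Expand annotation sets to their ancestor closure
#'
#' Replaces every protein's direct annotation set by the union of the
#' reflexive ancestor closures of its terms.  Useful for sensitivity
#' analysis: the predictors themselves use direct sets, with ancestor
#' semantics confined to the cosine term similarity.
#'
#' @param annotations Annotation map.
#' @inheritParams read_gaf
#' @return Annotation map with ancestor-closed term sets.
#' @export
close_annotations <- function(annotations, ontology) {
  lapply(annotations, function(ts)
    sort(unique(unlist(lapply(ts, function(t) ancestors(ontology, t))))))
}

#' Candidate functions of a protein's neighbourhood
#'
#' `FN(p)`: the union of the direct annotation sets of p's neighbours.
#' These are the candidate functions any neighbourhood-based predictor
#' can assign to p.
#'
#' @inheritParams protein_neighbors
#' @param annotations Annotation map.
#' @return Sorted character vector of term ids (possibly empty).
#' @export
neighborhood_functions <- function(network, p, annotations) {
  nb <- protein_neighbors(network, p)
  sort(unique(unlist(annotations[intersect(nb, names(annotations))])))
}
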