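# Similarity-based selection against a reference set, and the similarity
# graph used to inspect chemical-space overlap between datasets.

kept_records <- function(records, what) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "smiles_std", "status") %in% names(records)))
  if (any(records$status != "KEPT")) {
    stop(what, " must contain only KEPT records; filter on status first",
         call. = FALSE)
  }
  records
}

#' Select query compounds similar to a reference set
#'
#' Computes fragment fingerprints for the standardized query and reference
#' structures and keeps every query compound whose maximum Tanimoto
#' similarity to any reference compound reaches `cutoff` (inclusive). Each
#' id is returned once regardless of how many reference compounds it
#' matches.
#'
#' @param query,reference compound record tibbles (all `KEPT`).
#' @param cutoff similarity threshold in `(0, 1]`; default 0.5.
#' @param depth fingerprint path depth in bonds.
#' @return Character vector of selected query `compound_id`s, in query
#'   order.
#' @export
select_similar <- function(query, reference, cutoff = 0.5, depth = 7L) {
  query <- kept_records(query, "query")
  reference <- kept_records(reference, "reference")
  if (nrow(reference) == 0) {
    stop("reference set is empty", call. = FALSE)
  }
  stopifnot(cutoff > 0, cutoff <= 1)
  if (nrow(query) == 0) return(character())
  fq <- fragment_fingerprints(query$smiles_std, depth = depth)
  fr <- fragment_fingerprints(reference$smiles_std, depth = depth)
  sim <- tanimoto_matrix(fq, fr)
  query$compound_id[apply(sim, 1, max) >= cutoff]
}

#' Build the query/reference similarity graph
#'
#' Nodes are all query and reference compounds (labelled by source
#' dataset); edges join every pair — within or between datasets — whose
#' fragment-fingerprint Tanimoto similarity reaches `threshold`. Connected
#' components and singletons summarize how the two datasets cluster in
#' chemical space.
#'
#' @inheritParams select_similar
#' @param threshold minimum Tanimoto similarity for an edge.
#' @return An `igraph` object with vertex attribute `dataset`
#'   (`"query"`/`"reference"`), edge attribute `weight`, and graph
#'   attribute `threshold`.
#' @seealso [similarity_graph_summary()], [write_similarity_graph()]
#' @export
build_similarity_graph <- function(query, reference, threshold = 0.5,
                                   depth = 7L) {
  query <- kept_records(query, "query")
  reference <- kept_records(reference, "reference")
  stopifnot(threshold > 0, threshold <= 1)
  ids <- c(query$compound_id, reference$compound_id)
  if (anyDuplicated(ids)) {
    stop("query and reference compound ids overlap", call. = FALSE)
  }
  smiles <- c(query$smiles_std, reference$smiles_std)
  dataset <- rep(c("query", "reference"), c(nrow(query), nrow(reference)))
  fps <- fragment_fingerprints(smiles, depth = depth)
  sim <- tanimoto_matrix(fps, fps)
  keep <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      weight = sim[keep])
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, dataset = dataset))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Summarize a similarity graph
#'
#' @param g graph from [build_similarity_graph()].
#' @return A list with `n_nodes`, `n_edges`, `n_components` and
#'   `n_singletons` (components of size one).
#' @export
similarity_graph_summary <- function(g) {
  comp <- igraph::components(g)
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       n_components = comp$no,
       n_singletons = sum(comp$csize == 1))
}

#' Export a similarity graph for external layout tools
#'
#' Writes GraphML (for force-directed viewers) and a plain edge-list CSV.
#'
#' @param g graph from [build_similarity_graph()].
#' @param dir output directory (created if needed).
#' @param name basename for the two files.
#' @return Invisibly, the paths written.
#' @export
write_similarity_graph <- function(g, dir, name = "similarity_graph") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  graphml <- file.path(dir, paste0(name, ".graphml"))
  igraph::write_graph(g, graphml, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  csv <- file.path(dir, paste0(name, "_edges.csv"))
  utils::write.csv(edges, csv, row.names = FALSE)
  invisible(c(graphml = graphml, edges = csv))
}
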