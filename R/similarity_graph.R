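#' Build the thresholded similarity graph
#'
#' Nodes are all proteins of the proteome (isolated proteins included); an
#' edge connects a scored pair iff its normalized score is strictly
#' greater than `T`. The comparison is exact: normalized scores are ratios
#' of integers and reproduce bit-identically, so no epsilon is applied.
#'
#' @param scored data.frame from [score_pairs()].
#' @param proteome The `PanProteome`.
#' @param T Similarity threshold in \[0, 100\]; the explored range is
#'   25-99 (T = 100 yields an edgeless graph since scores never exceed
#'   100).
#' @return A `SimilarityGraph`: list with `nodes` (all protein ids) and
#'   `edges` (data.frame `id_a`, `id_b`, `weight` = normalized score).
#' @export
build_graph <- function(scored, proteome, T) {
  stopifnot(T >= 0, T <= 100)
  keep <- scored$normalized > T
  edges <- data.frame(id_a = scored$id_a[keep],
                      id_b = scored$id_b[keep],
                      weight = scored$normalized[keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = proteome$proteins$protein_id, edges = edges),
            class = "SimilarityGraph")
}

#' @exportS3Method base::print
print.SimilarityGraph <- function(x, ...) {
  cat(sprintf("SimilarityGraph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Connected components of the similarity graph
#'
#' Maximal connected node sets: candidate homology neighbourhoods that
#' capture not only directly connected proteins but also those joined
#' through a path (potential distant homologs). Isolated proteins become
#' singleton components. Components are ordered by their smallest member
#' id.
#'
#' @param graph A `SimilarityGraph`.
#' @param proteome Optional `PanProteome` used to attach species labels to
#'   each component.
#' @return List of `SimilarityComponent` objects: each a list with
#'   `members` (sorted protein ids), `edges` (induced weighted edges) and
#'   `species` (genome id per member, when a proteome is given).
#' @export
connected_components <- function(graph, proteome = NULL) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(graph$nodes), name = graph$nodes)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$id_a, graph$edges$id_b))
  }
  comp <- igraph::components(g)
  membership <- comp$membership[graph$nodes]
  groups <- unname(split(graph$nodes, membership))
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1))]

  edge_comp <- if (nrow(graph$edges) > 0)
    membership[graph$edges$id_a] else integer(0)
  lapply(groups, function(members) {
    cid <- membership[members[1]]
    edges <- graph$edges[edge_comp == cid, , drop = FALSE]
    rownames(edges) <- NULL
    species <- if (is.null(proteome)) NULL else
      proteome$proteins$genome_id[match(members,
                                        proteome$proteins$protein_id)]
    structure(list(members = members, edges = edges, species = species),
              class = "SimilarityComponent")
  })
}
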