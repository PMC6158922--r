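# Independent oracles. Each reimplements a stage's definition from first
# principles, on a different code path from the package.

# reference Smith-Waterman: Biostrings dynamic programming
oracle_sw <- function(a, b) {
  mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
    scoreOnly = TRUE))
}

# brute-force candidate pairs: double loop over all protein pairs,
# distinct-k-mer intersections against the retained k-mer set
oracle_candidates <- function(proteome, index, I) {
  prot <- proteome$proteins
  retained <- lapply(prot$sequence, function(s)
    intersect(extract_kmers(s, index$k), index$kmers))
  total <- lengths(retained)
  n <- nrow(prot)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(retained[[i]], retained[[j]]))
      if (shared == 0) next
      # shorter: smaller length, then fewer distinct k-mers, then id
      o <- order(prot$length[c(i, j)], total[c(i, j)],
                 prot$protein_id[c(i, j)])
      tot_short <- total[c(i, j)][o[1]]
      if (shared > I * tot_short) {
        ids <- sort(prot$protein_id[c(i, j)])
        rows[[length(rows) + 1]] <- data.frame(
          id_a = ids[1], id_b = ids[2], shared = shared,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      shared = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

# transitive closure by plain union-find over the edge list
oracle_components <- function(nodes, edge_a, edge_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in seq_along(edge_a)) {
    ra <- find(edge_a[e]); rb <- find(edge_b[e])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(nodes, find, "")
  canon(unname(split(nodes, roots)))
}

# reference MCL: dense matrix, coded from the published procedure; same
# numerical contract (self-loops = max off-diagonal of the column or 1,
# expansion power 2, inflation, prune, column renormalization), clusters
# read as the weakly connected components of the strongest-attractor map
# (igraph, not union-find)
oracle_mcl <- function(members, mat, inflation, prune = 1e-5, tol = 1e-6,
                       max_iters = 100L) {
  n <- length(members)
  if (n == 1) return(list(members))
  for (j in seq_len(n)) {
    top <- max(mat[-j, j])
    mat[j, j] <- if (top > 0) top else 1
  }
  for (j in seq_len(n)) mat[, j] <- mat[, j] / sum(mat[, j])
  for (it in seq_len(max_iters)) {
    old <- mat
    mat <- mat %*% mat
    mat <- mat^inflation
    mat[mat < prune] <- 0
    for (j in seq_len(n)) {
      s <- sum(mat[, j])
      if (s > 0) mat[, j] <- mat[, j] / s
    }
    if (max(abs(mat - old)) < tol) break
  }
  attractor <- integer(n)
  for (j in seq_len(n)) attractor[j] <- which.max(mat[, j])
  g <- igraph::graph_from_edgelist(cbind(seq_len(n), attractor),
                                   directed = TRUE)
  memb <- igraph::components(g, mode = "weak")$membership
  canon(unname(split(members, memb)))
}
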