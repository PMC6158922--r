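#' Rescale the similarity scores of one component
#'
#' Prepares a similarity component for Markov clustering by applying, in
#' order: (1) subtract the similarity threshold `T` from every edge weight,
#' emphasising the small differences among highly similar homologs;
#' (2) for every species pair with at least one inter-species edge in the
#' component, compute the species distance `D = 100 - mean(original
#' normalized scores of those edges)` and add `D` to each of those edges'
#' working weights, making clustering insensitive to evolutionary
#' divergence between species (intra-species edges are untouched);
#' (3) raise every working weight to the power `C`, the contrast exponent.
#' Distances in step 2 use the original normalized scores, not the
#' subtracted ones, and are averaged over existing edges only. Absent
#' edges stay 0 throughout.
#'
#' @param component A `SimilarityComponent` with at least 2 members and
#'   species labels.
#' @param T Similarity threshold used to build the graph.
#' @param C Contrast exponent (>= 1).
#' @return A `ComponentMatrix`: list with `members` (ordered ids) and `mat`
#'   (dense symmetric non-negative matrix, zero diagonal).
#' @export
rescale_component <- function(component, T, C) {
  stopifnot(length(component$members) >= 2, C >= 1)
  members <- component$members
  edges <- component$edges
  sp <- setNames(component$species, members)
  w <- edges$weight - T
  if (nrow(edges) > 0) {
    sp_a <- sp[edges$id_a]
    sp_b <- sp[edges$id_b]
    inter <- sp_a != sp_b
    if (any(inter)) {
      key <- ifelse(sp_a < sp_b, paste(sp_a, sp_b, sep = "\r"),
                    paste(sp_b, sp_a, sep = "\r"))
      D <- 100 - tapply(edges$weight[inter], key[inter], mean)
      w[inter] <- w[inter] + D[key[inter]]
    }
  }
  w <- w^C
  mat <- matrix(0, length(members), length(members),
                dimnames = list(members, members))
  if (nrow(edges) > 0) {
    ia <- match(edges$id_a, members)
    ib <- match(edges$id_b, members)
    mat[cbind(ia, ib)] <- w
    mat[cbind(ib, ia)] <- w
  }
  structure(list(members = members, mat = mat), class = "ComponentMatrix")
}

#' Markov clustering of a component matrix
#'
#' Standard MCL: add a self-loop to each node (weight = the maximum
#' off-diagonal entry of its column, or 1 if the column is empty), column
#' normalize into a stochastic matrix, then iterate expansion (matrix
#' square), inflation (entrywise power `inflation` followed by column
#' renormalization) and pruning of entries below `prune` until the max-norm
#' change drops below `tol` or `max_iters` is reached (then a warning is
#' emitted and the current matrix is interpreted). Clusters are read off by
#' assigning every node to its column's strongest attractor (ties: lowest
#' index) and following attractor assignments to their fixpoint, so the
#' result is always a partition of the members.
#'
#' @param cm A `ComponentMatrix` (symmetric, non-negative, >= 1 member).
#' @param inflation MCL inflation `M` (> 1 to allow splitting; 1 leaves the
#'   component whole).
#' @param prune Entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param tol Convergence tolerance on the max-norm change (default 1e-6).
#' @param max_iters Iteration cap (default 100).
#' @return List of character vectors: the clusters, each sorted, ordered by
#'   smallest member id.
#' @export
run_mcl <- function(cm, inflation, prune = 1e-5, tol = 1e-6,
                    max_iters = 100L) {
  members <- cm$members
  nm <- length(members)
  if (nm == 1) return(list(members))
  M <- cm$mat
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")
  for (iter in seq_len(max_iters)) {
    prev <- M
    M <- M %*% M                      # expansion
    M <- M^inflation                  # inflation
    M[M < prune] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1                  # fully pruned column: keep zeros
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - prev)) < tol) break
    if (iter == max_iters) {
      warning("MCL did not converge after ", max_iters,
              " iterations; interpreting current matrix")
    }
  }
  # assign each node to its strongest attractor (ties: lowest index) and
  # merge along the attractor mapping with union-find, so attractor
  # systems (including periodic ones) form a single cluster
  target <- apply(M, 2, which.max)
  parent <- seq_len(nm)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nm)) {
    ri <- find(i); rt <- find(target[i])
    if (ri != rt) parent[max(ri, rt)] <- min(ri, rt)
  }
  labels <- vapply(seq_len(nm), find, 0L)
  clusters <- split(members, labels)
  clusters <- lapply(clusters, sort)
  unname(clusters[order(vapply(clusters, `[`, "", 1))])
}

#' Named default parameter settings d1-d8
#'
#' Eight graded settings from strict (`d1`: one-to-one orthologs among
#' close relatives) to relaxed (`d8`: broad multi-gene families across
#' distant species), linearly decreasing the four clustering parameters.
#' The similarity-threshold ladder T = 95, 85, ..., 25 follows the
#' per-setting minimum in-group scores such settings produce; the I, M and
#' C ladders are linear interpolations across the explored ranges
#' (I: 0.1-0.01, M: 9.6-1.2, C: 8-1) and are this package's
#' reconstruction, not authoritative values — override them freely.
#'
#' @return data.frame with columns `setting`, `I`, `T`, `M`, `C`.
#' @export
default_settings <- function() {
  data.frame(setting = paste0("d", 1:8),
             I = round(seq(0.1, 0.01, length.out = 8), 3),
             T = seq(95, 25, by = -10),
             M = round(seq(9.6, 1.2, length.out = 8), 2),
             C = seq(8, 1, length.out = 8),
             stringsAsFactors = FALSE)
}

#' Assemble a full parameter set for homology grouping
#'
#' Starts from a named default setting (or `d1` structure with explicit
#' values) and applies any explicit overrides, which always win.
#'
#' @param setting Optional name `"d1"`..`"d8"`.
#' @param I,T,M,C Optional explicit clustering parameters (intersection
#'   rate, similarity threshold, MCL inflation, contrast exponent).
#' @param k K-mer length (default 6).
#' @param p Abundance rate for the index filter (default 0.001).
#' @param c Per-species occurrence allowance (default 50).
#' @param mcl_prune,mcl_tol,mcl_max_iters MCL numerical knobs.
#' @return A named list of parameters.
#' @export
homology_settings <- function(setting = NULL, I = NULL, T = NULL, M = NULL,
                              C = NULL, k = 6L, p = 0.001, c = 50L,
                              mcl_prune = 1e-5, mcl_tol = 1e-6,
                              mcl_max_iters = 100L) {
  base <- list(I = 0.05, T = 65, M = 4, C = 3)
  if (!is.null(setting)) {
    tab <- default_settings()
    row <- tab[tab$setting == setting, ]
    if (nrow(row) != 1) stop("unknown setting: ", setting)
    base <- as.list(row[, c("I", "T", "M", "C")])
  }
  if (!is.null(I)) base$I <- I
  if (!is.null(T)) base$T <- T
  if (!is.null(M)) base$M <- M
  if (!is.null(C)) base$C <- C
  c(base, list(k = as.integer(k), p = p, c = as.integer(c),
               mcl_prune = mcl_prune, mcl_tol = mcl_tol,
               mcl_max_iters = as.integer(mcl_max_iters)))
}

#' Infer homology groups across a pan-proteome
#'
#' The end-to-end pipeline: build and filter the hexamer index, enumerate
#' intersecting candidate pairs, align and normalize them, build the
#' thresholded similarity graph, find its connected components, and split
#' each component into homology groups by rescaled Markov clustering.
#' Components of size 1 or 2 bypass MCL (a 2-node positive-weight graph is
#' always one MCL cluster). The result is a deterministic partition of the
#' protein ids.
#'
#' @param proteome A `PanProteome`.
#' @param settings A parameter list from [homology_settings()] (or a
#'   setting name, passed through).
#' @return List of character vectors (the homology groups, each sorted,
#'   ordered by smallest member id), with a `stats` attribute of per-stage
#'   counts.
#' @export
#' @examples
#' sim <- simulate_proteomes(family_spec(n_families = 3, seed = 7))
#' groups <- infer_homology_groups(sim$proteome, homology_settings("d4"))
#' length(groups)
infer_homology_groups <- function(proteome, settings = homology_settings()) {
  if (is.character(settings)) settings <- homology_settings(settings)
  idx <- build_index(proteome, k = settings$k)
  retained_raw <- length(idx$kmers)
  idx <- filter_index(idx, p = settings$p, c = settings$c,
                      n = proteome$n, m = proteome$m)
  pairs <- find_intersecting_pairs(idx, proteome, I = settings$I)
  scored <- score_pairs(pairs, proteome, index = idx)
  graph <- build_graph(scored, proteome, T = settings$T)
  comps <- connected_components(graph, proteome)
  groups <- list()
  for (comp in comps) {
    if (length(comp$members) <= 2) {
      groups <- c(groups, list(comp$members))
    } else {
      cm <- rescale_component(comp, T = settings$T, C = settings$C)
      groups <- c(groups, run_mcl(cm, inflation = settings$M,
                                  prune = settings$mcl_prune,
                                  tol = settings$mcl_tol,
                                  max_iters = settings$mcl_max_iters))
    }
  }
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  attr(groups, "stats") <- list(
    n_proteins = proteome$n, n_proteomes = proteome$m,
    kmers_extracted = retained_raw, kmers_retained = length(idx$kmers),
    candidate_pairs = nrow(pairs), naive_pairs = naive_all_pairs(proteome),
    edges = nrow(graph$edges), components = length(comps),
    groups = length(groups))
  groups
}
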