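#' Find intersecting protein pairs from the filtered k-mer index
#'
#' Two proteins intersect when the number of distinct retained k-mers they
#' share is strictly greater than `I` times the distinct retained k-mer
#' count of the shorter protein. Only intersecting pairs are aligned
#' downstream, which is what makes the pipeline scale. "Shorter" means
#' smaller residue length; ties break by fewer distinct k-mers, then by
#' lexicographically smaller id. Pairs within one proteome are allowed (in
#' paralogs). Proteins with no retained k-mers yield no candidates.
#'
#' @param index A filtered `KmerIndex`.
#' @param proteome The `PanProteome` the index was built from.
#' @param I Intersection rate in (0, 1]; the explored range is 0.01-0.1.
#' @return data.frame with columns `id_a`, `id_b` (`id_a < id_b`
#'   lexicographically) and `shared` (distinct shared k-mers), sorted by
#'   `id_a` then `id_b`.
#' @export
find_intersecting_pairs <- function(index, proteome, I) {
  stopifnot(I > 0, I <= 1)
  ids <- index$protein_ids
  stopifnot(identical(ids, proteome$proteins$protein_id))
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      shared = integer(0), stringsAsFactors = FALSE)
  if (ncol(index$presence) == 0) return(empty)

  # shared distinct k-mer counts for all pairs at once
  shared_mat <- Matrix::tcrossprod(index$presence)
  shared_mat <- Matrix::triu(shared_mat, k = 1)
  tri <- methods::as(methods::as(shared_mat, "generalMatrix"), "TsparseMatrix")
  if (length(tri@x) == 0) return(empty)
  a <- tri@i + 1L
  b <- tri@j + 1L
  shared <- as.integer(tri@x)

  total <- as.integer(Matrix::rowSums(index$presence))
  len <- proteome$proteins$length
  # distinct k-mer total of the shorter protein of each pair
  a_shorter <- .a_is_shorter(len[a], len[b], total[a], total[b],
                             ids[a], ids[b])
  shorter_total <- ifelse(a_shorter, total[a], total[b])
  keep <- shared > I * shorter_total
  a <- a[keep]; b <- b[keep]; shared <- shared[keep]
  if (length(a) == 0) return(empty)

  id_a <- pmin(ids[a], ids[b])
  id_b <- pmax(ids[a], ids[b])
  ord <- order(id_a, id_b)
  data.frame(id_a = id_a[ord], id_b = id_b[ord], shared = shared[ord],
             stringsAsFactors = FALSE)
}

#' Number of comparisons a naive all-pairs approach would make
#'
#' `n * (n - 1) / 2` for `n` proteins; the yardstick against which the
#' k-mer prefilter's reduction is measured.
#'
#' @param proteome A `PanProteome` (or an integer protein count).
#' @return A numeric count.
#' @export
naive_all_pairs <- function(proteome) {
  n <- if (inherits(proteome, "PanProteome")) proteome$n else as.numeric(proteome)
  n * (n - 1) / 2
}
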