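#' Extract the distinct k-mers of an amino-acid sequence
#'
#' Returns the set of distinct length-`k` substrings. K-mers containing a
#' non-standard residue (B, Z, X, U, O) are excluded: they cannot be
#' matched meaningfully and the informativeness argument for the default
#' k assumes the 20-letter alphabet.
#'
#' @param sequence Amino-acid string.
#' @param k K-mer length (default 6, hexamers).
#' @return Character vector of distinct k-mers; empty if the sequence is
#'   shorter than `k`.
#' @export
#' @examples
#' extract_kmers("MKVLAAT", 6)
extract_kmers <- function(sequence, k = 6L) {
  stopifnot(k >= 1)
  len <- nchar(sequence)
  if (len < k) return(character(0))
  kmers <- substring(sequence, 1:(len - k + 1), k:len)
  kmers <- kmers[!grepl("[BZXUO]", kmers)]
  unique(kmers)
}

# all k-mer occurrences (with multiplicity), same exclusion rule
.all_kmers <- function(sequence, k) {
  len <- nchar(sequence)
  if (len < k) return(character(0))
  kmers <- substring(sequence, 1:(len - k + 1), k:len)
  kmers[!grepl("[BZXUO]", kmers)]
}

#' Smallest informative k-mer length
#'
#' The smallest `k` for which the probability that a fixed random k-mer
#' occurs at least once in a uniform random sequence of length `L` over an
#' alphabet of size `alpha`, `1 - (1 - alpha^(-k))^(L - k + 1)`, does not
#' exceed `p`. With the protein alphabet (`alpha = 20`), the longest known
#' protein (`L = 30000`) and `p = 0.001` this gives 6, the package's
#' default k (hexamers).
#'
#' @param alpha Alphabet size (default 20).
#' @param L Sequence-length bound (default 30000).
#' @param p Tolerated random-occurrence probability (default 0.001).
#' @return The smallest suitable integer k.
#' @export
#' @examples
#' min_informative_k()  # 6
min_informative_k <- function(alpha = 20, L = 30000, p = 0.001) {
  stopifnot(alpha >= 2, L >= 1, p > 0, p < 1)
  k <- 1L
  repeat {
    positions <- max(L - k + 1, 1)
    prob <- 1 - (1 - alpha^(-k))^positions
    if (prob <= p) return(k)
    k <- k + 1L
  }
}

#' Build the k-mer inverted index of a pan-proteome
#'
#' Records, for every extracted k-mer, which proteins contain it (distinct
#' presence) and its total occurrence count across all proteins (with
#' multiplicity). Sharing between proteins is counted over distinct k-mers;
#' the abundance filter of [filter_index()] uses the occurrence counts.
#'
#' @param proteome A `PanProteome`.
#' @param k K-mer length (default 6).
#' @return A `KmerIndex`: list with `k`, `kmers` (retained k-mer strings),
#'   `presence` (sparse proteins x k-mers 0/1 matrix of distinct presence),
#'   `frequency` (integer occurrence count per k-mer), `protein_ids`.
#' @export
build_index <- function(proteome, k = 6L) {
  stopifnot(inherits(proteome, "PanProteome"))
  n <- proteome$n
  occ <- lapply(proteome$proteins$sequence, .all_kmers, k = k)
  all_occ <- unlist(occ, use.names = FALSE)
  kmers <- sort(unique(all_occ))
  if (length(kmers) == 0) {
    presence <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     dims = c(n, 0))
    freq <- integer(0)
  } else {
    distinct <- lapply(occ, unique)
    i <- rep(seq_len(n), lengths(distinct))
    j <- match(unlist(distinct, use.names = FALSE), kmers)
    presence <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                     dims = c(n, length(kmers)))
    freq <- tabulate(match(all_occ, kmers), nbins = length(kmers))
  }
  structure(list(k = as.integer(k),
                 kmers = kmers,
                 presence = presence,
                 frequency = as.integer(freq),
                 protein_ids = proteome$proteins$protein_id),
            class = "KmerIndex")
}

#' @exportS3Method base::print
print.KmerIndex <- function(x, ...) {
  cat(sprintf("KmerIndex: %d retained %d-mers over %d proteins\n",
              length(x$kmers), x$k, length(x$protein_ids)))
  invisible(x)
}

#' Postings list of a k-mer
#'
#' @param index A `KmerIndex`.
#' @param kmer A k-mer string.
#' @return Character vector of protein ids containing the k-mer (empty if
#'   the k-mer is not in the index).
#' @export
postings <- function(index, kmer) {
  j <- match(kmer, index$kmers)
  if (is.na(j)) return(character(0))
  index$protein_ids[Matrix::which(index$presence[, j] > 0)]
}

#' Distinct retained k-mers per protein
#'
#' @param index A `KmerIndex`.
#' @return Named integer vector: number of distinct retained k-mers of each
#'   protein.
#' @export
per_protein_kmers <- function(index) {
  counts <- as.integer(Matrix::rowSums(index$presence))
  setNames(counts, index$protein_ids)
}

#' Filter abundant and rare k-mers from the index
#'
#' Drops every k-mer whose total occurrence count exceeds `p * n + c * m`
#' (extremely abundant, e.g. low-complexity runs like "QQQQQQ") and every
#' k-mer with frequency 1 (rare: it cannot witness a shared pair). `n` and
#' `m` default to the indexed proteome's protein and proteome counts.
#'
#' @param index A `KmerIndex`.
#' @param p Abundance rate (default 0.001).
#' @param c Per-species occurrence allowance (default 50).
#' @param n Total protein count.
#' @param m Total proteome count.
#' @return The filtered `KmerIndex` (idempotent under refiltering).
#' @export
filter_index <- function(index, p = 0.001, c = 50L, n, m) {
  cutoff <- p * n + c * m
  keep <- index$frequency <= cutoff & index$frequency != 1L
  index$kmers <- index$kmers[keep]
  index$presence <- index$presence[, keep, drop = FALSE]
  index$frequency <- index$frequency[keep]
  index
}
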