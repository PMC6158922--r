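#' Alignment parameters
#'
#' BLOSUM62 scoring with affine gap penalties, gap opening -10 and gap
#' extension -1. A gap of length g costs `|open| + g * |extend|` = 10 + g:
#' the opening penalty is charged once and the extension penalty applies to
#' every gap residue including the first (the EMBOSS/BLAST convention; the
#' alternative, charging only `open` for the first residue, shifts
#' normalized scores slightly).
#'
#' @param gap_open Gap opening penalty (negative, default -10).
#' @param gap_extend Gap extension penalty (negative, default -1).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @return An `AlignmentParams` list.
#' @export
alignment_params <- function(gap_open = -10L, gap_extend = -1L,
                             matrix = blosum62()) {
  stopifnot(gap_open < 0, gap_extend < 0, isSymmetric(unname(matrix)))
  structure(list(gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 matrix = matrix),
            class = "AlignmentParams")
}

#' Smith-Waterman local alignment score
#'
#' Maximum-scoring local alignment under the Gotoh three-state recurrence
#' with affine gaps; score only, no traceback. The score is a non-negative
#' integer (the empty alignment scores 0) and symmetric in its arguments.
#'
#' @param seq_a,seq_b Amino-acid strings (non-empty).
#' @param params An [alignment_params()] object.
#' @return Integer raw score.
#' @export
#' @examples
#' smith_waterman("KVL", "KVL")  # 13
smith_waterman <- function(seq_a, seq_b, params = alignment_params()) {
  stopifnot(nchar(seq_a) >= 1, nchar(seq_b) >= 1)
  .sw_score_cpp(.encode_sequence(seq_a), .encode_sequence(seq_b),
                params$matrix, -params$gap_open, -params$gap_extend)
}

#' Self-alignment score of a protein
#'
#' The score of aligning a protein to itself. All BLOSUM62 diagonal entries
#' are positive, so the gapless full-identity alignment is optimal and the
#' self score is simply the sum of diagonal entries over the residues;
#' it equals `smith_waterman(s, s)`.
#'
#' @param sequence Amino-acid string (non-empty).
#' @param params An [alignment_params()] object.
#' @return Integer self score (strictly positive).
#' @export
#' @examples
#' self_score("AAA")  # 12
self_score <- function(sequence, params = alignment_params()) {
  stopifnot(nchar(sequence) >= 1)
  codes <- .encode_sequence(sequence) + 1L
  sum(diag(params$matrix)[codes])
}

#' Normalize a raw alignment score
#'
#' `100 * raw / shorter_self`, where `shorter_self` is the self-alignment
#' score of the shorter protein of the pair. Because a local alignment of
#' two proteins can never outscore the shorter protein aligned to itself,
#' the normalized score lies in \[0, 100\] and self-comparisons score
#' exactly 100, making scores comparable across protein lengths.
#'
#' @param raw Integer raw score.
#' @param shorter_self Self score of the shorter protein (positive).
#' @return Numeric normalized score.
#' @export
normalize_score <- function(raw, shorter_self) {
  if (any(shorter_self <= 0)) {
    stop("non-positive self score: corrupted matrix or empty sequence")
  }
  100 * raw / shorter_self
}

# which member of a pair is "shorter": smaller residue length, ties by
# fewer distinct retained k-mers, then lexicographically smaller id.
# Returns TRUE where a is the shorter. Used identically by the candidate
# filter and the normalizer so both stages agree.
.a_is_shorter <- function(len_a, len_b, kc_a, kc_b, id_a, id_b) {
  len_a < len_b |
    (len_a == len_b & (kc_a < kc_b | (kc_a == kc_b & id_a < id_b)))
}

#' Score candidate pairs
#'
#' Runs Smith-Waterman on every candidate pair and normalizes each raw
#' score by the self score of the pair's shorter protein (same tie-break as
#' the candidate stage).
#'
#' @param pairs data.frame from [find_intersecting_pairs()] (columns
#'   `id_a`, `id_b`).
#' @param proteome The `PanProteome`.
#' @param params An [alignment_params()] object.
#' @param index Optional `KmerIndex` supplying distinct k-mer counts for
#'   the equal-length tie-break; without it the tie-break falls through to
#'   the id comparison (scores are unaffected unless lengths tie AND self
#'   scores differ).
#' @return data.frame with columns `id_a`, `id_b`, `raw`, `normalized`, in
#'   the input pair order.
#' @export
score_pairs <- function(pairs, proteome, params = alignment_params(),
                        index = NULL) {
  prot <- proteome$proteins
  if (nrow(pairs) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      raw = integer(0), normalized = numeric(0),
                      stringsAsFactors = FALSE))
  }
  enc <- lapply(prot$sequence, .encode_sequence)
  diag_scores <- diag(params$matrix)
  selfs <- vapply(enc, function(e) sum(diag_scores[e + 1L]), 0)
  kc <- if (is.null(index)) rep(0L, nrow(prot)) else
    as.integer(Matrix::rowSums(index$presence))
  ia <- match(pairs$id_a, prot$protein_id)
  ib <- match(pairs$id_b, prot$protein_id)
  if (anyNA(ia) || anyNA(ib)) stop("pair id(s) not in the proteome")
  raw <- integer(nrow(pairs))
  go <- -params$gap_open
  ge <- -params$gap_extend
  for (p in seq_len(nrow(pairs))) {
    raw[p] <- .sw_score_cpp(enc[[ia[p]]], enc[[ib[p]]], params$matrix,
                            go, ge)
  }
  a_short <- .a_is_shorter(prot$length[ia], prot$length[ib],
                           kc[ia], kc[ib], pairs$id_a, pairs$id_b)
  shorter_self <- ifelse(a_short, selfs[ia], selfs[ib])
  data.frame(id_a = pairs$id_a, id_b = pairs$id_b, raw = raw,
             normalized = normalize_score(raw, shorter_self),
             stringsAsFactors = FALSE)
}
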