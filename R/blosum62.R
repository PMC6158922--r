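# BLOSUM62 with the extended ambiguity rows (B = N/D, Z = Q/E, X = any).
# Bundled as source so alignment never depends on external data files.
# U (selenocysteine), O (pyrrolysine) and J are scored as X.

.blosum62_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                       "B", "Z", "X")

.blosum62_values <- c(
   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0, -2, -1, -1,
  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3, -1,  0, -1,
  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,  4,  0, -1,
  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,  4,  1, -1,
   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1, -3, -3, -1,
  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,  0,  4, -1,
  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,  1,  4, -1,
   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3, -1, -2, -1,
  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,  0,  0, -1,
  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3, -3, -3, -1,
  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1, -4, -3, -1,
  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,  0,  1, -1,
  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1, -3, -1, -1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1, -3, -3, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2, -2, -1, -1,
   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,  0,  0, -1,
   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0, -1, -1, -1,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3, -4, -2, -1,
  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1, -3, -2, -1,
   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4, -3, -2, -1,
  -2, -1,  4,  4, -3,  0,  1, -1,  0, -3, -4,  0, -3, -3, -2,  0, -1, -4, -3, -3,  4,  0, -1,
  -1,  0,  0,  1, -3,  4,  4, -2,  0, -3, -3,  1, -1, -3, -1,  0, -1, -2, -2, -2,  0,  4, -1,
  -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1)

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 amino-acid substitution matrix including the
#' ambiguity rows B, Z and X, as an integer matrix with residue letters as
#' dimnames. U, O and J are not rows of the matrix; the aligner maps them
#' to X.
#'
#' @return A symmetric 23 x 23 integer matrix.
#' @export
#' @examples
#' blosum62()["K", "K"]
blosum62 <- function() {
  m <- matrix(as.integer(.blosum62_values), nrow = 23, byrow = TRUE,
              dimnames = list(.blosum62_letters, .blosum62_letters))
  m
}

# residue -> 0-based row index into blosum62(); U/O/J fold into X
.residue_codes <- function() {
  codes <- setNames(seq_along(.blosum62_letters) - 1L, .blosum62_letters)
  c(codes, U = codes[["X"]], O = codes[["X"]], J = codes[["X"]])
}

# Encode an amino-acid string as 0-based integer codes for the C++ kernel.
.encode_sequence <- function(sequence) {
  codes <- .residue_codes()
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- codes[chars]
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("residue(s) with no substitution-matrix entry: ",
         paste(bad, collapse = ", "))
  }
  as.integer(unname(idx))
}
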