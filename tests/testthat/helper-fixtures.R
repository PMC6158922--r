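# shared fixture builders (everything generated in code; no data files)

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_proteome <- function(n, len_range = c(10, 60), m = 2) {
  data.frame(
    protein_id = sprintf("p%03d", seq_len(n)),
    genome_id = sprintf("g%d", rep_len(seq_len(m), n)),
    sequence = vapply(sample(len_range[1]:len_range[2], n, TRUE),
                      random_protein, ""),
    stringsAsFactors = FALSE)
}

write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# canonical form of a partition, for set-of-sets comparison
canon <- function(groups) {
  out <- unname(lapply(groups, sort))
  out[order(vapply(out, `[`, "", 1))]
}
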