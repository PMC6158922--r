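#' @useDynLib panhomology, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
#' @importFrom stats setNames rgeom rbinom runif median
#' @importFrom utils write.table
NULL

# Accepted residue alphabet: 20 standard residues plus ambiguity letters.
.accepted_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                        "B", "Z", "X", "U", "O")
.standard_alphabet <- .accepted_alphabet[1:20]

#' Load one or more proteome FASTA files into a pan-proteome
#'
#' Each input file is one proteome (one genome/species). Every FASTA record
#' becomes one protein record labelled with the file's genome id. Sequences
#' are uppercased; terminal stop codons (`*`) are stripped; a `*` anywhere
#' else, or any letter outside the accepted amino-acid alphabet
#' (20 standard residues plus B, Z, X, U, O), is an error, as are duplicate
#' protein ids across the whole input.
#'
#' @param paths Character vector of protein FASTA file paths.
#' @param genome_ids Optional character vector of proteome labels, one per
#'   file. Defaults to the file basenames without extension.
#' @return An object of class `PanProteome`: a list with `proteins` (a
#'   data.frame with columns `protein_id`, `genome_id`, `sequence`,
#'   `length`), `n` (protein count) and `m` (proteome count).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1", "MKVLAAT", ">p2", "MKVW"), fa)
#' pp <- load_proteomes(fa)
#' pp$n
load_proteomes <- function(paths, genome_ids = NULL) {
  stopifnot(length(paths) >= 1)
  if (is.null(genome_ids)) {
    genome_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (length(genome_ids) != length(paths)) {
    stop("genome_ids must have the same length as paths")
  }
  recs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stop("unreadable file: ", paths[i])
    # Biostrings silently drops invalid residue codes with a warning;
    # promote that to the error the alphabet policy requires
    set <- withCallingHandlers(
      Biostrings::readAAStringSet(paths[i]),
      warning = function(w) {
        if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
          stop("sequence with characters outside the accepted amino-acid ",
               "alphabet in file: ", paths[i])
        invokeRestart("muffleWarning")
      })
    if (length(set) == 0) stop("empty FASTA file: ", paths[i])
    ids <- sub("\\s.*$", "", names(set))
    seqs <- toupper(as.character(set))
    seqs <- sub("\\*+$", "", seqs)  # strip terminal stops
    recs[[i]] <- data.frame(protein_id = ids,
                            genome_id = genome_ids[i],
                            sequence = unname(seqs),
                            stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, recs)
  .validate_proteins(proteins)
  proteins$length <- nchar(proteins$sequence)
  new_pan_proteome(proteins)
}

.validate_proteins <- function(proteins) {
  dup <- proteins$protein_id[duplicated(proteins$protein_id)]
  if (length(dup) > 0) {
    stop("duplicate protein_id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(nchar(proteins$sequence) < 1)) {
    stop("empty sequence for protein(s): ",
         paste(proteins$protein_id[nchar(proteins$sequence) < 1],
               collapse = ", "))
  }
  ok <- grepl(paste0("^[", paste(.accepted_alphabet, collapse = ""), "]+$"),
              proteins$sequence)
  if (!all(ok)) {
    stop("sequence with characters outside the accepted amino-acid ",
         "alphabet (or internal '*') in protein(s): ",
         paste(proteins$protein_id[!ok], collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a PanProteome from an in-memory protein table
#'
#' Lower-level constructor used by [load_proteomes()] and the simulator.
#'
#' @param proteins data.frame with columns `protein_id`, `genome_id`,
#'   `sequence` (and optionally `length`, recomputed here).
#' @return A `PanProteome` object.
#' @export
new_pan_proteome <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "genome_id", "sequence") %in%
                  names(proteins)))
  .validate_proteins(proteins)
  proteins$length <- nchar(proteins$sequence)
  rownames(proteins) <- NULL
  structure(list(proteins = proteins,
                 n = nrow(proteins),
                 m = length(unique(proteins$genome_id))),
            class = "PanProteome")
}

#' @exportS3Method base::print
print.PanProteome <- function(x, ...) {
  cat(sprintf("PanProteome: %d proteins from %d proteome(s)\n", x$n, x$m))
  cat(sprintf("  residue lengths: %d-%d (median %.0f)\n",
              min(x$proteins$length), max(x$proteins$length),
              stats::median(x$proteins$length)))
  invisible(x)
}

#' Write homology groups to a flat text file
#'
#' One line per group, `G<zero-padded index>: id1 id2 ...`, member ids in
#' lexicographic order. The groups must form a partition (no id twice); ids
#' must belong to `proteome` when one is supplied.
#'
#' @param groups List of character vectors of protein ids.
#' @param path Output file path.
#' @param proteome Optional `PanProteome` to validate ids against.
#' @return Invisibly, the path.
#' @export
write_groups <- function(groups, path, proteome = NULL) {
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("overlapping groups: protein id(s) appear in more than one group")
  }
  if (!is.null(proteome)) {
    missing <- setdiff(ids, proteome$proteins$protein_id)
    if (length(missing) > 0) {
      stop("group member(s) not in the proteome: ",
           paste(missing, collapse = ", "))
    }
  }
  lines <- character(length(groups))
  for (i in seq_along(groups)) {
    lines[i] <- sprintf("G%07d: %s", i,
                        paste(sort(groups[[i]]), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read homology groups from a group file or a two-column TSV
#'
#' Accepts the [write_groups()] format (`G...: id1 id2 ...`) or a TSV
#' mapping `protein_id<TAB>group_id`. Returns disjoint id sets; a protein
#' mapped to two groups is an error.
#'
#' @param path Input file path.
#' @return List of character vectors (one per group), in file order for the
#'   group format, or ordered by first appearance of the group key for TSV.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  if (grepl(":", lines[1], fixed = TRUE)) {
    parts <- strsplit(lines, ":", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed group line: ", lines[bad][1])
    groups <- lapply(parts, function(p) {
      ids <- strsplit(trimws(p[2]), "[[:space:]]+")[[1]]
      ids[nzchar(ids)]
    })
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed TSV line: ", lines[bad][1])
    pid <- vapply(parts, `[`, "", 1)
    gid <- vapply(parts, `[`, "", 2)
    groups <- split(pid, factor(gid, levels = unique(gid)))
    groups <- unname(lapply(groups, as.character))
  }
  ids <- unlist(groups, use.names = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("protein id(s) appear in more than one group: ",
         paste(dup, collapse = ", "))
  }
  groups
}

#' Write the similarity edge list as TSV
#'
#' Columns `id1`, `id2`, `normalized_score` (4 decimal places).
#'
#' @param scored data.frame of scored pairs (`id_a`, `id_b`, `normalized`).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_edges <- function(scored, path) {
  df <- data.frame(id1 = scored$id_a, id2 = scored$id_b,
                   normalized_score = sprintf("%.4f", scored$normalized))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
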