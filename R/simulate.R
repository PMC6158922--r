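# run code under a given seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic multi-species protein-family world
#'
#' Describes the fixture the simulator generates: `n_families` unrelated
#' ancestral proteins, each copied into every species (with
#' `copies_per_species` in-paralog copies) and independently mutated down
#' to the target `within_family_identity`. Defaults model a handful of
#' moderately diverged eukaryote-like proteomes: 20 families across 3
#' species, one or two copies each, ancestral lengths uniform on 100-400
#' residues, 90% residue identity per copy.
#'
#' @param n_families Number of gene families (default 20).
#' @param species Character vector of species labels (default 3 species).
#' @param copies_per_species Integer, or named integer vector per species
#'   (default 1); values > 1 create in-paralogs.
#' @param ancestral_length Length-2 integer range for ancestral lengths
#'   (default c(100, 400)).
#' @param within_family_identity Target fractional identity of each copy
#'   to its ancestor, in (0, 1] (default 0.9).
#' @param indel_rate Indels per substitution (default 0.01, i.e. 1 indel
#'   per 100 substitutions; lengths geometric with mean 2).
#' @param seed Integer seed; the same spec is byte-identical every time.
#' @return A `FamilySpec` list.
#' @export
family_spec <- function(n_families = 20L,
                        species = c("spA", "spB", "spC"),
                        copies_per_species = 1L,
                        ancestral_length = c(100L, 400L),
                        within_family_identity = 0.9,
                        indel_rate = 0.01,
                        seed = 1L) {
  stopifnot(n_families >= 1, length(species) >= 1,
            all(copies_per_species >= 1),
            within_family_identity > 0, within_family_identity <= 1,
            ancestral_length[1] >= 1,
            ancestral_length[2] >= ancestral_length[1])
  if (length(copies_per_species) > 1 &&
      !all(species %in% names(copies_per_species))) {
    stop("per-species copies_per_species must name every species")
  }
  structure(list(n_families = as.integer(n_families), species = species,
                 copies_per_species = copies_per_species,
                 ancestral_length = as.integer(ancestral_length),
                 within_family_identity = within_family_identity,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "FamilySpec")
}

.random_protein <- function(len) {
  paste(sample(.standard_alphabet, len, replace = TRUE), collapse = "")
}

# mutate an ancestral sequence to the target identity: uniform point
# substitutions (to one of the other 19 residues) plus occasional short
# indels (geometric length, mean 2)
.mutate_sequence <- function(ancestral, identity, indel_rate) {
  chars <- strsplit(ancestral, "", fixed = TRUE)[[1]]
  L <- length(chars)
  n_sub <- round((1 - identity) * L)
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    for (i in pos) {
      chars[i] <- sample(setdiff(.standard_alphabet, chars[i]), 1)
    }
  }
  n_indel <- if (n_sub > 0) rbinom(1, n_sub, min(1, indel_rate)) else 0L
  for (e in seq_len(n_indel)) {
    g <- rgeom(1, 0.5) + 1L  # mean 2
    if (runif(1) < 0.5 && length(chars) > g + 1) {     # deletion
      at <- sample.int(length(chars) - g + 1, 1)
      chars <- chars[-(at:(at + g - 1))]
    } else {                                           # insertion
      at <- sample.int(length(chars) + 1, 1)
      ins <- sample(.standard_alphabet, g, replace = TRUE)
      chars <- append(chars, ins, after = at - 1)
    }
  }
  paste(chars, collapse = "")
}

.draw_ancestors <- function(spec) {
  lens <- sample(spec$ancestral_length[1]:spec$ancestral_length[2],
                 spec$n_families, replace = TRUE)
  vapply(lens, .random_protein, "")
}

.copies_for <- function(spec, sp) {
  if (length(spec$copies_per_species) > 1)
    spec$copies_per_species[[sp]] else spec$copies_per_species
}

.expand_families <- function(spec, ancestors, identity) {
  fam_id <- sprintf("F%03d", seq_len(spec$n_families))
  rows <- list()
  for (f in seq_len(spec$n_families)) {
    for (sp in spec$species) {
      for (cp in seq_len(.copies_for(spec, sp))) {
        seq <- .mutate_sequence(ancestors[f], identity, spec$indel_rate)
        rows[[length(rows) + 1]] <- data.frame(
          protein_id = sprintf("%s_%s_c%d", fam_id[f], sp, cp),
          genome_id = sp, sequence = seq, family = fam_id[f],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a seeded synthetic pan-proteome with known homology groups
#'
#' Draws one random ancestral protein per family (uniform over the 20
#' standard residues) and, for every species and copy, mutates it to the
#' target identity by uniform point substitutions plus occasional short
#' indels. Unrelated random ancestors of realistic length are effectively
#' never confusable with true homologs, so the family assignment is an
#' exact ground truth. Same seed, same bytes.
#'
#' @param spec A [family_spec()].
#' @return List with `proteome` (a `PanProteome`, records ordered by
#'   family/species/copy), `truth` (list of id sets, one per family),
#'   `truth_df` (data.frame `protein_id`, `group_id`) and `ancestors`
#'   (the ancestral sequence of each family, for identity checks).
#' @export
simulate_proteomes <- function(spec) {
  stopifnot(inherits(spec, "FamilySpec"))
  ancestors <- .with_seed(spec$seed, .draw_ancestors(spec))
  tab <- .with_seed(spec$seed + 1L, {
    .expand_families(spec, ancestors, spec$within_family_identity)
  })
  .as_simulation(tab, ancestors)
}

.as_simulation <- function(tab, ancestors) {
  proteome <- new_pan_proteome(tab[, c("protein_id", "genome_id",
                                       "sequence")])
  truth <- unname(lapply(split(tab$protein_id, tab$family), sort))
  list(proteome = proteome, truth = truth,
       truth_df = data.frame(protein_id = tab$protein_id,
                             group_id = tab$family,
                             stringsAsFactors = FALSE),
       ancestors = ancestors)
}

#' Generate a ladder of fixtures that differ only in divergence
#'
#' All fixtures share the same ancestral sequences (drawn once from the
#' spec's seed); each identity level then mutates them with its own
#' deterministic sub-seed, so comparisons across the ladder isolate the
#' effect of divergence. A single-level ladder reproduces
#' [simulate_proteomes()] at that identity exactly.
#'
#' @param spec A [family_spec()] (its `within_family_identity` is ignored).
#' @param identities Numeric vector of identity levels, descending.
#' @return Named list (by identity) of simulation results as returned by
#'   [simulate_proteomes()].
#' @export
divergence_ladder <- function(spec, identities) {
  stopifnot(inherits(spec, "FamilySpec"), length(identities) >= 1,
            !is.unsorted(rev(identities)))
  ancestors <- .with_seed(spec$seed, .draw_ancestors(spec))
  out <- vector("list", length(identities))
  for (i in seq_along(identities)) {
    tab <- .with_seed(spec$seed + i, {
      .expand_families(spec, ancestors, identities[i])
    })
    out[[i]] <- .as_simulation(tab, ancestors)
  }
  names(out) <- as.character(identities)
  out
}

#' Write a simulated pan-proteome to disk
#'
#' One FASTA per species plus `truth.tsv` (`protein_id<TAB>group_id`).
#'
#' @param sim Result of [simulate_proteomes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (FASTA files, then the truth TSV).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- sim$proteome$proteins
  paths <- character(0)
  for (sp in unique(prot$genome_id)) {
    sub <- prot[prot$genome_id == sp, ]
    path <- file.path(dir, paste0(sp, ".fa"))
    writeLines(paste0(">", sub$protein_id, "\n", sub$sequence), path)
    paths <- c(paths, path)
  }
  truth_path <- file.path(dir, "truth.tsv")
  write.table(sim$truth_df, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(paths, truth_path))
}
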