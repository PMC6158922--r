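test_that("simulate_proteomes produces the declared counts and ids", {
  sim <- simulate_proteomes(family_spec(n_families = 2,
                                        species = c("s1", "s2", "s3"),
                                        seed = 31))
  expect_equal(sim$proteome$n, 6L)
  expect_equal(sim$proteome$m, 3L)
  expect_equal(length(sim$truth), 2L)
  expect_true(all(lengths(sim$truth) == 3))
  expect_equal(sort(unlist(sim$truth)),
               sort(sim$proteome$proteins$protein_id))
})

test_that("copies_per_species > 1 creates in-paralogs", {
  sim <- simulate_proteomes(family_spec(n_families = 3,
                                        species = c("s1", "s2"),
                                        copies_per_species = 2L,
                                        seed = 32))
  expect_equal(sim$proteome$n, 12L)
  per_sp <- table(sim$proteome$proteins$genome_id,
                  sim$truth_df$group_id)
  expect_true(all(per_sp == 2))
})

test_that("the same seed reproduces identical bytes", {
  spec <- family_spec(n_families = 4, seed = 33)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(simulate_proteomes(spec), d1)
  write_simulation(simulate_proteomes(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and a different seed does not
  d3 <- tempfile()
  write_simulation(simulate_proteomes(family_spec(n_families = 4,
                                                  seed = 34)), d3)
  expect_false(identical(readLines(file.path(d1, "spA.fa")),
                         readLines(file.path(d3, "spA.fa"))))
})

test_that("written fixtures round-trip through the loaders", {
  sim <- simulate_proteomes(family_spec(n_families = 3, seed = 35))
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  fastas <- paths[-length(paths)]
  pp <- load_proteomes(fastas)
  expect_equal(pp$n, sim$proteome$n)
  expect_equal(canon(load_truth(file.path(dir, "truth.tsv"))),
               canon(sim$truth))
})

test_that("divergence_ladder shares ancestors and honours its contract", {
  spec <- family_spec(n_families = 3, seed = 36)
  lad <- divergence_ladder(spec, c(0.95, 0.75, 0.55))
  expect_equal(length(lad), 3L)
  expect_identical(lad[[1]]$ancestors, lad[[3]]$ancestors)
  # a single-level ladder reproduces the plain generator
  spec9 <- family_spec(n_families = 3, within_family_identity = 0.9,
                       seed = 36)
  one <- divergence_ladder(spec9, 0.9)
  expect_identical(one[[1]]$proteome$proteins,
                   simulate_proteomes(spec9)$proteome$proteins)
  expect_error(divergence_ladder(spec, numeric(0)))
  expect_error(divergence_ladder(spec, c(0.5, 0.9)))  # not descending
})

test_that("branch identities land within 5 points of the target", {
  # indel-free spec so positional identity is exact
  spec <- family_spec(n_families = 10, species = c("s1", "s2"),
                      within_family_identity = 0.85, indel_rate = 0,
                      seed = 37)
  sim <- simulate_proteomes(spec)
  prot <- sim$proteome$proteins
  fam <- sim$truth_df$group_id
  idents <- numeric(0)
  for (i in seq_len(nrow(prot))) {
    anc <- sim$ancestors[as.integer(sub("F", "", fam[i]))]
    a <- strsplit(anc, "")[[1]]
    b <- strsplit(prot$sequence[i], "")[[1]]
    idents <- c(idents, mean(a == b))
  }
  expect_true(all(abs(idents - 0.85) < 0.05))
})

test_that("between-family similarity stays below 30 (regression)", {
  sim <- simulate_proteomes(family_spec(n_families = 6,
                                        species = c("s1", "s2"),
                                        ancestral_length = c(100, 200),
                                        seed = 38))
  prot <- sim$proteome$proteins
  fam <- sim$truth_df$group_id
  for (i in seq(1, 10)) {
    j <- i + 2  # a member of the next family
    if (fam[i] == fam[j]) next
    raw <- smith_waterman(prot$sequence[i], prot$sequence[j])
    norm <- normalize_score(raw, min(self_score(prot$sequence[i]),
                                     self_score(prot$sequence[j])))
    expect_lt(norm, 30)
  }
})
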