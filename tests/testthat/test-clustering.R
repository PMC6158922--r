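make_component <- function(members, species, edges) {
  structure(list(members = members,
                 edges = data.frame(id_a = edges$id_a, id_b = edges$id_b,
                                    weight = edges$weight,
                                    stringsAsFactors = FALSE),
                 species = species),
            class = "SimilarityComponent")
}

test_that("rescale_component applies the three steps in order", {
  # single species: subtract T only, contrast 1
  comp <- make_component(c("a", "b"), c("g1", "g1"),
                         list(id_a = "a", id_b = "b", weight = 96))
  cm <- rescale_component(comp, T = 95, C = 1)
  expect_equal(cm$mat["a", "b"], 1)
  expect_equal(cm$mat["b", "a"], 1)
  expect_equal(diag(cm$mat), c(a = 0, b = 0))

  # two species: D = 100 - mean(60, 80) = 30 added to inter-species edges
  comp2 <- make_component(
    c("a", "b", "c"), c("g1", "g2", "g2"),
    list(id_a = c("a", "a"), id_b = c("b", "c"), weight = c(60, 80)))
  cm2 <- rescale_component(comp2, T = 25, C = 1)
  expect_equal(cm2$mat["a", "b"], (60 - 25) + 30)
  expect_equal(cm2$mat["a", "c"], (80 - 25) + 30)
  expect_equal(cm2$mat["b", "c"], 0)  # absent edge stays 0

  # intra-species edges skip the distance correction; contrast cubes
  comp3 <- make_component(
    c("a", "b", "c"), c("g1", "g1", "g2"),
    list(id_a = c("a", "a"), id_b = c("b", "c"), weight = c(27, 75)))
  cm3 <- rescale_component(comp3, T = 25, C = 3)
  expect_equal(cm3$mat["a", "b"], (27 - 25)^3)            # 8
  expect_equal(cm3$mat["a", "c"], ((75 - 25) + 25)^3)     # D = 100 - 75
})

test_that("species distances are averaged per species pair", {
  comp <- make_component(
    c("a1", "a2", "b1"), c("g1", "g1", "g2"),
    list(id_a = c("a1", "a2", "a1"), id_b = c("b1", "b1", "a2"),
         weight = c(60, 80, 90)))
  cm <- rescale_component(comp, T = 25, C = 1)
  # g1-g2 distance D = 100 - mean(60, 80) = 30; intra edge untouched
  expect_equal(cm$mat["a1", "b1"], 35 + 30)
  expect_equal(cm$mat["a2", "b1"], 55 + 30)
  expect_equal(cm$mat["a1", "a2"], 65)
})

test_that("run_mcl separates exact blocks and keeps singletons whole", {
  members <- sprintf("m%d", 1:4)
  mat <- matrix(0, 4, 4, dimnames = list(members, members))
  mat[1, 2] <- mat[2, 1] <- 5
  mat[3, 4] <- mat[4, 3] <- 7
  cl <- run_mcl(list(members = members, mat = mat), inflation = 2)
  expect_equal(canon(cl), list(c("m1", "m2"), c("m3", "m4")))
  expect_equal(run_mcl(list(members = "solo",
                            mat = matrix(0, 1, 1)), 2), list("solo"))
})

test_that("run_mcl splits a barbell into its two triangles", {
  members <- sprintf("v%d", 1:6)
  mat <- matrix(0, 6, 6, dimnames = list(members, members))
  tri <- function(i, j) mat[i, j] <<- mat[j, i] <<- 10
  tri(1, 2); tri(1, 3); tri(2, 3)
  tri(4, 5); tri(4, 6); tri(5, 6)
  mat[3, 4] <- mat[4, 3] <- 1  # weak bridge
  cm <- list(members = members, mat = mat)
  cl <- run_mcl(cm, inflation = 2)
  expect_equal(canon(cl), list(c("v1", "v2", "v3"), c("v4", "v5", "v6")))
  # and the independent reference agrees
  expect_equal(canon(cl), oracle_mcl(members, mat, inflation = 2))
})

test_that("run_mcl matches the reference MCL on random matrices (oracle)", {
  set.seed(414)
  for (rep in 1:30) {
    n <- sample(2:30, 1)
    members <- sprintf("m%02d", seq_len(n))
    mat <- matrix(0, n, n, dimnames = list(members, members))
    n_edges <- sample(n:(3 * n), 1)
    for (e in seq_len(n_edges)) {
      ij <- sample(n, 2)
      w <- round(runif(1, 0.5, 20), 2)
      mat[ij[1], ij[2]] <- mat[ij[2], ij[1]] <- w
    }
    M <- sample(c(1.5, 2, 4, 6), 1)
    got <- suppressWarnings(run_mcl(list(members = members, mat = mat), M))
    want <- suppressWarnings(oracle_mcl(members, mat, M))
    expect_equal(canon(got), want)
  }
})

test_that("default_settings ladder is graded strict to relaxed", {
  tab <- default_settings()
  expect_equal(tab$setting, paste0("d", 1:8))
  expect_equal(tab$T, seq(95, 25, by = -10))
  expect_true(all(diff(tab$I) < 0))
  expect_true(all(diff(tab$M) < 0))
  expect_true(all(diff(tab$C) < 0))
  expect_true(all(tab$I >= 0.01 & tab$I <= 0.1))
  s <- homology_settings("d3", M = 2)
  expect_equal(s$T, 75)
  expect_equal(s$M, 2)  # explicit override wins
  expect_error(homology_settings("d9"), "unknown setting")
})

test_that("mutually dissimilar proteins come out as singletons", {
  set.seed(415)
  tab <- random_proteome(8, len_range = c(30, 60), m = 2)
  pp <- new_pan_proteome(tab)
  groups <- infer_homology_groups(pp, homology_settings("d5"))
  expect_equal(length(groups), 8L)
  expect_true(all(lengths(groups) == 1))
})

test_that("exact duplicate families form exact groups", {
  seqs <- c("MKVLAWYHRNDEQPLV", "WYHRGGSTPACDEFIK")
  tab <- data.frame(
    protein_id = sprintf("p%d", 1:6),
    genome_id = rep(c("g1", "g2", "g3"), 2),
    sequence = rep(seqs, each = 3), stringsAsFactors = FALSE)
  pp <- new_pan_proteome(tab)
  groups <- infer_homology_groups(pp, homology_settings(I = 0.05, T = 50,
                                                        M = 2, C = 1, k = 3))
  expect_equal(canon(groups),
               list(c("p1", "p2", "p3"), c("p4", "p5", "p6")))
})

test_that("groups always partition the input and respect components", {
  set.seed(416)
  sim <- simulate_proteomes(family_spec(n_families = 6, seed = 21))
  groups <- infer_homology_groups(sim$proteome, homology_settings("d5"))
  ids <- unlist(groups)
  expect_setequal(ids, sim$proteome$proteins$protein_id)
  expect_equal(anyDuplicated(ids), 0L)
  # every group is contained in one similarity component
  st <- homology_settings("d5")
  idx <- filter_index(build_index(sim$proteome, st$k), st$p, st$c,
                      sim$proteome$n, sim$proteome$m)
  scored <- score_pairs(find_intersecting_pairs(idx, sim$proteome, st$I),
                        sim$proteome, index = idx)
  comps <- connected_components(build_graph(scored, sim$proteome, st$T))
  comp_members <- lapply(comps, `[[`, "members")
  for (g in groups) {
    expect_true(any(vapply(comp_members,
                           function(cc) all(g %in% cc), TRUE)))
  }
})
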