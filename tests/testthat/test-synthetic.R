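test_that("collections are deterministic and have the designed gene content", {
  d <- pangenome_design(c(soil = 2, water = 2), core_size = 50,
                        habitat_core_size = 0, cloud_size = 0,
                        gene_length_range = c(50, 80), seed = 7)
  col <- generate_pangenome_collection(d)
  # core-only design: every genome has exactly core_size genes
  expect_true(all(vapply(col$genomes, function(g) length(g$proteins),
                         integer(1)) == 50))
  col2 <- generate_pangenome_collection(d)
  expect_identical(
    lapply(col$genomes, function(g) as.character(g$proteins)),
    lapply(col2$genomes, function(g) as.character(g$proteins))
  )
  expect_identical(col$truth, col2$truth)
  # gene ids unique collection-wide, every family has a member
  expect_false(anyDuplicated(col$truth$gene_id) > 0)
  expect_true(all(table(col$truth$family_id) >= 1))
})

test_that("mutate_protein substitutes the exact rounded count and nothing else", {
  s <- rand_prot(20, seed = 3)
  expect_identical(mutate_protein(s, 100, seed = 1), s)
  m <- mutate_protein(s, 75, seed = 1)
  expect_equal(nchar(m), 20)
  diffs <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(diffs, 5)  # round(20 * 0.25)
  expect_error(mutate_protein("", 90), "non-empty")
  expect_error(mutate_protein(s, 0), "target_identity")
  expect_error(mutate_protein(s, 101), "target_identity")
})

test_that("mutator hits its identity target under global alignment", {
  s <- rand_prot(100, seed = 5)
  m <- mutate_protein(s, 80, seed = 9)
  expect_equal(global_identity(s, m), 80, tolerance = 1e-9)
})

test_that("within-family pairwise identity matches the design target", {
  col <- small_recovery_collection(n_genomes = 3, n_families = 20,
                                   identity = 90, seed = 13)
  fam_of <- stats::setNames(col$truth$family_id, col$truth$gene_id)
  seqs <- unlist(lapply(col$genomes, function(g) as.character(g$proteins)))
  names(seqs) <- unlist(lapply(col$genomes, function(g) names(g$proteins)))
  idents <- c()
  for (f in unique(fam_of)) {
    members <- names(fam_of)[fam_of == f]
    for (i in seq_len(length(members) - 1)) {
      for (j in seq(i + 1, length(members))) {
        st <- pairwise_align(seqs[[members[i]]], seqs[[members[j]]])
        idents <- c(idents, st$identity)
      }
    }
  }
  expect_gte(mean(idents), 85)
  expect_lte(mean(idents), 95)
})

test_that("network generators produce the requested graphs deterministically", {
  g <- generate_network("preferential_attachment", n = 100, m = 2, seed = 1)
  expect_equal(igraph::vcount(g), 100)
  expect_true(igraph::is_connected(g))
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  g2 <- generate_network("preferential_attachment", n = 100, m = 2, seed = 1)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))

  h <- generate_network("hierarchical_modular", module_size = 5, levels = 3)
  expect_equal(igraph::vcount(h), 125)
  expect_false(igraph::any_loop(h))
  expect_error(generate_network("preferential_attachment", n = 3),
               "n >= 4")
})

test_that("PA degree exponent agrees with an independent tally-and-fit", {
  g <- generate_network("preferential_attachment", n = 2000, m = 3, seed = 5)
  mine <- power_law_fit(degree_distribution(g))$exponent
  # oracle: raw histogram + log-log regression, built from scratch
  k <- igraph::degree(g)
  tab <- table(k)
  x <- as.numeric(names(tab))
  y <- as.numeric(tab) / length(k)
  fit <- stats::lm(log10(y) ~ log10(x))
  oracle <- -unname(coef(fit)[2])
  expect_lt(abs(mine - oracle), 0.4)
})

test_that("trait matrices have planted blocks, shape and noise behaviour", {
  m <- generate_trait_matrix(6, 10, blocks = 2, flip_noise = 0, seed = 4)
  expect_equal(dim(m), c(6, 10))
  blk <- attr(m, "block")
  for (b in unique(blk)) {
    rows <- m[blk == b, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(x) length(unique(x)) == 1)))
  }
  # distinct blocks differ
  expect_false(all(m[1, ] == m[6, ]))
  expect_error(generate_trait_matrix(1, 10), "n_genomes")
  expect_error(generate_trait_matrix(6, 10, flip_noise = 0.6), "flip_noise")
})

test_that("clade genomes carry the planted divergence hierarchy", {
  gs <- generate_clade_genomes(2, 2, genome_length = 2000,
                               within_divergence = 0.02,
                               between_divergence = 0.2, seed = 2)
  expect_equal(length(gs), 4)
  sites <- do.call(rbind, strsplit(as.character(gs), ""))
  pdiff <- function(i, j) mean(sites[i, ] != sites[j, ])
  within <- c(pdiff(1, 2), pdiff(3, 4))
  between <- c(pdiff(1, 3), pdiff(1, 4), pdiff(2, 3), pdiff(2, 4))
  expect_lt(max(within), min(between))
})

test_that("truth matrix reflects planted incidence exactly", {
  d <- pangenome_design(c(a = 2, b = 2), core_size = 3, habitat_core_size = 2,
                        cloud_size = 0, gene_length_range = c(50, 60),
                        seed = 21)
  col <- generate_pangenome_collection(d)
  tm <- truth_matrix(col)
  expect_equal(dim(tm), c(3 + 2 * 2, 4))
  core_rows <- grep("^core", rownames(tm))
  expect_true(all(tm[core_rows, ] == 1))
  a_rows <- grep("^pc_a_", rownames(tm))
  expect_true(all(tm[a_rows, grep("^a_", colnames(tm))] == 1))
  expect_true(all(tm[a_rows, grep("^b_", colnames(tm))] == 0))
})
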