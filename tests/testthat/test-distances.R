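test_that("Poisson correction matches closed forms and is monotone in p", {
  # two sequences differing at half their sites
  a <- paste(rep("AR", 50), collapse = "")
  b <- paste(rep("AK", 50), collapse = "")
  d <- poisson_distance_matrix(c(s1 = a, s2 = b))
  expect_equal(d["s1", "s2"], -log(0.5), tolerance = 1e-9)
  expect_equal(round(d["s1", "s2"], 4), 0.6931)

  # p = 0.1 over 100 sites
  a2 <- paste(rep("A", 100), collapse = "")
  b2 <- paste(c(rep("R", 10), rep("A", 90)), collapse = "")
  d2 <- poisson_distance_matrix(c(s1 = a2, s2 = b2))
  expect_equal(d2["s1", "s2"], 0.10536, tolerance = 1e-4)

  # identical -> 0; d >= p always, increasing in p
  expect_equal(poisson_distance_matrix(c(x = a, y = a))["x", "y"], 0)
  ps <- seq(0.05, 0.9, by = 0.05)
  ds <- -log(1 - ps)
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds >= ps))

  # saturated pair flagged as infinite
  expect_warning(
    dinf <- poisson_distance_matrix(c(x = "AAAA", y = "RRRR")),
    "infinite"
  )
  expect_true(is.infinite(dinf["x", "y"]))
})

test_that("gap columns are removed by complete deletion", {
  aln <- c(s1 = "AR-KL", s2 = "AR-KL", s3 = "AK-KI")
  d <- poisson_distance_matrix(aln)
  # 4 ungapped columns; s1 vs s3 differ at 2 of 4
  expect_equal(d["s1", "s3"], -log(1 - 0.5), tolerance = 1e-12)
  expect_equal(d["s1", "s2"], 0)
  expect_error(poisson_distance_matrix(c(a = "-", b = "-")), "no columns")
})

test_that("NJ reproduces additive distances exactly", {
  # additive matrix from tree ((A:2,B:3):1,(C:4,D:5))
  lab <- c("A", "B", "C", "D")
  m <- matrix(0, 4, 4, dimnames = list(lab, lab))
  m["A", "B"] <- m["B", "A"] <- 5
  m["A", "C"] <- m["C", "A"] <- 7
  m["A", "D"] <- m["D", "A"] <- 8
  m["B", "C"] <- m["C", "B"] <- 8
  m["B", "D"] <- m["D", "B"] <- 9
  m["C", "D"] <- m["D", "C"] <- 9
  tr <- nj_tree(m)
  path <- ape::cophenetic.phylo(tr)
  expect_equal(path[lab, lab], m, tolerance = 1e-10)

  # three taxa: closed-form branch lengths {1, 2, 3}
  m3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(m3)
  expect_setequal(round(tr3$edge.length, 10), c(1, 2, 3))

  m[1, 2] <- m[2, 1] <- Inf
  expect_error(nj_tree(m), "non-finite")
})

test_that("bootstrap support is 100% for a clean 2-clade alignment", {
  aln <- c(A1 = paste(rep("AR", 30), collapse = ""),
           A2 = paste(rep("AR", 30), collapse = ""),
           B1 = paste(rep("AK", 30), collapse = ""),
           B2 = paste(rep("AK", 30), collapse = ""))
  d <- poisson_distance_matrix(aln, bootstrap_reps = 100, seed = 7)
  reps <- attr(d, "replicates")
  expect_length(reps, 100)
  tr <- nj_tree(d, support_matrices = reps)
  expect_true(100 %in% tr$node.label)
  # replicate determinism
  d2 <- poisson_distance_matrix(aln, bootstrap_reps = 100, seed = 7)
  expect_identical(reps, attr(d2, "replicates"))
})

test_that("correlation dendrograms respect 1 - r distances and block structure", {
  x <- rbind(p1 = c(1, 2, 3, 4), p2 = c(2, 4, 6, 8), p3 = c(4, 3, 2, 1))
  tr <- expect_silent(correlation_dendrogram(x))
  cop <- ape::cophenetic.phylo(tr)
  expect_equal(cop["p1", "p2"], 0, tolerance = 1e-12)  # r = 1
  # perfectly anticorrelated pair -> distance 2
  tr2 <- correlation_dendrogram(x[c("p1", "p3"), ])
  expect_equal(ape::cophenetic.phylo(tr2)["p1", "p3"], 2, tolerance = 1e-12)
  expect_error(correlation_dendrogram(rbind(a = c(1, 1), b = c(1, 2))),
               "constant")

  # noiseless 2-block trait matrix splits at the root
  m <- generate_trait_matrix(8, 12, blocks = 2, flip_noise = 0, seed = 5)
  blk <- attr(m, "block")
  trb <- correlation_dendrogram(m)
  expect_setequal(trb$tip.label, rownames(m))
  expect_true(ape::is.monophyletic(trb, rownames(m)[blk == 1]))
  expect_true(ape::is.monophyletic(trb, rownames(m)[blk == 2]))
})

test_that("fragment ANI handles identity, strands and planted divergence", {
  g <- rand_dna(5000, seed = 14)
  expect_equal(as.numeric(ani_fragment(g, g, fragment_length = 1020)), 100)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  expect_equal(as.numeric(ani_fragment(g, rc, fragment_length = 1020)), 100)
  # 5% substituted copy -> ANI ~ 95
  mut <- substitute_dna(g, 250, seed = 15)
  ani <- as.numeric(ani_fragment(g, mut, fragment_length = 1020))
  expect_equal(ani, 95, tolerance = 0.5 / 95)
})

test_that("ANI matrices are symmetric and separate planted clades", {
  gs <- generate_clade_genomes(2, 2, genome_length = 4000,
                               within_divergence = 0.02,
                               between_divergence = 0.2, seed = 3)
  m <- ani_matrix(gs, mode = "whole_genome", fragment_length = 1000)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 100))
  clade <- attr(gs, "clade")
  within <- c(m[1, 2], m[3, 4])
  between <- c(m[1, 3], m[1, 4], m[2, 3], m[2, 4])
  expect_gt(min(within), max(between))

  # ortholog-core mode: identical gene sets give 100
  genes <- Biostrings::DNAStringSet(c(g1.f1 = rand_dna(300, seed = 4),
                                      g1.f2 = rand_dna(300, seed = 5)))
  x <- list(
    g1 = stats::setNames(genes, c("g1.f1", "g1.f2")),
    g2 = stats::setNames(genes, c("g2.f1", "g2.f2")),
    g3 = stats::setNames(genes, c("g3.f1", "g3.f2"))
  )
  cl <- structure(lapply(1:2, function(i) {
    list(cluster_id = paste0("C", i),
         members = data.frame(genome_id = c("g1", "g2", "g3"),
                              gene_id = paste0(c("g1", "g2", "g3"), ".f", i)))
  }), class = "ortholog_clusters")
  mo <- ani_matrix(x, mode = "ortholog_core", clusters = cl)
  expect_true(all(mo[upper.tri(mo)] == 100))
})
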