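test_that("pairwise_align reports identity, coverage and errors as specified", {
  s <- rand_prot(20, seed = 1)
  st <- pairwise_align(s, s)
  expect_equal(st$identity, 100)
  expect_equal(st$query_coverage, 100)

  # interior substitutions so the local alignment spans all 20 columns
  chars <- strsplit(s, "")[[1]]
  for (p in c(4, 7, 10, 13, 16)) {
    chars[p] <- setdiff(c("W", "C"), chars[p])[1]
  }
  mut <- paste(chars, collapse = "")
  st <- pairwise_align(s, mut)
  expect_equal(st$identity, 75)
  expect_equal(st$query_coverage, 100)

  expect_error(pairwise_align("", s), "non-empty")
  expect_error(pairwise_align(s, "MKV1"), "non-amino-acid")
})

test_that("unrelated sequences never pass the joint 75/75 filter", {
  # local alignments of unrelated proteins can reach high identity over
  # short segments, but their query coverage stays far below threshold
  set.seed(42)
  n_pass <- 0
  covs <- numeric(30)
  for (i in 1:30) {
    a <- rand_prot(200)
    b <- rand_prot(200)
    st <- pairwise_align(a, b)
    covs[i] <- st$query_coverage
    if (st$identity >= 75 && st$query_coverage >= 75) n_pass <- n_pass + 1
  }
  expect_equal(n_pass, 0)
  expect_lt(max(covs), 75)
})

test_that("best hits are reciprocal, tie-broken lexicographically, and threshold-monotone", {
  s1 <- rand_prot(80, seed = 2)
  s2 <- rand_prot(90, seed = 3)
  col <- make_collection(list(
    A = c(a1 = s1, a2 = s2),
    B = c(b2 = s2, b1 = s1, b1dup = s1)  # b1 and b1dup tie for a1
  ))
  bh <- best_hits(col, "A", "B")
  expect_equal(sort(bh$gene_a), c("a1", "a2"))
  expect_equal(bh$gene_b[bh$gene_a == "a1"], "b1")  # lexicographic tie-break
  expect_equal(bh$gene_b[bh$gene_a == "a2"], "b2")

  # reciprocity: swapping genomes swaps the pair orientation
  bh_rev <- best_hits(col, "B", "A")
  expect_setequal(paste(bh$gene_a, bh$gene_b),
                  paste(bh_rev$gene_b, bh_rev$gene_a))

  # planted families at ~50% identity fall below the default threshold
  far <- make_collection(list(
    A = c(a1 = s1),
    B = c(b1 = mutate_protein(s1, 50, seed = 4))
  ))
  expect_equal(nrow(best_hits(far, "A", "B")), 0)

  # raising min_identity never increases retained pairs
  col3 <- small_recovery_collection(3, 8, identity = 85, seed = 31)
  ps <- collection_pair_stats(col3)
  ids <- genome_ids(col3)
  counts <- vapply(c(70, 80, 90, 97), function(mi) {
    nrow(best_hits(col3, ids[1], ids[2], min_identity = mi, pair_stats = ps))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("BDBH clusters identical-family toys and matches the exhaustive oracle", {
  f1 <- rand_prot(60, seed = 5)
  f2 <- rand_prot(70, seed = 6)
  f3 <- rand_prot(80, seed = 7)
  col <- make_collection(list(
    A = c(A.f1 = f1, A.f2 = f2, A.f3 = f3),
    B = c(B.f1 = f1, B.f2 = f2, B.f3 = f3),
    C = c(C.f1 = f1, C.f2 = f2, C.f3 = f3)
  ))
  cl <- bdbh_clusters(col, reference = "A")
  expect_length(cl, 3)
  expect_true(all(vapply(cl, function(x) nrow(x$members), integer(1)) == 3))

  # family absent from one genome gives a size-2 cluster
  col2 <- make_collection(list(
    A = c(A.f1 = f1, A.f2 = f2),
    B = c(B.f1 = f1)
  ))
  cl2 <- bdbh_clusters(col2, reference = "A")
  sizes <- sort(vapply(cl2, function(x) nrow(x$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))

  # at most one member per genome in any cluster
  col3 <- small_recovery_collection(4, 6, identity = 88, seed = 17)
  cl3 <- bdbh_clusters(col3)
  for (x in cl3) {
    expect_false(anyDuplicated(x$members$genome_id) > 0)
  }

  # oracle equivalence on a small collection
  ref <- genome_ids(col3)[1]
  oracle <- naive_bdbh(col3, ref)
  mine <- lapply(cl3, function(x) sort(x$members$gene_id))
  names(mine) <- vapply(cl3, function(x) {
    x$members$gene_id[x$members$genome_id == ref]
  }, character(1))
  expect_identical(mine[names(oracle)], oracle)
})

test_that("COG-triangles requires 3 genomes, merges shared edges, reports pairs", {
  f1 <- rand_prot(60, seed = 8)
  two <- make_collection(list(A = c(a = f1), B = c(b = f1)))
  expect_error(cog_triangle_clusters(two), "bdbh")

  # one shared family in three genomes -> one triangle -> one cluster of 3
  col <- make_collection(list(A = c(a = f1), B = c(b = f1), C = c(c = f1)))
  cl <- cog_triangle_clusters(col)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 3)

  # family in 4 genomes: triangles share edges -> one merged cluster of 4
  col4 <- make_collection(list(A = c(a = f1), B = c(b = f1),
                               C = c(c = f1), D = c(d = f1)))
  cl4 <- cog_triangle_clusters(col4)
  expect_length(cl4, 1)
  expect_equal(nrow(cl4[[1]]$members), 4)

  # a family present in only two genomes stays an unmerged reciprocal pair
  f2 <- rand_prot(70, seed = 9)
  col5 <- make_collection(list(A = c(a1 = f1, a2 = f2), B = c(b1 = f1, b2 = f2),
                               C = c(c1 = f1)))
  cl5 <- cog_triangle_clusters(col5)
  expect_length(cl5, 1)
  pairs <- attr(cl5, "pairs")
  expect_equal(nrow(pairs), 1)
  expect_setequal(unlist(pairs[1, c("gene_a", "gene_b")]), c("a2", "b2"))
})

test_that("clustering recovers the planted partition on a divergent collection", {
  skip_if_not_installed("mclust")
  col <- small_recovery_collection(3, 10, identity = 90, seed = 23)
  truth <- stats::setNames(col$truth$family_id, col$truth$gene_id)
  ps <- collection_pair_stats(col)
  for (cl in list(bdbh_clusters(col, pair_stats = ps),
                  cog_triangle_clusters(col, pair_stats = ps))) {
    asg <- cluster_assignments(cl, col)
    expect_equal(ari(asg[names(truth)], truth), 1.0)
  }
})

test_that("presence/absence matrix encodes incidence with singleton rows", {
  m <- toy_matrix()  # conceptual target
  f1 <- rand_prot(60, seed = 10)
  f2 <- rand_prot(61, seed = 11)
  f3 <- rand_prot(62, seed = 12)
  f4 <- rand_prot(63, seed = 13)
  col <- make_collection(list(
    A = c(A.f1 = f1, A.f2 = f2),
    B = c(B.f1 = f1, B.f3 = f3),
    C = c(C.f1 = f1, C.f4 = f4)
  ))
  cl <- cog_triangle_clusters(col)
  pam <- presence_absence(cl, col)
  expect_setequal(colnames(pam), c("A", "B", "C"))
  # f1 cluster present everywhere; f2-f4 are singleton rows
  expect_equal(sort(unname(rowSums(pam)), decreasing = TRUE), c(3, 1, 1, 1))
  # row sums equal the number of distinct genomes per cluster
  for (x in cl) {
    expect_equal(unname(rowSums(pam)[x$cluster_id]),
                 length(unique(x$members$genome_id)))
  }
  # empty cluster list -> singletons only
  pam0 <- presence_absence(structure(list(), class = "ortholog_clusters"), col)
  expect_equal(nrow(pam0), 6)
  expect_true(all(rowSums(pam0) == 1))
})
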