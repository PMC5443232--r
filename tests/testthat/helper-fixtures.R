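# Fixtures built in code and independent brute-force oracles.

# Assemble a genome_collection directly from named gene lists:
# genes = list(genomeA = c(gene1 = "SEQ", ...), ...)
make_collection <- function(genes, habitats = NULL, truth = NULL) {
  genomes <- lapply(names(genes), function(gid) {
    list(genome_id = gid,
         habitat = if (is.null(habitats)) NA_character_ else habitats[[gid]],
         proteins = Biostrings::AAStringSet(genes[[gid]]))
  })
  names(genomes) <- names(genes)
  structure(list(genomes = genomes, truth = truth),
            class = "genome_collection")
}

rand_prot <- function(L, seed = NULL) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa, L, replace = TRUE), collapse = "")
}

rand_dna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","C","G","T"), L, replace = TRUE), collapse = "")
}

# Substitute exactly n positions of a DNA string (test-side implementation,
# independent of the package's mutator).
substitute_dna <- function(seq, n, seed = 1) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n)
  for (p in pos) chars[p] <- sample(setdiff(c("A","C","G","T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# Global (Needleman-Wunsch) percent identity oracle via Biostrings, used to
# verify mutator targets independently of the package's local aligner.
global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "global",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 11, gapExtension = 1)
  100 * Biostrings::nmatch(pa) /
    (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa))
}

# ---- O(N^3) brute-force network oracles over the raw adjacency matrix ----

bf_adjacency <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  diag(A) <- 0
  A
}

bf_degree_distribution <- function(g) {
  A <- bf_adjacency(g)
  k <- rowSums(A)
  tab <- table(k)
  stats::setNames(as.numeric(tab) / nrow(A), names(tab))
}

bf_clustering_profile <- function(g) {
  A <- bf_adjacency(g)
  n <- nrow(A)
  k <- rowSums(A)
  cc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] == 1)
    e <- 0
    for (u in nb) for (v in nb) if (u < v && A[u, v] == 1) e <- e + 1
    cc[i] <- 2 * e / (k[i] * (k[i] - 1))
  }
  keep <- !is.na(cc)
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  prof <- tapply(cc[keep], k[keep], mean)
  stats::setNames(as.numeric(prof), names(prof))
}

bf_neighborhood_connectivity <- function(g) {
  A <- bf_adjacency(g)
  n <- nrow(A)
  k <- rowSums(A)
  nc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (k[i] < 1) next
    nb <- which(A[i, ] == 1)
    nc[i] <- mean(k[nb])
  }
  keep <- !is.na(nc)
  prof <- tapply(nc[keep], k[keep], mean)
  stats::setNames(as.numeric(prof), names(prof))
}

# ---- exhaustive BDBH oracle: plain loops over pairwise_align() calls ----

naive_bdbh <- function(collection, reference, min_identity = 75,
                       min_coverage = 75) {
  ids <- novopan::genome_ids(collection)
  seqs <- lapply(collection$genomes, function(g) as.character(g$proteins))
  stats_dir <- function(qid, sid) {
    # all query genes of genome qid vs all of sid, one pairwise_align per pair
    q <- seqs[[qid]]; s <- seqs[[sid]]
    res <- list()
    for (qa in names(q)) {
      for (sb in names(s)) {
        st <- novopan::pairwise_align(q[[qa]], s[[sb]])
        res[[paste(qa, sb)]] <- c(score = st$score, identity = st$identity,
                                  coverage = st$query_coverage)
      }
    }
    res
  }
  best_of <- function(res, q, candidates) {
    keys <- paste(q, candidates)
    ok <- vapply(keys, function(k) {
      res[[k]]["identity"] >= min_identity & res[[k]]["coverage"] >= min_coverage
    }, logical(1))
    if (!any(ok)) return(NA_character_)
    cand <- candidates[ok]
    sc <- vapply(paste(q, cand), function(k) res[[k]]["score"], numeric(1))
    idn <- vapply(paste(q, cand), function(k) res[[k]]["identity"], numeric(1))
    cand[order(-sc, -idn, cand)][1]
  }
  members <- lapply(names(seqs[[reference]]), function(g) {
    data.frame(genome_id = reference, gene_id = g, stringsAsFactors = FALSE)
  })
  names(members) <- names(seqs[[reference]])
  for (other in setdiff(ids, reference)) {
    fwd <- stats_dir(reference, other)
    rev <- stats_dir(other, reference)
    for (rg in names(seqs[[reference]])) {
      b <- best_of(fwd, rg, names(seqs[[other]]))
      if (!is.na(b) && identical(best_of(rev, b, names(seqs[[reference]])), rg)) {
        members[[rg]] <- rbind(members[[rg]],
                               data.frame(genome_id = other, gene_id = b,
                                          stringsAsFactors = FALSE))
      }
    }
  }
  lapply(members, function(m) sort(m$gene_id))
}

# Adjusted Rand index between two labelings of the same genes (mclust).
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# Small synthetic collection used by several orthology tests.
small_recovery_collection <- function(n_genomes = 3, n_families = 10,
                                      identity = 90, seed = 11) {
  d <- pangenome_design(n_genomes, core_size = n_families,
                        within_family_identity = identity,
                        gene_length_range = c(60, 120), seed = seed)
  generate_pangenome_collection(d)
}

# Toy presence/absence matrix A{f1,f2}, B{f1,f3}, C{f1,f4}.
toy_matrix <- function() {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("f", 1:4), c("A", "B", "C")))
  m["f1", ] <- 1L
  m["f2", "A"] <- 1L
  m["f3", "B"] <- 1L
  m["f4", "C"] <- 1L
  m
}
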