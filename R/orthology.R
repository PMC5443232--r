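#' Reciprocal best hits between two genomes
#'
#' For every gene, the best-scoring hit in the other genome that passes the
#' identity and query-coverage thresholds is retained; a pair is reported
#' only if the two genes are each other's best hit. Score ties are broken by
#' higher identity, then by the lexicographically smaller candidate gene id.
#'
#' @param collection A `genome_collection`.
#' @param genome_a,genome_b Genome ids within the collection.
#' @param min_identity,min_coverage Percent thresholds applied jointly
#'   (default 75 / 75).
#' @param scoring A [scoring_config()].
#' @param pair_stats Optional [collection_pair_stats()] cache.
#' @return Data frame with one row per reciprocal pair: `gene_a`, `gene_b`,
#'   `score`, `identity`, `coverage_a`, `coverage_b`.
#' @export
best_hits <- function(collection, genome_a, genome_b,
                      min_identity = 75, min_coverage = 75,
                      scoring = scoring_config(), pair_stats = NULL) {
  st <- get_pair_stats(collection, genome_a, genome_b, pair_stats, scoring)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage_a = numeric(0), coverage_b = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(st$score) == 0 || ncol(st$score) == 0) {
    warning("empty genome in pair (", genome_a, ", ", genome_b, ")")
    return(empty)
  }
  pick_best <- function(scores, identities, ok, candidate_ids) {
    # best passing candidate for one gene; NA if none passes
    idx <- which(ok)
    if (length(idx) == 0) return(NA_integer_)
    o <- order(-scores[idx], -identities[idx], candidate_ids[idx])
    idx[o[1]]
  }
  genes_a <- rownames(st$score)
  genes_b <- colnames(st$score)
  # direction A -> B: query is the A gene, coverage on A side
  best_ab <- vapply(seq_along(genes_a), function(i) {
    ok <- st$identity[i, ] >= min_identity & st$cov_a[i, ] >= min_coverage
    pick_best(st$score[i, ], st$identity[i, ], ok, genes_b)
  }, integer(1))
  best_ba <- vapply(seq_along(genes_b), function(j) {
    ok <- st$identity[, j] >= min_identity & st$cov_b[, j] >= min_coverage
    pick_best(st$score[, j], st$identity[, j], ok, genes_a)
  }, integer(1))
  rows <- list()
  for (i in seq_along(genes_a)) {
    j <- best_ab[i]
    if (!is.na(j) && !is.na(best_ba[j]) && best_ba[j] == i) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = genes_a[i], gene_b = genes_b[j],
        score = st$score[i, j], identity = st$identity[i, j],
        coverage_a = st$cov_a[i, j], coverage_b = st$cov_b[i, j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

new_clusters <- function(members_list, prefix) {
  clusters <- lapply(seq_along(members_list), function(i) {
    m <- members_list[[i]]
    m <- m[order(m$genome_id, m$gene_id), , drop = FALSE]
    rownames(m) <- NULL
    list(cluster_id = sprintf("%s%04d", prefix, i), members = m)
  })
  structure(clusters, class = "ortholog_clusters")
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) nrow(cl$members), integer(1))
  cat("ortholog_clusters:", length(x), "clusters; size range",
      if (length(sizes)) paste(min(sizes), "-", max(sizes)) else "NA", "\n")
  invisible(x)
}

#' Bidirectional best-hit (BDBH) ortholog clusters
#'
#' Every gene of the reference genome seeds a cluster; a gene of another
#' genome joins the cluster if and only if it forms a reciprocal best-hit
#' pair with the seed at the thresholds. Clusters therefore contain at most
#' one member per genome.
#'
#' @inheritParams best_hits
#' @param reference Reference genome id; defaults to the first genome of the
#'   collection.
#' @return An `ortholog_clusters` list; each element has `cluster_id` and a
#'   `members` data frame (`genome_id`, `gene_id`).
#' @export
bdbh_clusters <- function(collection, reference = NULL,
                          min_identity = 75, min_coverage = 75,
                          scoring = scoring_config(), pair_stats = NULL) {
  ids <- genome_ids(collection)
  reference <- reference %||% ids[1]
  if (!reference %in% ids) stop("reference genome not in collection: ",
                                reference)
  ref_genes <- names(collection$genomes[[reference]]$proteins)
  members <- lapply(ref_genes, function(g) {
    data.frame(genome_id = reference, gene_id = g, stringsAsFactors = FALSE)
  })
  names(members) <- ref_genes
  for (other in setdiff(ids, reference)) {
    bh <- best_hits(collection, reference, other,
                    min_identity, min_coverage, scoring, pair_stats)
    for (r in seq_len(nrow(bh))) {
      seed <- bh$gene_a[r]
      members[[seed]] <- rbind(members[[seed]],
                               data.frame(genome_id = other,
                                          gene_id = bh$gene_b[r],
                                          stringsAsFactors = FALSE))
    }
  }
  new_clusters(members, "BDBH")
}

#' COG-triangles ortholog clusters
#'
#' Builds reciprocal best-hit pairs for every genome pair, detects triangles
#' (three genes in three genomes that are pairwise reciprocal best hits) and
#' merges triangles that share an edge into clusters. Because a gene must
#' belong to a single cluster, triangles connected through shared genes are
#' merged as well (clusters are the connected components of the triangle
#' edges). Reciprocal pairs supported by no triangle are returned in the
#' `"pairs"` attribute.
#'
#' @inheritParams best_hits
#' @return An `ortholog_clusters` list with attribute `pairs`, a data frame
#'   of unmerged reciprocal best-hit pairs.
#' @export
cog_triangle_clusters <- function(collection,
                                  min_identity = 75, min_coverage = 75,
                                  scoring = scoring_config(),
                                  pair_stats = NULL) {
  ids <- genome_ids(collection)
  if (length(ids) < 3) {
    stop("COG-triangles clustering needs >= 3 genomes; use bdbh_clusters()")
  }
  gene_genome <- unlist(lapply(collection$genomes, function(g) {
    stats::setNames(rep(g$genome_id, length(g$proteins)), names(g$proteins))
  }), use.names = TRUE)
  names(gene_genome) <- unlist(lapply(collection$genomes,
                                      function(g) names(g$proteins)))
  edges <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq((i + 1), length(ids))) {
      bh <- best_hits(collection, ids[i], ids[j],
                      min_identity, min_coverage, scoring, pair_stats)
      if (nrow(bh) > 0) {
        edges[[length(edges) + 1L]] <- bh[, c("gene_a", "gene_b")]
      }
    }
  }
  if (length(edges) == 0) {
    out <- new_clusters(list(), "COG")
    attr(out, "pairs") <- data.frame(gene_a = character(0),
                                     gene_b = character(0))
    return(out)
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  tri <- igraph::triangles(g)
  tri_edges <- character(0)
  if (length(tri) > 0) {
    tm <- matrix(igraph::V(g)$name[tri], ncol = 3, byrow = TRUE)
    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    tri_edges <- unique(c(pair_key(tm[, 1], tm[, 2]),
                          pair_key(tm[, 1], tm[, 3]),
                          pair_key(tm[, 2], tm[, 3])))
  }
  all_keys <- paste(pmin(el$gene_a, el$gene_b),
                    pmax(el$gene_a, el$gene_b), sep = "\r")
  in_tri <- all_keys %in% tri_edges
  leftover <- el[!in_tri, , drop = FALSE]
  rownames(leftover) <- NULL
  clusters <- list()
  if (any(in_tri)) {
    sub <- igraph::graph_from_data_frame(el[in_tri, , drop = FALSE],
                                         directed = FALSE)
    comp <- igraph::components(sub)
    for (k in seq_len(comp$no)) {
      genes <- names(comp$membership)[comp$membership == k]
      clusters[[length(clusters) + 1L]] <-
        data.frame(genome_id = unname(gene_genome[genes]),
                   gene_id = genes, stringsAsFactors = FALSE)
    }
    # deterministic ordering by smallest member gene id
    clusters <- clusters[order(vapply(clusters,
                                      function(m) min(m$gene_id),
                                      character(1)))]
  }
  out <- new_clusters(clusters, "COG")
  attr(out, "pairs") <- leftover
  out
}

#' Presence/absence matrix of ortholog clusters
#'
#' Rows are clusters (plus one singleton row per gene belonging to no
#' cluster), columns are the genomes of the collection; cells are 0/1 or,
#' optionally, per-genome copy counts.
#'
#' @param clusters An `ortholog_clusters` object (may be empty).
#' @param collection The `genome_collection` the clusters were built from.
#' @param count If `TRUE`, cells hold member counts instead of 0/1.
#' @return Integer matrix, clusters x genomes.
#' @export
presence_absence <- function(clusters, collection, count = FALSE) {
  ids <- genome_ids(collection)
  clustered <- unlist(lapply(clusters, function(cl) cl$members$gene_id))
  all_genes <- unlist(lapply(collection$genomes,
                             function(g) names(g$proteins)))
  gene_genome <- rep(ids, vapply(collection$genomes,
                                 function(g) length(g$proteins), integer(1)))
  singletons <- !(all_genes %in% clustered)
  n_rows <- length(clusters) + sum(singletons)
  mat <- matrix(0L, nrow = n_rows, ncol = length(ids),
                dimnames = list(NULL, ids))
  row_ids <- character(n_rows)
  r <- 0L
  for (cl in clusters) {
    r <- r + 1L
    row_ids[r] <- cl$cluster_id
    tab <- table(cl$members$genome_id)
    mat[r, names(tab)] <- as.integer(tab)
  }
  for (i in which(singletons)) {
    r <- r + 1L
    row_ids[r] <- paste0("s_", all_genes[i])
    mat[r, gene_genome[i]] <- 1L
  }
  rownames(mat) <- row_ids
  if (!count) mat[mat > 1L] <- 1L
  mat
}

#' Gene-to-cluster assignment vector
#'
#' Flattens an `ortholog_clusters` object into a named vector mapping each
#' gene of the collection to its cluster id; genes in no cluster are labelled
#' as their own singletons. Useful for comparing a clustering against a
#' planted family partition (e.g. with an adjusted Rand index).
#'
#' @inheritParams presence_absence
#' @return Named character vector, gene id -> cluster label.
#' @export
cluster_assignments <- function(clusters, collection) {
  all_genes <- unlist(lapply(collection$genomes,
                             function(g) names(g$proteins)))
  lab <- stats::setNames(paste0("s_", all_genes), all_genes)
  for (cl in clusters) {
    lab[cl$members$gene_id] <- cl$cluster_id
  }
  lab
}
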