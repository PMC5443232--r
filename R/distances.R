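#' Fragment-based average nucleotide identity between two genomes
#'
#' Implements the classic fragment protocol: the first genome is chopped
#' into consecutive fragments (default 1,020 bp), each fragment is aligned
#' locally against the second genome on both strands, and the ANI is the
#' mean percent identity of fragments whose best alignment passes the
#' identity (default >= 30%) and fragment-coverage (default >= 70%)
#' filters. Alignment uses match +1 / mismatch -1 with gap open 2.
#'
#' @param genome_a,genome_b Nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param fragment_length Fragment size in bp.
#' @param min_fragment_identity,min_fragment_coverage Percent filters a
#'   fragment's best alignment must pass to contribute.
#' @param scoring A [scoring_config()]; defaults to [ani_scoring()].
#' @return ANI percent, or `NA` if no fragment passes the filters (with the
#'   number of fragments attempted in attribute `n_fragments`).
#' @export
ani_fragment <- function(genome_a, genome_b, fragment_length = 1020,
                         min_fragment_identity = 30,
                         min_fragment_coverage = 70,
                         scoring = ani_scoring()) {
  a <- toupper(as.character(genome_a))
  b <- toupper(as.character(genome_b))
  stop_if_empty_seq(a, "genome_a")
  stop_if_empty_seq(b, "genome_b")
  starts <- seq(1L, nchar(a), by = fragment_length)
  frags <- substring(a, starts, pmin(starts + fragment_length - 1L, nchar(a)))
  # drop a trailing sliver too short to be meaningfully filtered
  frags <- frags[nchar(frags) >= min(100L, nchar(a))]
  fr <- Biostrings::DNAStringSet(frags)
  subj <- Biostrings::DNAString(b)
  align_set <- function(set) {
    pa <- Biostrings::pairwiseAlignment(
      set, subj, type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend
    )
    nm <- Biostrings::nmatch(pa)
    nmm <- Biostrings::nmismatch(pa)
    p <- Biostrings::pattern(pa)
    list(score = Biostrings::score(pa),
         identity = 100 * nm / (nm + nmm),
         coverage = 100 * (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) /
           Biostrings::width(set))
  }
  fwd <- align_set(fr)
  rev <- align_set(Biostrings::reverseComplement(fr))
  use_rev <- rev$score > fwd$score
  identity <- ifelse(use_rev, rev$identity, fwd$identity)
  coverage <- ifelse(use_rev, rev$coverage, fwd$coverage)
  pass <- identity >= min_fragment_identity & coverage >= min_fragment_coverage
  ani <- if (any(pass)) mean(identity[pass]) else NA_real_
  attr(ani, "n_fragments") <- length(frags)
  attr(ani, "n_passing") <- sum(pass)
  ani
}

#' Pairwise ANI matrix over a genome set
#'
#' `"whole_genome"` mode runs [ani_fragment()] in both directions for each
#' genome pair and reports the mean (the fragmenting direction is mildly
#' asymmetric). `"ortholog_core"` mode averages the percent identity of
#' global pairwise alignments of single-copy core genes shared by each
#' genome pair.
#'
#' @param x For `"whole_genome"`: a named [Biostrings::DNAStringSet] (or
#'   named character vector) of genome sequences. For `"ortholog_core"`: a
#'   named list, genome id -> named [Biostrings::DNAStringSet] of gene
#'   nucleotide sequences, with names `<genome_id>.<family>` or matching
#'   `clusters`.
#' @param mode `"whole_genome"` or `"ortholog_core"`.
#' @param clusters For `"ortholog_core"`: an `ortholog_clusters` object of
#'   single-copy core clusters; each cluster's member genes are aligned
#'   pairwise between genomes.
#' @param ... Passed to [ani_fragment()] in whole-genome mode.
#' @return Symmetric matrix of ANI percentages with 100 on the diagonal
#'   (`NA` where no fragment passed).
#' @export
ani_matrix <- function(x, mode = c("whole_genome", "ortholog_core"),
                       clusters = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "whole_genome") {
    ids <- names(x)
    if (is.null(ids)) stop("genome sequences must be named")
    n <- length(ids)
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(m) <- 100
    if (n < 2) return(m)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        ab <- ani_fragment(x[[i]], x[[j]], ...)
        ba <- ani_fragment(x[[j]], x[[i]], ...)
        v <- mean(c(ab, ba), na.rm = TRUE)
        m[i, j] <- m[j, i] <- if (is.nan(v)) NA_real_ else v
      }
    }
    m
  } else {
    if (is.null(clusters)) stop("ortholog_core mode requires `clusters`")
    ids <- names(x)
    n <- length(ids)
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(m) <- 100
    sc <- ani_scoring()
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        idents <- c()
        for (cl in clusters) {
          mem <- cl$members
          gi <- mem$gene_id[mem$genome_id == ids[i]]
          gj <- mem$gene_id[mem$genome_id == ids[j]]
          if (length(gi) == 1 && length(gj) == 1 &&
              gi %in% names(x[[i]]) && gj %in% names(x[[j]])) {
            pa <- Biostrings::pairwiseAlignment(
              x[[i]][[gi]], x[[j]][[gj]], type = "global",
              substitutionMatrix = sc$matrix,
              gapOpening = sc$gap_open, gapExtension = sc$gap_extend
            )
            nm <- Biostrings::nmatch(pa)
            nmm <- Biostrings::nmismatch(pa)
            idents <- c(idents, 100 * nm / (nm + nmm))
          }
        }
        m[i, j] <- m[j, i] <- if (length(idents)) mean(idents) else NA_real_
      }
    }
    m
  }
}

#' Hierarchical dendrogram from Pearson correlation of row profiles
#'
#' Computes the correlation distance 1 - r between every pair of rows and
#' clusters agglomeratively (average linkage by default, the conventional
#' choice for expression-style matrices; complete and single linkage are
#' exposed). The rows of an ANI matrix, or of a binary trait matrix, are
#' both valid profiles. Set `direct_distance = TRUE` to skip the correlation
#' step and cluster a precomputed distance matrix directly.
#'
#' @param x Numeric matrix with named rows (profiles), or a symmetric
#'   distance matrix when `direct_distance = TRUE`.
#' @param linkage Agglomeration method.
#' @param direct_distance Treat `x` as distances rather than profiles.
#' @return An [ape::phylo] tree (serializable as Newick).
#' @export
correlation_dendrogram <- function(x, linkage = c("average", "complete",
                                                  "single"),
                                   direct_distance = FALSE) {
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 rows")
  if (direct_distance) {
    d <- stats::as.dist(x)
  } else {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      stop("constant row(s), correlation undefined: ",
           paste(rownames(x)[sds == 0], collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(t(x)))
  }
  hc <- stats::hclust(d, method = linkage)
  ape::as.phylo(hc)
}

as_char_alignment <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet")) {
    seqs <- as.character(alignment)
  } else if (is.matrix(alignment)) {
    return(alignment)
  } else {
    seqs <- as.character(alignment)
    names(seqs) <- names(alignment)
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("sequences must be aligned to equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

poisson_from_sites <- function(m) {
  n <- nrow(m)
  labs <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  inf_pairs <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      p <- mean(m[i, ] != m[j, ])
      if (p >= 1) {
        d[i, j] <- d[j, i] <- Inf
        inf_pairs <- c(inf_pairs, paste(labs[i], labs[j], sep = "-"))
      } else {
        d[i, j] <- d[j, i] <- -log(1 - p)
      }
    }
  }
  if (length(inf_pairs) > 0) {
    warning("infinite Poisson distance (p >= 1) for: ",
            paste(inf_pairs, collapse = ", "))
  }
  d
}

#' Poisson-corrected protein distance matrix
#'
#' For each pair of aligned sequences the fraction p of differing sites is
#' converted to the Poisson-corrected distance d = -ln(1 - p), the expected
#' number of substitutions per site under a Poisson substitution process.
#' Columns containing a gap in any sequence are removed first (complete
#' deletion; `"pairwise"` restricts deletion to each pair). Optional
#' bootstrap replicates resample alignment columns with replacement.
#'
#' @param alignment Aligned, equal-length sequences: an
#'   [Biostrings::AAStringSet], named character vector, or a character
#'   matrix of sites.
#' @param bootstrap_reps Number of bootstrap replicate matrices.
#' @param seed Integer seed for the bootstrap.
#' @param gap_mode `"complete"` (default) or `"pairwise"` deletion.
#' @return Symmetric distance matrix (substitutions/site); replicate
#'   matrices, if requested, are in attribute `replicates`.
#' @export
poisson_distance_matrix <- function(alignment, bootstrap_reps = 0, seed = 1,
                                    gap_mode = c("complete", "pairwise")) {
  gap_mode <- match.arg(gap_mode)
  m <- as_char_alignment(alignment)
  if (nrow(m) < 2) stop("need >= 2 sequences")
  gap <- m == "-" | m == "."
  if (gap_mode == "complete") {
    keep <- colSums(gap) == 0
    m <- m[, keep, drop = FALSE]
    if (ncol(m) == 0) stop("no columns left after complete gap deletion")
    d <- poisson_from_sites(m)
  } else {
    n <- nrow(m)
    labs <- rownames(m)
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        keep <- !gap[i, ] & !gap[j, ]
        if (!any(keep)) stop("no shared ungapped sites for pair ",
                             labs[i], "-", labs[j])
        p <- mean(m[i, keep] != m[j, keep])
        d[i, j] <- d[j, i] <- if (p >= 1) Inf else -log(1 - p)
      }
    }
  }
  if (bootstrap_reps > 0) {
    if (gap_mode != "complete") {
      stop("bootstrap is supported with complete deletion only")
    }
    reps <- with_seed(seed, lapply(seq_len(bootstrap_reps), function(r) {
      cols <- sample.int(ncol(m), replace = TRUE)
      poisson_from_sites(m[, cols, drop = FALSE])
    }))
    attr(d, "replicates") <- reps
  }
  d
}

#' Neighbor-joining tree with optional bootstrap support
#'
#' Canonical Saitou-Nei neighbor joining on a distance matrix. If replicate
#' distance matrices are supplied (e.g. from the Poisson bootstrap), a tree
#' is built from each and internal nodes are annotated with the percentage
#' of replicate trees containing the same bipartition. Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to zero.
#'
#' @param matrix Symmetric distance matrix with labels; all entries finite.
#' @param support_matrices List of replicate distance matrices (or the
#'   `replicates` attribute of [poisson_distance_matrix()]).
#' @return An [ape::phylo] tree; bootstrap percentages, when computed, are
#'   in `node.label`.
#' @export
nj_tree <- function(matrix, support_matrices = list()) {
  m <- as.matrix(matrix)
  if (nrow(m) < 3) stop("need >= 3 labels")
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m) & upper.tri(m), arr.ind = TRUE)
    stop("non-finite distances for pairs: ",
         paste(paste(rownames(m)[bad[, 1]], colnames(m)[bad[, 2]],
                     sep = "-"), collapse = ", "))
  }
  tree <- ape::nj(m)
  tree$edge.length[tree$edge.length < 0] <- 0
  if (length(support_matrices) > 0) {
    rep_trees <- lapply(support_matrices, ape::nj)
    class(rep_trees) <- "multiPhylo"
    cnt <- ape::prop.clades(tree, rep_trees, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tree$node.label <- round(100 * cnt / length(rep_trees), 1)
  }
  tree
}
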