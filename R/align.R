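#' Alignment scoring configuration
#'
#' Defaults are the standard protein settings: BLOSUM62 with affine gaps
#' (open 11, extend 1). `ani_scoring()` returns the nucleotide settings used
#' by the fragment-based ANI protocol: match +1, mismatch -1, gap open 2,
#' gap extend 1.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (protein) or an explicit numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_config")
}

#' @rdname scoring_config
#' @export
ani_scoring <- function() {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  structure(list(matrix = m, gap_open = 2, gap_extend = 1),
            class = "scoring_config")
}

check_protein <- function(x, arg) {
  stop_if_empty_seq(x, arg)
  bad <- setdiff(unique(strsplit(toupper(x), "", fixed = TRUE)[[1]]), AA20)
  if (length(bad) > 0) {
    stop("`", arg, "` contains non-amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Local pairwise protein alignment statistics
#'
#' Smith-Waterman local alignment with a substitution matrix and affine
#' gaps. Percent identity is the fraction of identical residue pairs over
#' the aligned (non-gap) columns; query coverage is the aligned span of the
#' query over its full length. These are the two quantities thresholded at
#' >= 75 / >= 75 by the ortholog-clustering stage.
#'
#' @param query,subject Non-empty protein strings (standard 20 residues).
#' @param scoring A [scoring_config()].
#' @return An `alignment_stats` list with `identity`, `query_coverage`
#'   (both percent) and `score`.
#' @export
pairwise_align <- function(query, subject, scoring = scoring_config()) {
  check_protein(query, "query")
  check_protein(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(query)),
    Biostrings::AAString(toupper(subject)),
    type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend
  )
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  p <- Biostrings::pattern(pa)
  structure(
    list(
      identity = 100 * nm / (nm + nmm),
      query_coverage = 100 * (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) /
        nchar(query),
      score = Biostrings::score(pa)
    ),
    class = "alignment_stats"
  )
}

# All-vs-all local alignment statistics between two protein sets.
# Returns score / identity matrices plus coverage of the A gene (cov_a) and
# of the B gene (cov_b), each |A| x |B|. One alignment per unordered pair:
# the local score and identity are symmetric, only coverage depends on which
# side is the query.
genome_pair_stats <- function(proteins_a, proteins_b,
                              scoring = scoring_config()) {
  na <- length(proteins_a)
  nb <- length(proteins_b)
  score <- identity <- cov_a <- cov_b <-
    matrix(NA_real_, na, nb, dimnames = list(names(proteins_a),
                                             names(proteins_b)))
  if (na == 0 || nb == 0) {
    return(list(score = score, identity = identity,
                cov_a = cov_a, cov_b = cov_b))
  }
  wa <- Biostrings::width(proteins_a)
  for (j in seq_len(nb)) {
    pa <- Biostrings::pairwiseAlignment(
      proteins_a, proteins_b[[j]],
      type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend
    )
    nm <- Biostrings::nmatch(pa)
    nmm <- Biostrings::nmismatch(pa)
    p <- Biostrings::pattern(pa)
    s <- Biostrings::subject(pa)
    score[, j] <- Biostrings::score(pa)
    identity[, j] <- 100 * nm / (nm + nmm)
    cov_a[, j] <- 100 * (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) / wa
    cov_b[, j] <- 100 * (BiocGenerics::end(s) - BiocGenerics::start(s) + 1) /
      Biostrings::width(proteins_b)[j]
  }
  list(score = score, identity = identity, cov_a = cov_a, cov_b = cov_b)
}

#' Precompute alignment statistics for every genome pair
#'
#' Ortholog clustering aligns every gene of one genome against every gene of
#' another for each genome pair; this helper computes those statistics once
#' so that BDBH and COG-triangles clustering (and repeated threshold sweeps)
#' can share them.
#'
#' @param collection A `genome_collection`.
#' @param scoring A [scoring_config()].
#' @return Named list keyed `"A|B"` (first id lexicographically smaller in
#'   genome order) of [genome_pair_stats] results.
#' @export
collection_pair_stats <- function(collection, scoring = scoring_config()) {
  ids <- genome_ids(collection)
  out <- list()
  if (length(ids) < 2) return(out)
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq((i + 1), length(ids))) {
      key <- paste(ids[i], ids[j], sep = "|")
      out[[key]] <- genome_pair_stats(collection$genomes[[ids[i]]]$proteins,
                                      collection$genomes[[ids[j]]]$proteins,
                                      scoring)
    }
  }
  out
}

# Fetch (or compute) the pair stats for an ordered genome pair (a, b),
# returning matrices oriented genes-of-a x genes-of-b.
get_pair_stats <- function(collection, a, b, pair_stats = NULL,
                           scoring = scoring_config()) {
  ids <- genome_ids(collection)
  ia <- match(a, ids)
  ib <- match(b, ids)
  if (is.na(ia) || is.na(ib)) stop("genome not in collection: ",
                                   if (is.na(ia)) a else b)
  flip <- ia > ib
  key <- if (flip) paste(b, a, sep = "|") else paste(a, b, sep = "|")
  st <- pair_stats[[key]]
  if (is.null(st)) {
    st <- genome_pair_stats(collection$genomes[[min(ia, ib)]]$proteins,
                            collection$genomes[[max(ia, ib)]]$proteins,
                            scoring)
  }
  if (flip) {
    st <- list(score = t(st$score), identity = t(st$identity),
               cov_a = t(st$cov_b), cov_b = t(st$cov_a))
  }
  st
}
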