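# Plain-text readers and writers: per-genome protein FASTA plus genomes.tsv
# and truth.tsv sidecars for collections, CSV for presence/absence matrices.

#' Write a genome collection to a directory
#'
#' Writes one protein multi-FASTA per genome (`<genome_id>.faa`, headers are
#' bare gene ids), a `genomes.tsv` (genome_id, habitat, file) and, when the
#' collection carries planted truth, a `truth.tsv` (gene_id, family_id) so
#' that downstream evaluation never needs to parse FASTA headers.
#'
#' @param collection A `genome_collection`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- genome_ids(collection)
  files <- paste0(ids, ".faa")
  for (i in seq_along(ids)) {
    Biostrings::writeXStringSet(collection$genomes[[i]]$proteins,
                                file.path(dir, files[i]))
  }
  hab <- collection_habitats(collection)
  hab$file <- files
  utils::write.table(hab, file.path(dir, "genomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(collection$truth)) {
    utils::write.table(collection$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a genome collection from a directory
#'
#' Inverse of [write_collection()]: reads `genomes.tsv`, the per-genome
#' FASTA files it references and `truth.tsv` if present.
#'
#' @param dir Directory written by [write_collection()].
#' @return A `genome_collection`.
#' @export
read_collection <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "genomes.tsv"),
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  genomes <- lapply(seq_len(nrow(tab)), function(i) {
    list(genome_id = tab$genome_id[i],
         habitat = tab$habitat[i],
         proteins = Biostrings::readAAStringSet(file.path(dir, tab$file[i])))
  })
  names(genomes) <- tab$genome_id
  truth <- NULL
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) {
    truth <- utils::read.delim(tf, stringsAsFactors = FALSE)
  }
  structure(list(genomes = genomes, truth = truth),
            class = "genome_collection")
}

#' Write / read a presence-absence matrix as CSV
#'
#' Rows are gene families (first column `cluster_id`), remaining columns are
#' genomes with 0/1 (or count) cells.
#'
#' @param matrix Families x genomes matrix with dimnames.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_pa_matrix <- function(matrix, path) {
  df <- data.frame(cluster_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pa_matrix
#' @export
read_pa_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Flatten ortholog clusters to a table
#'
#' @param clusters An `ortholog_clusters` object.
#' @return Data frame with columns `cluster_id`, `genome_id`, `gene_id`.
#' @export
clusters_table <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(cluster_id = character(0), genome_id = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, cl$members,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read genome -> gene-symbol sets from TSV
#'
#' Expects columns `genome_id` and `symbols` (semicolon-separated), as used
#' by the pathway-completeness screens.
#'
#' @param path TSV path.
#' @return Named list, genome id -> character vector of symbols.
#' @export
read_gene_symbols <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("genome_id", "symbols") %in% names(df)))
  out <- lapply(df$symbols, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  names(out) <- df$genome_id
  out
}
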