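#' Group genomes by habitat
#'
#' Builds the habitat grouping used by the habitat-core and specific-gene
#' analyses. Genomes without a habitat label are excluded, as are habitats
#' represented by fewer than `min_genomes` genomes (default 3, the usual
#' inclusion rule for drawing habitat-level conclusions; lower it to
#' override).
#'
#' @param x A `genome_collection` or a data frame with columns `genome_id`
#'   and `habitat` (NA or empty habitat = unassigned).
#' @param min_genomes Minimum genomes per included habitat.
#' @return A named list (`habitat_grouping`), habitat -> genome ids.
#' @export
habitat_grouping <- function(x, min_genomes = 3) {
  df <- if (inherits(x, "genome_collection")) collection_habitats(x) else x
  stopifnot(all(c("genome_id", "habitat") %in% names(df)))
  if (anyDuplicated(df$genome_id)) stop("duplicate genome ids in grouping")
  df <- df[!is.na(df$habitat) & nzchar(df$habitat), , drop = FALSE]
  grp <- split(df$genome_id, df$habitat)
  grp <- grp[vapply(grp, length, integer(1)) >= min_genomes]
  structure(grp, class = "habitat_grouping")
}

check_habitat_args <- function(matrix, grouping) {
  ids <- unlist(grouping)
  if (anyDuplicated(ids)) stop("habitat grouping has overlapping genomes")
  missing <- setdiff(ids, colnames(matrix))
  if (length(missing) > 0) {
    stop("grouping genomes absent from matrix: ",
         paste(missing, collapse = ", "))
  }
}

#' Habitat core genome
#'
#' Gene families present in every genome of a habitat.
#'
#' @param matrix Presence/absence matrix, families x genomes.
#' @param grouping A [habitat_grouping()].
#' @param habitat Habitat label to extract.
#' @return Character vector of family (row) ids.
#' @export
habitat_core <- function(matrix, grouping, habitat) {
  if (!habitat %in% names(grouping)) stop("unknown habitat: ", habitat)
  check_habitat_args(matrix, grouping)
  ids <- grouping[[habitat]]
  sub <- matrix[, ids, drop = FALSE] > 0
  rownames(matrix)[rowSums(sub) == length(ids)]
}

#' Habitat-specific gene families
#'
#' For each habitat, the families of its core genome that are not shared
#' with the other habitats. In `"core"` mode (the default) the comparison is
#' core against core: a family is specific if it is in this habitat's core
#' and in no other habitat's core. In `"strict"` mode a family must
#' additionally be absent from every individual genome of the other
#' habitats.
#'
#' @inheritParams habitat_core
#' @param mode `"core"` or `"strict"` (see Details).
#' @return Named list, habitat -> character vector of family ids.
#' @export
habitat_specific <- function(matrix, grouping, mode = c("core", "strict")) {
  mode <- match.arg(mode)
  if (length(grouping) < 2) stop("need >= 2 habitats")
  check_habitat_args(matrix, grouping)
  cores <- lapply(names(grouping), function(h) habitat_core(matrix, grouping, h))
  names(cores) <- names(grouping)
  out <- lapply(names(grouping), function(h) {
    others <- setdiff(names(grouping), h)
    if (mode == "core") {
      excl <- unique(unlist(cores[others]))
    } else {
      other_ids <- unlist(grouping[others])
      sub <- matrix[, other_ids, drop = FALSE] > 0
      excl <- rownames(matrix)[rowSums(sub) > 0]
    }
    setdiff(cores[[h]], excl)
  })
  names(out) <- names(grouping)
  out
}

#' Cloud gene content across habitats
#'
#' Families whose genome incidence spans at most `max_habitats` habitats
#' (default 2): the variably distributed fraction of the pangenome, as
#' opposed to families shared broadly across habitats.
#'
#' @inheritParams habitat_core
#' @param max_habitats Maximum number of habitats a cloud family may span.
#' @return Character vector of family ids.
#' @export
cloud_content <- function(matrix, grouping, max_habitats = 2) {
  check_habitat_args(matrix, grouping)
  span <- rowSums(vapply(names(grouping), function(h) {
    rowSums(matrix[, grouping[[h]], drop = FALSE] > 0) > 0
  }, logical(nrow(matrix))))
  rownames(matrix)[span <= max_habitats]
}

#' Define a metabolic pathway by its gene symbols
#'
#' @param pathway_id Identifier.
#' @param required Character vector of gene symbols that must all be present
#'   for the pathway to be complete (non-empty).
#' @param optional Symbols reported but not required (e.g. `ectD` extending
#'   ectoine synthesis to hydroxyectoine).
#' @return A `pathway_definition` list.
#' @export
pathway_definition <- function(pathway_id, required, optional = character(0)) {
  if (length(required) == 0) stop("`required` must be non-empty")
  structure(list(pathway_id = pathway_id,
                 required = as.character(required),
                 optional = as.character(optional)),
            class = "pathway_definition")
}

#' Pathway completeness of a gene repertoire
#'
#' Matches gene symbols exactly (case-insensitively) against the pathway's
#' required genes. A genome is `complete` if all required genes are present,
#' `partial` if some are, and `absent` if none are.
#'
#' @param gene_symbols Character vector of gene symbols found in a genome.
#' @param pathway A [pathway_definition()].
#' @return List with `status` (`"complete"`, `"partial"` or `"absent"`) and
#'   `missing` (required symbols not found).
#' @export
pathway_completeness <- function(gene_symbols, pathway) {
  stopifnot(inherits(pathway, "pathway_definition"))
  present <- tolower(pathway$required) %in% tolower(gene_symbols)
  status <- if (all(present)) "complete" else if (any(present)) "partial" else "absent"
  list(status = status, missing = pathway$required[!present])
}

#' Pathway completeness report over genomes
#'
#' @param genome_symbols Named list, genome id -> character vector of gene
#'   symbols.
#' @param pathways List of [pathway_definition()]s.
#' @return Data frame with columns `genome_id`, `pathway_id`, `status`,
#'   `missing` (semicolon-separated).
#' @export
pathway_report <- function(genome_symbols, pathways) {
  rows <- list()
  for (g in names(genome_symbols)) {
    for (p in pathways) {
      res <- pathway_completeness(genome_symbols[[g]], p)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g, pathway_id = p$pathway_id, status = res$status,
        missing = paste(res$missing, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a pathway catalog from TSV
#'
#' Expects columns `pathway_id`, `required`, `optional` with
#' semicolon-separated gene symbols.
#'
#' @param path TSV file path.
#' @return List of [pathway_definition()]s.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway_id", "required") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    opt <- if ("optional" %in% names(df) && nzchar(df$optional[i])) {
      strsplit(df$optional[i], ";", fixed = TRUE)[[1]]
    } else character(0)
    pathway_definition(df$pathway_id[i],
                       strsplit(df$required[i], ";", fixed = TRUE)[[1]],
                       opt)
  })
}
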