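#' Genome size and GC content
#'
#' Sums all contigs of a nucleotide FASTA (or sequence set). Size counts
#' every base; GC percent is (G + C) / (A + C + G + T) x 100,
#' case-insensitive, with ambiguous bases (N etc.) excluded from the
#' denominator.
#'
#' @param x Path to a FASTA file, a [Biostrings::DNAStringSet], or a
#'   character vector of sequences.
#' @param genome_id Optional id recorded in the result.
#' @return A `genome_metrics` list: `genome_id`, `size` (bp), `gc` (%).
#' @export
genome_metrics <- function(x, genome_id = NA_character_) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
    if (is.na(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(x))
  } else if (inherits(x, "DNAStringSet")) {
    seqs <- x
  } else {
    seqs <- Biostrings::DNAStringSet(toupper(as.character(x)))
  }
  if (length(seqs) == 0 || sum(Biostrings::width(seqs)) == 0) {
    stop("empty genome sequence")
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  counts <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  denom <- sum(counts)
  gc <- if (denom == 0) 0 else 100 * (counts[["G"]] + counts[["C"]]) / denom
  structure(list(genome_id = genome_id,
                 size = sum(Biostrings::width(seqs)),
                 gc = gc),
            class = "genome_metrics")
}

normalize_grouping <- function(values, grouping) {
  if (inherits(grouping, "habitat_grouping") || is.list(grouping)) {
    ids <- unlist(grouping)
    if (anyDuplicated(ids)) stop("a value is assigned to more than one group")
    grp <- rep(names(grouping), vapply(grouping, length, integer(1)))
    names(grp) <- ids
    keep <- names(values)[names(values) %in% ids]
    data.frame(value = unname(values[keep]), group = unname(grp[keep]),
               stringsAsFactors = FALSE)
  } else {
    stopifnot(length(grouping) == length(values))
    keep <- !is.na(grouping)
    data.frame(value = unname(values[keep]),
               group = as.character(grouping[keep]),
               stringsAsFactors = FALSE)
  }
}

#' Per-group summary (n, mean, SD)
#'
#' @param values Named numeric vector (names = genome ids) or plain vector
#'   aligned with `grouping`.
#' @param grouping A [habitat_grouping()] / named list, or a vector of group
#'   labels aligned with `values` (NA = excluded).
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(values, grouping, sd_type = c("sample",
                                                        "population")) {
  sd_type <- match.arg(sd_type)
  df <- normalize_grouping(values, grouping)
  if (any(!unique(df$group) %in% df$group[!is.na(df$value)])) {
    stop("empty group")
  }
  sdfun <- function(x) {
    if (sd_type == "sample") stats::sd(x)
    else sqrt(mean((x - mean(x))^2))
  }
  agg <- lapply(split(df$value, df$group), function(v) {
    c(n = length(v), mean = mean(v), sd = sdfun(v))
  })
  out <- data.frame(group = names(agg),
                    n = vapply(agg, `[[`, numeric(1), "n"),
                    mean = vapply(agg, `[[`, numeric(1), "mean"),
                    sd = vapply(agg, `[[`, numeric(1), "sd"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-way fixed-effects ANOVA
#'
#' F = MSB / MSW with df (groups - 1, n - groups); identical values across
#' the board yield F = 0, p = 1 rather than 0/0.
#'
#' @inheritParams group_summary
#' @return An `anova_result` list: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, `group_means`, `group_sds`.
#' @export
one_way_anova <- function(values, grouping) {
  df <- normalize_grouping(values, grouping)
  sizes <- table(df$group)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2)) {
    stop("every group needs n >= 2 (violated by: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  }
  gm <- vapply(split(df$value, df$group), mean, numeric(1))
  gs <- vapply(split(df$value, df$group), stats::sd, numeric(1))
  if (diff(range(df$value)) < .Machine$double.eps * max(1, abs(mean(df$value)))) {
    return(structure(list(f_statistic = 0,
                          df_between = length(sizes) - 1L,
                          df_within = nrow(df) - length(sizes),
                          p_value = 1,
                          group_means = gm, group_sds = gs),
                     class = "anova_result"))
  }
  an <- stats::anova(stats::lm(value ~ group, data = df))
  structure(list(f_statistic = an$`F value`[1],
                 df_between = an$Df[1],
                 df_within = an$Df[2],
                 p_value = an$`Pr(>F)`[1],
                 group_means = gm, group_sds = gs),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Genome characteristics of the 27 Novosphingobium strains
#'
#' Loads the bundled metadata table for the 27 publicly available
#' Novosphingobium genomes analysed by the workflow: strain, habitat
#' assignment (rhizosphere, contaminated soil, freshwater, marine water, or
#' NA for strains with unknown isolation site or an under-represented
#' habitat), genome size (bp), GC percent, gene count and GenBank accession.
#'
#' @return Data frame with one row per strain.
#' @export
novosphingobium_genomes <- function() {
  path <- system.file("extdata", "novosphingobium_genomes.tsv",
                      package = "novopan")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df
}
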