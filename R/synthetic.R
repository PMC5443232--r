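#' Design for a synthetic pangenome collection
#'
#' Describes the planted structure of a simulated genome collection: a
#' universal core shared by every genome, a private core per habitat
#' (families carried by every genome of that habitat and no other), and a
#' cloud of accessory families carried independently by each genome with a
#' fixed probability. Family members diverge from a common ancestral protein
#' so that the expected pairwise amino-acid identity within a family equals
#' `within_family_identity`.
#'
#' @param n_per_habitat Named integer vector mapping habitat label to genome
#'   count. An unnamed scalar generates that many genomes with no habitat
#'   label.
#' @param core_size Number of universal core families.
#' @param habitat_core_size Number of private-core families per habitat.
#' @param cloud_size Number of accessory (cloud) families.
#' @param cloud_presence_prob Probability that a given genome carries a given
#'   cloud family.
#' @param within_family_identity Target mean pairwise percent amino-acid
#'   identity among members of a family, in (0, 100].
#' @param gene_length_range Two integers; protein lengths are drawn uniformly
#'   from this range (residues).
#' @param seed Integer seed; the same seed and design reproduce the
#'   collection exactly.
#' @return A `pangenome_design` object.
#' @export
pangenome_design <- function(n_per_habitat,
                             core_size,
                             habitat_core_size = 0,
                             cloud_size = 0,
                             cloud_presence_prob = 0.25,
                             within_family_identity = 90,
                             gene_length_range = c(100, 400),
                             seed = 1) {
  if (is.null(names(n_per_habitat))) {
    if (length(n_per_habitat) != 1L) {
      stop("`n_per_habitat` must be named unless it is a single count")
    }
    names(n_per_habitat) <- NA_character_
  }
  stopifnot(
    all(n_per_habitat >= 0), sum(n_per_habitat) > 0,
    core_size >= 0, habitat_core_size >= 0, cloud_size >= 0,
    cloud_presence_prob >= 0, cloud_presence_prob <= 1,
    within_family_identity > 0, within_family_identity <= 100,
    length(gene_length_range) == 2L, all(gene_length_range >= 1),
    gene_length_range[1] <= gene_length_range[2]
  )
  structure(
    list(
      n_per_habitat = n_per_habitat,
      core_size = as.integer(core_size),
      habitat_core_size = as.integer(habitat_core_size),
      cloud_size = as.integer(cloud_size),
      cloud_presence_prob = cloud_presence_prob,
      within_family_identity = within_family_identity,
      gene_length_range = as.integer(gene_length_range),
      seed = as.integer(seed)
    ),
    class = "pangenome_design"
  )
}

#' Substitute residues to reach a target percent identity
#'
#' Substitutes `round(L * (1 - target_identity/100))` positions, chosen
#' uniformly without replacement, each replaced by one of the 19 alternative
#' residues drawn uniformly. No indels are introduced, so the realized
#' identity of a gapless alignment against the parent is exactly the target
#' (up to rounding of the substitution count).
#'
#' @param sequence Single non-empty protein string.
#' @param target_identity Target percent identity in (0, 100].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Mutated protein string of the same length.
#' @export
mutate_protein <- function(sequence, target_identity, seed = NULL) {
  stop_if_empty_seq(sequence, "sequence")
  if (target_identity <= 0 || target_identity > 100) {
    stop("`target_identity` must be in (0, 100]")
  }
  with_seed(seed, {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n_sub <- as.integer(round(length(chars) * (1 - target_identity / 100)))
    if (n_sub > 0L) {
      pos <- sample.int(length(chars), n_sub)
      for (p in pos) {
        chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
      }
    }
    paste(chars, collapse = "")
  })
}

# DNA analogue of mutate_protein; divergence given as a fraction.
mutate_dna <- function(sequence, divergence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n_sub <- as.integer(round(length(chars) * divergence))
  if (n_sub > 0L) {
    pos <- sample.int(length(chars), n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA4, chars[p]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a genome collection with planted gene-family structure
#'
#' Each genome receives one copy of every universal core family, one copy of
#' each private-core family of its habitat, and each cloud family
#' independently with probability `cloud_presence_prob`. Every family member
#' is mutated from the family's ancestral protein at half the target
#' divergence, so the expected pairwise identity between two members is the
#' design's `within_family_identity` (each member carries an independent half
#' of the divergence). A cloud family that is sampled into no genome is
#' assigned one member in a random genome so that every planted family has at
#' least one member.
#'
#' @param design A [pangenome_design()].
#' @return A `genome_collection`: a list with `genomes` (each a list with
#'   `genome_id`, `habitat`, `proteins` as a named [Biostrings::AAStringSet])
#'   and `truth`, a data frame mapping `gene_id` to the planted `family_id`.
#' @export
generate_pangenome_collection <- function(design) {
  stopifnot(inherits(design, "pangenome_design"))
  with_seed(design$seed, {
    habs <- names(design$n_per_habitat)
    counts <- design$n_per_habitat

    fam_ids <- c(
      if (design$core_size > 0) sprintf("core%04d", seq_len(design$core_size)),
      unlist(lapply(habs[!is.na(habs)], function(h) {
        if (design$habitat_core_size > 0) {
          sprintf("pc_%s_%03d", h, seq_len(design$habitat_core_size))
        }
      })),
      if (design$cloud_size > 0) sprintf("cloud%04d", seq_len(design$cloud_size))
    )
    lens <- sample(seq(design$gene_length_range[1], design$gene_length_range[2]),
                   length(fam_ids), replace = TRUE)
    ancestors <- vapply(lens, random_protein, character(1))
    names(ancestors) <- fam_ids

    # each member takes half the divergence so pairwise identity hits target
    member_identity <- 100 - (100 - design$within_family_identity) / 2

    genome_ids <- unlist(lapply(seq_along(habs), function(i) {
      prefix <- if (is.na(habs[i])) "g" else paste0(habs[i], "_g")
      if (counts[i] > 0) sprintf("%s%02d", prefix, seq_len(counts[i]))
    }))
    genome_hab <- rep(habs, counts)

    cloud_ids <- grep("^cloud", fam_ids, value = TRUE)
    cloud_occ <- NULL
    if (length(cloud_ids) > 0) {
      cloud_occ <- matrix(
        stats::runif(length(cloud_ids) * length(genome_ids)) <
          design$cloud_presence_prob,
        nrow = length(cloud_ids),
        dimnames = list(cloud_ids, genome_ids)
      )
      empty <- rownames(cloud_occ)[rowSums(cloud_occ) == 0]
      for (f in empty) {
        cloud_occ[f, sample.int(length(genome_ids), 1L)] <- TRUE
      }
    }

    truth_gene <- character(0)
    truth_fam <- character(0)
    genomes <- vector("list", length(genome_ids))
    names(genomes) <- genome_ids
    for (gi in seq_along(genome_ids)) {
      gid <- genome_ids[gi]
      hab <- genome_hab[gi]
      fams <- grep("^core", fam_ids, value = TRUE)
      if (!is.na(hab)) {
        fams <- c(fams, grep(paste0("^pc_", hab, "_"), fam_ids, value = TRUE))
      }
      if (!is.null(cloud_occ)) {
        fams <- c(fams, cloud_ids[cloud_occ[, gid]])
      }
      seqs <- vapply(fams, function(f) {
        mutate_protein(ancestors[[f]], member_identity)
      }, character(1))
      gene_ids <- paste0(gid, ".", fams)
      names(seqs) <- gene_ids
      genomes[[gi]] <- list(
        genome_id = gid,
        habitat = hab,
        proteins = Biostrings::AAStringSet(seqs)
      )
      truth_gene <- c(truth_gene, gene_ids)
      truth_fam <- c(truth_fam, fams)
    }

    structure(
      list(
        genomes = genomes,
        truth = data.frame(gene_id = truth_gene, family_id = truth_fam,
                           stringsAsFactors = FALSE),
        design = design
      ),
      class = "genome_collection"
    )
  })
}

#' @export
print.genome_collection <- function(x, ...) {
  n_genes <- sum(vapply(x$genomes, function(g) length(g$proteins), integer(1)))
  cat("genome_collection:", length(x$genomes), "genomes,",
      n_genes, "genes,", length(unique(x$truth$family_id)),
      "planted families\n")
  invisible(x)
}

#' Genome ids of a collection
#' @param collection A `genome_collection`.
#' @return Character vector of genome ids.
#' @export
genome_ids <- function(collection) {
  vapply(collection$genomes, `[[`, character(1), "genome_id")
}

#' Genome-to-habitat table of a collection
#' @param collection A `genome_collection`.
#' @return Data frame with columns `genome_id` and `habitat`.
#' @export
collection_habitats <- function(collection) {
  data.frame(
    genome_id = genome_ids(collection),
    habitat = vapply(collection$genomes, function(g) {
      if (is.null(g$habitat)) NA_character_ else g$habitat
    }, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Generate a random interaction network
#'
#' Two generators are offered as fixtures for network-topology analysis:
#' `"preferential_attachment"` grows a connected scale-free graph
#' (Barabasi-Albert, `m` edges per added node), and `"hierarchical_modular"`
#' builds the deterministic Ravasz-style replication hierarchy: a complete
#' module of `module_size` nodes is copied `module_size - 1` times at each of
#' `levels - 1` replication steps and all peripheral nodes of the copies are
#' wired to the root hub. The hierarchical wiring is deterministic; the seed
#' only permutes node labels, so the characteristic C(k) ~ 1/k profile is
#' reproducible.
#'
#' @param model `"preferential_attachment"` or `"hierarchical_modular"`.
#' @param n Number of nodes (preferential attachment; must be >= 4).
#' @param m Edges attached per new node (preferential attachment).
#' @param module_size,levels Hierarchical model size; the graph has
#'   `module_size^levels` nodes.
#' @param seed Integer seed.
#' @return A simple undirected [igraph::igraph] graph with named vertices.
#' @export
generate_network <- function(model = c("preferential_attachment",
                                       "hierarchical_modular"),
                             n = 100, m = 2,
                             module_size = 4, levels = 3,
                             seed = 1) {
  model <- match.arg(model)
  if (model == "preferential_attachment") {
    if (n < 4) stop("preferential attachment requires n >= 4")
    if (m < 1) stop("m must be >= 1")
    g <- with_seed(seed, igraph::sample_pa(n, power = 1, m = m,
                                           directed = FALSE))
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("v%04d", seq_len(n))
    g
  } else {
    if (module_size < 3) stop("module_size must be >= 3")
    if (levels < 1) stop("levels must be >= 1")
    edges <- t(utils::combn(seq_len(module_size), 2))
    periph <- 2:module_size
    n_nodes <- module_size
    if (levels > 1) {
      for (l in seq_len(levels - 1)) {
        e_new <- edges
        p_new <- integer(0)
        for (cp in seq_len(module_size - 1)) {
          off <- cp * n_nodes
          e_new <- rbind(e_new, edges + off)
          p_new <- c(p_new, periph + off)
        }
        e_new <- rbind(e_new, cbind(p_new, 1L))
        edges <- e_new
        periph <- p_new
        n_nodes <- n_nodes * module_size
      }
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    labels <- sprintf("v%04d", seq_len(n_nodes))
    perm <- with_seed(seed, sample.int(n_nodes))
    igraph::V(g)$name <- labels[perm]
    igraph::simplify(g)
  }
}

#' Generate nucleotide genomes with a planted clade structure
#'
#' Simulates a small set of genome sequences split into clades: each clade
#' descends from a clade ancestor that diverged from a common root, and each
#' genome diverges from its clade ancestor. Divergences are split in half on
#' each branch so the expected pairwise divergence within a clade is
#' `within_divergence` and between clades approximately `between_divergence`.
#' Intended as a fixture for average-nucleotide-identity analysis.
#'
#' @param n_clades,genomes_per_clade Clade layout.
#' @param genome_length Length of each genome (bp).
#' @param within_divergence,between_divergence Expected pairwise substitution
#'   fractions within and between clades.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet] with a `clade` attribute.
#' @export
generate_clade_genomes <- function(n_clades = 2, genomes_per_clade = 3,
                                   genome_length = 20000,
                                   within_divergence = 0.02,
                                   between_divergence = 0.15,
                                   seed = 1) {
  stopifnot(n_clades >= 1, genomes_per_clade >= 1, genome_length >= 100,
            within_divergence >= 0, between_divergence >= within_divergence)
  with_seed(seed, {
    root <- random_dna(genome_length)
    seqs <- character(0)
    clade <- character(0)
    for (ci in seq_len(n_clades)) {
      anc <- mutate_dna(root, between_divergence / 2)
      for (gi in seq_len(genomes_per_clade)) {
        seqs <- c(seqs, mutate_dna(anc, within_divergence / 2))
        clade <- c(clade, sprintf("clade%d", ci))
      }
    }
    names(seqs) <- sprintf("%s_g%d", clade,
                           rep(seq_len(genomes_per_clade), times = n_clades))
    out <- Biostrings::DNAStringSet(seqs)
    attr(out, "clade") <- stats::setNames(clade, names(seqs))
    out
  })
}

#' Generate a block-structured binary trait matrix
#'
#' Plants `blocks` groups of genomes that share a trait profile, then flips
#' each cell independently with probability `flip_noise`. Block profiles are
#' guaranteed non-constant and pairwise distinct so that row correlations are
#' defined and blocks are separable at zero noise.
#'
#' @param n_genomes,n_traits Matrix dimensions.
#' @param blocks Number of equal-sized blocks (integer) or a vector of block
#'   sizes summing to `n_genomes`.
#' @param flip_noise Per-cell flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return Binary `n_genomes x n_traits` matrix with a `block` attribute
#'   giving each genome's planted block.
#' @export
generate_trait_matrix <- function(n_genomes, n_traits, blocks = 2,
                                  flip_noise = 0, seed = 1) {
  stopifnot(n_genomes >= 2, n_traits >= 2,
            flip_noise >= 0, flip_noise < 0.5)
  if (length(blocks) == 1L) {
    base <- n_genomes %/% blocks
    sizes <- rep(base, blocks)
    sizes[seq_len(n_genomes - base * blocks)] <-
      sizes[seq_len(n_genomes - base * blocks)] + 1L
  } else {
    sizes <- as.integer(blocks)
  }
  if (sum(sizes) != n_genomes) stop("block sizes must sum to n_genomes")
  if (2^n_traits - 2 < length(sizes)) {
    stop("too few traits to give each block a distinct non-constant profile")
  }
  with_seed(seed, {
    profiles <- list()
    for (b in seq_along(sizes)) {
      repeat {
        p <- stats::rbinom(n_traits, 1L, 0.5)
        ok <- sum(p) > 0 && sum(p) < n_traits &&
          !any(vapply(profiles, function(q) all(q == p), logical(1)))
        if (ok) break
      }
      profiles[[b]] <- p
    }
    mat <- do.call(rbind, lapply(seq_along(sizes), function(b) {
      matrix(profiles[[b]], nrow = sizes[b], ncol = n_traits, byrow = TRUE)
    }))
    if (flip_noise > 0) {
      flips <- matrix(stats::runif(length(mat)) < flip_noise, nrow = nrow(mat))
      mat[flips] <- 1L - mat[flips]
    }
    rownames(mat) <- sprintf("g%02d", seq_len(n_genomes))
    colnames(mat) <- sprintf("t%02d", seq_len(n_traits))
    attr(mat, "block") <- rep(seq_along(sizes), sizes)
    mat
  })
}

#' Presence/absence matrix of the planted families
#'
#' Builds the family x genome incidence matrix directly from a synthetic
#' collection's truth map, i.e. the matrix an exact ortholog clustering
#' would produce. Useful for testing the downstream set algebra and
#' rarefaction independently of the clustering stage.
#'
#' @param collection A `genome_collection` with a truth map.
#' @return Binary matrix, planted families x genomes.
#' @export
truth_matrix <- function(collection) {
  if (is.null(collection$truth)) stop("collection has no truth map")
  ids <- genome_ids(collection)
  gene_genome <- rep(ids, vapply(collection$genomes,
                                 function(g) length(g$proteins), integer(1)))
  names(gene_genome) <- unlist(lapply(collection$genomes,
                                      function(g) names(g$proteins)))
  fams <- sort(unique(collection$truth$family_id))
  mat <- matrix(0L, length(fams), length(ids),
                dimnames = list(fams, ids))
  gg <- gene_genome[collection$truth$gene_id]
  for (r in seq_len(nrow(collection$truth))) {
    mat[collection$truth$family_id[r], gg[r]] <- 1L
  }
  mat
}
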