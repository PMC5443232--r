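habitat_fixture <- function() {
  # 2 habitats x 2 genomes, explicit incidence
  m <- matrix(0L, 6, 4,
              dimnames = list(c("u1", "u2", "hx1", "hy1", "c1", "c2"),
                              c("x1", "x2", "y1", "y2")))
  m[c("u1", "u2"), ] <- 1L          # universal
  m["hx1", c("x1", "x2")] <- 1L     # habitat-x private core
  m["hy1", c("y1", "y2")] <- 1L     # habitat-y private core
  m["c1", "x1"] <- 1L               # cloud in one genome
  m["c2", c("x1", "y1")] <- 1L      # shared but not core anywhere
  grp <- structure(list(x = c("x1", "x2"), y = c("y1", "y2")),
                   class = "habitat_grouping")
  list(m = m, grp = grp)
}

test_that("habitat grouping excludes unlabelled and under-represented habitats", {
  df <- data.frame(
    genome_id = c("a1", "a2", "a3", "b1", "b2", "u1"),
    habitat = c("soil", "soil", "soil", "water", "water", NA)
  )
  grp <- habitat_grouping(df, min_genomes = 3)
  expect_equal(names(grp), "soil")
  grp2 <- habitat_grouping(df, min_genomes = 2)
  expect_setequal(names(grp2), c("soil", "water"))
  expect_false("u1" %in% unlist(grp2))
})

test_that("habitat core is the intersection of the habitat's genomes", {
  fx <- habitat_fixture()
  expect_setequal(habitat_core(fx$m, fx$grp, "x"), c("u1", "u2", "hx1"))
  expect_setequal(habitat_core(fx$m, fx$grp, "y"), c("u1", "u2", "hy1"))
  expect_error(habitat_core(fx$m, fx$grp, "mars"), "unknown habitat")
  # A{f1,f2}, B{f1,f3} -> {f1}
  m <- matrix(c(1, 1, 0, 1, 0, 1), 3, 2,
              dimnames = list(c("f1", "f2", "f3"), c("A", "B")))
  grp <- structure(list(h = c("A", "B")), class = "habitat_grouping")
  expect_equal(habitat_core(m, grp, "h"), "f1")
})

test_that("habitat-specific sets subtract other habitats in both modes", {
  fx <- habitat_fixture()
  sp <- habitat_specific(fx$m, fx$grp, mode = "core")
  expect_setequal(sp$x, "hx1")
  expect_setequal(sp$y, "hy1")
  # universal families never specific
  expect_false(any(c("u1", "u2") %in% unlist(sp)))

  # strict mode is a subset of core mode, and specific sets live in the core
  st <- habitat_specific(fx$m, fx$grp, mode = "strict")
  for (h in names(fx$grp)) {
    expect_true(all(st[[h]] %in% sp[[h]]))
    expect_true(all(sp[[h]] %in% habitat_core(fx$m, fx$grp, h)))
  }
  # c2 is in x1 and y1: core mode for x would not exclude it (not in y's
  # core) were it core in x; strict mode must exclude it regardless
  expect_false("c2" %in% st$x)
  # specific sets are pairwise disjoint
  expect_length(intersect(sp$x, sp$y), 0)
})

test_that("cloud content is bounded by habitat span and monotone in the bound", {
  fx <- habitat_fixture()
  cl1 <- cloud_content(fx$m, fx$grp, max_habitats = 1)
  expect_setequal(cl1, c("hx1", "hy1", "c1"))
  cl2 <- cloud_content(fx$m, fx$grp, max_habitats = 2)
  expect_true(all(cl1 %in% cl2))
  expect_setequal(cl2, rownames(fx$m))  # bound = habitat count -> everything
})

test_that("planted private cores are recovered exactly by the set algebra", {
  d <- pangenome_design(c(r = 3, s = 3, f = 3, m = 3), core_size = 20,
                        habitat_core_size = 5, cloud_size = 0,
                        gene_length_range = c(50, 60), seed = 12)
  col <- generate_pangenome_collection(d)
  tm <- truth_matrix(col)
  grp <- habitat_grouping(collection_habitats(col))
  sp <- habitat_specific(tm, grp, mode = "strict")
  expect_setequal(names(sp), c("r", "s", "f", "m"))
  for (h in names(sp)) {
    expect_length(sp[[h]], 5)
    expect_true(all(grepl(paste0("^pc_", h, "_"), sp[[h]])))
  }
  # habitat core = universal core + that habitat's private core
  for (h in names(grp)) {
    expect_setequal(habitat_core(tm, grp, h),
                    c(grep("^core", rownames(tm), value = TRUE), sp[[h]]))
  }
})

test_that("pathway completeness distinguishes complete, partial and absent", {
  ect <- pathway_definition("ectoine", c("ectA", "ectB", "ectC"), "ectD")
  expect_equal(pathway_completeness(c("ectA", "ectB", "ectC"), ect)$status,
               "complete")
  res <- pathway_completeness(c("ectA", "ectB"), ect)
  expect_equal(res$status, "partial")
  expect_equal(res$missing, "ectC")
  expect_equal(pathway_completeness(c("tauD"), ect)$status, "absent")
  # case-insensitive symbol matching
  expect_equal(pathway_completeness(c("ECTA", "Ectb", "ectc"), ect)$status,
               "complete")
  tau <- pathway_definition("taurine", c("tauA", "tauB", "tauC", "tauD"))
  res <- pathway_completeness("tauD", tau)
  expect_equal(res$status, "partial")
  expect_setequal(res$missing, c("tauA", "tauB", "tauC"))
  expect_error(pathway_definition("x", character(0)), "non-empty")
})

test_that("bundled catalogs reproduce the published ectoine calls", {
  pw <- read_pathways(system.file("extdata", "pathways.tsv",
                                  package = "novopan"))
  ect <- pw[[which(vapply(pw, `[[`, character(1), "pathway_id") == "ectoine")]]
  sym <- read_gene_symbols(system.file("extdata", "ectoine_genes.tsv",
                                       package = "novopan"))
  rep <- pathway_report(sym, list(ect))
  complete <- rep$genome_id[rep$status == "complete"]
  expect_setequal(complete, c("Musc273", "PP1Y", "US6-1", "KN65.2"))
  expect_equal(rep$status[rep$genome_id == "LL02"], "partial")
  expect_equal(rep$status[rep$genome_id == "MBES04"], "absent")
})
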