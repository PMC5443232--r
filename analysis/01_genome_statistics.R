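#!/usr/bin/env Rscript
# Habitat-level statistics of the 27-genome Novosphingobium collection.
#
# Recomputes the collection-wide genome-size summary, the per-habitat means
# and SDs, and the one-way ANOVA testing whether mean genome size differs
# between the four habitats (rhizosphere, contaminated soil, freshwater,
# marine water). Writes results/group_stats.csv and results/anova.json.

suppressMessages(library(novopan))
dir.create("results", showWarnings = FALSE)

tab <- novosphingobium_genomes()
mbp <- stats::setNames(tab$genome_size_bp / 1e6, tab$strain)

cat(sprintf("collection: %d strains, mean %.2f Mbp (range %.2f-%.2f)\n",
            length(mbp), mean(mbp), min(mbp), max(mbp)))
cat(sprintf("GC content range: %.1f%% (%s) to %.1f%% (%s)\n",
            min(tab$gc_percent), tab$strain[which.min(tab$gc_percent)],
            max(tab$gc_percent), tab$strain[which.max(tab$gc_percent)]))

grp <- habitat_grouping(data.frame(genome_id = tab$strain,
                                   habitat = tab$habitat))
gs <- group_summary(mbp, grp)
print(gs)
write.csv(gs, "results/group_stats.csv", row.names = FALSE)

an_size <- one_way_anova(mbp, grp)
cat("genome size by habitat: ")
print(an_size)
gc <- stats::setNames(tab$gc_percent, tab$strain)
an_gc <- one_way_anova(gc, grp)
cat("GC percent by habitat:  ")
print(an_gc)

jsonlite::write_json(list(
  genome_size = list(f = an_size$f_statistic, df = c(an_size$df_between,
                                                     an_size$df_within),
                     p = an_size$p_value),
  gc_percent = list(f = an_gc$f_statistic, df = c(an_gc$df_between,
                                                  an_gc$df_within),
                    p = an_gc$p_value)
), "results/anova.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/group_stats.csv and results/anova.json\n")
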