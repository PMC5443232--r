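#!/usr/bin/env Rscript
# Core/pangenome rarefaction of the simulated collection: genomes are added
# in 10 random orders, core (families in all sampled genomes) and pan
# (families in any) are tracked, and the Tettelin-style exponential decay
# and Heaps power law are fitted to the mean curves.

suppressMessages(library(novopan))
pam <- read_pa_matrix("results/presence_absence.csv")

r <- rarefy(pam, n_permutations = 10, seed = 2017)
print(r)
write.csv(rarefaction_table(r), "results/rarefaction.csv", row.names = FALSE)

core_fit <- fit_core_decay(r)
print(core_fit)
pan_fit <- fit_pan_growth(r, model = "heaps_power")
print(pan_fit)
pan_el <- fit_pan_growth(r, model = "exponential_linear")
print(pan_el)

cat(sprintf("asymptotic core size omega = %.1f families; Heaps gamma = %.3f (%s pangenome)\n",
            core_fit$params[["omega"]], pan_fit$params[["gamma"]],
            if (pan_fit$params[["gamma"]] > 0.05) "open" else "closed"))

jsonlite::write_json(list(
  core_exponential = as.list(core_fit$params),
  heaps_power = as.list(pan_fit$params),
  pan_exponential_linear = as.list(pan_el$params),
  rss = list(core = core_fit$rss, heaps = pan_fit$rss, exp_linear = pan_el$rss)
), "results/fits.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/rarefaction.csv and results/fits.json\n")
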