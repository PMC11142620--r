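#!/usr/bin/env Rscript
# Parameter-recovery demonstration: inject extra verb-verb encyclopedic
# feature sharing into the generator (reuse multiplier 3, with acquisition
# order coupled to encyclopedic hub-ness) and verify that the pipeline
# recovers the qualitative signature of early verb vocabularies -- a
# verb-above-noun normalized-degree cluster in the encyclopedic network
# spanning most of vocabulary development.

suppressPackageStartupMessages(library(featnet))

seed <- 20234
out <- "results/effect_recovery"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ncfg <- inject_effect(norms_config(), "verb", "encyclopedic", 3)
lex <- generate_lexicon(ncfg, seed = seed)
pop <- generate_population(lex, population_config(n_children = 500),
                           seed = seed + 1)
sp <- sample_space(enumerate_space(pop), seed = seed)
h <- assemble_histograms(sp, lex, restrictions = "encyclopedic",
                         reps = 200, seed = seed)
rec <- normalize_children(pop, lex, h)
res <- compare_pos_within_type(rec, "encyclopedic", n_perm = 1000,
                               seed = seed)

v <- rec$normalized_degree[rec$pos == "verb"]
n <- rec$normalized_degree[rec$pos == "noun"]
cat("Mean normalized encyclopedic degree: verbs", round(mean(v), 1),
    "vs nouns", round(mean(n), 1), "\n")
print(res)

utils::write.table(res$clusters, file.path(out, "clusters.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$bin_stats, file.path(out, "bin_diagnostics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Tables written under", out, "\n")
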