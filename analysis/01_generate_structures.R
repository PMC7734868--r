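#!/usr/bin/env Rscript
# Step 1: generate the synthetic structure pools.
#
# Two pools of drug-impurity-like structures: a "query" pool standing in
# for a large public compound sample (with a realistic share of defective
# records: mixtures, metal-containing structures, invalid lines,
# duplicates, salts) and a smaller clean "reference" pool standing in for
# a proprietary intermediates collection.

suppressMessages(library(qsardrift))

dir.create("results/structures", showWarnings = FALSE, recursive = TRUE)
seed <- 20180501

query <- generate_structures(400, seed = seed, defect_fraction = 0.15)
reference <- generate_structures(120, seed = seed + 1L, prefix = "ref")

write_smiles(query, "results/structures/query_pool.smi")
write_smiles(reference, "results/structures/reference_set.smi")

cat("wrote", nrow(query), "query structures and", nrow(reference),
    "reference structures under results/structures/\n")
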