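#!/usr/bin/env Rscript
# Step 2: curate a chemical-space-matched dataset.
#
# Standardizes the query pool (validation, stereo/isotope removal,
# group I/II counterion stripping, mixture/metal filters, charge
# neutralization), selects the compounds with fragment-fingerprint
# Tanimoto similarity >= 0.5 to the reference set, removes structures
# present in an exclusion list, and exports the similarity graph and a
# structural-alert frequency profile.

suppressMessages(library(qsardrift))

dir.create("results/curation", showWarnings = FALSE, recursive = TRUE)

query <- read_structures("results/structures/query_pool.smi")
reference <- read_structures("results/structures/reference_set.smi")

recs <- standardize_structures(query$smiles, query$compound_id)
refs <- standardize_structures(reference$smiles, reference$compound_id)
kept <- recs[recs$status == "KEPT", ]
rkept <- refs[refs$status == "KEPT", ]

cat("standardization funnel:\n")
print(table(ifelse(recs$status == "KEPT", "KEPT", recs$reject_reason)))

selected <- select_similar(kept, rkept, cutoff = 0.5, depth = 7)
# the first 30 reference structures stand in for training-set /
# assay-database overlap
final <- exclude_known(selected, kept, reference$smiles[1:30])
cat("selected at Tanimoto >= 0.5:", length(selected),
    "| after exclusion:", length(final), "\n")

curated <- kept[kept$compound_id %in% final, ]
utils::write.csv(recs, "results/curation/standardization_records.csv",
                 row.names = FALSE)
utils::write.csv(curated, "results/curation/curated_set.csv",
                 row.names = FALSE)

g <- build_similarity_graph(kept, rkept, threshold = 0.5, depth = 7)
s <- similarity_graph_summary(g)
cat("similarity graph:", s$n_nodes, "nodes,", s$n_edges, "edges,",
    s$n_components, "components (", s$n_singletons, "singletons )\n")
write_similarity_graph(g, "results/curation")

prof <- profile_alerts(curated, read_smarts(), top_k = 6)
print(prof)
write_alert_profile(prof, "results/curation/alert_profile.csv")
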