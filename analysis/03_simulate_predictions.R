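#!/usr/bin/env Rscript
# Step 3: simulate the multi-vendor prediction history.
#
# The default study: 3367 compounds scored by three vendors' statistical
# and rule-based models at versions released in 2014, 2016 and 2018, with
# per-step transition kernels drifting a few percent of calls per update
# and a shared latent mutagenicity coupling each vendor's two models.
# Raw calls are written in each vendor's own vocabulary so the
# harmonization step is exercised end-to-end.

suppressMessages(library(qsardrift))

dir.create("results/predictions", showWarnings = FALSE, recursive = TRUE)

spec <- default_history_spec(n_compounds = 3367, seed = 20180502)
raw <- simulate_history(spec)

write_prediction_table(raw[, setdiff(names(raw), "call")],
                       "results/predictions/preds_raw.csv")
cat("wrote", nrow(raw), "prediction rows (",
    length(unique(raw$compound_id)), "compounds x",
    nrow(unique(raw[c("vendor", "model_type", "version_label")])),
    "model versions ) to results/predictions/preds_raw.csv\n")
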