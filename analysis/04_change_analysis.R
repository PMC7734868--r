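#!/usr/bin/env Rscript
# Step 4: harmonize and quantify version-to-version prediction changes.
#
# Maps the raw vendor terms to the common four-category vocabulary,
# validates the complete prediction matrix, and writes the report set:
# per-version marginal category counts, per-model cumulative change
# percentages over 2014-2018, the consensus combination summary, and the
# unchanged-percentage grid with its mean.

suppressMessages(library(qsardrift))

raw <- read_raw_predictions("results/predictions/preds_raw.csv")
tab <- harmonize_table(raw, load_vocab_map())

files <- write_run_outputs(tab, "results/changes", 2014, 2018,
                           denominator = "total")
cat("report files written:\n")
for (f in files) cat(" -", f, "\n")

unch <- utils::read.csv(files[["unchanged"]])
cat(sprintf("mean unchanged consensus predictions 2014-2018: %.1f%%\n",
            mean(unch$unchanged_percent)))
cons <- utils::read.csv(files[["consensus_changes"]])
np <- cons[cons$from == "NEGATIVE" & cons$to == "POSITIVE", ]
cat(sprintf("mean consensus negative-to-positive change: %.1f%% of compounds\n",
            np$mean_percent))
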