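#!/usr/bin/env Rscript

# Step 3: call NMD-responding skipped-exon events.
#
# Per-replicate PSI values are computed from inclusion/skipping junction
# counts; each event is tested in the two comparisons of the design (dKD vs
# CTR and RESC vs dKD) with a moderated t-statistic on logit-PSI, and an
# event is called NMD-responding when both comparisons pass FDR < 0.05, the
# knockdown shift is at least 10% PSI, and the rescue moves in the opposite
# direction. Calls are scored against the planted truth.

suppressPackageStartupMessages({
  library(nmdsense)
  library(data.table)
  library(jsonlite)
})

counts <- read_junction_counts("results/sim/junction_counts.tsv")
results <- test_events(counts)
decisions <- select_nmd_events(results)
fwrite(results[decisions, on = "event_id"], "results/event_decisions.tsv",
       sep = "\t")

truth <- fromJSON("results/sim/truth.json")
tr <- as.data.table(truth$events)
m <- tr[decisions[selected == TRUE], on = "event_id"]

cat(sprintf("Tested %d events; selected %d (%d inclusion / %d exclusion).\n",
            nrow(results), sum(decisions$selected),
            sum(decisions$subclass == "inclusion"),
            sum(decisions$subclass == "exclusion")))
cat(sprintf("Recovered %d of %d planted events (%.1f%% sensitivity); ",
            sum(m$is_nmd), sum(tr$is_nmd), 100 * sum(m$is_nmd) / sum(tr$is_nmd)))
cat(sprintf("%d false calls (%.1f%% of selections).\n",
            sum(!m$is_nmd), 100 * sum(!m$is_nmd) / max(nrow(m), 1)))
cat(sprintf("Subclass concordance among recovered events: %.1f%%.\n",
            100 * mean(m[is_nmd == TRUE, subclass == i.subclass])))
cat("Decisions written to results/event_decisions.tsv\n")
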