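#!/usr/bin/env Rscript

# Step 4: reduce each selected event to one NMD-sensitive and one
# NMD-insensitive representative transcript.
#
# The gene-level start codon of the principal isoform is projected onto every
# transcript of the merged annotation to define ORFs and 3'UTRs; transcripts
# without a projectable coding region are discarded. For each selected event
# the exon-including and exon-skipping isoforms are labelled by the event
# subclass, and the most abundant transcript (mean over CTR + dKD samples)
# represents each side.

suppressPackageStartupMessages({
  library(nmdsense)
  library(data.table)
})

merged <- read_gtf("results/merged.gtf")
genome <- read_genome("results/sim/genome.fa")
starts <- load_principal_starts("results/sim/principal_starts.tsv")
orfs <- project_orfs(merged, starts, genome)
fwrite(orfs[, !"junction_distances"], "results/orf_annotations.tsv", sep = "\t")

decisions <- fread("results/event_decisions.tsv")[, .(event_id, selected, subclass)]
events <- read_events("results/sim/events.tsv")
abundance <- read_abundance("results/sim/abundance.tsv")
samples <- grep("^(CTR|dKD)", names(abundance), value = TRUE)
pairs <- build_pairs(decisions, events, merged, orfs, abundance, samples)
fwrite(pairs, "results/pairs.tsv", sep = "\t")

drops <- attr(pairs, "drops")
cat(sprintf("Projected ORFs for %d transcripts (%d ok, %d rejected).\n",
            nrow(orfs), sum(orfs$status == "ok"), sum(orfs$status != "ok")))
cat(sprintf("Built %d sensitive/insensitive pairs from %d selected events",
            nrow(pairs), sum(decisions$selected)))
if (sum(drops) > 0) {
  cat(sprintf(" (%d dropped: %s)",
              sum(drops), paste(names(drops)[drops > 0], collapse = ", ")))
}
cat(".\nPair table: results/pairs.tsv\n")
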