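#!/usr/bin/env Rscript

# Step 2: augment the reference transcriptome with the novel isoforms.
#
# Novel transcript models (standing in for long-read assemblies) are merged
# into the reference by intron-chain identity: a model is added only when its
# exact junction set is new; chain matches are collapsed, keeping the longer
# terminal ends. We then ask what fraction of the merged exon universe is
# absent from the reference annotation.

suppressPackageStartupMessages({
  library(nmdsense)
  library(data.table)
})

reference <- read_gtf("results/sim/reference.gtf")
novel <- read_gtf("results/sim/novel.gtf")
merged <- merge_transcriptomes(reference, novel)

stats <- merge_stats(merged)
fwrite(stats, "results/merge_stats.tsv", sep = "\t")
write_gtf(merged, "results/merged.gtf")

all_exons <- unique(merged$exons[, .(chrom, start, end, strand)])
frac <- novel_exon_fraction(merged, reference, all_exons)

cat(sprintf("Reference transcripts: %d; novel models: %d.\n",
            stats$reference_transcripts, stats$novel_transcripts))
cat(sprintf("Added as new isoforms: %d; collapsed into existing chains: %d.\n",
            stats$added, stats$collapsed))
cat(sprintf("%.1f%% of merged exons are absent from the reference annotation.\n",
            100 * frac))
cat("Merged annotation: results/merged.gtf; statistics: results/merge_stats.tsv\n")
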