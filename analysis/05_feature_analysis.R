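#!/usr/bin/env Rscript

# Step 5: compare NMD-determining features between the paired sensitive and
# insensitive isoforms.
#
# Features: exon-exon junctions downstream of the termination codon and
# 3'UTR length (K-S comparisons, with a stratified comparison restricted to
# stop-in-last-exon transcripts), translated uORFs in the 5'UTR, splice-site
# strength of poised vs control exons under the default positional log-odds
# model, window conservation, and the gene-vs-isoform differential-expression
# cross-tabulation.

suppressPackageStartupMessages({
  library(nmdsense)
  library(data.table)
})

merged <- read_gtf("results/merged.gtf")
genome <- read_genome("results/sim/genome.fa")
starts <- load_principal_starts("results/sim/principal_starts.tsv")
orfs <- project_orfs(merged, starts, genome)
pairs <- fread("results/pairs.tsv")
events <- read_events("results/sim/events.tsv")
decisions <- fread("results/event_decisions.tsv")[, .(event_id, selected, subclass)]

## 3'UTR junctions and length -------------------------------------------------
feats <- utr3_features(pairs, orfs)
fwrite(feats, "results/utr3_features.tsv", sep = "\t")
prev <- feats[, .(frac = mean(n_junctions_3utr > 0)), by = group]
ks_jx <- ks_compare(feats[group == "sensitive", n_junctions_3utr],
                    feats[group == "insensitive", n_junctions_3utr])
cat(sprintf("3'UTR junction prevalence: %.0f%% of sensitive vs %.0f%% of insensitive isoforms (K-S p = %.2g).\n",
            100 * prev[group == "sensitive", frac],
            100 * prev[group == "insensitive", frac], ks_jx$p))
strat <- last_exon_stratified_lengths(feats)
if (all(strat$counts >= 2)) {
  ks_len <- ks_compare(strat$sensitive, strat$insensitive)
  cat(sprintf("Stratified 3'UTR length (stop in last exon, n=%d/%d): K-S p = %.2f — %s.\n",
              strat$counts[1], strat$counts[2], ks_len$p,
              if (ks_len$p > 0.05) "no length difference once junctions are removed"
              else "length differs even within the stratum"))
}

## uORFs ----------------------------------------------------------------------
evid <- read_bed("results/sim/uorf_evidence.bed")
uorfs <- rbindlist(lapply(unique(feats$transcript_id), function(id) {
  tx <- get_transcript(merged, id)
  u <- find_uorfs(transcript_sequence(tx, genome), orfs[J(id), cds_start])
  if (nrow(u)) u[, transcript_id := id]
  u
}), fill = TRUE)
translated <- unique(filter_translated_uorfs(uorfs, evid)$transcript_id)
enr <- uorf_enrichment(feats, translated)
fwrite(enr, "results/uorf_enrichment.tsv", sep = "\t")
st <- enr[stratum == "stop_in_last_exon"]
cat(sprintf("Translated uORFs in the stop-in-last-exon stratum: %.1f%% of sensitive vs %.1f%% of insensitive isoforms.\n",
            100 * st[group == "sensitive", fraction],
            100 * st[group == "insensitive", fraction]))

## splice-site strength and conservation of poised vs control exons -----------
cfg <- run_config(genome = "results/sim/genome.fa",
                  reference = "results/sim/reference.gtf",
                  novel = "results/sim/novel.gtf",
                  principal_starts = "results/sim/principal_starts.tsv",
                  junction_counts = "results/sim/junction_counts.tsv",
                  events = "results/sim/events.tsv",
                  abundance = "results/sim/abundance.tsv",
                  conservation = "results/sim/conservation.bedGraph",
                  uorf_evidence = "results/sim/uorf_evidence.bed",
                  out_dir = "results/pipeline", seed = 1)
splice <- nmdsense:::splice_feature_table(pairs, events, decisions, merged,
                                          orfs, genome, cfg)
fwrite(splice$table, "results/splice_features.tsv", sep = "\t")
sm <- splice$summary
cat(sprintf("Mean acceptor score: %.1f bits (poised) vs %.1f bits (control); donor: %.1f vs %.1f.\n",
            sm[group == "NMD", mean_acceptor_score],
            sm[group == "control", mean_acceptor_score],
            sm[group == "NMD", mean_donor_score],
            sm[group == "control", mean_donor_score]))
cons <- splice$table[, .(acc_cons = mean(acceptor_conservation, na.rm = TRUE)),
                     by = group]
cat(sprintf("Mean acceptor-window conservation: %.2f (poised) vs %.2f (control).\n",
            cons[group == "NMD", acc_cons], cons[group == "control", acc_cons]))

## gene-level vs isoform-level differential expression ------------------------
ab <- read_abundance("results/sim/abundance.tsv")
ctr <- grep("^CTR", names(ab), value = TRUE)
kd <- grep("^dKD", names(ab), value = TRUE)
tx_de <- simple_de(ab, "transcript_id", ctr, kd)
tx_de[, gene_id := sub("\\.T[12]$", "", transcript_id)]
gene_ab <- ab[, lapply(.SD, sum), by = .(gene_id = sub("\\.T[12]$", "", transcript_id)),
              .SDcols = c(ctr, kd)]
gene_de <- simple_de(gene_ab, "gene_id", ctr, kd)
ct <- gene_isoform_cross_tab(gene_de, tx_de, pairs)
fwrite(ct$scatter, "results/gene_isoform_scatter.tsv", sep = "\t")
cat(sprintf("Gene vs isoform significance: both %d, isoform-only %d, gene-only %d, neither %d.\n",
            ct$counts["both"], ct$counts["isoform_only"],
            ct$counts["gene_only"], ct$counts["neither"]))
cat("Feature tables written under results/\n")
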