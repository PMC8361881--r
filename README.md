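# nmdsense

Isoform-resolution identification of endogenous targets of nonsense-mediated
mRNA decay (NMD) from an augmented transcriptome and replicate splicing
quantifications, plus the downstream analysis of what makes an isoform
NMD-sensitive.

NMD degrades mRNAs that terminate translation prematurely — canonically,
transcripts retaining an exon-junction complex downstream of the stop codon.
Alternative splicing creates such substrates constantly: a "poised" exon
whose inclusion (or skipping) introduces a premature termination codon (PTC)
makes one splice form of a gene unstable while the other persists. Given a
knockdown/rescue perturbation of NMD, this package calls the responding
skipped-exon events, resolves them to transcript pairs, and quantifies the
features that distinguish the sensitive isoform. It is aimed at
transcriptomics analysts studying RNA surveillance or isoform-level
regulation.

## What it computes

For each skipped-exon event with inclusion/skipping junction counts
$(I, S)$ and effective lengths $(L_I, L_S)$, the percent-spliced-in per
replicate is

$$\psi = \frac{I/L_I}{I/L_I + S/L_S}.$$

An event is called NMD-responding when, across replicates,

* FDR < 0.05 in **both** comparisons (knockdown vs control, rescue vs
  knockdown; moderated t on logit-PSI, Benjamini–Hochberg within each
  comparison),
* $|\Delta\psi_{\mathrm{kd}}| \ge 0.10$, and
* $\mathrm{sign}(\Delta\psi_{\mathrm{resc}}) =
  -\mathrm{sign}(\Delta\psi_{\mathrm{kd}})$ — the rescue must revert the
  shift.

Events with $\Delta\psi_{\mathrm{kd}} > 0$ form the *inclusion* subclass
(the exon-including isoform is NMD-sensitive), the rest the *exclusion*
subclass. Upstream, novel transcript models are merged into the reference by
intron-chain identity; a gene-level start codon (principal-isoform table) is
projected onto every transcript to define 5'UTR/CDS/3'UTR. Downstream, each
selected event is reduced to its most abundant sensitive and insensitive
transcript, and the pairs are compared for: exon-exon junctions downstream
of the termination codon, 3'UTR length (overall and restricted to
stop-in-last-exon transcripts), translated uORFs in the 5'UTR, splice-site
strength (positional log-odds, bits) and conservation of poised vs control
exons, and gene-level vs isoform-level differential expression.

A synthetic-data generator (`generate_dataset`) emits a complete study
bundle — genome, reference + novel GTFs, junction counts under the
CTR/dKD/RESC design, abundances, conservation track, uORF evidence — with
planted ground truth, so the whole workflow is validated by recovery.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic data
(1,200 genes, 180 planted NMD events, three replicates at ~50x junction
coverage):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_merge_annotation.R
Rscript analysis/03_select_events.R
Rscript analysis/04_pair_isoforms.R
Rscript analysis/05_feature_analysis.R
```

which prints, among other things:

```
Tested 1200 events; selected 172 (111 inclusion / 61 exclusion).
Recovered 171 of 180 planted events (95.0% sensitivity); 1 false calls (0.6% of selections).
Subclass concordance among recovered events: 100.0%.
...
3'UTR junction prevalence: 79% of sensitive vs 24% of insensitive isoforms (K-S p = 0).
Stratified 3'UTR length (stop in last exon, n=36/130): K-S p = 0.69 — no length difference once junctions are removed.
Translated uORFs in the stop-in-last-exon stratum: 33.3% of sensitive vs 26.2% of insensitive isoforms.
Mean acceptor score: -24.4 bits (poised) vs 33.3 bits (control); donor: -9.2 vs 13.4.
Gene vs isoform significance: both 39, isoform-only 116, gene-only 1, neither 16.
```

Reading the output: the dual-FDR directional filter recovers 95% of the
planted events with a single false call and assigns every recovered event
the correct subclass. The feature tables then reproduce the planted biology —
sensitive isoforms are strongly enriched for a junction downstream of the
stop; once transcripts with such junctions are removed (the
stop-in-last-exon stratum), 3'UTR lengths no longer differ, while uORFs
remain modestly enriched; and most poised exons use far weaker, less
conserved splice sites than matched control exons, with gene-level tests
missing most of the isoform-level changes.

Tables land under `results/`; `run_pipeline()` runs the same stages as one
call with a JSON run report. See `vignettes/nmdsense-methods.Rmd` for the
models, parameter conventions and what the synthetic data does and does not
emulate.

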