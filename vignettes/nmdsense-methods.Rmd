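---
title: "Calling NMD-sensitive mRNA isoforms: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling NMD-sensitive mRNA isoforms: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological problem

Nonsense-mediated mRNA decay (NMD) degrades transcripts that terminate
translation prematurely. Its canonical trigger is an exon-junction complex
(EJC) left on the mRNA downstream of the termination codon: junctions more
than roughly 30–55 nt behind the stop are not stripped by the terminating
ribosome and mark the transcript for decay. Alternative splicing routinely
produces such isoforms — a "poised" exon whose inclusion (or skipping)
introduces a premature termination codon (PTC) turns one splice form of a
gene into an NMD substrate while the other form is stable.

`nmdsense` implements an isoform-resolution workflow for identifying these
endogenous NMD targets from splicing quantifications collected under NMD
perturbation, and for characterising what distinguishes the sensitive from
the insensitive isoform of the same event: 3'UTR junction content, 3'UTR
length, upstream open reading frames (uORFs), and the strength and
conservation of the poised exon's splice sites.

# The pipeline model

The workflow runs in five stages, each exposed as ordinary functions and
driven by the numbered scripts under `analysis/`:

1. **Transcriptome augmentation** (`merge_transcriptomes`). Novel transcript
   models — in the emulated study, assemblies from long reads — are merged
   into the reference annotation by *intron-chain identity*: a multi-exon
   model is added only when its exact ordered junction set (same chromosome
   and strand) matches no existing transcript; on a match it is collapsed
   into the existing entry, keeping the longer terminal ends. Single-exon
   models are added unless fully contained in an existing exon of the locus.
   This reproduces the observable behaviour of assembler merges without
   re-implementing read-level assembly; how a particular assembler resolves
   conflicting terminal exons is not claimed, only the junction-set rule.
   Novel models inherit the gene id of the reference gene they overlap most
   (exonic bases); orphans get a `NOVG_` prefix; id collisions are suffixed
   `.n1` rather than dropped.

2. **ORF projection** (`project_orf`). One start codon per gene, taken from a
   principal-isoform table (APPRIS-style), is mapped through the genome into
   every transcript of that gene. The spliced sequence must read `ATG` at the
   mapped offset (the start may itself be spliced across two exons — mapping
   is by the genomic first base, verification reads transcript space); codons
   are then scanned to the first in-frame `TAA`/`TAG`/`TGA`. Codons
   containing `N` never terminate the scan (conservative). Each failure mode
   is a distinct status (`no_principal_start`, `start_not_exonic`,
   `start_interrupted`, `no_stop_found`) so downstream filtering can report
   why a transcript was excluded. Junction distances are measured from the
   first base *after* the stop codon — stated explicitly because the
   alternative (from the stop's first base) shifts everything by 3 nt.

3. **Event selection** (`test_events`, `select_nmd_events`). PSI per
   replicate is the length-normalised inclusion fraction
   $\psi = (I/L_I)\,/\,(I/L_I + S/L_S)$; replicates with $I=S=0$ carry no
   information and are dropped, not imputed. An event is NMD-responding when
   (i) FDR < 0.05 in *both* the knockdown-vs-control and rescue-vs-knockdown
   comparisons, (ii) $|\Delta\psi_{\mathrm{kd}}| \ge 0.10$, and (iii) the
   rescue shift has the opposite sign. Events split into an *inclusion*
   subclass ($\Delta\psi_{\mathrm{kd}}>0$: the exon-including form
   accumulates when NMD is off) and an *exclusion* subclass. The rescue
   condition label is a parameter, since designs may rescue with different
   factors.

4. **Isoform pairing** (`build_pairs`). Candidate transcripts for an event
   are those of the same gene whose *pre-mRNA span* covers the target exon —
   intron-spanning isoforms count even when the exon is absent from their
   mature form. The inclusion set requires the target exon with both
   boundaries exact (boundary-shift variants belong to other event types);
   the exclusion set requires the direct flank-to-flank junction. Subclass
   assigns sensitivity labels, transcripts without a projectable ORF are
   discarded, and the most abundant transcript per side (mean over control
   and knockdown samples; ties break lexicographically so runs are
   reproducible) represents the pair.

5. **Feature analysis**. Per pair side: number of junctions downstream of the
   stop (any distance; the >55 nt refinement is a separate column via
   `stop_context`, threshold configurable because the literature quotes both
   ~30 and ~55 nt), 3'UTR length, the stop-in-last-exon stratum (where the
   junction signal is absent by construction, isolating length effects),
   uORFs, splice windows and conservation, and a gene-vs-isoform
   differential-expression cross-tabulation. Distribution comparisons use the
   two-sample two-sided Kolmogorov–Smirnov test with the asymptotic p-value.

# Statistical choices

**Replicate-aware event testing.** The per-event contract is a two-sided
Welch test on logit-PSI with pseudocount $\varepsilon = 0.01$
(`test_event`); it is exposed and tested as such. As the *pipeline default*,
however, `test_events` fits the same logit-PSI values with limma and uses the
moderated t-statistic. With three replicates per condition a per-event Welch
test has four residual degrees of freedom; its noncentral-t tail is so heavy
that even a 0.3 PSI shift at 50x junction coverage cannot be detected
reliably once Benjamini–Hochberg correction over thousands of events pushes
the working threshold to $p \approx 5\times10^{-3}$. Moderating the
per-event variance across all events of the table — the standard small-n
expression-analysis remedy — restores the power the design intends while
remaining replicate-aware. The test sits behind a single `method` argument
(`"moderated"` / `"welch"`), so the plain Welch contract remains one flag
away.

**FDR granularity.** BH adjustment is computed within each comparison across
all events of the table, mirroring how event-level differential-splicing
tools report FDR per contrast.

**uORF definition.** An ATG strictly upstream of the main start, extended to
its first in-frame stop, kept when the total length (stop included) is at
least 15 nt and the uORF ends at or before the main CDS start ("entirely
upstream"). The 15 nt default follows the stricter of the two conventions in
circulation (five codons *including* the stop); the threshold is a
parameter. Translation evidence requires the uORF interval to be *fully
contained* in an evidence interval — containment, not overlap, is the
package's convention where the literature is silent. Multiple uORFs count
once for prevalence: presence, not dosage, is the reported quantity.

**Splice-site scoring.** Windows follow the field's maximum-entropy tool
conventions: 20 intronic + 3 exonic bases at the acceptor (23 nt), 3 exonic +
6 intronic at the donor (9 nt), in transcript orientation. The default
scorer is a positional log-odds model (pseudocount 0.5, uniform background,
bits) trained on the annotation's own constitutive internal-exon windows;
externally fitted parameter tables load through `read_splice_model` into the
same scoring interface. The default is deliberately download-free; absolute
scores are not comparable to published maximum-entropy scores, but the
poised-vs-control *contrast* — the quantity the analysis consumes — is.

**Conservation.** Mean per-base track value over a window; windows with less
than 50% track coverage report a missing value rather than 0, since absence
of coverage is not evidence of non-conservation. Covered-base averaging
(rather than zero-filling uncovered bases) is the package's choice where the
convention is unstated.

**Control exons.** As many internal exons as there are poised exons, sampled
uniformly without replacement from coding, non-NMD-sensitive transcripts, at
most one exon per gene (so a single exon-rich gene cannot dominate the
control distribution), excluding event target exons, deterministic under a
seed.

# The synthetic-data generator

`generate_dataset` emits everything the pipeline consumes — genome FASTA,
reference and novel GTFs, principal-start table, junction counts, abundance
matrix, conservation bedGraph, uORF-evidence BED — plus a truth table, so
every downstream claim can be scored against what was planted.

**Gene template.** Each gene has two alternative first exons (one per
isoform, pure 5'UTR — this lets uORF presence differ between the isoforms of
a pair), a shared start-codon exon, two flanking coding exons around an
alternative target exon, and a last exon carrying the canonical stop and
3'UTR. Strand is random; minus-strand genes are laid out by mirroring the
whole locus. One skipped-exon event per gene.

**Planted NMD structure.** For an inclusion-subclass event the exon-including
isoform carries the PTC: either an in-frame stop inside the poised exon
itself (at least one junction downstream of the PTC, guaranteed and verified)
or — for the configured 20% minority — a frame-shifting exon whose resulting
stop lands in the last exon, emulating sensitive isoforms with no 3'UTR
junction. Exclusion-subclass events mirror this for the skipping form.
Insensitive isoforms get a 3'UTR junction with probability 0.3. Every plant
is verified by running `project_orf` at generation time before the bundle is
written.

**The T-free alphabet.** Exon bodies are drawn from {A,C,G}; all start
codons, stop codons and uORFs are planted motifs (every stop codon and ATG
contains T, and plants are kept ≥6 nt apart, so cross-frame reads through a
planted motif can never create a spurious signal). This makes ORF and uORF
truth exact by construction. It is a deliberate simplification: real
transcripts carry chance ATGs and stops in all frames, so the generator does
not emulate codon statistics, uORF false-positive pressure, or GC content —
and passing recovery tests says nothing about those properties of real data.
The uORF *finder* itself is exercised on full-alphabet random sequence
against a brute-force oracle, so the simplification is confined to the
planted cohorts.

**Counts model.** Per event, condition and replicate: depth ~
Poisson(coverage 50), inclusion reads $I \sim \mathrm{Binomial}(d, p)$ with
$p = \psi L_I / (\psi L_I + (1-\psi) L_S)$, $L_I = 2, L_S = 1$ (two
inclusion junctions vs one skip junction), $S = d - I$. True events shift
PSI by ±0.3 in the knockdown and revert fully under rescue (the reversal
fraction is configurable); base PSI is uniform on [0.15, 0.55] for inclusion
events, [0.45, 0.85] for exclusion events, [0.2, 0.8] for null events. There
is no between-replicate overdispersion beyond binomial noise — another
stated limit of emulation.

**3'UTR length law.** Uniform on [150, 400] nt, *identical for both groups*,
so that the stratified (stop-in-last-exon) length comparison is null by
design; frame alignment perturbs a planted length by at most 2 nt,
identically distributed in both groups.

**Splice windows and conservation.** Window sequences are written into the
genome from near-deterministic consensus weight matrices (canonical
GT/AG cores at 0.995, other positions 0.9 dominant) or from uniform
degenerate matrices; the poised exon's pair is degenerate with probability
0.8, all constitutive sites are consensus. Exonic window positions stay
T-free so overwriting exon edges cannot break reading frames. The
conservation track assigns each window a constant value ~ N(1.5, 0.2) for
consensus and N(0, 0.2) for degenerate windows, giving the
strong-and-conserved vs weak-and-unconserved contrast the feature analysis
is meant to detect.

**Abundance.** Log-normal baseline per gene; sensitive isoforms at 0.3x in
control (degraded), 0.9x in knockdown, 0.4x under rescue; the insensitive
isoform flat. This produces isoform-level derepression with modest gene-level
movement, the structure the gene-vs-isoform cross-tabulation visualises.

# Validation design and problem sizes

The test suite regenerates everything it checks. The sizes are the package's
chosen validation conditions: event recovery on 2,000 events (200 true,
ΔPSI = 0.3, coverage 50, three replicates) expecting ≥90% sensitivity and
≤10% false discoveries with exact subclass agreement; an all-null design
(2,000 events × 10 seeds) expecting ≤1% selections; feature-prevalence
recovery on a cohort sized so the smallest compared stratum (sensitive
transcripts with the stop in the last exon, ~20% of pairs) holds ~500
transcripts, within ±0.04 of the planted 0.8/0.3 junction and 0.35/0.25 uORF
prevalences; 100 seeded runs of the null stratified length comparison
expecting K-S p > 0.05 in ≥90; brute-force-oracle equality for the uORF
finder, K-S statistic, BH adjustment, junction counting and coordinate
mapping on hundreds to thousands of randomized instances; and ≥2-bit
separation between degenerate poised-exon and control splice-site scores.
`scripts/acceptance.R` recomputes the same quantities from scratch under a
caller-supplied seed.

# Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; GTF converts at the I/O
  boundary only, bedGraph/BED are natively half-open.
* logit-PSI uses $\log((\psi+\varepsilon)/(1-\psi+\varepsilon))$ with
  $\varepsilon = 0.01$.
* Zero-variance-both-sides Welch comparisons: p = 1 on equal means, 0
  otherwise (deterministic, no jitter is injected).
* Ties in representative selection resolve to the lexicographically smallest
  transcript id; control-exon sampling shuffles before the per-gene pick so
  the one-exon-per-gene choice is unbiased.
* `N` bases: never a stop codon; skipped in splice scoring.
* An event whose intervals are inconsistent, a window of the wrong width, an
  empty exon set, or a sample with fewer than two values fail fast with a
  named error rather than propagating silently.

# Known limitations

* The event test models junction counts only through PSI; a count-level
  hierarchical model (as event-level splicing tools use) could gain power at
  very low coverage.
* Pairing and features are implemented for skipped exons; the selection
  filter itself is event-type agnostic, but other event types would need
  their own pairing geometry.
* The default splice model is annotation-trained log-odds, not a published
  maximum-entropy parameterisation; only contrasts, not absolute scores, are
  meaningful.
* The generator's simplifications (T-free exons, binomial counts, constant
  conservation per window, one event per gene) are listed above; conclusions
  about real data should lean on the oracle-checked primitives, not on
  recovery rates alone.
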