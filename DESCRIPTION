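Package: nmdsense
Title: Identification of Endogenous NMD-Sensitive mRNA Isoforms from Splicing Quantifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls endogenous targets of nonsense-mediated mRNA decay (NMD) at
    isoform resolution from an augmented (long-read-informed) transcriptome and
    replicate skipped-exon splicing quantifications across knockdown and rescue
    conditions. Provides intron-chain merging of novel transcript models into a
    reference annotation, projection of gene-level start codons onto every
    isoform to define open reading frames and 3'UTRs, a replicate-aware
    dual-comparison directional filter on percent-spliced-in (PSI) values,
    reduction of each significant event to a non-redundant pair of NMD-sensitive
    and NMD-insensitive representative transcripts, and downstream analysis of
    NMD-determining features: exon-exon junctions downstream of the termination
    codon, 3'UTR length, upstream open reading frames with translation evidence,
    splice-site strength and conservation of poised versus control exons. A
    synthetic-data generator with planted ground truth supports end-to-end
    validation of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
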