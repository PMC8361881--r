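# Feature analysis of NMD-sensitive vs insensitive transcript pairs:
# 3'UTR junctions and length, uORFs with translation evidence, splice-site
# strength and conservation of poised vs control exons, and the gene-vs-
# isoform significance cross-tabulation.

#' Per-transcript 3'UTR feature table for a pair set
#'
#' One row per pair side with the number of exon-exon junctions downstream of
#' the termination codon (any distance), the 3'UTR length and the
#' stop-in-last-exon flag.
#'
#' @param pairs table from [build_pairs()].
#' @param orfs table from [project_orfs()].
#' @param threshold_nt distance threshold for the additional
#'   beyond-threshold junction column (default 55 nt).
#' @return data.table with `event_id`, `transcript_id`, `group`
#'   (`sensitive`/`insensitive`), `n_junctions_3utr` (any distance),
#'   `n_junctions_beyond_threshold`, `utr3_len`, `stop_in_last_exon`.
#' @export
utr3_features <- function(pairs, orfs, threshold_nt = 55) {
  long <- rbind(
    data.table(event_id = pairs$event_id, transcript_id = pairs$sensitive_tx,
               group = "sensitive"),
    data.table(event_id = pairs$event_id, transcript_id = pairs$insensitive_tx,
               group = "insensitive"))
  merged <- orfs[long, on = "transcript_id"]
  if (any(merged$status != "ok"))
    stopf("utr3_features requires ORF status 'ok' for all pair transcripts")
  merged[, .(event_id, transcript_id, group,
             n_junctions_3utr = junctions_downstream_of_stop,
             n_junctions_beyond_threshold = vapply(
               junction_distances, function(d) sum(d > threshold_nt),
               integer(1)),
             utr3_len, stop_in_last_exon)]
}

#' 3'UTR length distributions restricted to stop-in-last-exon transcripts
#'
#' The stratification removes the junction signal so that 3'UTR length can be
#' compared between groups on its own.
#'
#' @param table output of [utr3_features()].
#' @return list with numeric vectors `sensitive` and `insensitive` plus a
#'   `counts` vector; if a group is empty after filtering, a notice is given.
#' @export
last_exon_stratified_lengths <- function(table) {
  tb <- as.data.table(table)[stop_in_last_exon == TRUE]
  out <- list(sensitive = tb[group == "sensitive", utr3_len],
              insensitive = tb[group == "insensitive", utr3_len])
  out$counts <- c(sensitive = length(out$sensitive),
                  insensitive = length(out$insensitive))
  if (any(out$counts == 0))
    message("last_exon_stratified_lengths: a group is empty after filtering; ",
            "comparison will be skipped")
  out
}

# ---------------------------------------------------------------------------
# uORFs
# ---------------------------------------------------------------------------

#' Find upstream open reading frames in a 5'UTR
#'
#' Every ATG strictly upstream of the main start codon is extended to its
#' first in-frame stop; the uORF is kept when the stop exists, the total
#' length (including the stop codon) is at least `min_len`, and the uORF ends
#' at or before the main CDS start ("entirely upstream"). Overlapping and
#' nested uORFs are all reported.
#'
#' @param tx_seq spliced transcript sequence.
#' @param cds_start 0-based transcript offset of the main start codon.
#' @param min_len minimum uORF length in nt, stop included (default 15).
#' @return data.table with 0-based half-open `start`, `end` (past the stop)
#'   and `length`.
#' @export
find_uorfs <- function(tx_seq, cds_start, min_len = 15) {
  empty <- data.table(start = integer(0), end = integer(0), length = integer(0))
  if (cds_start < 6L) return(empty)
  utr <- substring(tx_seq, 1L, cds_start)
  hits <- gregexpr("(?=ATG)", utr, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(empty)
  starts0 <- as.integer(hits) - 1L
  rows <- lapply(starts0, function(s) {
    cs <- seq.int(s, cds_start - 3L, by = 3L)
    if (!length(cs)) return(NULL)
    codons <- substring(tx_seq, cs + 1L, cs + 3L)
    k <- which(codons %in% STOP_CODONS)[1]
    if (is.na(k)) return(NULL)                      # no stop before CDS start
    end <- s + 3L * k
    len <- end - s
    if (len < min_len || end > cds_start) return(NULL)
    data.table(start = s, end = as.integer(end), length = as.integer(len))
  })
  out <- rbindlist(rows)
  if (!nrow(out)) return(empty)
  setorder(out, start, end)
  out
}

#' Keep uORFs with translation evidence
#'
#' A uORF is retained when its interval is fully contained in one evidence
#' interval of the same transcript (or chromosome, for genome-space
#' evidence).
#'
#' @param uorfs data.table with `transcript_id`, `start`, `end` (transcript
#'   space unless `space = "genome"`, in which case genomic coordinates are
#'   expected in the same columns with `chrom`).
#' @param evidence data.table of intervals: `chrom`, `start`, `end` (0-based
#'   half-open; for transcript space, `chrom` holds the transcript id).
#' @param space `"transcript"` or `"genome"`; must match how the evidence was
#'   produced.
#' @return the subset of `uorfs` with evidence, with `translated = TRUE`.
#' @export
filter_translated_uorfs <- function(uorfs, evidence, space = c("transcript", "genome")) {
  space <- match.arg(space)
  u <- as.data.table(uorfs)
  ev <- as.data.table(evidence)
  if (!nrow(u)) { u[, translated := logical(0)]; return(u) }
  key_col <- if (space == "transcript") "transcript_id" else "chrom"
  if (!key_col %in% names(u))
    stopf("uORF table lacks '%s' column required for %s-space evidence",
          key_col, space)
  if (!nrow(ev)) { u <- u[0]; u[, translated := logical(0)]; return(u) }
  keep <- vapply(seq_len(nrow(u)), function(i) {
    e <- ev[chrom == u[[key_col]][i]]
    any(e$start <= u$start[i] & e$end >= u$end[i])
  }, logical(1))
  out <- u[keep]
  out[, translated := TRUE]
  out[]
}

#' uORF prevalence in sensitive vs insensitive transcripts
#'
#' Fraction of transcripts carrying at least one translated uORF per group,
#' pooled and (optionally) restricted to the stop-in-last-exon stratum, where
#' the 3'UTR junction signal is absent and the uORF contribution becomes
#' visible. Multiple uORFs in one transcript count once.
#'
#' @param utr3_table output of [utr3_features()].
#' @param uorf_tx character vector of transcript ids with >= 1 translated
#'   uORF.
#' @param stratify_no_3utr_junctions also compute the stratum fractions.
#' @return data.table with `group`, `stratum` (`all` /
#'   `stop_in_last_exon`), `n`, `n_with_uorf`, `fraction` (NA when the
#'   stratum is empty).
#' @export
uorf_enrichment <- function(utr3_table, uorf_tx,
                            stratify_no_3utr_junctions = TRUE) {
  tb <- as.data.table(utr3_table)
  tb[, has_uorf := transcript_id %in% uorf_tx]
  frac <- function(sub, stratum) sub[, .(
    stratum = stratum, n = .N, n_with_uorf = sum(has_uorf),
    fraction = if (.N) sum(has_uorf) / .N else NA_real_), by = group]
  out <- frac(tb, "all")
  if (stratify_no_3utr_junctions)
    out <- rbind(out, frac(tb[stop_in_last_exon == TRUE], "stop_in_last_exon"))
  # groups absent from a stratum are reported with an undefined fraction
  grid <- CJ(group = unique(tb$group),
             stratum = unique(out$stratum), unique = TRUE)
  out <- out[grid, on = c("group", "stratum")]
  out[is.na(n), `:=`(n = 0L, n_with_uorf = 0L)]
  setorder(out, stratum, group)
  out[]
}

# ---------------------------------------------------------------------------
# Splice-site windows, scoring model, conservation
# ---------------------------------------------------------------------------

ACCEPTOR_INTRON <- 20L; ACCEPTOR_EXON <- 3L   # 23-nt acceptor window
DONOR_EXON <- 3L; DONOR_INTRON <- 6L          # 9-nt donor window

#' Extract acceptor and donor windows around an internal exon
#'
#' The acceptor window covers 20 intronic + 3 exonic bases at the 3' splice
#' site; the donor window 3 exonic + 6 intronic bases at the 5' splice site.
#' Sequences are reported in transcript orientation. Terminal exons have no
#' flanking introns on both sides and yield `NULL`.
#'
#' @param tx host transcript object.
#' @param exon_start,exon_end genomic coordinates (0-based half-open) of an
#'   exon of `tx`.
#' @param genome genome sequence.
#' @return list with `acceptor`, `donor` (sequences), `acceptor_interval`,
#'   `donor_interval` (genomic, 0-based half-open), or `NULL` for a terminal
#'   exon.
#' @export
extract_splice_windows <- function(tx, exon_start, exon_end, genome) {
  ex <- tx$exons
  i <- which(ex$start == exon_start & ex$end == exon_end)
  if (!length(i)) stopf("exon [%d,%d) not in transcript %s",
                        exon_start, exon_end, tx$id)
  if (i == 1L || i == nrow(ex)) return(NULL)
  if (tx$strand == "+") {
    acc_iv <- c(exon_start - ACCEPTOR_INTRON, exon_start + ACCEPTOR_EXON)
    don_iv <- c(exon_end - DONOR_EXON, exon_end + DONOR_INTRON)
    acc <- genome_subseq(genome, tx$chrom, acc_iv[1], acc_iv[2])
    don <- genome_subseq(genome, tx$chrom, don_iv[1], don_iv[2])
  } else {
    acc_iv <- c(exon_end - ACCEPTOR_EXON, exon_end + ACCEPTOR_INTRON)
    don_iv <- c(exon_start - DONOR_INTRON, exon_start + DONOR_EXON)
    acc <- revcomp_chr(genome_subseq(genome, tx$chrom, acc_iv[1], acc_iv[2]))
    don <- revcomp_chr(genome_subseq(genome, tx$chrom, don_iv[1], don_iv[2]))
  }
  list(acceptor = acc, donor = don,
       acceptor_interval = as.integer(acc_iv),
       donor_interval = as.integer(don_iv))
}

#' Train the default positional log-odds splice model
#'
#' Per-position base frequencies (pseudocount 0.5) over training windows,
#' scored as log2 odds against a uniform background. Serves as the default
#' splice-strength backend; externally fitted maximum-entropy-style parameter
#' tables can be loaded through [read_splice_model()] and scored through the
#' same interface.
#'
#' @param acceptor_seqs,donor_seqs character vectors of 23-nt / 9-nt windows.
#' @param pseudocount added to each base count per position.
#' @return object of class `splice_model`.
#' @export
train_splice_model <- function(acceptor_seqs, donor_seqs, pseudocount = 0.5) {
  pwm <- function(seqs, width) {
    seqs <- seqs[nchar(seqs) == width]
    if (!length(seqs)) stopf("no training windows of width %d", width)
    m <- matrix(pseudocount, nrow = 4, ncol = width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    for (j in seq_len(width)) {
      tb <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
      m[, j] <- m[, j] + as.numeric(tb)
    }
    p <- sweep(m, 2, colSums(m), "/")
    log2(p / 0.25)
  }
  structure(list(acceptor = pwm(acceptor_seqs, ACCEPTOR_INTRON + ACCEPTOR_EXON),
                 donor = pwm(donor_seqs, DONOR_EXON + DONOR_INTRON)),
            class = "splice_model")
}

#' Load an external splice-model parameter table
#'
#' TSV with columns `site` (`acceptor`/`donor`), `position` (1-based),
#' `base`, `weight` (log2-odds contribution); scored identically to the
#' trained default model.
#'
#' @param path TSV path.
#' @return object of class `splice_model`.
#' @export
read_splice_model <- function(path) {
  tb <- fread(path, sep = "\t")
  req <- c("site", "position", "base", "weight")
  miss <- setdiff(req, names(tb))
  if (length(miss)) stopf("splice-model table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  build <- function(sub, width) {
    m <- matrix(0, nrow = 4, ncol = width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_len(nrow(sub)))
      m[sub$base[i], sub$position[i]] <- sub$weight[i]
    m
  }
  structure(list(acceptor = build(tb[site == "acceptor"],
                                  ACCEPTOR_INTRON + ACCEPTOR_EXON),
                 donor = build(tb[site == "donor"], DONOR_EXON + DONOR_INTRON)),
            class = "splice_model")
}

#' Score a splice-site window
#'
#' Sum of per-position log2-odds; positions with `N` are skipped.
#'
#' @param window window sequence (23 nt for acceptor, 9 nt for donor).
#' @param model `splice_model` object.
#' @param site `"acceptor"` or `"donor"`.
#' @return score in bits.
#' @export
score_splice_site <- function(window, model, site = c("acceptor", "donor")) {
  site <- match.arg(site)
  m <- model[[site]]
  if (nchar(window) != ncol(m))
    stopf("window length %d does not match %s model width %d",
          nchar(window), site, ncol(m))
  bases <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  keep <- bases %in% rownames(m)
  sum(m[cbind(match(bases[keep], rownames(m)), which(keep))])
}

#' Read a bedGraph conservation track
#'
#' @param path bedGraph path.
#' @return data.table `chrom`, `start`, `end` (0-based half-open), `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = as.numeric(S4Vectors::mcols(gr)$score))
}

#' Read a BED interval file
#'
#' @param path BED path.
#' @return data.table `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Mean per-base conservation over a genomic interval
#'
#' Average of the track value over covered bases; when fewer than half of the
#' interval's bases are covered the mean is reported as `NA` (a missing-value
#' marker, not 0). Intervals on chromosomes absent from the track are also
#' `NA`.
#'
#' @param chrom,start,end interval (0-based half-open).
#' @param track data.table from [read_bedgraph()].
#' @return mean score or `NA_real_`.
#' @export
mean_conservation <- function(chrom, start, end, track) {
  if (end <= start) stopf("empty interval")
  iv_chrom <- chrom; iv_start <- start; iv_end <- end
  sub <- track[chrom == iv_chrom & start < iv_end & end > iv_start]
  if (!nrow(sub)) return(NA_real_)
  s <- pmax(sub$start, iv_start); e <- pmin(sub$end, iv_end)
  w <- e - s
  covered <- sum(w)
  if (covered < (iv_end - iv_start) / 2) return(NA_real_)
  sum(sub$value * w) / covered
}

#' Sample control exons for the splice-signal comparison
#'
#' Uniformly samples `n` internal exons, at most one per gene, from coding
#' transcripts (ORF status ok) that are not NMD-sensitive, excluding the
#' target exons of selected events. Deterministic under `seed`.
#'
#' @param ann `nmd_annotation`.
#' @param orfs table from [project_orfs()].
#' @param n number of exons (matched to the NMD exon count by the caller).
#' @param seed integer seed.
#' @param exclude_tx transcript ids to exclude (NMD-sensitive transcripts).
#' @param exclude_exons optional data.table of exons (`chrom`,`start`,`end`)
#'   never to sample (event target exons).
#' @return data.table `transcript_id`, `gene_id`, `chrom`, `strand`, `start`,
#'   `end`.
#' @export
sample_control_exons <- function(ann, orfs, n, seed, exclude_tx = character(0),
                                 exclude_exons = NULL) {
  ok_tx <- setdiff(orfs[status == "ok", transcript_id], exclude_tx)
  ex <- ann$exons[transcript_id %in% ok_tx]
  setorder(ex, transcript_id, start)
  internal <- ex[, .SD[-c(1L, .N)], by = transcript_id]
  if (!is.null(exclude_exons) && nrow(exclude_exons)) {
    bad <- paste(exclude_exons$chrom, exclude_exons$start, exclude_exons$end)
    internal <- internal[!paste(chrom, start, end) %in% bad]
  }
  # one candidate exon per gene, then sample genes
  internal <- unique(internal, by = c("gene_id", "chrom", "start", "end"))
  with_seed(seed, {
    internal <- internal[sample(.N)]           # shuffle before per-gene pick
    one_per_gene <- internal[!duplicated(gene_id)]
    if (nrow(one_per_gene) < n)
      stopf("only %d eligible genes for %d requested control exons",
            nrow(one_per_gene), n)
    picked <- one_per_gene[sample(.N, n)]
  })
  picked[, .(transcript_id, gene_id, chrom, strand, start, end)]
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided statistic with the asymptotic p-value.
#'
#' @param sample_a,sample_b numeric vectors with at least 2 values each.
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stopf("ks_compare needs >= 2 values per sample")
  kt <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

# ---------------------------------------------------------------------------
# Gene-vs-isoform significance cross-tabulation
# ---------------------------------------------------------------------------

#' Cross-tabulate gene-level vs isoform-level significance
#'
#' For every gene with an NMD-sensitive isoform, classify whether the
#' differential-expression change is significant at the gene level, the
#' isoform level (the sensitive isoform), both, or neither.
#'
#' @param gene_de data.frame with `gene_id`, `log2fc`, `significant`.
#' @param tx_de data.frame with `transcript_id`, `gene_id`, `log2fc`,
#'   `significant`.
#' @param pairs table from [build_pairs()].
#' @return list with `counts` (named vector: both, isoform_only, gene_only,
#'   neither, unquantified) and `scatter` (data.table of gene and isoform
#'   log2 fold changes).
#' @export
gene_isoform_cross_tab <- function(gene_de, tx_de, pairs) {
  gde <- as.data.table(gene_de); tde <- as.data.table(tx_de)
  counts <- c(both = 0L, isoform_only = 0L, gene_only = 0L, neither = 0L,
              unquantified = 0L)
  genes <- unique(pairs[, .(gene_id, sensitive_tx)])
  scat <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- gde[gene_id == genes$gene_id[i]]
    t <- tde[transcript_id == genes$sensitive_tx[i]]
    if (!nrow(g) || !nrow(t)) { counts["unquantified"] <- counts["unquantified"] + 1L; next }
    cls <- if (g$significant[1] && t$significant[1]) "both"
    else if (t$significant[1]) "isoform_only"
    else if (g$significant[1]) "gene_only"
    else "neither"
    counts[cls] <- counts[cls] + 1L
    scat[[i]] <- data.table(gene_id = genes$gene_id[i],
                            transcript_id = genes$sensitive_tx[i],
                            gene_log2fc = g$log2fc[1],
                            isoform_log2fc = t$log2fc[1], class = cls)
  }
  list(counts = counts, scatter = rbindlist(scat))
}

#' Simple log-scale Welch differential-expression helper
#'
#' A deliberately plain helper for producing the gene/isoform DE inputs of
#' [gene_isoform_cross_tab()] from an abundance matrix when no external DE
#' table is available: Welch t-test on `log2(x + 0.5)` between two sample
#' groups with BH adjustment.
#'
#' @param abundance data.table with an id column plus sample columns.
#' @param id_col name of the id column.
#' @param samples_a,samples_b sample column names of the two groups.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return data.table `id`, `log2fc` (b vs a), `p`, `fdr`, `significant`.
#' @export
simple_de <- function(abundance, id_col, samples_a, samples_b, alpha = 0.05) {
  ab <- as.data.table(abundance)
  la <- log2(as.matrix(ab[, ..samples_a]) + 0.5)
  lb <- log2(as.matrix(ab[, ..samples_b]) + 0.5)
  p <- vapply(seq_len(nrow(ab)), function(i) {
    if (var(la[i, ]) == 0 && var(lb[i, ]) == 0)
      return(if (isTRUE(all.equal(mean(la[i, ]), mean(lb[i, ])))) 1 else 0)
    t.test(la[i, ], lb[i, ], var.equal = FALSE)$p.value
  }, numeric(1))
  out <- data.table(id = ab[[id_col]],
                    log2fc = rowMeans(lb) - rowMeans(la),
                    p = p, fdr = adjust_fdr(p))
  out[, significant := fdr < alpha]
  setnames(out, "id", id_col)
  out[]
}
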