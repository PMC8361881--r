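# ORF projection: one gene-level start codon (principal-isoform table)
# projected onto every transcript of the gene, defining 5'UTR/CDS/3'UTR and
# the stop-codon context used by the downstream NMD feature analysis.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Load a principal-isoform start-codon table
#'
#' The TSV carries one row per gene with the genomic position of the first
#' base of the annotated start codon (1-based in the file, converted to the
#' internal 0-based convention). Duplicated genes keep the first row, with a
#' warning.
#'
#' @param path TSV with columns `gene_id`, `chrom`, `strand`, `start_codon_pos`.
#' @return data.table keyed by `gene_id` with 0-based `start_pos`.
#' @export
load_principal_starts <- function(path) {
  if (!file.exists(path)) stopf("principal-start table not found: %s", path)
  tb <- fread(path, sep = "\t", colClasses = list(character = "gene_id"))
  req <- c("gene_id", "chrom", "strand", "start_codon_pos")
  miss <- setdiff(req, names(tb))
  if (length(miss)) stopf("principal-start table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(tb$gene_id)) {
    warnf("%d duplicated gene id(s) in principal-start table; first row kept",
          sum(duplicated(tb$gene_id)))
    tb <- tb[!duplicated(gene_id)]
  }
  out <- tb[, .(gene_id, chrom, strand, start_pos = as.integer(start_codon_pos) - 1L)]
  setkey(out, gene_id)
  out
}

#' Project the gene-level start codon onto one transcript
#'
#' Maps the genomic start-codon base to a transcript offset, verifies an ATG
#' at that offset in the spliced sequence, then scans codons to the first
#' in-frame stop (TAA/TAG/TGA; codons containing N never terminate). On
#' success the annotation records UTR/CDS lengths and the positions of all
#' exon-exon junctions downstream of the termination codon, measured from the
#' first base after the stop.
#'
#' @param tx transcript object from [get_transcript()].
#' @param starts table from [load_principal_starts()].
#' @param genome genome sequence.
#' @param tx_seq optional precomputed spliced sequence (performance hook).
#' @return list of class `orf_annotation` with fields `transcript_id`,
#'   `status` (`ok`, `no_principal_start`, `start_not_exonic`,
#'   `start_interrupted`, `no_stop_found`), and when `ok`: `cds_start`,
#'   `cds_end` (half-open, past the stop), `utr5_len`, `cds_len`, `utr3_len`,
#'   `junctions_downstream_of_stop`, `junction_distances`,
#'   `stop_in_last_exon`.
#' @export
project_orf <- function(tx, starts, genome, tx_seq = NULL) {
  res <- list(transcript_id = tx$id, status = "ok")
  class(res) <- "orf_annotation"
  row <- starts[J(tx$gene_id), nomatch = NULL]
  if (!nrow(row)) { res$status <- "no_principal_start"; return(res) }
  if (row$chrom[1] != tx$chrom || row$strand[1] != tx$strand) {
    res$status <- "start_not_exonic"; return(res)
  }
  off <- genomic_to_transcript(tx, row$start_pos[1])
  if (is.na(off)) { res$status <- "start_not_exonic"; return(res) }
  if (is.null(tx_seq)) tx_seq <- transcript_sequence(tx, genome)
  len <- nchar(tx_seq)
  if (off + 3L > len || substring(tx_seq, off + 1L, off + 3L) != "ATG") {
    res$status <- "start_interrupted"; return(res)
  }
  codon_starts <- seq.int(off, len - 3L, by = 3L)
  codons <- substring(tx_seq, codon_starts + 1L, codon_starts + 3L)
  stop_i <- which(codons %in% STOP_CODONS)
  if (!length(stop_i)) { res$status <- "no_stop_found"; return(res) }
  k <- stop_i[1]
  cds_end <- off + 3L * k                # just past the stop codon
  jx <- junction_offsets(tx)
  down <- jx[jx >= cds_end] - cds_end
  res$cds_start <- as.integer(off)
  res$cds_end <- as.integer(cds_end)
  res$utr5_len <- as.integer(off)
  res$cds_len <- as.integer(3L * k)
  res$utr3_len <- as.integer(len - cds_end)
  res$junction_distances <- as.integer(sort(down))
  res$junctions_downstream_of_stop <- length(down)
  res$stop_in_last_exon <- length(down) == 0L
  res
}

#' @export
print.orf_annotation <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<orf_annotation> %s ok: utr5=%d cds=%d utr3=%d junctions_after_stop=%d\n",
                x$transcript_id, x$utr5_len, x$cds_len, x$utr3_len,
                x$junctions_downstream_of_stop))
  else cat(sprintf("<orf_annotation> %s: %s\n", x$transcript_id, x$status))
  invisible(x)
}

#' Project ORFs onto every transcript of an annotation
#'
#' @param ann an `nmd_annotation`.
#' @param starts table from [load_principal_starts()].
#' @param genome genome sequence.
#' @return data.table with one row per transcript (`junction_distances` is a
#'   list column); transcripts whose gene lacks a principal start get status
#'   `no_principal_start`.
#' @export
project_orfs <- function(ann, starts, genome) {
  ex <- copy(ann$exons)
  setorder(ex, transcript_id, start)
  meta <- ex[, .(gene_id = gene_id[1], chrom = chrom[1], strand = strand[1]),
             by = transcript_id]
  parts <- split(ex[, .(start, end)], ex$transcript_id)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$transcript_id[i]
    tx <- list(id = id, gene_id = meta$gene_id[i], chrom = meta$chrom[i],
               strand = meta$strand[i], exons = parts[[id]])
    o <- project_orf(tx, starts, genome)
    data.table(transcript_id = o$transcript_id, status = o$status,
               cds_start = o$cds_start %||% NA_integer_,
               cds_end = o$cds_end %||% NA_integer_,
               utr5_len = o$utr5_len %||% NA_integer_,
               cds_len = o$cds_len %||% NA_integer_,
               utr3_len = o$utr3_len %||% NA_integer_,
               junctions_downstream_of_stop =
                 o$junctions_downstream_of_stop %||% NA_integer_,
               stop_in_last_exon = o$stop_in_last_exon %||% NA,
               junction_distances = list(o$junction_distances %||% integer(0)))
  })
  out <- rbindlist(rows)
  setkey(out, transcript_id)
  out
}

#' Stop-codon junction context
#'
#' Counts exon-exon junctions downstream of the termination codon, both in
#' total and beyond a distance threshold (default 55 nt, the canonical
#' EJC-escape distance; the threshold is a parameter because reported rules
#' vary between ~30 and ~55 nt).
#'
#' @param orf an `orf_annotation` with status `ok`.
#' @param threshold_nt distance threshold in nucleotides.
#' @return list with `junction_count_total`, `junction_count_beyond_threshold`,
#'   `stop_in_last_exon`.
#' @export
stop_context <- function(orf, threshold_nt = 55) {
  if (!identical(orf$status, "ok"))
    stopf("stop_context requires an ORF with status 'ok' (got '%s')", orf$status)
  d <- orf$junction_distances
  list(junction_count_total = length(d),
       junction_count_beyond_threshold = sum(d > threshold_nt),
       stop_in_last_exon = orf$stop_in_last_exon)
}
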