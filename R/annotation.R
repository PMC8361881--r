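#' @import data.table
#' @importFrom stats p.adjust ks.test rbinom rnorm rpois runif setNames t.test var
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

# ---------------------------------------------------------------------------
# Gene-model container
#
# A `nmd_annotation` wraps a data.table of exons in 0-based half-open genomic
# coordinates (GTF I/O converts at the boundary):
#   chrom, start, end, strand, transcript_id, gene_id, source ("reference"|"novel")
# ---------------------------------------------------------------------------

#' Construct a genome annotation from an exon table
#'
#' @param exons data.frame/data.table with columns `chrom`, `start`, `end`,
#'   `strand`, `transcript_id`, `gene_id` and optionally `source`. Coordinates
#'   are 0-based half-open.
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return an object of class `nmd_annotation`.
#' @export
annotation <- function(exons, chrom_lengths = NULL) {
  ex <- as.data.table(exons)
  req <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  miss <- setdiff(req, names(ex))
  if (length(miss)) stopf("exon table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"source" %in% names(ex)) ex[, source := "reference"]
  ex <- ex[, c(req, "source"), with = FALSE]
  if (nrow(ex)) {
    if (any(ex$start >= ex$end)) stopf("exon with start >= end")
    if (!all(ex$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
    bad <- ex[, .(n = uniqueN(paste(chrom, strand)), g = uniqueN(gene_id)),
              by = transcript_id][n > 1L | g > 1L]
    if (nrow(bad)) stopf("transcript '%s' mixes chromosomes, strands or genes",
                         bad$transcript_id[1])
    setorder(ex, chrom, transcript_id, start)
    ov <- ex[, .(ov = any(start[-1L] < end[-.N])), by = transcript_id][ov == TRUE]
    if (nrow(ov)) stopf("transcript '%s' has overlapping exons", ov$transcript_id[1])
  }
  structure(list(exons = ex, chrom_lengths = chrom_lengths),
            class = "nmd_annotation")
}

#' @export
print.nmd_annotation <- function(x, ...) {
  cat(sprintf("<nmd_annotation> %d transcripts / %d genes / %d exon records\n",
              uniqueN(x$exons$transcript_id), uniqueN(x$exons$gene_id),
              nrow(x$exons)))
  invisible(x)
}

#' Transcript ids of an annotation
#' @param ann an `nmd_annotation`.
#' @return character vector of transcript ids.
#' @export
transcript_ids <- function(ann) unique(ann$exons$transcript_id)

#' Extract one transcript as a structured object
#'
#' @param ann an `nmd_annotation`.
#' @param id transcript id.
#' @return list with `id`, `gene_id`, `chrom`, `strand`, `source`, and `exons`
#'   (data.table of `start`,`end` sorted by genomic coordinate).
#' @export
get_transcript <- function(ann, id) {
  ex <- ann$exons[transcript_id == id]
  if (!nrow(ex)) stopf("unknown transcript id '%s'", id)
  setorder(ex, start)
  list(id = id, gene_id = ex$gene_id[1], chrom = ex$chrom[1],
       strand = ex$strand[1], source = ex$source[1],
       exons = ex[, .(start, end)])
}

#' Spliced length of a transcript
#' @param tx transcript object from [get_transcript()].
#' @return integer total exonic length.
#' @export
transcript_length <- function(tx) sum(tx$exons$end - tx$exons$start)

# Per-transcript summary used by merge and pairing: span, exon count, chain key.
transcript_index <- function(ann) {
  ann$exons[, .(
    chrom = chrom[1], strand = strand[1], gene_id = gene_id[1],
    source = source[1],
    span_start = min(start), span_end = max(end), n_exons = .N,
    chain = {
      s <- sort(start); e <- sort(end)
      if (.N > 1L) paste(e[-.N], s[-1L], sep = "-", collapse = ";") else ""
    }
  ), by = transcript_id]
}

# Intron-chain identity key (chromosome + strand + ordered junction list).
chain_key <- function(idx) {
  ifelse(idx$n_exons > 1L,
         paste(idx$chrom, idx$strand, idx$chain, sep = "|"),
         NA_character_)
}

# ---------------------------------------------------------------------------
# GTF I/O (Ensembl attribute dialect). Internal 0-based half-open; GTF is
# 1-based closed, converted at this boundary only.
# ---------------------------------------------------------------------------

#' Read a GTF annotation
#'
#' Exon features are grouped per transcript and sorted by genomic coordinate;
#' GTF 1-based closed coordinates become 0-based half-open. Exon records
#' without a `transcript_id` attribute are dropped with a warning.
#'
#' @param path GTF file path.
#' @return an `nmd_annotation`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stopf("GTF parse error in %s: %s",
                                           path, conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  keep <- !is.na(md$type) & md$type == "exon"
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  if (!length(gr)) return(annotation(empty_exon_table()))
  txid <- as.character(md$transcript_id)
  no_tx <- is.na(txid) | txid == ""
  if (any(no_tx)) {
    warnf("%d exon record(s) without transcript_id dropped", sum(no_tx))
    gr <- gr[!no_tx]; md <- md[!no_tx, , drop = FALSE]; txid <- txid[!no_tx]
  }
  src <- if ("source" %in% names(md)) as.character(md$source) else "reference"
  src <- ifelse(src == "novel", "novel", "reference")
  ex <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = txid,
    gene_id = as.character(md$gene_id),
    source = src)
  annotation(ex)
}

empty_exon_table <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             strand = character(), transcript_id = character(),
             gene_id = character(), source = character())
}

#' Write an annotation as GTF
#'
#' Emits one exon feature per exon, 1-based closed coordinates, Ensembl-style
#' `gene_id`/`transcript_id` attributes, ordered by (chrom, start,
#' transcript id) so output is byte-deterministic.
#'
#' @param ann an `nmd_annotation`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gtf <- function(ann, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write GTF to %s: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines("#!genome-build synthetic", con)
  ex <- copy(ann$exons)
  if (nrow(ex)) {
    setorder(ex, chrom, start, transcript_id, end)
    lines <- sprintf(
      '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      ex$chrom, ex$source, ex$start + 1L, ex$end, ex$strand,
      ex$gene_id, ex$transcript_id)
    writeLines(lines, con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genome sequence access. A genome is either a Biostrings::DNAStringSet or a
# named character vector of chromosome sequences; all coordinates 0-based
# half-open.
# ---------------------------------------------------------------------------

#' Read a genome FASTA
#' @param path FASTA file path.
#' @return a named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

genome_subseq <- function(genome, chrom, start, end) {
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stopf("chromosome '%s' not in genome", chrom)
    chrlen <- Biostrings::width(genome[[chrom]])
    if (start < 0 || end > chrlen) stopf("interval [%d,%d) outside chromosome '%s'",
                                         start, end, chrom)
    return(as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end)))
  }
  if (!chrom %in% names(genome)) stopf("chromosome '%s' not in genome", chrom)
  chrlen <- nchar(genome[[chrom]], type = "bytes")   # O(1); sequences are ASCII
  if (start < 0 || end > chrlen) stopf("interval [%d,%d) outside chromosome '%s'",
                                       start, end, chrom)
  substring(genome[[chrom]], start + 1L, end)
}

#' Spliced transcript sequence
#'
#' Concatenates exonic genome sequence in 5'-to-3' transcript orientation;
#' minus-strand transcripts are reverse-complemented.
#'
#' @param tx transcript object from [get_transcript()].
#' @param genome genome from [read_genome()] (or a DNAStringSet).
#' @return nucleotide string.
#' @export
transcript_sequence <- function(tx, genome) {
  pieces <- vapply(seq_len(nrow(tx$exons)), function(i)
    genome_subseq(genome, tx$chrom, tx$exons$start[i], tx$exons$end[i]),
    character(1))
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") revcomp_chr(s) else s
}

# ---------------------------------------------------------------------------
# Coordinate mapping between genome and spliced transcript space.
# ---------------------------------------------------------------------------

#' Map a genomic position to a transcript offset
#'
#' @param tx transcript object.
#' @param genomic_pos 0-based genomic position.
#' @return 0-based offset along the spliced transcript (strand aware), or
#'   `NA_integer_` when the position is intronic or outside the transcript.
#' @export
genomic_to_transcript <- function(tx, genomic_pos) {
  ex <- tx$exons
  lens <- ex$end - ex$start
  hit <- which(genomic_pos >= ex$start & genomic_pos < ex$end)
  if (!length(hit)) return(NA_integer_)
  before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0L
  plus_off <- before + (genomic_pos - ex$start[hit])
  if (tx$strand == "+") as.integer(plus_off)
  else as.integer(sum(lens) - 1L - plus_off)
}

#' Map a transcript offset back to a genomic position
#'
#' Inverse of [genomic_to_transcript()] on exonic positions.
#'
#' @param tx transcript object.
#' @param offset 0-based transcript offset.
#' @return 0-based genomic position.
#' @export
transcript_to_genomic <- function(tx, offset) {
  ex <- tx$exons
  lens <- ex$end - ex$start
  total <- sum(lens)
  if (offset < 0 || offset >= total) stopf("offset %d outside transcript", offset)
  plus_off <- if (tx$strand == "+") offset else total - 1L - offset
  cum <- cumsum(lens)
  hit <- which(plus_off < cum)[1]
  before <- if (hit > 1L) cum[hit - 1L] else 0L
  as.integer(ex$start[hit] + (plus_off - before))
}

# Transcript-space offsets of the first base after each exon-exon junction,
# in transcript orientation (sorted ascending, one per intron).
junction_offsets <- function(tx) {
  lens <- tx$exons$end - tx$exons$start
  if (length(lens) < 2L) return(integer(0))
  if (tx$strand == "-") lens <- rev(lens)
  cumsum(lens)[-length(lens)]
}
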