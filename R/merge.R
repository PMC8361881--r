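# Intron-chain merge of a novel transcriptome into a reference annotation.

#' Merge novel transcript models into a reference annotation
#'
#' A novel multi-exon transcript is added if and only if its intron chain (the
#' exact ordered junction set on the same chromosome and strand) matches no
#' transcript already present; on a match it is collapsed into the existing
#' entry, extending terminal exons so the longer terminal ends are kept. A
#' single-exon novel transcript is added unless it is fully contained in an
#' existing exon of the gene locus it overlaps. Added transcripts keep
#' `source = "novel"` and inherit the gene id of the reference gene whose
#' exons they overlap most (by bases); with no overlap a new `"NOVG_"`-prefixed
#' gene id is minted. Novel transcript ids colliding with reference ids are
#' suffixed `".n1"`.
#'
#' @param reference,novel `nmd_annotation` objects sharing a chromosome
#'   namespace.
#' @return merged `nmd_annotation`; attribute `"merge_stats"` holds a
#'   data.table with counts of reference/collapsed/added transcripts.
#' @export
merge_transcriptomes <- function(reference, novel) {
  ref_ex <- copy(reference$exons)
  nov_ex <- copy(novel$exons)
  ref_chroms <- unique(c(ref_ex$chrom, names(reference$chrom_lengths)))
  bad_chr <- setdiff(unique(nov_ex$chrom), ref_chroms)
  if (length(bad_chr))
    stopf("novel annotation uses chromosome(s) absent from the reference namespace: %s",
          paste(bad_chr, collapse = ", "))

  merged <- copy(ref_ex)
  added <- list()                       # exon tables of accepted novel tx, by id
  n_collapsed <- 0L; n_added <- 0L; n_novel_gene <- 0L
  if (nrow(nov_ex)) {
    ref_idx <- transcript_index(reference)
    ref_keys <- chain_key(ref_idx)
    known_chains <- new.env(parent = emptyenv())
    for (i in which(!is.na(ref_keys)))
      assign(ref_keys[i], ref_idx$transcript_id[i], envir = known_chains)

    nov_idx <- transcript_index(novel)
    nov_keys <- chain_key(nov_idx)
    existing_ids <- new.env(parent = emptyenv())
    for (id in unique(ref_ex$transcript_id)) assign(id, TRUE, envir = existing_ids)
    nov_split <- split(novel$exons, by = "transcript_id", keep.by = FALSE)

    for (i in seq_len(nrow(nov_idx))) {
      nid <- nov_idx$transcript_id[i]
      nex <- nov_split[[nid]][order(start)]
      key <- nov_keys[i]
      if (!is.na(key) && exists(key, envir = known_chains)) {
        # Same intron chain: collapse, keep longer terminal ends.
        host_id <- get(key, envir = known_chains)
        if (!is.null(added[[host_id]])) {
          host <- added[[host_id]]
          host$start[1] <- min(host$start[1], nex$start[1])
          host$end[nrow(host)] <- max(host$end[nrow(host)], nex$end[nrow(nex)])
          added[[host_id]] <- host
        } else {
          host <- merged[transcript_id == host_id][order(start)]
          merged[transcript_id == host_id & start == host$start[1],
                 start := min(host$start[1], nex$start[1])]
          merged[transcript_id == host_id & end == host$end[nrow(host)],
                 end := max(host$end[nrow(host)], nex$end[nrow(nex)])]
        }
        n_collapsed <- n_collapsed + 1L
        next
      }
      ntx <- list(id = nid, gene_id = nov_idx$gene_id[i],
                  chrom = nov_idx$chrom[i], strand = nov_idx$strand[i],
                  exons = nex)
      gid <- assign_gene(ntx, ref_ex)
      if (is.na(gid)) {
        n_novel_gene <- n_novel_gene + 1L
        gid <- paste0("NOVG_", ntx$gene_id)
      }
      if (nrow(nex) == 1L) {
        # Single-exon model: skip if fully contained in an existing exon of
        # the same gene locus.
        contained <- merged[gene_id == gid & chrom == ntx$chrom &
                              start <= nex$start & end >= nex$end]
        if (nrow(contained)) { n_collapsed <- n_collapsed + 1L; next }
      }
      new_id <- nid
      while (exists(new_id, envir = existing_ids)) new_id <- paste0(new_id, ".n1")
      assign(new_id, TRUE, envir = existing_ids)
      added[[new_id]] <- data.table(chrom = ntx$chrom, start = nex$start,
                                    end = nex$end, strand = ntx$strand,
                                    transcript_id = new_id, gene_id = gid,
                                    source = "novel")
      if (!is.na(key)) assign(key, new_id, envir = known_chains)
      n_added <- n_added + 1L
    }
  }
  if (length(added)) merged <- rbind(merged, rbindlist(added))
  out <- annotation(merged, chrom_lengths = reference$chrom_lengths)
  attr(out, "merge_stats") <- data.table(
    reference_transcripts = uniqueN(ref_ex$transcript_id),
    novel_transcripts = uniqueN(nov_ex$transcript_id),
    collapsed = n_collapsed, added = n_added,
    novel_gene_ids = n_novel_gene,
    merged_transcripts = uniqueN(merged$transcript_id))
  out
}

# Gene id of the reference gene whose exons overlap the transcript most
# (bases of exonic overlap); NA when nothing overlaps.
assign_gene <- function(tx, ref_ex) {
  cand <- ref_ex[chrom == tx$chrom & strand == tx$strand &
                   start < max(tx$exons$end) & end > min(tx$exons$start)]
  if (!nrow(cand)) return(NA_character_)
  ov_by_gene <- cand[, {
    total <- 0L
    for (j in seq_len(nrow(tx$exons))) {
      o <- pmin(end, tx$exons$end[j]) - pmax(start, tx$exons$start[j])
      total <- total + sum(pmax(o, 0L))
    }
    .(ov = total)
  }, by = gene_id][ov > 0L]
  if (!nrow(ov_by_gene)) return(NA_character_)
  setorder(ov_by_gene, -ov, gene_id)
  ov_by_gene$gene_id[1]
}

#' Merge statistics of a merged annotation
#' @param merged result of [merge_transcriptomes()].
#' @return data.table of kept/collapsed/added counts.
#' @export
merge_stats <- function(merged) attr(merged, "merge_stats")

#' Fraction of exons that are novel after merging
#'
#' An exon counts as novel when its exact (chrom, start, end, strand) appears
#' in the merged annotation but not in the reference.
#'
#' @param merged,reference `nmd_annotation` objects.
#' @param exon_set data.table/data.frame of exons (`chrom`,`start`,`end`,`strand`).
#' @return fraction in \[0,1\].
#' @export
novel_exon_fraction <- function(merged, reference, exon_set) {
  es <- as.data.table(exon_set)
  if (!nrow(es)) stopf("exon_set is empty: novel fraction undefined")
  key_of <- function(dt) unique(paste(dt$chrom, dt$start, dt$end, dt$strand))
  in_merged <- key_of(merged$exons)
  in_ref <- key_of(reference$exons)
  keys <- paste(es$chrom, es$start, es$end, es$strand)
  mean(keys %in% setdiff(in_merged, in_ref))
}
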