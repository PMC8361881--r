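# Mapping selected events to transcripts and reducing each event to one
# (NMD-sensitive, NMD-insensitive) representative transcript pair.

#' Transcripts providing evidence for a skipped-exon event
#'
#' Candidate transcripts belong to the event's gene and their pre-mRNA span
#' (first exon start to last exon end) covers the target exon interval, so
#' intron-spanning isoforms count even when the exon is absent from their
#' mature form. The inclusion set contains candidates carrying the target
#' exon with both boundaries exact; the exclusion set contains candidates
#' carrying the direct upstream-flank-end to downstream-flank-start junction
#' (target exon skipped). Candidates matching neither are discarded.
#'
#' @param ann an `nmd_annotation`.
#' @param ev one event (list or one-row data.frame with `gene_id`, `chrom`,
#'   `target_start`, `target_end`, `up_end`, `down_start`).
#' @return list with character vectors `inclusion` and `exclusion`.
#' @export
transcripts_for_event <- function(ann, ev) {
  ev <- as.list(ev)
  gx <- ann$exons[gene_id == ev$gene_id & chrom == ev$chrom]
  if (!nrow(gx)) stopf("event gene '%s' absent from annotation", ev$gene_id)
  idx <- gx[, .(span_start = min(start), span_end = max(end)), by = transcript_id]
  cands <- idx[span_start <= ev$target_start & span_end >= ev$target_end,
               transcript_id]
  if (!length(cands)) return(list(inclusion = character(0), exclusion = character(0)))
  inc <- gx[transcript_id %in% cands & start == ev$target_start &
              end == ev$target_end, unique(transcript_id)]
  exc <- vapply(setdiff(cands, inc), function(id) {
    e <- gx[transcript_id == id][order(start)]
    any(e$end[-nrow(e)] == ev$up_end & e$start[-1L] == ev$down_start)
  }, logical(1))
  list(inclusion = sort(inc), exclusion = sort(names(exc)[exc]))
}

#' Assign NMD sensitivity labels from the event subclass
#'
#' For an inclusion-subclass event (PSI rises when NMD is repressed) the
#' exon-including transcripts are NMD-sensitive; for an exclusion-subclass
#' event the labels swap.
#'
#' @param decision one row of [select_nmd_events()] output (must be selected).
#' @param inclusion_set,exclusion_set transcript id vectors.
#' @return list with `sensitive` and `insensitive` id vectors.
#' @export
label_sensitivity <- function(decision, inclusion_set, exclusion_set) {
  decision <- as.list(decision)
  if (!isTRUE(decision$selected))
    stopf("label_sensitivity requires a selected event")
  if (identical(decision$subclass, "inclusion"))
    list(sensitive = inclusion_set, insensitive = exclusion_set)
  else
    list(sensitive = exclusion_set, insensitive = inclusion_set)
}

#' Read a transcript abundance table
#'
#' @param path TSV with a `transcript_id` column and one numeric column per
#'   sample (sample names encode condition and replicate, e.g. `CTR_1`).
#' @return data.table keyed by `transcript_id`.
#' @export
read_abundance <- function(path) {
  tb <- fread(path, sep = "\t")
  if (!"transcript_id" %in% names(tb))
    stopf("abundance table lacks a transcript_id column")
  setkey(tb, transcript_id)
  tb
}

#' Representative transcript of a set: highest mean abundance
#'
#' The mean is taken over the given samples (by convention the control and
#' knockdown samples); transcripts absent from the table count as abundance 0,
#' and ties resolve to the lexicographically smallest id.
#'
#' @param tx_set character vector of transcript ids (non-empty).
#' @param abundance table from [read_abundance()].
#' @param samples character vector of sample column names.
#' @return a single transcript id.
#' @export
select_representative <- function(tx_set, abundance, samples) {
  if (!length(tx_set)) stopf("select_representative: empty transcript set")
  samples <- intersect(samples, names(abundance))
  means <- vapply(tx_set, function(id) {
    row <- abundance[J(id), nomatch = NULL]
    if (!nrow(row) || !length(samples)) 0
    else mean(as.numeric(row[1, ..samples]))
  }, numeric(1))
  ord <- order(-means, tx_set)
  tx_set[ord[1]]
}

#' Build the non-redundant NMD-sensitive / insensitive transcript pairs
#'
#' For every selected event: find the inclusion and exclusion transcript sets,
#' drop transcripts without a projectable coding region (`status != "ok"`),
#' assign sensitivity labels from the subclass, and keep the most abundant
#' transcript on each side. Events losing a whole side are dropped and
#' counted by reason.
#'
#' @param decisions table from [select_nmd_events()].
#' @param events event definition table (see [read_events()]).
#' @param ann merged `nmd_annotation`.
#' @param orfs table from [project_orfs()].
#' @param abundance table from [read_abundance()].
#' @param samples sample columns used for the abundance mean (control +
#'   knockdown samples).
#' @return data.table with one row per retained event: `event_id`, `gene_id`,
#'   `subclass`, `sensitive_tx`, `insensitive_tx`, `sensitive_abundance`,
#'   `insensitive_abundance`; attribute `"drops"` tabulates dropped events by
#'   reason.
#' @export
build_pairs <- function(decisions, events, ann, orfs, abundance, samples) {
  dec <- as.data.table(decisions)[selected == TRUE]
  evs <- as.data.table(events)
  ok_tx <- orfs[status == "ok", transcript_id]
  samples <- intersect(samples, names(abundance))
  drops <- c(no_coding_sensitive = 0L, no_coding_insensitive = 0L,
             no_candidates = 0L)
  rows <- vector("list", nrow(dec))
  for (i in seq_len(nrow(dec))) {
    ev <- evs[event_id == dec$event_id[i]]
    if (!nrow(ev)) next
    sets <- transcripts_for_event(ann, ev[1])
    lab <- label_sensitivity(dec[i], sets$inclusion, sets$exclusion)
    if (!length(lab$sensitive) && !length(lab$insensitive)) {
      drops["no_candidates"] <- drops["no_candidates"] + 1L; next
    }
    sens <- intersect(lab$sensitive, ok_tx)
    insens <- intersect(lab$insensitive, ok_tx)
    if (!length(sens)) { drops["no_coding_sensitive"] <- drops["no_coding_sensitive"] + 1L; next }
    if (!length(insens)) { drops["no_coding_insensitive"] <- drops["no_coding_insensitive"] + 1L; next }
    s_id <- select_representative(sens, abundance, samples)
    i_id <- select_representative(insens, abundance, samples)
    mean_ab <- function(id) {
      row <- abundance[J(id), nomatch = NULL]
      if (!nrow(row) || !length(samples)) 0 else mean(as.numeric(row[1, ..samples]))
    }
    rows[[i]] <- data.table(event_id = dec$event_id[i],
                            gene_id = ev$gene_id[1],
                            subclass = dec$subclass[i],
                            sensitive_tx = s_id, insensitive_tx = i_id,
                            sensitive_abundance = mean_ab(s_id),
                            insensitive_abundance = mean_ab(i_id))
  }
  out <- rbindlist(rows)
  if (!nrow(out))
    out <- data.table(event_id = character(), gene_id = character(),
                      subclass = character(), sensitive_tx = character(),
                      insensitive_tx = character(),
                      sensitive_abundance = numeric(),
                      insensitive_abundance = numeric())
  attr(out, "drops") <- drops
  out
}
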