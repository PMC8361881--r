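# End-to-end orchestration: merge -> project -> select -> pair -> features,
# with a machine-readable run report.

#' Pipeline run configuration
#'
#' @param genome,reference,novel,principal_starts,junction_counts,events,abundance
#'   input file paths (see the corresponding readers). `novel`,
#'   `conservation` and `uorf_evidence` may be `NULL`; the affected stages
#'   degrade gracefully.
#' @param conservation optional bedGraph path.
#' @param uorf_evidence optional BED path (transcript-space intervals).
#' @param out_dir output directory.
#' @param fdr_cut,min_dpsi selection thresholds.
#' @param uorf_min_len minimum uORF length (nt, stop included).
#' @param junction_threshold_nt distance threshold for the stop-context
#'   column.
#' @param rescue condition label of the rescue arm.
#' @param ctr,kd condition labels of control and knockdown.
#' @param test_method `"moderated"` or `"welch"` (see [test_events()]).
#' @param seed seed for the control-exon sample.
#' @return list of class `run_config`.
#' @export
run_config <- function(genome, reference, novel = NULL, principal_starts,
                       junction_counts, events, abundance,
                       conservation = NULL, uorf_evidence = NULL,
                       out_dir = "nmdsense_out",
                       fdr_cut = 0.05, min_dpsi = 0.10, uorf_min_len = 15,
                       junction_threshold_nt = 55,
                       rescue = "RESC", ctr = "CTR", kd = "dKD",
                       test_method = "moderated", seed = 1) {
  cfg <- as.list(environment())
  if (fdr_cut <= 0 || fdr_cut > 1 || min_dpsi < 0 || min_dpsi > 1)
    stopf("thresholds out of range")
  for (nm in c("genome", "reference", "principal_starts", "junction_counts",
               "events", "abundance")) {
    if (!file.exists(cfg[[nm]])) stopf("input '%s' not found: %s", nm, cfg[[nm]])
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full NMD-isoform pipeline
#'
#' Stages: read inputs; merge novel transcripts into the reference; project
#' ORFs; test and select NMD-responding events; build sensitive/insensitive
#' pairs; compute 3'UTR, uORF, splice-score and conservation feature tables
#' and their K-S comparisons. Writes TSV tables plus a JSON report with
#' counts at every stage, and returns the report (with tables attached)
#' invisibly.
#'
#' @param config a [run_config()].
#' @return list with all stage outputs; written artifacts live in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  genome <- stage("read_genome", read_genome(config$genome))
  reference <- stage("read_reference", read_gtf(config$reference))
  merged <- if (!is.null(config$novel)) {
    novel <- stage("read_novel", read_gtf(config$novel))
    stage("merge", merge_transcriptomes(reference, novel))
  } else reference
  mstats <- merge_stats(merged) %||%
    data.table(reference_transcripts = uniqueN(reference$exons$transcript_id),
               novel_transcripts = 0L, collapsed = 0L, added = 0L,
               novel_gene_ids = 0L,
               merged_transcripts = uniqueN(reference$exons$transcript_id))
  fwrite(mstats, file.path(config$out_dir, "merge_stats.tsv"), sep = "\t")

  starts <- stage("principal_starts", load_principal_starts(config$principal_starts))
  orfs <- stage("project_orfs", project_orfs(merged, starts, genome))

  counts <- stage("junction_counts", read_junction_counts(config$junction_counts))
  results <- stage("test_events",
                   test_events(counts, ctr = config$ctr, kd = config$kd,
                               resc = config$rescue, method = config$test_method))
  decisions <- stage("select_events",
                     select_nmd_events(results, min_dpsi = config$min_dpsi,
                                       fdr_cut = config$fdr_cut))
  dec_out <- results[decisions, on = "event_id"]
  # alias columns in the familiar event-level tool naming
  dec_out[, `:=`(IncLevelDifference = dpsi_dkd, FDR = fdr_dkd)]
  fwrite(dec_out, file.path(config$out_dir, "event_decisions.tsv"), sep = "\t")

  events <- stage("read_events", read_events(config$events))
  abundance <- stage("read_abundance", read_abundance(config$abundance))
  samp_cols <- setdiff(names(abundance), "transcript_id")
  ctrkd <- samp_cols[grepl(paste0("^(", config$ctr, "|", config$kd, ")"), samp_cols)]
  pairs <- stage("build_pairs",
                 build_pairs(decisions, events, merged, orfs, abundance, ctrkd))
  fwrite(pairs, file.path(config$out_dir, "pairs.tsv"), sep = "\t")

  report <- list(
    thresholds = config[c("fdr_cut", "min_dpsi", "uorf_min_len",
                          "junction_threshold_nt", "rescue", "test_method")],
    seed = config$seed,
    counts = list(
      reference_transcripts = mstats$reference_transcripts,
      merged_transcripts = mstats$merged_transcripts,
      events_tested = nrow(results),
      events_selected = sum(decisions$selected),
      subclass_inclusion = sum(decisions$subclass == "inclusion"),
      subclass_exclusion = sum(decisions$subclass == "exclusion"),
      pairs = nrow(pairs),
      pair_drops = as.list(attr(pairs, "drops"))))

  features <- NULL
  if (nrow(pairs)) {
    features <- stage("utr3_features",
                      utr3_features(pairs, orfs,
                                    threshold_nt = config$junction_threshold_nt))
    fwrite(features, file.path(config$out_dir, "utr3_features.tsv"), sep = "\t")
    ks_jx <- if (all(table(features$group) >= 2))
      ks_compare(features[group == "sensitive", n_junctions_3utr],
                 features[group == "insensitive", n_junctions_3utr]) else NULL
    strat <- last_exon_stratified_lengths(features)
    ks_len <- if (all(strat$counts >= 2))
      ks_compare(strat$sensitive, strat$insensitive) else NULL

    # uORFs with translation evidence
    uorf_frac <- NULL
    uorfs_all <- stage("uorfs", {
      rows <- lapply(unique(c(pairs$sensitive_tx, pairs$insensitive_tx)), function(id) {
        o <- orfs[J(id)]
        tx <- get_transcript(merged, id)
        u <- find_uorfs(transcript_sequence(tx, genome), o$cds_start,
                        min_len = config$uorf_min_len)
        if (nrow(u)) u[, transcript_id := id]
        u
      })
      rbindlist(rows, fill = TRUE)
    })
    if (!is.null(config$uorf_evidence)) {
      evid <- stage("uorf_evidence", read_bed(config$uorf_evidence))
      uorfs_tr <- filter_translated_uorfs(uorfs_all, evid, space = "transcript")
      uorf_frac <- uorf_enrichment(features, unique(uorfs_tr$transcript_id))
      fwrite(uorf_frac, file.path(config$out_dir, "uorf_enrichment.tsv"), sep = "\t")
    } else message("no uORF evidence supplied; uORF enrichment skipped")

    splice <- stage("splice_features",
                    splice_feature_table(pairs, events, decisions, merged, orfs,
                                         genome, config))
    if (!is.null(splice)) {
      fwrite(splice$table, file.path(config$out_dir, "splice_features.tsv"),
             sep = "\t")
    }
    report$feature_summary <- list(
      junction_prevalence = features[, .(frac = mean(n_junctions_3utr > 0)),
                                     by = group],
      ks_junctions = ks_jx, ks_utr3_len_stratified = ks_len,
      uorf = uorf_frac)
    report$splice_summary <- splice$summary %||% NULL
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(c(report, list(results = results, decisions = decisions,
                           pairs = pairs, features = features, orfs = orfs,
                           merged = merged)))
}

# Splice-window scores and conservation for poised (target) exons of selected
# events vs sampled control exons. Degrades to NULL when no event target exon
# is internal to a sensitive transcript.
splice_feature_table <- function(pairs, events, decisions, ann, orfs, genome,
                                 config) {
  evs <- as.data.table(events)[event_id %in% pairs$event_id]
  if (!nrow(evs)) return(NULL)
  track <- if (!is.null(config$conservation) && file.exists(config$conservation))
    read_bedgraph(config$conservation) else NULL
  if (is.null(track)) message("no conservation track; conservation columns skipped")

  window_row <- function(tx, ex_start, ex_end, group, id) {
    w <- extract_splice_windows(tx, ex_start, ex_end, genome)
    if (is.null(w)) return(NULL)
    data.table(id = id, group = group,
               acceptor = w$acceptor, donor = w$donor,
               acc_start = w$acceptor_interval[1], acc_end = w$acceptor_interval[2],
               don_start = w$donor_interval[1], don_end = w$donor_interval[2],
               chrom = tx$chrom)
  }

  # NMD rows: the target exon within the transcript that contains it
  nmd_rows <- list()
  for (i in seq_len(nrow(evs))) {
    ev <- evs[i]
    pr <- pairs[event_id == ev$event_id][1]
    host_id <- for_both <- c(pr$sensitive_tx, pr$insensitive_tx)
    host <- NULL
    for (id in for_both) {
      tx <- get_transcript(ann, id)
      if (any(tx$exons$start == ev$target_start & tx$exons$end == ev$target_end)) {
        host <- tx; break
      }
    }
    if (is.null(host)) next
    nmd_rows[[i]] <- window_row(host, ev$target_start, ev$target_end, "NMD",
                                ev$event_id)
  }
  nmd <- rbindlist(nmd_rows)
  if (!nrow(nmd)) return(NULL)

  sens_tx <- unique(pairs$sensitive_tx)
  controls <- sample_control_exons(
    ann, orfs, n = nrow(nmd), seed = config$seed, exclude_tx = sens_tx,
    exclude_exons = evs[, .(chrom, start = target_start, end = target_end)])
  ctrl_rows <- lapply(seq_len(nrow(controls)), function(j) {
    tx <- get_transcript(ann, controls$transcript_id[j])
    window_row(tx, controls$start[j], controls$end[j], "control",
               controls$transcript_id[j])
  })
  tab <- rbind(nmd, rbindlist(ctrl_rows))

  # default splice model trained on the constitutive (non-target, non-NMD)
  # internal exon windows of the annotation
  train <- rbindlist(lapply(seq_len(nrow(controls)), function(j) {
    tx <- get_transcript(ann, controls$transcript_id[j])
    w <- extract_splice_windows(tx, controls$start[j], controls$end[j], genome)
    if (is.null(w)) return(NULL)
    data.table(acceptor = w$acceptor, donor = w$donor)
  }))
  model <- train_splice_model(train$acceptor, train$donor)
  tab[, acceptor_score := vapply(acceptor, score_splice_site, numeric(1),
                                 model = model, site = "acceptor")]
  tab[, donor_score := vapply(donor, score_splice_site, numeric(1),
                              model = model, site = "donor")]
  if (!is.null(track)) {
    tab[, acceptor_conservation := vapply(seq_len(.N), function(j)
      mean_conservation(chrom[j], acc_start[j], acc_end[j], track), numeric(1))]
    tab[, donor_conservation := vapply(seq_len(.N), function(j)
      mean_conservation(chrom[j], don_start[j], don_end[j], track), numeric(1))]
  }
  summary <- tab[, .(mean_acceptor_score = mean(acceptor_score),
                     mean_donor_score = mean(donor_score)), by = group]
  list(table = tab[, !c("acceptor", "donor")], summary = summary,
       model = model)
}
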