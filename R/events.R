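# PSI computation, replicate-aware differential splicing, and the
# dual-comparison directional filter defining NMD-responding events.

#' Percent spliced in from junction counts
#'
#' Length-normalized inclusion fraction `(I/LI) / ((I/LI) + (S/LS))`.
#' A replicate with `I = S = 0` carries no information and yields `NA`
#' (dropped from the event's test downstream).
#'
#' @param I,S inclusion / skipping junction read counts (non-negative).
#' @param LI,LS effective lengths of the inclusion / skipping forms (> 0).
#' @return PSI values in \[0,1\] (vectorized), `NA` where `I = S = 0`.
#' @export
compute_psi <- function(I, S, LI, LS) {
  if (any(I < 0 | S < 0)) stopf("junction counts must be non-negative")
  if (any(LI <= 0 | LS <= 0)) stopf("effective lengths must be positive")
  ni <- I / LI; ns <- S / LS
  out <- ni / (ni + ns)
  out[I == 0 & S == 0] <- NA_real_
  out
}

#' Per-event replicate test on logit-PSI (Welch)
#'
#' Two-sided Welch t-test on logit-transformed PSI with pseudocount
#' `eps = 0.01`. When both sides have zero variance the p-value is 1 for
#' equal means and 0 otherwise.
#'
#' @param psi_a,psi_b numeric replicate vectors (at least 2 defined values
#'   each).
#' @param eps pseudocount for the logit transform.
#' @return list with `dpsi = mean(psi_b) - mean(psi_a)` and `p`.
#' @export
test_event <- function(psi_a, psi_b, eps = 0.01) {
  psi_a <- psi_a[!is.na(psi_a)]; psi_b <- psi_b[!is.na(psi_b)]
  if (length(psi_a) < 2L || length(psi_b) < 2L)
    stopf("test_event needs >= 2 defined replicates per side")
  la <- logit_psi(psi_a, eps); lb <- logit_psi(psi_b, eps)
  if (var(la) == 0 && var(lb) == 0) {
    p <- if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
  } else {
    p <- t.test(la, lb, var.equal = FALSE)$p.value
  }
  list(dpsi = mean(psi_b) - mean(psi_a), p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p_values vector of p-values.
#' @return BH step-up q-values (empty input gives empty output).
#' @export
adjust_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Read a junction-count table
#'
#' @param path TSV with columns `event_id`, `condition`, `replicate`,
#'   `inclusion_count`, `skipping_count`, `inclusion_length`,
#'   `skipping_length`.
#' @return data.table of junction counts.
#' @export
read_junction_counts <- function(path) {
  tb <- fread(path, sep = "\t")
  req <- c("event_id", "condition", "replicate", "inclusion_count",
           "skipping_count", "inclusion_length", "skipping_length")
  miss <- setdiff(req, names(tb))
  if (length(miss)) stopf("junction-count table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tb
}

#' Differential-splicing test for all events across the knockdown design
#'
#' Computes per-replicate PSI, then tests each event in the two comparisons of
#' the design: knockdown vs control and rescue vs knockdown. The default
#' method is a limma moderated t-statistic on logit-PSI (replicate-aware, with
#' the per-event variance moderated across all events of the table);
#' `method = "welch"` runs the plain per-event Welch test instead. FDR is
#' adjusted within each comparison across all testable events.
#'
#' @param counts junction-count table (see [read_junction_counts()]).
#' @param ctr,kd,resc condition labels for control, knockdown and rescue;
#'   the rescue label is a parameter because designs may use different rescue
#'   arms.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param eps logit pseudocount.
#' @return data.table with per-event mean PSI per condition, `dpsi_dkd`
#'   (kd - ctr), `dpsi_resc` (resc - kd), `p_dkd`, `p_resc`, `fdr_dkd`,
#'   `fdr_resc`. Events with fewer than 2 defined replicates on any side are
#'   excluded with a warning.
#' @export
test_events <- function(counts, ctr = "CTR", kd = "dKD", resc = "RESC",
                        method = c("moderated", "welch"), eps = 0.01) {
  method <- match.arg(method)
  cnt <- as.data.table(counts)
  cnt <- cnt[condition %in% c(ctr, kd, resc)]
  if (!nrow(cnt)) stopf("no rows for conditions %s/%s/%s", ctr, kd, resc)
  cnt[, psi := compute_psi(inclusion_count, skipping_count,
                           inclusion_length, skipping_length)]

  wide <- dcast(cnt, event_id ~ condition + replicate, value.var = "psi")
  cond_of <- sub("_[^_]+$", "", names(wide)[-1])
  cols <- names(wide)[-1]
  mat <- as.matrix(wide[, ..cols])
  rownames(mat) <- wide$event_id

  n_ok <- function(cond) rowSums(!is.na(mat[, cond_of == cond, drop = FALSE]))
  testable <- n_ok(ctr) >= 2 & n_ok(kd) >= 2 & n_ok(resc) >= 2
  if (any(!testable))
    warnf("%d event(s) with < 2 defined replicates in a condition excluded",
          sum(!testable))
  mat <- mat[testable, , drop = FALSE]
  if (!nrow(mat)) stopf("no testable events")

  mean_cond <- function(cond) rowMeans(mat[, cond_of == cond, drop = FALSE],
                                       na.rm = TRUE)
  psi_ctr <- mean_cond(ctr); psi_kd <- mean_cond(kd); psi_resc <- mean_cond(resc)

  lmat <- logit_psi(mat, eps)
  pvals <- function(cond_a, cond_b) {
    sel <- cond_of %in% c(cond_a, cond_b)
    sub <- lmat[, sel, drop = FALSE]
    if (method == "moderated") {
      design <- cbind(Intercept = 1,
                      b = as.integer(cond_of[sel] == cond_b))
      fit <- limma::eBayes(limma::lmFit(sub, design))
      fit$p.value[, "b"]
    } else {
      psub <- mat[, sel, drop = FALSE]
      grp <- cond_of[sel]
      apply_res <- vapply(seq_len(nrow(psub)), function(i)
        test_event(psub[i, grp == cond_a], psub[i, grp == cond_b], eps)$p,
        numeric(1))
      apply_res
    }
  }
  p_dkd <- pvals(ctr, kd)
  p_resc <- pvals(kd, resc)

  out <- data.table(event_id = rownames(mat),
                    psi_ctr = psi_ctr, psi_dkd = psi_kd, psi_resc = psi_resc,
                    dpsi_dkd = psi_kd - psi_ctr,
                    dpsi_resc = psi_resc - psi_kd,
                    p_dkd = as.numeric(p_dkd), p_resc = as.numeric(p_resc))
  out[, fdr_dkd := adjust_fdr(p_dkd)]
  out[, fdr_resc := adjust_fdr(p_resc)]
  out[]
}

#' Select NMD-responding events
#'
#' An event is selected when both comparisons pass the FDR cut, the knockdown
#' shift is at least `min_dpsi` in absolute value, and the rescue shift has
#' the opposite sign (the directional reversal that distinguishes genuine NMD
#' responses from drift). Selected events split into an `inclusion` subclass
#' (PSI rises when NMD is repressed) and an `exclusion` subclass (PSI falls).
#'
#' @param results table from [test_events()].
#' @param min_dpsi minimum |dPSI| in the knockdown comparison (default 0.10).
#' @param fdr_cut FDR threshold applied to both comparisons (default 0.05).
#' @return data.table with `event_id`, `selected`, `subclass`
#'   (`inclusion`/`exclusion`/`none`).
#' @export
select_nmd_events <- function(results, min_dpsi = 0.10, fdr_cut = 0.05) {
  res <- as.data.table(results)
  req <- c("event_id", "dpsi_dkd", "dpsi_resc", "fdr_dkd", "fdr_resc")
  miss <- setdiff(req, names(res))
  if (length(miss)) stopf("results table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  incomplete <- !stats::complete.cases(res[, ..req])
  if (any(incomplete)) {
    warnf("%d event(s) with a missing comparison skipped", sum(incomplete))
    res <- res[!incomplete]
  }
  sel <- res$fdr_dkd < fdr_cut & res$fdr_resc < fdr_cut &
    abs(res$dpsi_dkd) >= min_dpsi & res$dpsi_dkd != 0 &
    sign(res$dpsi_resc) == -sign(res$dpsi_dkd)
  data.table(event_id = res$event_id,
             selected = sel,
             subclass = fifelse(!sel, "none",
                                fifelse(res$dpsi_dkd > 0, "inclusion", "exclusion")))
}

#' Read a skipped-exon event definition table
#'
#' @param path TSV with columns `event_id`, `gene_id`, `chrom`, `strand`,
#'   `target_start`, `target_end`, `up_end`, `down_start` (0-based half-open;
#'   `up_end`/`down_start` bound the flanking exons in plus-strand genomic
#'   order).
#' @return data.table of events.
#' @export
read_events <- function(path) {
  tb <- fread(path, sep = "\t")
  req <- c("event_id", "gene_id", "chrom", "strand", "target_start",
           "target_end", "up_end", "down_start")
  miss <- setdiff(req, names(tb))
  if (length(miss)) stopf("event table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- tb[!(up_end <= target_start & target_start < target_end &
                target_end <= down_start)]
  if (nrow(bad)) stopf("event '%s' violates flank ordering", bad$event_id[1])
  tb
}
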