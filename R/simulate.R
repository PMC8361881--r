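# Synthetic-data generator with planted ground truth.
#
# Emits a download-free bundle emulating the study design: a genome, a
# reference annotation plus "novel" (long-read-style) isoforms carrying poised
# exons, a principal-start table, junction counts under a CTR/dKD/RESC design,
# transcript abundances, a conservation track and uORF translation evidence.
#
# Construction invariant: exon bodies are drawn from a T-free alphabet
# ({A,C,G}), so the only start codons, stop codons and uORFs a transcript can
# contain are the planted ones. Intronic sequence (and splice windows) uses
# the full alphabet.

BASES4 <- c("A", "C", "G", "T")
BASES3 <- c("A", "C", "G")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: a double-knockdown that
#' raises inclusion of poised exons by `delta_psi` with full reversal under
#' rescue, three replicates per condition, binomial junction counts at mean
#' coverage 50, 80%/30% prevalence of a 3'UTR junction in sensitive /
#' insensitive isoforms, 35%/25% uORF prevalence, and an 80% share of weak
#' (degenerate) splice sites among poised exons.
#'
#' @param n_genes number of genes (one skipped-exon event each).
#' @param frac_nmd fraction of genes with a planted poised exon.
#' @param frac_inclusion subclass share of inclusion-type events among planted
#'   events.
#' @param delta_psi PSI shift of true events in the knockdown.
#' @param rescue_revert_frac fraction of the shift reverted under rescue.
#' @param n_replicates replicates per condition.
#' @param mean_coverage mean junction read depth per replicate.
#' @param p_junction_sensitive probability that a sensitive isoform's PTC has
#'   at least one exon junction downstream (else the PTC lands in the last
#'   exon).
#' @param p_junction_insensitive probability that the insensitive isoform's
#'   stop codon is followed by a 3'UTR junction.
#' @param p_uorf_sensitive,p_uorf_insensitive probability of one planted,
#'   translated uORF in the sensitive / insensitive isoform's 5'UTR.
#' @param weak_site_fraction fraction of poised exons with degenerate splice
#'   windows (the remainder get consensus windows, like control exons).
#' @param utr3_range 3'UTR length law (uniform over this range, in nt), shared
#'   by both groups so that stratified length comparisons are null by design.
#' @param seed integer seed; the emitted bundle is byte-deterministic given
#'   the configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, frac_nmd = 0.1, frac_inclusion = 0.6,
                       delta_psi = 0.3, rescue_revert_frac = 1.0,
                       n_replicates = 3, mean_coverage = 50,
                       p_junction_sensitive = 0.8,
                       p_junction_insensitive = 0.3,
                       p_uorf_sensitive = 0.35, p_uorf_insensitive = 0.25,
                       weak_site_fraction = 0.8,
                       utr3_range = c(150, 400), seed = 1) {
  cfg <- as.list(environment())
  probs <- c(frac_nmd, frac_inclusion, p_junction_sensitive,
             p_junction_insensitive, p_uorf_sensitive, p_uorf_insensitive,
             weak_site_fraction)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
  if (n_genes < 1 || n_replicates < 2 || mean_coverage <= 0 ||
      delta_psi <= 0 || delta_psi >= 1)
    stopf("invalid sim_config sizes")
  class(cfg) <- "sim_config"
  cfg
}

# --- splice-window weight matrices -----------------------------------------
# Exonic positions are supported on {A,C,G} (the T-free exon alphabet);
# intronic positions use the full alphabet with canonical GT/AG dinucleotides.

consensus_pwms <- function() {
  strong <- function(base, support = BASES4, p = 0.9) {
    v <- setNames(rep(0, 4), BASES4)
    minor <- setdiff(support, base)
    v[minor] <- (1 - p) / length(minor)
    v[base] <- p
    v
  }
  acc_cons <- c("C", "T", "C", "T", "T", "C", "T", "T", "C", "T",
                "T", "C", "T", "T", "T", "C", "T", "C", "A", "G",   # intron, AG
                "G", "C", "A")                                      # exon
  don_cons <- c("C", "A", "G",                                      # exon
                "G", "T", "A", "A", "G", "T")                       # intron
  acc <- vapply(seq_along(acc_cons), function(j)
    strong(acc_cons[j], if (j > 20) BASES3 else BASES4,
           p = if (j %in% c(19, 20)) 0.995 else 0.9), numeric(4))
  don <- vapply(seq_along(don_cons), function(j)
    strong(don_cons[j], if (j <= 3) BASES3 else BASES4,
           p = if (j %in% c(4, 5)) 0.995 else 0.9), numeric(4))
  list(acceptor = acc, donor = don)
}

degenerate_pwms <- function() {
  acc <- matrix(0.25, 4, 23, dimnames = list(BASES4, NULL))
  don <- matrix(0.25, 4, 9, dimnames = list(BASES4, NULL))
  acc[, 21:23] <- c(1, 1, 1, 0) / 3     # exonic positions stay T-free
  don[, 1:3] <- c(1, 1, 1, 0) / 3
  list(acceptor = acc, donor = don)
}

# n window sequences from a probability PWM, as an n x width character matrix.
sample_pwm <- function(pwm, n) {
  w <- ncol(pwm)
  m <- matrix("", n, w)
  for (j in seq_len(w)) m[, j] <- sample(BASES4, n, TRUE, prob = pwm[, j])
  m
}

# --- per-gene planning ------------------------------------------------------

# Lay out one gene in local plus-orientation coordinates: exon intervals,
# intron gaps, start codon, canonical stop and optional plants. Returns a
# plan list consumed by the assembler.
plan_gene <- function(cfg, is_nmd, subclass) {
  u1_len <- sample(90:140, 1); u2_len <- sample(90:140, 1)
  utr5_extra <- sample(20:40, 1)
  es_cds <- 3L * sample(21:40, 1)
  ea_len <- 3L * sample(30:50, 1)
  t_base <- 3L * sample(30:50, 1)
  eb_len <- 3L * sample(30:50, 1)
  el_cds_tail <- 3L * sample(10:20, 1)
  gaps <- c(gA = sample(40:80, 1), gB = sample(60:120, 1),
            g1 = sample(80:200, 1), g2 = sample(80:200, 1),
            g3 = sample(80:200, 1), g4 = sample(80:200, 1))
  draw_u3 <- function() as.integer(round(runif(1, cfg$utr3_range[1], cfg$utr3_range[2])))
  plan <- list(is_nmd = is_nmd, subclass = subclass,
               u1_len = u1_len, u2_len = u2_len, utr5_extra = utr5_extra,
               es_cds = es_cds, ea_len = ea_len, t_base = t_base,
               t_shift = 0L, eb_len = eb_len, el_cds_tail = el_cds_tail,
               gaps = gaps, u3_ins = draw_u3(), u3_sens = draw_u3(),
               variant_junction = TRUE, ins_jx = FALSE,
               uorf1 = FALSE, uorf2 = FALSE,
               site_class = "consensus")
  plan
}

# Plant the poised exon and its premature termination codon into a gene plan.
#
# For an inclusion-subclass event the exon-including isoform carries the PTC;
# with `variant_junction` the stop sits inside the poised exon itself (>= 1
# junction downstream guaranteed), otherwise exon inclusion shifts the frame
# and the resulting stop is planted in the last exon (no downstream
# junction). Exclusion-subclass events mirror this for the exon-skipping
# isoform. The generator verifies every plant through project_orf() before a
# bundle is written.
plant_poised_exon <- function(plan, subclass = c("inclusion", "exclusion"),
                              variant_junction = TRUE) {
  subclass <- match.arg(subclass)
  plan$is_nmd <- TRUE
  plan$subclass <- subclass
  plan$variant_junction <- variant_junction
  needs_shift <- (subclass == "exclusion") ||
    (subclass == "inclusion" && !variant_junction)
  plan$t_shift <- if (needs_shift) sample(1:2, 1) else 0L
  plan
}

# Resolve all plant offsets of a plan; returns the plan augmented with
# absolute local coordinates and plant positions, or retries u3 draws when
# two last-exon plants collide.
resolve_plan <- function(plan, cfg) {
  t_len <- plan$t_base + plan$t_shift
  g <- plan$gaps
  flank <- 50L
  # a last-exon PTC needs its own stop position well clear of the canonical
  # one; keep the two 3'UTR draws >= 12 nt apart so frame alignment can never
  # collide them
  if (plan$is_nmd && !plan$variant_junction) {
    for (try in 1:100) {
      if (abs(plan$u3_sens - plan$u3_ins) >= 12L) break
      plan$u3_sens <- as.integer(round(runif(1, cfg$utr3_range[1],
                                             cfg$utr3_range[2])))
      if (try == 100) stopf("could not separate 3'UTR length draws")
    }
  }
  u1_s <- flank; u1_e <- u1_s + plan$u1_len
  u2_s <- u1_e + g[["gA"]]; u2_e <- u2_s + plan$u2_len
  es_s <- u2_e + g[["gB"]]; es_e <- es_s + plan$utr5_extra + plan$es_cds
  ea_s <- es_e + g[["g1"]]; ea_e <- ea_s + plan$ea_len
  t_s <- ea_e + g[["g2"]]; t_e <- t_s + t_len
  eb_s <- t_e + g[["g3"]]; eb_e <- eb_s + plan$eb_len

  u3_max <- max(plan$u3_ins, plan$u3_sens)
  el_len <- plan$el_cds_tail + 3L + u3_max
  el_s <- eb_e + g[["g4"]]; el_e <- el_s + el_len
  L <- el_e + flank

  align_down <- function(o, fr) o - ((o - fr) %% 3L)
  # CDS consumed before each downstream exon, per isoform path
  c_after_ea <- plan$es_cds + plan$ea_len                # multiple of 3
  inc1 <- plan$subclass != "exclusion"                   # iso1 includes T
  c_eb_iso1 <- c_after_ea + if (inc1) t_len else 0L
  c_eb_iso2 <- c_after_ea + if (!inc1) t_len else 0L
  c_el_iso1 <- c_eb_iso1 + plan$eb_len
  c_el_iso2 <- c_eb_iso2 + plan$eb_len
  fr_el_iso1 <- (3L - (c_el_iso1 %% 3L)) %% 3L
  fr_el_iso2 <- (3L - (c_el_iso2 %% 3L)) %% 3L
  fr_eb_iso2 <- (3L - (c_eb_iso2 %% 3L)) %% 3L

  plants <- list()  # list of (exon, offset, motif)
  # insensitive (iso2) canonical stop
  if (plan$ins_jx) {
    tail_nt <- sample(15:40, 1)
    o2 <- align_down(plan$eb_len - 3L - tail_nt, fr_eb_iso2)
    plan$ins_stop <- list(exon = "eb", offset = o2)
  } else {
    o2 <- align_down(el_len - 3L - plan$u3_ins, fr_el_iso2)
    plan$ins_stop <- list(exon = "el", offset = o2)
  }
  # sensitive (iso1) premature stop for planted genes; canonical stop for nulls
  if (!plan$is_nmd) {
    # null gene: iso1 shares iso2's stop (same frame: t_shift = 0)
    plan$sens_stop <- plan$ins_stop
  } else if (plan$subclass == "inclusion" && plan$variant_junction) {
    o1 <- align_down(floor(t_len / 2), 0L)
    plan$sens_stop <- list(exon = "t", offset = o1)
  } else if (plan$subclass == "exclusion" && plan$variant_junction) {
    plan$sens_stop <- list(exon = "eb", offset = 18L)  # frame 0; iso2 frame differs
  } else {
    # stop-in-last-exon variants: plant in El in iso1's frame
    for (try in 1:60) {
      o1 <- align_down(el_len - 3L - plan$u3_sens, fr_el_iso1)
      ok <- !(identical(plan$ins_stop$exon, "el") &&
                abs(o1 - plan$ins_stop$offset) < 6L)
      if (ok && o1 >= 6L) break
      plan$u3_sens <- as.integer(round(runif(1, cfg$utr3_range[1],
                                             min(cfg$utr3_range[2], u3_max))))
      if (try == 60) stopf("could not place last-exon PTC without collision")
    }
    plan$sens_stop <- list(exon = "el", offset = o1)
  }

  # uORF plants (one per alternative first exon, when drawn)
  place_uorf <- function(ulen) {
    len <- 3L * sample(3:8, 1) + 6L      # 15..30 nt including the stop
    off <- sample(5:(ulen - len - 5L), 1)
    list(offset = off, length = len)
  }
  if (plan$uorf1) plan$uorf1_pos <- place_uorf(plan$u1_len)
  if (plan$uorf2) plan$uorf2_pos <- place_uorf(plan$u2_len)

  plan$coords <- list(u1 = c(u1_s, u1_e), u2 = c(u2_s, u2_e),
                      es = c(es_s, es_e), ea = c(ea_s, ea_e),
                      t = c(t_s, t_e), eb = c(eb_s, eb_e),
                      el = c(el_s, el_e))
  plan$t_len <- t_len; plan$el_len <- el_len; plan$L <- L
  plan$atg_local <- es_s + plan$utr5_extra
  plan
}

# Assemble the local plus-orientation sequence of one resolved plan.
# `win` supplies pre-sampled window sequences (list of character matrices and
# cursors managed by the caller).
assemble_gene_sequence <- function(plan) {
  L <- plan$L
  seq <- sample(BASES4, L, TRUE)
  cc <- plan$coords
  for (nm in names(cc)) {
    iv <- cc[[nm]]
    seq[(iv[1] + 1L):iv[2]] <- sample(BASES3, iv[2] - iv[1], TRUE)
  }
  seq
}

# Write a motif (character vector) at local 0-based position pos.
put_motif <- function(seq, pos, motif) {
  seq[(pos + 1L):(pos + length(motif))] <- motif
  seq
}

#' Generate a synthetic dataset bundle with planted truth
#'
#' Writes `genome.fa`, `reference.gtf`, `novel.gtf`, `principal_starts.tsv`,
#' `junction_counts.tsv`, `events.tsv`, `abundance.tsv`,
#' `conservation.bedGraph`, `uorf_evidence.bed` and `truth.json` into
#' `out_dir`. Junction counts are sampled per replicate as
#' `I ~ Binomial(depth, psi * LI / (psi * LI + (1 - psi) * LS))`,
#' `S = depth - I` with `depth ~ Poisson(mean_coverage)`; PSI rises by
#' `delta_psi` in the knockdown for true events and reverts under rescue.
#' Every planted poised exon is verified through [project_orf()] before the
#' bundle is written.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return list with `dir`, named `paths`, the `truth` tables and the
#'   in-memory `genome`, `reference`, `novel` annotation objects.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, generate_dataset_impl(config, out_dir))
}

generate_dataset_impl <- function(cfg, out_dir) {
  n <- cfg$n_genes
  n_nmd <- round(n * cfg$frac_nmd)
  gene_ids <- sprintf("G%05d", seq_len(n))
  strands <- sample(c("+", "-"), n, TRUE)
  is_nmd <- seq_len(n) <= n_nmd
  subclass <- ifelse(is_nmd,
                     ifelse(runif(n) < cfg$frac_inclusion, "inclusion", "exclusion"),
                     "none")

  # per-gene plans
  plans <- vector("list", n)
  for (i in seq_len(n)) {
    p <- plan_gene(cfg, is_nmd[i], subclass[i])
    if (is_nmd[i])
      p <- plant_poised_exon(p, subclass[i],
                             variant_junction = runif(1) < cfg$p_junction_sensitive)
    p$ins_jx <- runif(1) < cfg$p_junction_insensitive
    p$uorf1 <- runif(1) < (if (is_nmd[i]) cfg$p_uorf_sensitive else cfg$p_uorf_insensitive)
    p$uorf2 <- runif(1) < cfg$p_uorf_insensitive
    p$site_class <- if (is_nmd[i] && runif(1) < cfg$weak_site_fraction)
      "degenerate" else "consensus"
    plans[[i]] <- resolve_plan(p, cfg)
  }

  # batch-sample splice windows: 5 acceptors + 6 donors per gene; the poised
  # exon's pair takes the gene's site class, everything else is consensus
  cons <- consensus_pwms(); degen <- degenerate_pwms()
  n_degen <- sum(vapply(plans, function(p) p$site_class == "degenerate", logical(1)))
  acc_cons <- sample_pwm(cons$acceptor, 5L * n)
  don_cons <- sample_pwm(cons$donor, 6L * n)
  acc_deg <- if (n_degen) sample_pwm(degen$acceptor, n_degen) else NULL
  don_deg <- if (n_degen) sample_pwm(degen$donor, n_degen) else NULL
  ic <- 0L; id_ <- 0L; ig <- 0L   # cursors: consensus acc, consensus don, degenerate

  gene_seqs <- vector("list", n)
  offsets <- integer(n)
  cursor <- 0L
  spacer <- 120L
  chrom <- "chrS1"

  # plain-vector accumulators (tables are built once after the loop)
  ex_acc <- list(start = vector("list", n), end = vector("list", n),
                 tx = vector("list", n), src = vector("list", n),
                 strand = vector("list", n), gene = vector("list", n))
  ev_field <- function(mode) vector(mode, n)
  ev <- list(target_start = ev_field("integer"), target_end = ev_field("integer"),
             up_end = ev_field("integer"), down_start = ev_field("integer"),
             atg = ev_field("integer"),
             acc_s = ev_field("integer"), acc_e = ev_field("integer"),
             don_s = ev_field("integer"), don_e = ev_field("integer"),
             site_class = ev_field("character"))
  tx_jx1 <- integer(n); tx_jx2 <- integer(n)
  win_s <- vector("list", n); win_e <- vector("list", n); win_cl <- vector("list", n)
  uorf_acc <- list(chrom = vector("list", n), start = vector("list", n),
                   end = vector("list", n))
  verify_tx <- vector("list", n)

  for (i in seq_len(n)) {
    p <- plans[[i]]
    seqv <- assemble_gene_sequence(p)
    cc <- p$coords

    # splice windows: acceptors at es, ea, t, eb, el; donors at u1, u2, es, ea, t, eb
    acc_at <- c("es", "ea", "t", "eb", "el")
    don_at <- c("u1", "u2", "es", "ea", "t", "eb")
    win_iv <- list()
    for (nm in acc_at) {
      s <- cc[[nm]][1]
      use_deg <- nm == "t" && p$site_class == "degenerate"
      if (use_deg) { w <- acc_deg[ig + 1L, ] } else { ic <- ic + 1L; w <- acc_cons[ic, ] }
      seqv <- put_motif(seqv, s - 20L, w)
      win_iv[[paste0("acc_", nm)]] <- c(s - 20L, s + 3L)
    }
    for (nm in don_at) {
      e <- cc[[nm]][2]
      use_deg <- nm == "t" && p$site_class == "degenerate"
      if (use_deg) { w <- don_deg[ig + 1L, ] } else { id_ <- id_ + 1L; w <- don_cons[id_, ] }
      seqv <- put_motif(seqv, e - 3L, w)
      win_iv[[paste0("don_", nm)]] <- c(e - 3L, e + 6L)
    }
    if (p$site_class == "degenerate") ig <- ig + 1L

    # plants: start codon, stops, uORFs
    seqv <- put_motif(seqv, p$atg_local, c("A", "T", "G"))
    stop_at <- function(sp) cc[[sp$exon]][1] + sp$offset
    seqv <- put_motif(seqv, stop_at(p$ins_stop), c("T", "A", "A"))
    if (!identical(p$sens_stop, p$ins_stop))
      seqv <- put_motif(seqv, stop_at(p$sens_stop), c("T", "A", "A"))
    if (p$uorf1) {
      u <- p$uorf1_pos
      seqv <- put_motif(seqv, cc$u1[1] + u$offset, c("A", "T", "G"))
      seqv <- put_motif(seqv, cc$u1[1] + u$offset + u$length - 3L, c("T", "A", "A"))
    }
    if (p$uorf2) {
      u <- p$uorf2_pos
      seqv <- put_motif(seqv, cc$u2[1] + u$offset, c("A", "T", "G"))
      seqv <- put_motif(seqv, cc$u2[1] + u$offset + u$length - 3L, c("T", "A", "A"))
    }

    # strand flip
    strand <- strands[i]
    L <- p$L
    flip <- function(iv) c(L - iv[2], L - iv[1])
    if (strand == "-") {
      seqv <- rev(unname(COMP[seqv]))
      cc_g <- lapply(cc, flip)
      win_iv <- lapply(win_iv, flip)
      atg_g <- L - 1L - p$atg_local
    } else {
      cc_g <- cc
      atg_g <- p$atg_local
    }
    off <- cursor
    offsets[i] <- off
    cursor <- cursor + L + spacer
    gene_seqs[[i]] <- seqv

    gid <- gene_ids[i]
    tx1 <- paste0(gid, ".T1"); tx2 <- paste0(gid, ".T2")
    inc1 <- p$subclass != "exclusion"
    iso_names <- function(include_t, first)
      c(first, "es", "ea", if (include_t) "t", "eb", "el")
    nm1 <- iso_names(inc1, "u1"); nm2 <- iso_names(!inc1, "u2")
    s1 <- vapply(cc_g[nm1], `[`, numeric(1), 1) + off
    e1 <- vapply(cc_g[nm1], `[`, numeric(1), 2) + off
    s2 <- vapply(cc_g[nm2], `[`, numeric(1), 1) + off
    e2 <- vapply(cc_g[nm2], `[`, numeric(1), 2) + off
    src1 <- if (p$is_nmd) "novel" else "reference"
    ex_acc$start[[i]] <- as.integer(c(s1, s2))
    ex_acc$end[[i]] <- as.integer(c(e1, e2))
    ex_acc$tx[[i]] <- c(rep(tx1, length(s1)), rep(tx2, length(s2)))
    ex_acc$src[[i]] <- c(rep(src1, length(s1)), rep("reference", length(s2)))
    ex_acc$strand[[i]] <- rep(strand, length(s1) + length(s2))
    ex_acc$gene[[i]] <- rep(gid, length(s1) + length(s2))
    if (p$is_nmd)
      verify_tx[[i]] <- list(
        list(id = tx1, gene_id = gid, chrom = chrom, strand = strand,
             exons = data.table(start = as.integer(sort(s1)),
                                end = as.integer(sort(e1)))),
        list(id = tx2, gene_id = gid, chrom = chrom, strand = strand,
             exons = data.table(start = as.integer(sort(s2)),
                                end = as.integer(sort(e2)))))

    # event definition in plus-strand genomic order
    t_iv <- cc_g$t
    left <- if (strand == "+") cc_g$ea else cc_g$eb
    right <- if (strand == "+") cc_g$eb else cc_g$ea
    ev$target_start[i] <- t_iv[1] + off; ev$target_end[i] <- t_iv[2] + off
    ev$up_end[i] <- left[2] + off; ev$down_start[i] <- right[1] + off
    ev$atg[i] <- atg_g + off
    ev$site_class[i] <- if (p$is_nmd) p$site_class else "consensus"
    ev$acc_s[i] <- win_iv$acc_t[1] + off; ev$acc_e[i] <- win_iv$acc_t[2] + off
    ev$don_s[i] <- win_iv$don_t[1] + off; ev$don_e[i] <- win_iv$don_t[2] + off

    # expected per-transcript features (iso1 first)
    tx_jx1[i] <- if (!p$is_nmd) {
      if (p$ins_jx) 1L else 0L
    } else if (p$subclass == "inclusion" && p$variant_junction) 2L
    else if (p$subclass == "exclusion" && p$variant_junction) 1L
    else 0L
    tx_jx2[i] <- if (p$ins_jx) 1L else 0L

    if (p$uorf1 || p$uorf2) {
      uorf_acc$chrom[[i]] <- c(if (p$uorf1) tx1, if (p$uorf2) tx2)
      uorf_acc$start[[i]] <- c(if (p$uorf1) p$uorf1_pos$offset,
                               if (p$uorf2) p$uorf2_pos$offset)
      uorf_acc$end[[i]] <- c(
        if (p$uorf1) p$uorf1_pos$offset + p$uorf1_pos$length,
        if (p$uorf2) p$uorf2_pos$offset + p$uorf2_pos$length)
    }

    # conservation windows: consensus elevated, degenerate at baseline
    wn <- names(win_iv)
    win_s[[i]] <- vapply(win_iv, `[`, numeric(1), 1) + off
    win_e[[i]] <- vapply(win_iv, `[`, numeric(1), 2) + off
    win_cl[[i]] <- ifelse(grepl("_t$", wn) & p$site_class == "degenerate",
                          "degenerate", "consensus")
  }

  exons <- data.table(chrom = chrom,
                      start = unlist(ex_acc$start), end = unlist(ex_acc$end),
                      strand = unlist(ex_acc$strand),
                      transcript_id = unlist(ex_acc$tx),
                      gene_id = unlist(ex_acc$gene),
                      source = unlist(ex_acc$src))
  tx1_ids <- paste0(gene_ids, ".T1"); tx2_ids <- paste0(gene_ids, ".T2")
  events <- data.table(
    event_id = sprintf("EV%05d", seq_len(n)), gene_id = gene_ids,
    chrom = chrom, strand = strands,
    target_start = ev$target_start, target_end = ev$target_end,
    up_end = ev$up_end, down_start = ev$down_start,
    is_nmd = is_nmd, subclass = subclass, atg_pos = ev$atg,
    site_class = ev$site_class,
    acc_start = ev$acc_s, acc_end = ev$acc_e,
    don_start = ev$don_s, don_end = ev$don_e)
  tx_truth <- data.table(
    transcript_id = as.vector(rbind(tx1_ids, tx2_ids)),
    gene_id = rep(gene_ids, each = 2L),
    role = as.vector(rbind(ifelse(is_nmd, "sensitive", "null_inc"),
                           ifelse(is_nmd, "insensitive", "null_exc"))),
    planted_junctions_3utr = as.vector(rbind(tx_jx1, tx_jx2)),
    planted_stop_last_exon = as.vector(rbind(tx_jx1 == 0L, tx_jx2 == 0L)),
    planted_uorf = as.vector(rbind(
      vapply(plans, function(p) p$uorf1, logical(1)),
      vapply(plans, function(p) p$uorf2, logical(1)))))
  genome_str <- paste(unlist(lapply(gene_seqs, function(s)
    c(s, rep("A", spacer)))), collapse = "")
  genome <- setNames(genome_str, chrom)

  reference <- annotation(exons[source == "reference"],
                          chrom_lengths = setNames(nchar(genome_str), chrom))
  novel <- annotation(exons[source == "novel"])

  # principal starts (1-based in the file)
  starts_dt <- data.table(gene_id = gene_ids, chrom = chrom,
                          strand = strands,
                          start_codon_pos = events$atg_pos + 1L)
  starts <- data.table(gene_id = gene_ids, chrom = chrom, strand = strands,
                       start_pos = events$atg_pos)
  setkey(starts, gene_id)

  # verify every planted poised exon through the projection module
  verify_plants(plans, verify_tx, starts, genome, gene_ids)

  # junction counts
  base_psi <- numeric(n)
  base_psi[subclass == "inclusion"] <- runif(sum(subclass == "inclusion"), 0.15, 0.55)
  base_psi[subclass == "exclusion"] <- runif(sum(subclass == "exclusion"), 0.45, 0.85)
  base_psi[subclass == "none"] <- runif(sum(subclass == "none"), 0.20, 0.80)
  eff <- fifelse(subclass == "inclusion", cfg$delta_psi,
                 fifelse(subclass == "exclusion", -cfg$delta_psi, 0))
  conds <- c("CTR", "dKD", "RESC")
  reps <- seq_len(cfg$n_replicates)
  grid <- CJ(gene = seq_len(n), condition = conds, replicate = reps, sorted = FALSE)
  psi_cond <- base_psi[grid$gene] +
    eff[grid$gene] * (grid$condition == "dKD") +
    eff[grid$gene] * (1 - cfg$rescue_revert_frac) * (grid$condition == "RESC")
  psi_cond <- pmin(pmax(psi_cond, 0.02), 0.98)
  LI <- 2; LS <- 1
  p_inc <- psi_cond * LI / (psi_cond * LI + (1 - psi_cond) * LS)
  depth <- pmax(rpois(nrow(grid), cfg$mean_coverage), 2L)
  I <- rbinom(nrow(grid), depth, p_inc)
  counts <- data.table(event_id = sprintf("EV%05d", grid$gene),
                       condition = grid$condition, replicate = grid$replicate,
                       inclusion_count = I, skipping_count = depth - I,
                       inclusion_length = LI, skipping_length = LS)
  setorder(counts, event_id, condition, replicate)

  # abundance: sensitive isoforms are degraded in CTR, derepressed in dKD
  samples <- paste(rep(conds, each = cfg$n_replicates), reps, sep = "_")
  ns <- length(samples)
  base_ab <- exp(rnorm(n, log(50), 0.4))
  cond_fac <- c(0.3, 0.9, 0.4)[match(rep(conds, each = cfg$n_replicates), conds)]
  ab_mat <- matrix(0, nrow = 2L * n, ncol = ns)
  for (i in seq_len(n)) {
    fac1 <- if (is_nmd[i]) cond_fac else rep(0.7, ns)
    ab_mat[2L * i - 1L, ] <- base_ab[i] * fac1 * exp(rnorm(ns, 0, 0.1))
    ab_mat[2L * i, ] <- base_ab[i] * exp(rnorm(ns, 0, 0.1))
  }
  abundance <- data.table(transcript_id = as.vector(rbind(tx1_ids, tx2_ids)))
  abundance <- cbind(abundance, as.data.table(ab_mat))
  setnames(abundance, c("transcript_id", samples))

  # conservation track
  winds <- data.table(start = as.integer(unlist(win_s)),
                      end = as.integer(unlist(win_e)),
                      class = unlist(win_cl))
  winds[, value := round(fifelse(class == "degenerate",
                                 rnorm(.N, 0, 0.2), rnorm(.N, 1.5, 0.2)), 4)]
  setorder(winds, start)
  track <- winds[, .(chrom = chrom, start, end, value)]

  uorf_evidence <- data.table(chrom = unlist(uorf_acc$chrom),
                              start = as.integer(unlist(uorf_acc$start)),
                              end = as.integer(unlist(uorf_acc$end)))
  if (!nrow(uorf_evidence))
    uorf_evidence <- data.table(chrom = character(), start = integer(),
                                end = integer())

  # --- write bundle ---------------------------------------------------------
  paths <- c(genome = "genome.fa", reference = "reference.gtf",
             novel = "novel.gtf", principal_starts = "principal_starts.tsv",
             junction_counts = "junction_counts.tsv", events = "events.tsv",
             abundance = "abundance.tsv", conservation = "conservation.bedGraph",
             uorf_evidence = "uorf_evidence.bed", truth = "truth.json")
  paths <- setNames(file.path(out_dir, paths), names(paths))
  write_genome(genome, paths[["genome"]])
  write_gtf(reference, paths[["reference"]])
  write_gtf(novel, paths[["novel"]])
  fwrite(starts_dt, paths[["principal_starts"]], sep = "\t")
  fwrite(counts, paths[["junction_counts"]], sep = "\t")
  ev_out <- events[, .(event_id, gene_id, chrom, strand, target_start,
                       target_end, up_end, down_start)]
  fwrite(ev_out, paths[["events"]], sep = "\t")
  fwrite(abundance, paths[["abundance"]], sep = "\t")
  fwrite(track, paths[["conservation"]], sep = "\t", col.names = FALSE)
  fwrite(uorf_evidence, paths[["uorf_evidence"]], sep = "\t", col.names = FALSE)

  truth <- list(
    events = cbind(events[, .(event_id, gene_id, is_nmd, subclass, site_class,
                              acc_start, acc_end, don_start, don_end)],
                   base_psi = round(base_psi, 4),
                   dpsi = eff,
                   sensitive_tx = fifelse(is_nmd, paste0(gene_ids, ".T1"), NA_character_),
                   insensitive_tx = fifelse(is_nmd, paste0(gene_ids, ".T2"), NA_character_)),
    transcripts = tx_truth)
  jsonlite::write_json(list(config = unclass(cfg)[setdiff(names(cfg), "utr3_range")],
                            utr3_range = cfg$utr3_range,
                            events = truth$events,
                            transcripts = truth$transcripts),
                       paths[["truth"]], dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)

  list(dir = out_dir, paths = paths, truth = truth, config = cfg,
       genome = genome, reference = reference, novel = novel,
       samples = samples)
}

# Generation-time self check: every planted gene's isoforms must project to
# the planned ORF structure.
verify_plants <- function(plans, verify_tx, starts, genome, gene_ids) {
  for (i in seq_along(plans)) {
    p <- plans[[i]]
    if (!p$is_nmd) next
    o1 <- project_orf(verify_tx[[i]][[1]], starts, genome)
    o2 <- project_orf(verify_tx[[i]][[2]], starts, genome)
    if (o1$status != "ok" || o2$status != "ok")
      stopf("plant verification failed for gene %s: status %s/%s",
            gene_ids[i], o1$status, o2$status)
    if (p$variant_junction && o1$junctions_downstream_of_stop < 1L)
      stopf("gene %s: poised isoform lacks a junction downstream of its PTC",
            gene_ids[i])
    if (!p$variant_junction && o1$junctions_downstream_of_stop != 0L)
      stopf("gene %s: last-exon PTC variant has downstream junctions",
            gene_ids[i])
    exp2 <- if (p$ins_jx) 1L else 0L
    if (o2$junctions_downstream_of_stop != exp2)
      stopf("gene %s: insensitive isoform junction count %d != planned %d",
            gene_ids[i], o2$junctions_downstream_of_stop, exp2)
  }
  invisible(TRUE)
}
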