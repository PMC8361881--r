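test_that("uORF finder on hand-scanned examples", {
  # 5'UTR "AA ATG AAA CCC GGG TAA" then main ORF
  seq <- paste0("AAATGAAACCCGGGTAA", "ATGCCCTAA")
  u <- find_uorfs(seq, cds_start = 17)
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 2L)
  expect_equal(u$length, 15L)
  # 12-nt uORF is below the threshold
  seq2 <- paste0("AAATGAAACCCTAA", "ATGCCCTAA")
  expect_equal(nrow(find_uorfs(seq2, 14)), 0L)
  expect_equal(nrow(find_uorfs(seq2, 14, min_len = 12)), 1L)
  # first in-frame stop past the CDS start: not entirely upstream, excluded
  seq3 <- paste0("AAATGAAACCCGGG", "ATGCCCTAA")
  expect_equal(nrow(find_uorfs(seq3, 14)), 0L)
})

test_that("uORF finder equals the brute-force oracle on random 5'UTRs", {
  with_seed_test(41, {
    for (rep in 1:200) {
      n <- sample(30:200, 1)
      seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      cds_start <- sample(10:(n - 3), 1)
      got <- find_uorfs(seq, cds_start)[, .(start, end)]
      want <- uorf_oracle(seq, cds_start)
      expect_equal(got, want)
    }
  })
})

test_that("translation-evidence filtering requires full containment", {
  u <- data.table(transcript_id = "T1", start = 10L, end = 25L, length = 15L)
  none <- filter_translated_uorfs(u, data.table(chrom = character(),
                                                start = integer(),
                                                end = integer()))
  expect_equal(nrow(none), 0L)
  exact <- filter_translated_uorfs(u, data.table(chrom = "T1", start = 10L,
                                                 end = 25L))
  expect_equal(nrow(exact), 1L)
  expect_true(exact$translated)
  partial <- filter_translated_uorfs(u, data.table(chrom = "T1", start = 10L,
                                                   end = 18L))
  expect_equal(nrow(partial), 0L)
  other_tx <- filter_translated_uorfs(u, data.table(chrom = "T2", start = 0L,
                                                    end = 100L))
  expect_equal(nrow(other_tx), 0L)
})

test_that("uORF enrichment reports pooled and stratified fractions", {
  tb <- data.table(event_id = paste0("E", 1:8),
                   transcript_id = paste0("X", 1:8),
                   group = rep(c("sensitive", "insensitive"), each = 4),
                   n_junctions_3utr = c(0, 0, 1, 1, 0, 0, 0, 2),
                   utr3_len = 100,
                   stop_in_last_exon = c(TRUE, TRUE, FALSE, FALSE,
                                         TRUE, TRUE, TRUE, FALSE))
  enr <- uorf_enrichment(tb, uorf_tx = c("X1", "X3", "X5"))
  expect_equal(enr[group == "sensitive" & stratum == "all", fraction], 0.5)
  expect_equal(enr[group == "sensitive" & stratum == "stop_in_last_exon",
                   fraction], 0.5)
  expect_equal(enr[group == "insensitive" & stratum == "stop_in_last_exon",
                   fraction], 1 / 3)
  pooled <- uorf_enrichment(tb, c("X1", "X3", "X5"),
                            stratify_no_3utr_junctions = FALSE)
  expect_equal(nrow(pooled), 2L)
  expect_equal(pooled[group == "sensitive", fraction], 0.5)
})

test_that("splice windows have fixed widths and strand symmetry", {
  with_seed_test(13, {
    g <- setNames(random_chrom(300), "chrT")
  })
  ann <- toy_annotation("+")
  tx <- get_transcript(ann, "T1")
  w <- extract_splice_windows(tx, 60L, 90L, g)
  expect_equal(nchar(w$acceptor), 23L)
  expect_equal(nchar(w$donor), 9L)
  expect_equal(w$acceptor, unname(substring(g, 60 - 20 + 1, 60 + 3)))
  expect_equal(w$donor, unname(substring(g, 90 - 3 + 1, 90 + 6)))
  expect_equal(w$acceptor_interval, c(40L, 63L))

  # terminal exon: no windows
  expect_null(extract_splice_windows(tx, 10L, 40L, g))

  # mirrored minus-strand locus gives identical window sequences
  L <- 300L
  gm <- setNames(paste(rev(chartr("ACGT", "TGCA", strsplit(g[[1]], "")[[1]])),
                       collapse = ""), "chrT")
  annm <- annotation(data.table(chrom = "chrT",
                                start = L - c(40L, 90L, 150L),
                                end = L - c(10L, 60L, 120L), strand = "-",
                                transcript_id = "T1", gene_id = "G1"))
  txm <- get_transcript(annm, "T1")
  wm <- extract_splice_windows(txm, L - 90L, L - 60L, gm)
  expect_equal(wm$acceptor, w$acceptor)
  expect_equal(wm$donor, w$donor)
})

test_that("splice scoring is a positional log-odds sum", {
  uniform <- structure(list(
    acceptor = matrix(0, 4, 23, dimnames = list(c("A", "C", "G", "T"), NULL)),
    donor = matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))),
    class = "splice_model")
  expect_equal(score_splice_site(strrep("A", 23), uniform, "acceptor"), 0)
  expect_equal(score_splice_site("ACGTACGTA", uniform, "donor"), 0)
  expect_error(score_splice_site("ACGT", uniform, "donor"), "length")

  # model trained on a repeated consensus: consensus maximal, any single
  # mismatch strictly lower
  cons <- strrep("A", 9)
  model <- train_splice_model(rep(strrep("C", 23), 50), rep(cons, 50))
  s_cons <- score_splice_site(cons, model, "donor")
  for (j in 1:9) {
    mm <- cons
    substr(mm, j, j) <- "G"
    expect_lt(score_splice_site(mm, model, "donor"), s_cons)
  }
  # N positions are skipped
  nn <- cons; substr(nn, 3, 3) <- "N"
  expect_equal(score_splice_site(nn, model, "donor"),
               s_cons - unname(model$donor["A", 3]))

  # hand-summed toy: external table backend
  f <- tempfile()
  tab <- CJ(site = "donor", position = 1:9, base = c("A", "C", "G", "T"))
  tab[, weight := 0]
  tab[position == 1 & base == "A", weight := 1]
  tab[position == 2 & base == "C", weight := -2]
  rbind_acc <- CJ(site = "acceptor", position = 1:23,
                  base = c("A", "C", "G", "T"))[, weight := 0]
  fwrite(rbind(tab, rbind_acc), f, sep = "\t")
  ext <- read_splice_model(f)
  expect_equal(score_splice_site("ACAAAAAAA", ext, "donor"), 1 - 2)
})

test_that("mean conservation averages covered bases with a coverage floor", {
  track <- data.table(chrom = "chrT", start = c(0L, 50L), end = c(50L, 100L),
                      value = c(1.7, 1.7))
  expect_equal(mean_conservation("chrT", 10, 40, track), 1.7)
  half <- data.table(chrom = "chrT", start = c(0L, 10L), end = c(10L, 20L),
                     value = c(0, 2))
  expect_equal(mean_conservation("chrT", 0, 20, half), 1)
  # < 50% coverage and unknown chromosome are missing markers, not zeros
  sparse <- data.table(chrom = "chrT", start = 0L, end = 4L, value = 5)
  expect_true(is.na(mean_conservation("chrT", 0, 10, sparse)))
  expect_true(is.na(mean_conservation("chrX", 0, 10, track)))

  # random sparse track vs per-base loop oracle
  with_seed_test(23, {
    for (rep in 1:30) {
      n_iv <- sample(1:8, 1)
      s <- sort(sample(0:80, n_iv))
      iv <- data.table(chrom = "chrT", start = s,
                       end = s + sample(1:10, n_iv, TRUE),
                       value = round(runif(n_iv, -2, 2), 3))
      iv <- iv[!duplicated(start)]
      iv[, end := pmin(end, c(start[-1], 100L))]   # disjoint
      iv <- iv[end > start]
      q <- sort(sample(0:90, 2)); if (q[1] == q[2]) q[2] <- q[2] + 1
      per_base <- unlist(lapply(seq_len(nrow(iv)), function(k)
        if (iv$end[k] > q[1] && iv$start[k] < q[2])
          rep(iv$value[k], min(iv$end[k], q[2]) - max(iv$start[k], q[1]))))
      want <- if (is.null(per_base) ||
                  length(per_base) < (q[2] - q[1]) / 2) NA_real_
      else mean(per_base)
      expect_equal(mean_conservation("chrT", q[1], q[2], iv), want)
    }
  })
})

test_that("control-exon sampling is one-per-gene, seeded and exclusion-aware", {
  b <- shared_bundle()
  ref <- b$reference
  orfs <- data.table(transcript_id = transcript_ids(ref), status = "ok")
  setkey(orfs, transcript_id)
  s1 <- sample_control_exons(ref, orfs, 20, seed = 5)
  s2 <- sample_control_exons(ref, orfs, 20, seed = 5)
  s3 <- sample_control_exons(ref, orfs, 20, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_equal(nrow(s1), 20L)
  expect_equal(anyDuplicated(s1$gene_id), 0L)
  # internal exons only
  for (i in 1:5) {
    tx <- get_transcript(ref, s1$transcript_id[i])
    idx <- which(tx$exons$start == s1$start[i])
    expect_gt(idx, 1)
    expect_lt(idx, nrow(tx$exons))
  }
  expect_error(sample_control_exons(ref, orfs, 10000, seed = 1), "eligible")
})

test_that("K-S comparison equals a CDF-sweep oracle", {
  same <- ks_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_compare(1:100, 201:300)$D, 1)
  expect_error(ks_compare(1, 1:5), ">= 2")

  ks_oracle <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
  }
  with_seed_test(8, {
    for (rep in 1:50) {
      a <- sample(1:20, sample(5:30, 1), TRUE)
      b <- sample(1:20, sample(5:30, 1), TRUE) + sample(0:3, 1)
      expect_equal(ks_compare(a, b)$D, ks_oracle(a, b))
    }
  })
})

test_that("gene-vs-isoform cross-tabulation covers the quadrants", {
  pairs <- data.table(event_id = c("E1", "E2", "E3", "E4"),
                      gene_id = paste0("G", 1:4),
                      sensitive_tx = paste0("T", 1:4),
                      insensitive_tx = paste0("U", 1:4))
  gde <- data.table(gene_id = paste0("G", 1:4), log2fc = c(1, 0.1, 2, 0),
                    significant = c(TRUE, FALSE, TRUE, FALSE))
  tde <- data.table(transcript_id = paste0("T", 1:3),
                    gene_id = paste0("G", 1:3), log2fc = c(2, 1.5, 0.2),
                    significant = c(TRUE, TRUE, FALSE))
  ct <- gene_isoform_cross_tab(gde, tde, pairs)
  expect_equal(unname(ct$counts["both"]), 1L)
  expect_equal(unname(ct$counts["isoform_only"]), 1L)
  expect_equal(unname(ct$counts["gene_only"]), 1L)
  expect_equal(unname(ct$counts["unquantified"]), 1L)  # T4 not quantified
  expect_equal(nrow(ct$scatter), 3L)

  all_sig <- copy(gde)[, significant := TRUE]
  tde_sig <- copy(tde)[, significant := TRUE]
  ct2 <- gene_isoform_cross_tab(all_sig, tde_sig, pairs[1:3])
  expect_equal(unname(ct2$counts["isoform_only"]), 0L)

  empty <- gene_isoform_cross_tab(gde, tde, pairs[0])
  expect_true(all(empty$counts == 0L))
})

test_that("stratified 3'UTR lengths drop non-last-exon rows and flag empties", {
  tb <- data.table(event_id = "E", transcript_id = paste0("X", 1:4),
                   group = c("sensitive", "sensitive", "insensitive",
                             "insensitive"),
                   n_junctions_3utr = c(0, 1, 0, 0),
                   utr3_len = c(100, 300, 150, 120),
                   stop_in_last_exon = c(TRUE, FALSE, TRUE, TRUE))
  out <- last_exon_stratified_lengths(tb)
  expect_equal(out$sensitive, 100)
  expect_equal(sort(out$insensitive), c(120, 150))
  expect_message(last_exon_stratified_lengths(tb[group == "sensitive"]),
                 "empty")
})
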