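starts_table <- function(gene_id, chrom, strand, pos0) {
  out <- data.table(gene_id = gene_id, chrom = chrom, strand = strand,
                    start_pos = as.integer(pos0))
  setkey(out, gene_id)
  out
}

test_that("principal-start table loads with coordinate shift and dedup", {
  f <- tempfile()
  writeLines(c("gene_id\tchrom\tstrand\tstart_codon_pos",
               "G1\tchrT\t+\t101",
               "G1\tchrT\t+\t500",
               "G2\tchrT\t-\t31"), f)
  expect_warning(tb <- load_principal_starts(f), "duplicated")
  expect_equal(nrow(tb), 2L)
  expect_equal(tb[J("G1"), start_pos], 100L)   # 1-based file -> 0-based

  f2 <- tempfile()
  writeLines("gene_id\tchrom\tstrand\tstart_codon_pos", f2)
  expect_equal(nrow(load_principal_starts(f2)), 0L)

  f3 <- tempfile()
  writeLines(c("gene_id\tchrom", "G1\tchrT"), f3)
  expect_error(load_principal_starts(f3), "lacks column")
})

test_that("ORF projection on a hand-translated single-exon toy", {
  genome <- setNames("GGATGAAATAAGG", "chrT")
  ann <- annotation(data.table(chrom = "chrT", start = 0L, end = 13L,
                               strand = "+", transcript_id = "T",
                               gene_id = "G"))
  tx <- get_transcript(ann, "T")
  orf <- project_orf(tx, starts_table("G", "chrT", "+", 2), genome)
  expect_equal(orf$status, "ok")
  expect_equal(orf$cds_start, 2L)
  expect_equal(orf$cds_len, 9L)       # ATG AAA TAA
  expect_equal(orf$utr5_len, 2L)
  expect_equal(orf$utr3_len, 2L)
  expect_equal(orf$junctions_downstream_of_stop, 0L)
  expect_true(orf$stop_in_last_exon)
})

test_that("ORF projection failure modes are distinct statuses", {
  genome <- setNames("GGATGAAATAAGGCCCCCCCC", "chrT")
  two_ex <- annotation(data.table(chrom = "chrT", start = c(0L, 15L),
                                  end = c(10L, 21L), strand = "+",
                                  transcript_id = "T", gene_id = "G"))
  tx <- get_transcript(two_ex, "T")
  # start codon position in the intron of this isoform
  orf <- project_orf(tx, starts_table("G", "chrT", "+", 12), genome)
  expect_equal(orf$status, "start_not_exonic")
  # position exonic but not an ATG
  orf2 <- project_orf(tx, starts_table("G", "chrT", "+", 0), genome)
  expect_equal(orf2$status, "start_interrupted")
  # gene missing entirely
  orf3 <- project_orf(tx, starts_table("OTHER", "chrT", "+", 2), genome)
  expect_equal(orf3$status, "no_principal_start")
  # no in-frame stop after the start
  genome2 <- setNames("GGATGAAAAAAGG", "chrT")
  ann2 <- annotation(data.table(chrom = "chrT", start = 0L, end = 13L,
                                strand = "+", transcript_id = "T",
                                gene_id = "G"))
  orf4 <- project_orf(get_transcript(ann2, "T"),
                      starts_table("G", "chrT", "+", 2), genome2)
  expect_equal(orf4$status, "no_stop_found")
})

test_that("stop context counts junctions beyond the threshold separately", {
  mk <- function(d) structure(list(transcript_id = "T", status = "ok",
                                   junction_distances = as.integer(d),
                                   stop_in_last_exon = length(d) == 0),
                              class = "orf_annotation")
  expect_equal(stop_context(mk(integer(0))),
               list(junction_count_total = 0L,
                    junction_count_beyond_threshold = 0L,
                    stop_in_last_exon = TRUE))
  expect_equal(stop_context(mk(40))[1:2],
               list(junction_count_total = 1L,
                    junction_count_beyond_threshold = 0L))
  sc <- stop_context(mk(c(40, 300)))
  expect_equal(sc$junction_count_total, 2L)
  expect_equal(sc$junction_count_beyond_threshold, 1L)
  expect_false(sc$stop_in_last_exon)
  bad <- mk(1); bad$status <- "no_stop_found"
  expect_error(stop_context(bad), "ok")
})

test_that("ORF length conservation and single terminal stop hold on random genes", {
  with_seed_test(31, {
    for (rep in 1:30) {
      # random 3-exon gene with an ATG planted in exon 1 and stop-free CDS
      e1 <- sample(30:60, 1); e2 <- sample(30:60, 1); e3 <- sample(60:90, 1)
      utr5 <- sample(3:10, 1)
      body_len <- e1 + e2 + e3
      body <- sample(c("A", "C", "G"), body_len, replace = TRUE)
      body[(utr5 + 1):(utr5 + 3)] <- c("A", "T", "G")
      stop_off <- utr5 + 3 * sample(10:15, 1)
      body[(stop_off + 1):(stop_off + 3)] <- c("T", "A", "A")
      i1 <- sample(20:50, 1); i2 <- sample(20:50, 1)
      starts <- c(0L, e1 + i1, e1 + i1 + e2 + i2)
      ends <- starts + c(e1, e2, e3)
      spliced_parts <- list(1:e1, (e1 + 1):(e1 + e2), (e1 + e2 + 1):body_len)
      chrom_v <- rep("C", max(ends))
      for (k in 1:3) chrom_v[(starts[k] + 1):ends[k]] <- body[spliced_parts[[k]]]
      genome <- setNames(paste(chrom_v, collapse = ""), "chrT")
      ann <- annotation(data.table(chrom = "chrT", start = starts, end = ends,
                                   strand = "+", transcript_id = "T",
                                   gene_id = "G"))
      tx <- get_transcript(ann, "T")
      orf <- project_orf(tx, starts_table("G", "chrT", "+", utr5), genome)
      expect_equal(orf$status, "ok")
      expect_equal(orf$utr5_len + orf$cds_len + orf$utr3_len,
                   transcript_length(tx))
      expect_equal(orf$cds_len %% 3, 0)
      # independent codon walk over the spliced sequence: exactly one stop,
      # at the end of the reported CDS
      seqs <- transcript_sequence(tx, genome)
      cds <- substring(seqs, orf$cds_start + 1, orf$cds_end)
      codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
      expect_equal(which(codons %in% c("TAA", "TAG", "TGA")), length(codons))
      # junction bookkeeping: stop_in_last_exon <=> zero downstream junctions
      expect_equal(orf$stop_in_last_exon,
                   orf$junctions_downstream_of_stop == 0L)
      # oracle: junctions downstream = exons overlapping the 3'UTR - 1
      if (orf$utr3_len > 0) {
        utr3_g <- vapply(orf$cds_end:(transcript_length(tx) - 1),
                         function(o) transcript_to_genomic(tx, o), integer(1))
        n_ex <- sum(vapply(seq_len(nrow(tx$exons)), function(k)
          any(utr3_g >= tx$exons$start[k] & utr3_g < tx$exons$end[k]),
          logical(1)))
        expect_equal(orf$junctions_downstream_of_stop, n_ex - 1L)
      }
    }
  })
})

test_that("ORF projection is strand-symmetric", {
  with_seed_test(77, {
    for (rep in 1:10) {
      # build a plus-strand gene, then mirror the whole locus
      L <- 400L
      e <- sort(sample(5:(L - 5), 6))
      starts <- e[c(1, 3, 5)]; ends <- e[c(2, 4, 6)]
      lens <- ends - starts
      if (sum(lens) < 40) next
      body <- sample(c("A", "C", "G"), sum(lens), replace = TRUE)
      body[3:5] <- c("A", "T", "G")
      so <- 2 + 3 * sample(3:8, 1)
      if (so + 3 > sum(lens)) next
      body[(so + 1):(so + 3)] <- c("T", "A", "A")
      chrom_v <- rep("A", L)
      pos <- 1L
      for (k in 1:3) {
        chrom_v[(starts[k] + 1):ends[k]] <- body[pos:(pos + lens[k] - 1)]
        pos <- pos + lens[k]
      }
      gplus <- setNames(paste(chrom_v, collapse = ""), "chrT")
      annp <- annotation(data.table(chrom = "chrT", start = starts, end = ends,
                                    strand = "+", transcript_id = "T",
                                    gene_id = "G"))
      txp <- get_transcript(annp, "T")
      start_g <- transcript_to_genomic(txp, 2L)
      orfp <- project_orf(txp, starts_table("G", "chrT", "+", start_g), gplus)

      gminus <- setNames(paste(rev(chartr("ACGT", "TGCA",
                                          strsplit(gplus, "")[[1]])),
                               collapse = ""), "chrT")
      annm <- annotation(data.table(chrom = "chrT",
                                    start = L - ends, end = L - starts,
                                    strand = "-", transcript_id = "T",
                                    gene_id = "G"))
      txm <- get_transcript(annm, "T")
      orfm <- project_orf(txm, starts_table("G", "chrT", "-", L - 1L - start_g),
                          gminus)
      for (fld in c("status", "cds_start", "cds_end", "utr5_len", "cds_len",
                    "utr3_len", "junctions_downstream_of_stop",
                    "junction_distances", "stop_in_last_exon"))
        expect_equal(orfm[[fld]], orfp[[fld]], info = fld)
    }
  })
})
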