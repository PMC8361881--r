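test_that("GTF reading converts coordinates and sorts exons per transcript", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrT\tx\texon\t121\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrT\tx\texon\t101\t200\t.\t+\t.\tgene_id "G2"; transcript_id "T2";',
    'chrT\tx\texon\t11\t40\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    gtf)
  ann <- read_gtf(gtf)
  t2 <- get_transcript(ann, "T2")
  expect_equal(t2$exons$start, 100L)   # 1-based closed -> 0-based half-open
  expect_equal(t2$exons$end, 200L)
  t1 <- get_transcript(ann, "T1")
  expect_equal(t1$exons$start, c(10L, 120L))   # sorted despite file order
})

test_that("exon records without transcript_id are dropped with a warning", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrT\tx\texon\t11\t40\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrT\tx\texon\t51\t80\t.\t+\t.\tgene_id "G1";'),
    gtf)
  expect_warning(ann <- read_gtf(gtf), "without transcript_id")
  expect_equal(transcript_ids(ann), "T1")
})

test_that("GTF round trip is structure-identical and writing is deterministic", {
  with_seed_test(11, {
    exs <- rbindlist(lapply(1:5, function(i) {
      n <- sample(1:4, 1)
      bounds <- sort(sample(1:400, 2 * n))
      data.table(chrom = "chrT", start = bounds[seq(1, 2 * n, 2)],
                 end = bounds[seq(2, 2 * n, 2)],
                 strand = sample(c("+", "-"), 1),
                 transcript_id = paste0("T", i), gene_id = paste0("G", i))
    }))
  })
  ann <- annotation(exs)
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(ann, f1)
  back <- read_gtf(f1)
  o1 <- ann$exons[order(transcript_id, start)]
  o2 <- back$exons[order(transcript_id, start)]
  expect_equal(o1$start, o2$start)
  expect_equal(o1$end, o2$end)
  expect_equal(o1$transcript_id, o2$transcript_id)
  expect_equal(o1$gene_id, o2$gene_id)
  write_gtf(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # empty annotation gives a header-only file
  f3 <- tempfile()
  write_gtf(annotation(data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  transcript_id = character(),
                                  gene_id = character())), f3)
  expect_equal(length(readLines(f3)), 1L)
})

test_that("transcript_sequence respects strand and exon order", {
  genome <- setNames("AACGTTGCAAGGTCCA", "chrT")
  one <- annotation(data.table(chrom = "chrT", start = 2L, end = 8L,
                               strand = "+", transcript_id = "P",
                               gene_id = "G"))
  expect_equal(transcript_sequence(get_transcript(one, "P"), genome), "CGTTGC")
  onem <- annotation(data.table(chrom = "chrT", start = 2L, end = 8L,
                                strand = "-", transcript_id = "M",
                                gene_id = "G"))
  expect_equal(transcript_sequence(get_transcript(onem, "M"), genome), "GCAACG")

  # 3-exon minus-strand vs per-exon reverse-complement-and-reverse-order oracle
  with_seed_test(5, {
    g <- setNames(random_chrom(200), "chrT")
    ann <- annotation(data.table(chrom = "chrT",
                                 start = c(10L, 50L, 120L),
                                 end = c(30L, 80L, 140L), strand = "-",
                                 transcript_id = "T", gene_id = "G"))
    tx <- get_transcript(ann, "T")
    oracle <- paste(rev(vapply(1:3, function(i) {
      piece <- substring(g, tx$exons$start[i] + 1, tx$exons$end[i])
      paste(rev(strsplit(chartr("ACGT", "TGCA", piece), "")[[1]]), collapse = "")
    }, character(1))), collapse = "")
    expect_equal(transcript_sequence(tx, g), oracle)
  })
})

test_that("genome-to-transcript mapping round-trips on exonic positions", {
  ann <- toy_annotation("+")
  tx <- get_transcript(ann, "T1")
  expect_equal(genomic_to_transcript(tx, 10L), 0L)   # first exonic base
  expect_true(is.na(genomic_to_transcript(tx, 45L))) # intronic
  annm <- toy_annotation("-")
  txm <- get_transcript(annm, "T1")
  expect_equal(genomic_to_transcript(txm, 149L), 0L) # last genomic base is 5' on minus

  with_seed_test(21, {
    for (rep in 1:25) {
      rt <- random_transcript(sample(2:5, 1))
      ex <- rt$tx$exons
      for (pos in unlist(Map(seq, ex$start, ex$end - 1L))) {
        off <- genomic_to_transcript(rt$tx, pos)
        expect_false(is.na(off))
        expect_equal(transcript_to_genomic(rt$tx, off), pos)
      }
    }
  })
})

test_that("intron-chain merge collapses matching chains and adds new ones", {
  ref <- toy_annotation("+")
  # idempotence: merging an annotation with itself changes nothing
  m0 <- merge_transcriptomes(ref, ref)
  expect_equal(sort(transcript_ids(m0)), sort(transcript_ids(ref)))
  expect_equal(merge_stats(m0)$added, 0L)

  # same chain, 50 nt longer terminal exon: collapsed, terminal end extended
  nov <- annotation(data.table(chrom = "chrT",
                               start = c(10L, 60L, 120L),
                               end = c(40L, 90L, 200L), strand = "+",
                               transcript_id = "N1", gene_id = "G1",
                               source = "novel"))
  m1 <- merge_transcriptomes(ref, nov)
  expect_equal(uniqueN(m1$exons$transcript_id), 2L)
  expect_equal(max(m1$exons[transcript_id == "T1", end]), 200L)

  # new internal exon = new junction pair: transcript added as novel
  nov2 <- annotation(data.table(chrom = "chrT",
                                start = c(10L, 60L, 100L, 120L),
                                end = c(40L, 90L, 110L, 150L), strand = "+",
                                transcript_id = "N2", gene_id = "G1",
                                source = "novel"))
  m2 <- merge_transcriptomes(ref, nov2)
  expect_equal(uniqueN(m2$exons$transcript_id), 3L)
  expect_equal(unique(m2$exons[transcript_id == "N2", source]), "novel")
  expect_equal(unique(m2$exons[transcript_id == "N2", gene_id]), "G1")

  # monotonicity
  n_ref <- uniqueN(ref$exons$transcript_id)
  expect_gte(uniqueN(m2$exons$transcript_id), n_ref)
  expect_lte(uniqueN(m2$exons$transcript_id), n_ref + 1L)

  # unknown chromosome is a named error
  novX <- annotation(data.table(chrom = "chrX", start = 1L, end = 50L,
                                strand = "+", transcript_id = "NX",
                                gene_id = "GX", source = "novel"))
  expect_error(merge_transcriptomes(ref, novX), "chrX")
})

test_that("duplicate novel transcript ids are suffixed, id-less genes prefixed", {
  ref <- toy_annotation("+")
  nov <- annotation(data.table(chrom = "chrT",
                               start = c(10L, 60L, 100L, 120L),
                               end = c(40L, 90L, 110L, 150L), strand = "+",
                               transcript_id = "T1", gene_id = "G9",
                               source = "novel"))
  m <- merge_transcriptomes(ref, nov)
  expect_true("T1.n1" %in% transcript_ids(m))
  expect_equal(unique(m$exons[transcript_id == "T1.n1", gene_id]), "G1")

  # no overlap with any reference gene: NOVG-prefixed gene id
  nov2 <- annotation(data.table(chrom = "chrT", start = c(200L, 250L),
                                end = c(220L, 270L), strand = "+",
                                transcript_id = "NN", gene_id = "GZ",
                                source = "novel"))
  m2 <- merge_transcriptomes(ref, nov2)
  expect_equal(unique(m2$exons[transcript_id == "NN", gene_id]), "NOVG_GZ")
})

test_that("novel exon fraction counts exact-coordinate membership", {
  ref <- toy_annotation("+")
  nov <- annotation(data.table(chrom = "chrT",
                               start = c(10L, 60L, 100L, 120L),
                               end = c(40L, 90L, 110L, 150L), strand = "+",
                               transcript_id = "N2", gene_id = "G1",
                               source = "novel"))
  m <- merge_transcriptomes(ref, nov)
  all_ref <- ref$exons[, .(chrom, start, end, strand)]
  expect_equal(novel_exon_fraction(m, ref, all_ref), 0)
  only_new <- data.table(chrom = "chrT", start = 100L, end = 110L, strand = "+")
  expect_equal(novel_exon_fraction(m, ref, only_new), 1)
  mixed <- rbind(all_ref[1:8], only_new, only_new[, .(chrom, start = start + 1L,
                                                      end, strand)])
  # 1 of 10 exons novel-and-present (the shifted copy is in neither set)
  expect_equal(novel_exon_fraction(m, ref, mixed), 0.1)
  expect_error(novel_exon_fraction(m, ref, all_ref[0]), "empty")
})
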