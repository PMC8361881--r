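# Shared in-code fixtures: tiny hand-built gene models and genomes.

suppressPackageStartupMessages(library(data.table))

# A two-transcript toy gene on the plus strand of a 300-nt chromosome.
#   T1: exons [10,40) [60,90) [120,150)   (includes middle exon)
#   T2: exons [10,40) [120,150)           (skips it)
toy_annotation <- function(strand = "+") {
  ex <- data.table(
    chrom = "chrT",
    start = c(10L, 60L, 120L, 10L, 120L),
    end = c(40L, 90L, 150L, 40L, 150L),
    strand = strand,
    transcript_id = c("T1", "T1", "T1", "T2", "T2"),
    gene_id = "G1")
  annotation(ex)
}

random_chrom <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

toy_genome <- function(len = 300, seed = 42) {
  with_seed_test(seed, setNames(random_chrom(len), "chrT"))
}

# local seed helper for fixtures (independent of package internals)
with_seed_test <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Random multi-exon transcript on a random genome; returns list(tx, genome).
random_transcript <- function(n_exons = 4, strand = NULL, chrom_len = 500) {
  strand <- strand %||% sample(c("+", "-"), 1)
  bounds <- sort(sample(5:(chrom_len - 5), 2 * n_exons))
  starts <- bounds[seq(1, 2 * n_exons, 2)]
  ends <- bounds[seq(2, 2 * n_exons, 2)]
  keep <- ends > starts
  ex <- data.table(chrom = "chrT", start = starts[keep], end = ends[keep],
                   strand = strand, transcript_id = "TX", gene_id = "G")
  ann <- annotation(ex)
  list(tx = get_transcript(ann, "TX"),
       genome = setNames(random_chrom(chrom_len), "chrT"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accessors for internal primitives exercised against oracles.
junction_offsets_for_test <- function(tx) nmdsense:::junction_offsets(tx)
chain_key_for_test <- function(ann)
  nmdsense:::chain_key(nmdsense:::transcript_index(ann))

# Independent brute-force uORF oracle: regex ATG scan + codon walk.
uorf_oracle <- function(seq, cds_start, min_len = 15) {
  hits <- gregexpr("(?=ATG)", substring(seq, 1, cds_start), perl = TRUE)[[1]]
  out <- list()
  if (hits[1] != -1) {
    for (s in as.integer(hits) - 1L) {
      pos <- s
      repeat {
        if (pos + 3 > cds_start) break
        codon <- substring(seq, pos + 1, pos + 3)
        if (pos > s && codon %in% c("TAA", "TAG", "TGA")) {
          if (pos + 3 - s >= min_len)
            out[[length(out) + 1]] <- c(s, pos + 3)
          break
        }
        pos <- pos + 3
      }
    }
  }
  if (!length(out)) return(data.table(start = integer(0), end = integer(0)))
  dt <- unique(as.data.table(do.call(rbind, out)))
  setnames(dt, c("start", "end"))
  setorder(dt, start, end)
  dt
}

# Small generated dataset reused by several test files (cached per session).
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "nmdsense_shared_bundle")
      cfg <- sim_config(n_genes = 120, frac_nmd = 0.25, seed = 7)
      cache <<- generate_dataset(cfg, dir)
    }
    cache
  }
})
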