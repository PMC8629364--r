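# SL prefix recognition, trimming, and trans-splicing calls.

sl <- mlig_sl_sequence()

test_that("full and partial SL prefixes are matched and trimmed", {
  m <- match_sl_prefix(paste0(sl, "AAGGTTCC"))
  expect_equal(m$overlap, 35L)
  expect_equal(m$mismatches, 0L)
  expect_equal(m$trimmed_seq, "AAGGTTCC")
  # 12-nt suffix at min_overlap = 12, cross-checked against the
  # try-every-overlap oracle
  read <- paste0(substr(sl, 24, 35), "ACGTACGTACGTACGT")
  m12 <- match_sl_prefix(read, min_overlap = 12L)
  o <- oracle_sl_match(read, sl, 12L)
  expect_equal(m12$overlap, o$overlap)
  expect_equal(m12$overlap, 12L)
  expect_null(match_sl_prefix(strrep("T", 60)))
  expect_error(match_sl_prefix("ACGTXX"), "non-nucleotide")
})

test_that("matcher agrees with the brute-force oracle on noisy reads", {
  set.seed(11)
  for (i in 1:200) {
    ov <- sample(12:35, 1)
    body <- random_seq(40)
    prefix <- substr(sl, 35 - ov + 1, 35)
    # up to 2 random substitutions anywhere in the read
    read <- paste0(prefix, body)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      ch <- strsplit(read, "")[[1]]
      pos <- sample(length(ch), nmut)
      ch[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      read <- paste0(ch, collapse = "")
    }
    got <- match_sl_prefix(read, min_overlap = 12L)
    want <- oracle_sl_match(read, sl, 12L)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$overlap, want$overlap)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("trimming returns the exact transcript prefix at 0 mismatches", {
  set.seed(5)
  for (i in 1:50) {
    ov <- sample(12:35, 1)
    body <- random_seq(50)
    m <- match_sl_prefix(paste0(substr(sl, 35 - ov + 1, 35), body))
    expect_equal(m$trimmed_seq, body)
  }
})

test_that("TS calls follow the window/min_reads rule", {
  g <- make_genes(c("gA", "gB"), c(1000, 5000), c(2000, 6000), "+")
  pl <- data.frame(
    read_id = paste0("r", 1:9),
    scaffold = "chr1",
    strand = c(rep("+", 8), "-"),
    five_prime_pos = c(995, 1000, 1005,      # gA: 3 reads within +/- 10
                       5500, 5510, 5520, 5530, 5540,  # gB: body hits
                       1000))                # opposite strand, ignored
  calls <- call_ts_transcripts(pl, g, window = 10L, min_reads = 2L)
  # counting oracle: gA has 3 concordant starts in [990, 1010]
  expect_equal(unname(calls["gA"]), "TS")
  # 5 placements 500 bp inside the body do not qualify
  expect_equal(unname(calls["gB"]), "nonTS")
  # a single read is below min_reads
  calls1 <- call_ts_transcripts(pl[2, ], g, window = 10L, min_reads = 2L)
  expect_equal(unname(calls1["gA"]), "nonTS")
  # minus-strand gene start is end - 1
  gm <- make_genes("gM", 100, 400, "-")
  plm <- data.frame(read_id = c("a", "b"), scaffold = "chr1",
                    strand = "-", five_prime_pos = c(399, 395))
  expect_equal(unname(call_ts_transcripts(plm, gm)["gM"]), "TS")
  # unknown scaffold placements are skipped with a warning
  plu <- rbind(pl, data.frame(read_id = "rX", scaffold = "chrZ",
                              strand = "+", five_prime_pos = 5))
  expect_warning(call_ts_transcripts(plu, g), "unknown scaffold")
})

test_that("tag_reads round-trips FASTQ and SAM/TSV placements parse", {
  reads <- c(r1 = paste0(sl, "ACGTACGTAAACCC"),
             r2 = strrep("G", 40),
             r3 = paste0(substr(sl, 20, 35), random_seq(30)))
  fq <- tempfile(fileext = ".fastq")
  dna <- Biostrings::DNAStringSet(reads)
  qs <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(strrep("I", nchar(reads))))
  Biostrings::writeQualityScaledXStringSet(qs, fq)
  out <- tempfile(fileext = ".fastq")
  tab <- tag_reads(fq, trimmed_fastq = out)
  expect_setequal(tab$read_id, c("r1", "r3"))
  expect_equal(tab$trimmed_seq[tab$read_id == "r1"], "ACGTACGTAAACCC")
  trimmed <- Biostrings::readDNAStringSet(out, format = "fastq")
  expect_equal(as.character(trimmed[["r1"]]), "ACGTACGTAAACCC")
  # SAM: reverse-strand 5' end sits at the alignment's right edge
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    paste("q1", 0, "chr1", 101, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("q2", 16, "chr1", 201, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t")
  ), sam)
  pl <- read_placements(sam)
  expect_equal(pl$five_prime_pos[pl$read_id == "q1"], 100L)
  expect_equal(pl$strand[pl$read_id == "q2"], "-")
  expect_equal(pl$five_prime_pos[pl$read_id == "q2"], 209L)
})
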