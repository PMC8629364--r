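# Junction windows, Fisher enrichment, shuffling, motif discovery.

test_that("junction windows follow the coordinate contract", {
  set.seed(41)
  chrom <- random_seq(1000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  g <- gene_models("g1", "chr1", "+", 100L, 400L,
                   exons = list(cbind(c(100L, 300L), c(200L, 400L))),
                   ts_status = "TS")
  don <- extract_junction_windows(g, genome, flank = 50L, "cis_donor")
  acc <- extract_junction_windows(g, genome, flank = 50L, "cis_acceptor")
  tra <- extract_junction_windows(g, genome, flank = 50L, "trans_acceptor")
  expect_equal(don$seq, substr(chrom, 151, 250))   # genome[150:250]
  expect_equal(acc$seq, substr(chrom, 251, 350))   # genome[250:350]
  expect_equal(tra$seq, substr(chrom, 51, 150))    # genome[50:150]
  expect_equal(don$junction_at, 50L)
  # minus-strand gene: windows are reverse complements of the mirrored
  # junctions
  gm <- gene_models("g2", "chr1", "-", 100L, 400L,
                    exons = list(cbind(c(100L, 300L), c(200L, 400L))),
                    ts_status = "TS")
  donm <- extract_junction_windows(gm, genome, flank = 50L, "cis_donor")
  expect_equal(donm$seq, revcomp_str(substr(chrom, 251, 350)))
  tram <- extract_junction_windows(gm, genome, flank = 50L, "trans_acceptor")
  expect_equal(tram$seq, revcomp_str(substr(chrom, 351, 450)))
  # single-exon gene has no cis windows; non-TS gene no trans window
  g1ex <- gene_models("g3", "chr1", "+", 500L, 700L, ts_status = "nonTS")
  expect_equal(nrow(extract_junction_windows(g1ex, genome, 50L,
                                             "cis_donor")), 0L)
  expect_equal(nrow(extract_junction_windows(g1ex, genome, 50L,
                                             "trans_acceptor")), 0L)
  # windows clipped at the scaffold edge are dropped with a warning
  edge <- gene_models("g4", "chr1", "+", 10L, 60L, ts_status = "TS")
  expect_warning(
    w <- extract_junction_windows(edge, genome, 50L, "trans_acceptor"),
    "dropped")
  expect_equal(nrow(w), 0L)
})

test_that("fisher_enrichment matches hand-enumerated tables", {
  expect_equal(fisher_enrichment(5, 5, 0, 5), 1 / choose(10, 5))
  expect_gte(fisher_enrichment(3, 10, 3, 10), 0.5)
  expect_equal(fisher_enrichment(0, 10, 5, 10), 1.0)
  expect_error(fisher_enrichment(-1, 5, 0, 5), "negative")
})

test_that("fisher_enrichment equals hypergeometric-tail enumeration", {
  set.seed(53)
  # random tables with total <= 30, plus exhaustive small tables
  for (i in 1:400) {
    pt <- sample(1:15, 1); bt <- sample(0:15, 1)
    pw <- sample(0:pt, 1); bw <- sample(0:max(bt, 1), 1)
    bw <- min(bw, bt)
    expect_equal(fisher_enrichment(pw, pt, bw, bt),
                 oracle_fisher_tail(pw, pt, bw, bt), tolerance = 1e-12)
  }
  for (pt in 1:4) for (bt in 0:4) for (pw in 0:pt) for (bw in 0:bt) {
    expect_equal(fisher_enrichment(pw, pt, bw, bt),
                 oracle_fisher_tail(pw, pt, bw, bt), tolerance = 1e-12)
  }
})

test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  set.seed(61)
  for (i in 1:50) {
    s <- random_seq(sample(10:80, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
})

test_that("planted donor words are recovered with junction positioning", {
  set.seed(71)
  n <- 200L
  win <- vapply(seq_len(n), function(i) {
    s <- random_seq(100)
    if (i <= 0.8 * n) {
      substr(s, 51, 55) <- "GTAAG"   # right of the junction at offset 50
    }
    s
  }, character(1))
  res <- discover_motifs(win, k_range = c(4L, 6L), seed = 9L)
  expect_gt(nrow(res), 0L)
  top <- res[1, ]
  # the top motif matches at least 95 % of the planted sites
  planted <- win[seq_len(0.8 * n)]
  hit <- grepl(gsub("R", "[AG]", top$word), planted)
  expect_gte(mean(hit), 0.95)
  expect_lte(top$e_value, 1e-10)
  expect_equal(top$pos_mode, 50L)
  # reported counts equal an independent containment scan
  rex <- paste0(vapply(strsplit(top$word, "")[[1]], function(ch) {
    exp <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
             S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]")[[ch]]
    exp
  }, ""), collapse = "")
  expect_equal(top$pos_with, sum(grepl(rex, win)))
})

test_that("acceptor-style words left of the junction rank first", {
  set.seed(73)
  n <- 150L
  win <- vapply(seq_len(n), function(i) {
    s <- random_seq(100)
    substr(s, 48, 50) <- "CAG"   # immediately left of the junction
    s
  }, character(1))
  res <- discover_motifs(win, k_range = c(3L, 4L), seed = 2L)
  expect_true(grepl("CAG", res$word[1]))
  # the motif's modal placement ends exactly at the junction (offset 50)
  expect_equal(res$pos_mode[1] + nchar(res$word[1]), 50L)
})

test_that("no motif is reported when positives equal the background", {
  set.seed(79)
  win <- vapply(1:100, function(i) random_seq(60), character(1))
  res <- discover_motifs(win, background = win, k_range = c(3L, 5L),
                         e_cutoff = 0.05, seed = 4L)
  expect_equal(nrow(res), 0L)
})

test_that("k_max larger than the window length errors", {
  expect_error(discover_motifs(c("ACGT", "TTTT"), k_range = c(3L, 8L)),
               "window length")
})
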