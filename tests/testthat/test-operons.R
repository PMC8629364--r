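# Adjacent pairs, repeat-adjusted distances, modes, operon chaining.

test_that("adjacent pairs enumerate same-strand neighbours", {
  g <- make_genes(c("A", "B", "C"), c(0, 300, 900), c(100, 400, 1000), "+")
  p <- adjacent_pairs(g)
  expect_equal(p$upstream_gene, c("A", "B"))
  expect_equal(p$downstream_gene, c("B", "C"))
  expect_equal(p$raw_distance, c(200L, 500L))
})

test_that("opposite-strand genes interrupt a pair", {
  g <- make_genes(c("A", "X", "B"), c(0, 150, 300), c(100, 250, 400),
                  c("+", "-", "+"))
  p <- adjacent_pairs(g)
  expect_equal(nrow(p), 0L)
})

test_that("strand reversal swaps upstream/downstream", {
  g <- make_genes(c("B", "A"), c(0, 300), c(100, 400), "-")
  p <- adjacent_pairs(g)
  expect_equal(p$upstream_gene, "A")   # rightmost transcribes first
  expect_equal(p$downstream_gene, "B")
  expect_equal(p$raw_distance, 200L)
})

test_that("nested genes are skipped; overlapping neighbours get distance 0", {
  g <- make_genes(c("big", "inner", "next"), c(0, 100, 1200),
                  c(1000, 200, 1500), "+")
  p <- adjacent_pairs(g)
  expect_equal(p$upstream_gene, "big")
  expect_equal(p$downstream_gene, "next")
  g2 <- make_genes(c("a", "b"), c(0, 80), c(100, 300), "+")
  expect_equal(adjacent_pairs(g2)$raw_distance, 0L)
})

test_that("repeat-adjusted distance matches the worked interval example", {
  pairs <- data.frame(upstream_gene = "u", downstream_gene = "d",
                      scaffold = "chr1", strand = "+",
                      gap_start = 100L, gap_end = 600L,
                      raw_distance = 500L, category = "TS->TS")
  reps <- parse_repeat_track(local({
    f <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t50\t200", "chr1\t150\t350", "chr1\t550\t700"), f)
    f
  }))
  adj <- repeat_adjusted_distances(pairs, reps)
  # union covers [100,350) + [550,600) = 300 of the 500 bp interval
  expect_equal(adj$adjusted_distance, 200L)
  expect_equal(repeat_adjusted_distances(pairs, NULL)$adjusted_distance, 500L)
  all_rep <- repeat_track("chr1", 0, 10000)
  expect_equal(repeat_adjusted_distances(pairs, all_rep)$adjusted_distance, 0L)
})

test_that("repeat adjustment equals the per-base boolean-array oracle", {
  set.seed(77)
  for (i in 1:1000) {
    gs <- sample(0:2000, 1)
    ge <- gs + sample(0:800, 1)
    nr <- sample(0:6, 1)
    rs <- sample(0:2500, nr, replace = TRUE)
    rl <- sample(1:500, nr, replace = TRUE)
    pairs <- data.frame(upstream_gene = "u", downstream_gene = "d",
                        scaffold = "chr1", strand = "+",
                        gap_start = gs, gap_end = ge,
                        raw_distance = max(0L, ge - gs),
                        category = "TS->TS")
    reps <- if (nr > 0) repeat_track("chr1", rs, rs + rl) else NULL
    got <- repeat_adjusted_distances(pairs, reps)$adjusted_distance
    want <- oracle_adjusted_distance(gs, ge, rs, rs + rl)
    expect_equal(got, want)
  }
})

test_that("mode detection recovers a planted bimodal gap distribution", {
  set.seed(3)
  d <- c(round(stats::rlnorm(500, log(100), 0.4)),
         round(stats::rlnorm(500, log(5000), 0.4)))
  pairs <- data.frame(category = "TS->TS", adjusted_distance = d,
                      raw_distance = d)
  dist <- distance_distributions(pairs)[[1]]
  expect_gte(length(dist$modes), 2)
  expect_true(dist$modes[1] >= 50 && dist$modes[1] <= 200)
  expect_true(dist$valley >= 300 && dist$valley <= 3000)
  # degenerate cases
  same <- data.frame(category = "TS->TS", adjusted_distance = rep(100L, 20),
                     raw_distance = rep(100L, 20))
  ds <- distance_distributions(same)[[1]]
  expect_equal(ds$modes, 100L)
  empty <- data.frame(category = character(0),
                      adjusted_distance = integer(0),
                      raw_distance = integer(0))
  de <- distance_distributions(empty)[[1]]
  expect_length(de$modes, 0)
  expect_null(de$valley)
})

test_that("operon chaining follows the downstream-TS rule", {
  # TS-TS at distance 100 links
  g <- make_genes(c("a", "b"), c(0, 200), c(100, 300), "+", ts = "TS")
  op <- call_operons(g, threshold = 1000L)
  expect_equal(nrow(op), 1L)
  expect_equal(op$size, 2L)
  # nonTS,TS,TS chains with starts_nonTS
  g3 <- make_genes(c("a", "b", "c"), c(0, 300, 700), c(100, 400, 800), "+",
                   ts = c("nonTS", "TS", "TS"))
  op3 <- call_operons(g3, threshold = 1000L)
  expect_equal(op3$size, 3L)
  expect_true(op3$starts_nonTS)
  expect_equal(op3$genes, "a,b,c")
  # TS,nonTS does not link (downstream must be TS)
  g2 <- make_genes(c("a", "b"), c(0, 150), c(100, 250), "+",
                   ts = c("TS", "nonTS"))
  expect_equal(nrow(call_operons(g2, threshold = 1000L)), 0L)
  # distances at/above threshold do not link
  far <- make_genes(c("a", "b"), c(0, 1100), c(100, 1300), "+", ts = "TS")
  expect_equal(nrow(call_operons(far, threshold = 1000L)), 0L)
  # missing ts_map entries warn and count as nonTS
  expect_warning(
    call_operons(g, ts_map = c(a = "TS"), threshold = 1000L),
    "missing")
})

test_that("operon membership is invariant under scaffold mirror reversal", {
  set.seed(21)
  L <- 100000L
  n <- 40L
  starts <- sort(sample(seq(0, L - 2000, by = 1500), n))
  ends <- starts + sample(200:800, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ts <- sample(c("TS", "nonTS"), n, replace = TRUE, prob = c(0.6, 0.4))
  ids <- sprintf("g%02d", 1:n)
  g <- make_genes(ids, starts, ends, strands, ts = ts)
  gm <- gene_models(ids, "chr1", ifelse(strands == "+", "-", "+"),
                    L - ends, L - starts, ts_status = ts)
  op1 <- call_operons(g, threshold = 1000L)
  op2 <- call_operons(gm, threshold = 1000L)
  # transcription order is a strand-intrinsic property, so mirroring the
  # scaffold leaves each operon's gene list unchanged
  expect_setequal(op1$genes, op2$genes)
  expect_equal(sort(op1$size), sort(op2$size))
  expect_equal(sort(op1$span_length), sort(op2$span_length))
})

test_that("raising the threshold never removes genes from operons", {
  set.seed(33)
  n <- 60L
  starts <- cumsum(sample(c(100:300, 1000:3000), n, replace = TRUE)) * 2L
  ends <- starts + 150L
  g <- make_genes(sprintf("g%02d", 1:n), starts, ends, "+",
                  ts = sample(c("TS", "nonTS"), n, TRUE, prob = c(.7, .3)))
  counts <- vapply(c(200L, 500L, 1000L, 2000L, 5000L), function(th) {
    sum(call_operons(g, threshold = th)$size)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("operon summaries tally sizes and fractions", {
  ops <- data.frame(operon_id = sprintf("o%d", 1:4), scaffold = "c",
                    strand = "+",
                    genes = c("a,b", "c,d", "e,f", "g,h,i"),
                    size = c(2L, 2L, 2L, 3L),
                    span_length = c(500L, 600L, 700L, 1500L),
                    starts_nonTS = c(FALSE, TRUE, FALSE, FALSE))
  s <- operon_summary(ops, ts_map = c(rep("TS", 10), rep("nonTS", 5)),
                      n_genes_total = 30L)
  expect_equal(as.integer(s$size_hist), c(3L, 1L))
  expect_equal(s$genes_in_operons, 9L)
  expect_equal(s$nonts_starts, 1L)
  expect_equal(s$pct_ts_genes_in_operons, pct_fraction(8, 10, 1))
  empty <- operon_summary(ops[0, ])
  expect_equal(empty$genes_in_operons, 0L)
})
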