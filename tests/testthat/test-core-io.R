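# Coordinate conventions, annotation parsing, label attachment.

test_that("GFF3 coordinates convert to 0-based half-open and sort by start", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t501\t700\t.\t+\t.\tID=gB",
    "chr1\tsrc\texon\t501\t700\t.\t+\t.\tParent=gB",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=gA"
  ), gff)
  g <- read_gene_annotation(gff, dialect = "gff3")
  expect_equal(g$gene_id, c("gA", "gB"))     # sorted despite file order
  expect_equal(g$start, c(100L, 500L))       # 1-based inclusive -> 0-based
  expect_equal(g$end, c(200L, 700L))
  # conversion property: internal width == on-disk (end - start + 1)
  expect_equal(g$end - g$start, c(200L - 101L + 1L, 700L - 501L + 1L))
})

test_that("BED12 is taken as already 0-based half-open, with exon blocks", {
  bed <- tempfile(fileext = ".bed")
  writeLines(paste(
    "chr1", 100, 400, "gX", 0, "+", 100, 400, "0", 2,
    "50,100", "0,200", sep = "\t"), bed)
  g <- read_gene_annotation(bed, dialect = "bed12")
  expect_equal(g$start, 100L)
  expect_equal(g$end, 400L)
  ex <- g$exons[[1]]
  expect_equal(unname(ex[, "start"]), c(100L, 300L))
  expect_equal(unname(ex[, "end"]), c(150L, 400L))
})

test_that("malformed annotation records are rejected with a line number", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101"), gff)
  expect_error(read_gene_annotation(gff, dialect = "gff3"), "line 2")
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\tabc\t200\t.\t+\t.\tID=g"), bad)
  expect_error(read_gene_annotation(bad, dialect = "gff3"), "line 2")
})

test_that("gene models round-trip through GFF3", {
  g <- gene_models(
    gene_id = c("a", "b"), scaffold = "chr2", strand = c("+", "-"),
    start = c(10L, 500L), end = c(400L, 900L),
    exons = list(cbind(c(10L, 200L), c(100L, 400L)),
                 cbind(c(500L, 700L), c(600L, 900L))))
  path <- tempfile(fileext = ".gff3")
  write_gene_gff3(g, path)
  g2 <- read_gene_annotation(path, dialect = "gff3")
  expect_equal(g2$gene_id, g$gene_id)
  expect_equal(g2$start, g$start)
  expect_equal(g2$end, g$end)
  expect_equal(g2$strand, g$strand)
  for (i in seq_len(nrow(g))) {
    expect_equal(unname(g2$exons[[i]]), unname(g$exons[[i]]))
  }
})

test_that("gene model invariants are enforced", {
  expect_error(gene_models("a", "c", "+", 10, 10), "start < end")
  expect_error(gene_models("a", "c", "*", 10, 20), "strand")
  expect_error(gene_models(c("a", "a"), "c", "+", c(1, 50), c(20, 90)),
               "duplicate")
  expect_error(
    gene_models("a", "c", "+", 10, 100,
                exons = list(cbind(c(10, 40), c(50, 80)))),
    "overlapping")
})

test_that("repeat tracks parse without merging and honor conventions", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t15\t30"), bed)
  r <- parse_repeat_track(bed)
  expect_equal(nrow(r), 2L)                  # overlapping kept as-is
  expect_equal(r$start, c(10L, 15L))
  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_repeat_track(empty)), 0L)
  # RepeatMasker .out rows are 1-based inclusive
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query",
    "score  div. del. ins.  sequence  begin  end",
    "",
    "  463  1.3  0.6  1.7  chr1  101  200  (0) + AluY SINE/Alu 1 100 (0) 1"
  ), out)
  r2 <- parse_repeat_track(out)
  expect_equal(r2$start, 100L)
  expect_equal(r2$end, 200L)
})

test_that("labels attach by gene_id; unmatched rows are reported", {
  g <- make_genes(c("g1", "g2"), c(0, 500), c(100, 900), "+")
  lab <- data.frame(gene_id = c("g1", "g9"), ts_status = c("TS", "nonTS"),
                    cons_class = c("conserved", "non-coding"),
                    cell_label = c("neoblast", "none"))
  expect_message(g2 <- attach_labels(g, lab), "g9")
  expect_equal(g2$ts_status, c("TS", "unknown"))
  expect_equal(g2$cell_label, c("neoblast", "none"))
  expect_equal(attr(g2, "unmatched_labels"), "g9")
  # empty label table leaves genes unchanged
  g3 <- attach_labels(g, lab[0, ])
  expect_equal(g3$ts_status, g$ts_status)
  # duplicate gene ids are an error
  expect_error(attach_labels(g, lab[c(1, 1), ]), "duplicate")
})
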