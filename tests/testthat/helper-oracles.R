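# Independent oracles and tiny fixture builders used across the suite.
# Oracles are deliberately naive (per-base arrays, exhaustive recursion,
# direct combinatorial sums) so they share no code path with the
# implementation they check.

# per-base boolean-array coverage oracle for repeat-adjusted distances
oracle_adjusted_distance <- function(gap_start, gap_end, rep_starts,
                                     rep_ends) {
  raw <- max(0L, gap_end - gap_start)
  if (raw == 0L) return(0L)
  covered <- rep(FALSE, raw)
  for (i in seq_along(rep_starts)) {
    lo <- max(rep_starts[i], gap_start)
    hi <- min(rep_ends[i], gap_end)
    if (hi > lo) covered[(lo - gap_start + 1L):(hi - gap_start)] <- TRUE
  }
  raw - sum(covered)
}

# exhaustive enumeration of nested structures: maximum pair count
oracle_max_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + 1L, j)) {
      if (k - i <= min_loop) next
      if (ok(s[i], s[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(s))
}

# hypergeometric upper-tail by direct combinatorial summation
oracle_fisher_tail <- function(pos_with, pos_total, bg_with, bg_total) {
  K <- pos_with + bg_with
  N <- pos_total + bg_total
  n <- pos_total
  xs <- seq(pos_with, min(K, n))
  xs <- xs[(n - xs) <= (N - K)]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# brute-force SL suffix matcher: try every overlap, keep the longest
oracle_sl_match <- function(read, sl, min_overlap, mm_per12 = 1L) {
  L <- nchar(sl)
  best <- NULL
  for (ov in seq(min_overlap, min(L, nchar(read)))) {
    a <- strsplit(substr(sl, L - ov + 1L, L), "")[[1]]
    b <- strsplit(substr(read, 1L, ov), "")[[1]]
    mm <- sum(a != b)
    if (mm <= (ov %/% 12L) * mm_per12) best <- list(overlap = ov,
                                                    mismatches = mm)
  }
  best
}

# quick gene-table builder: one scaffold, single-exon genes
make_genes <- function(ids, starts, ends, strands, scaffold = "chr1",
                       ts = "unknown") {
  gene_models(ids, scaffold, strands, starts, ends, ts_status = ts)
}

# independent reverse complement (no package code)
revcomp_str <- function(x) {
  paste0(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
         collapse = "")
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# gene-level operon membership F1 against a truth table
operon_f1 <- function(operons, truth_genes) {
  pred <- unlist(strsplit(operons$genes, ","))
  tru <- truth_genes$gene_id[!is.na(truth_genes$operon_id) &
                               truth_genes$operon_id != "NA"]
  tp <- length(intersect(pred, tru))
  fp <- length(setdiff(pred, tru))
  fn <- length(setdiff(tru, pred))
  2 * tp / (2 * tp + fp + fn)
}

# shared small synthetic dataset, generated once per test run
synth_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "sloperon_small")
      cache <<- generate_dataset(
        synth_config(seed = 101, n_scaffolds = 4, n_genes = 300), dir)
    }
    cache
  }
})
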