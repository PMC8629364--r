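# SL tagging: recognize the spliced-leader sequence at read 5' ends,
# trim it, and call genes trans-spliced when enough trimmed-read 5' ends
# pile up at an annotated transcription start.

#' Match a spliced-leader suffix at a read 5' end
#'
#' Finds the longest suffix of the SL sequence (length `>= min_overlap`)
#' that aligns ungapped to the read prefix with at most
#' `floor(overlap / 12) * max_mismatch_per_12nt` mismatches. An `N` in
#' either sequence counts as a mismatch.
#'
#' @param read_seq Read sequence (ACGTN).
#' @param sl_seq SL sequence; default [mlig_sl_sequence()].
#' @param min_overlap Minimum matched SL suffix length (default 12 nt,
#'   keeping the random-match rate near 4^-12).
#' @param max_mismatch_per_12nt Mismatches tolerated per 12 matched nt
#'   (default 1).
#' @return A list with `overlap`, `mismatches`, `trimmed_seq`, or `NULL`
#'   if no qualifying overlap exists.
#' @export
#' @examples
#' sl <- mlig_sl_sequence()
#' match_sl_prefix(paste0(sl, "AAGGTT"))$overlap  # 35
match_sl_prefix <- function(read_seq, sl_seq = mlig_sl_sequence(),
                            min_overlap = 12L, max_mismatch_per_12nt = 1L) {
  if (nchar(sl_seq) == 0L) stop("sl_seq must be non-empty")
  if (min_overlap > nchar(sl_seq)) stop("min_overlap exceeds SL length")
  assert_nucleotides(read_seq, what = "read")
  assert_nucleotides(sl_seq, what = "SL sequence")
  read_seq <- toupper(read_seq); sl_seq <- toupper(sl_seq)
  L <- nchar(sl_seq)
  rchars <- strsplit(read_seq, "")[[1]]
  schars <- strsplit(sl_seq, "")[[1]]
  top <- min(L, length(rchars))
  if (top < min_overlap) return(NULL)
  for (ov in seq(top, min_overlap)) {
    suff <- schars[(L - ov + 1L):L]
    pref <- rchars[1:ov]
    mm <- sum(suff != pref | suff == "N" | pref == "N")
    if (mm <= (ov %/% 12L) * max_mismatch_per_12nt) {
      return(list(overlap = ov, mismatches = mm,
                  trimmed_seq = substr(read_seq, ov + 1L, nchar(read_seq))))
    }
  }
  NULL
}

#' Tag and trim SL-containing reads
#'
#' Applies [match_sl_prefix()] to every read in a FASTQ file (or named
#' character vector) and optionally writes the trimmed SL-positive reads
#' back out as FASTQ.
#'
#' @param reads FASTQ path or named character vector of read sequences.
#' @param sl_seq,min_overlap,max_mismatch_per_12nt See [match_sl_prefix()].
#' @param trimmed_fastq Optional output path for trimmed SL reads.
#' @return A data.frame `read_id`/`sl_overlap`/`mismatches`/`trimmed_seq`
#'   with one row per SL-positive read.
#' @export
tag_reads <- function(reads, sl_seq = mlig_sl_sequence(), min_overlap = 12L,
                      max_mismatch_per_12nt = 1L, trimmed_fastq = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
  } else {
    seqs <- reads
    if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  }
  hits <- lapply(seqs, match_sl_prefix, sl_seq = sl_seq,
                 min_overlap = min_overlap,
                 max_mismatch_per_12nt = max_mismatch_per_12nt)
  keep <- !vapply(hits, is.null, logical(1))
  out <- data.frame(
    read_id = names(seqs)[keep],
    sl_overlap = vapply(hits[keep], `[[`, integer(1), "overlap"),
    mismatches = vapply(hits[keep], `[[`, integer(1), "mismatches"),
    trimmed_seq = vapply(hits[keep], `[[`, character(1), "trimmed_seq"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(trimmed_fastq)) {
    trimmed <- out[nchar(out$trimmed_seq) > 0L, ]
    dna <- Biostrings::DNAStringSet(trimmed$trimmed_seq)
    names(dna) <- trimmed$read_id
    qual <- Biostrings::PhredQuality(strrep("I", nchar(trimmed$trimmed_seq)))
    qss <- Biostrings::QualityScaledDNAStringSet(dna, qual)
    Biostrings::writeQualityScaledXStringSet(qss, trimmed_fastq)
  }
  out
}

#' Read trimmed-read 5'-end placements
#'
#' Accepts either a 4-column TSV (`read_id  scaffold  strand
#' five_prime_pos`, 0-based) or a minimal text SAM (QNAME/FLAG/RNAME/POS;
#' reverse-strand reads additionally need the SEQ field so the 5' end can
#' be placed at the alignment's right edge).
#'
#' @param path Placement file path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"sam"`.
#' @return A data.frame `read_id`/`scaffold`/`strand`/`five_prime_pos`.
#' @export
read_placements <- function(path, format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "scaffold", "strand", "five_prime_pos")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) stop("placement TSV missing column(s): ",
                               paste(miss, collapse = ", "))
    tab$five_prime_pos <- as.integer(tab$five_prime_pos)
    if (any(tab$five_prime_pos < 0L)) stop("negative five_prime_pos")
    return(tab[need])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4) stop("malformed SAM record at line ", i)
    flag <- as.integer(f[2]); pos <- as.integer(f[4])
    if (is.na(flag) || is.na(pos)) stop("malformed SAM record at line ", i)
    rev <- bitwAnd(flag, 16L) != 0L
    if (bitwAnd(flag, 4L) != 0L) return(NULL)   # unmapped
    p5 <- if (!rev) pos - 1L else {
      if (length(f) < 10 || f[10] == "*") {
        stop("reverse-strand SAM record at line ", i,
             " lacks SEQ; cannot place 5' end")
      }
      pos - 1L + nchar(f[10]) - 1L
    }
    data.frame(read_id = f[1], scaffold = f[3],
               strand = if (rev) "-" else "+",
               five_prime_pos = p5, stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Call SL trans-spliced transcripts from read placements
#'
#' A gene is called `TS` iff at least `min_reads` strand-concordant
#' placements have their 5' end within `window` nt of the gene's
#' annotated transcription start (`start` for `+` genes, `end - 1` for
#' `-` genes); all other genes are `nonTS`.
#'
#' @param placements Data.frame from [read_placements()] (typically
#'   restricted to SL-tagged reads).
#' @param genes A `gene_models` data.frame.
#' @param window Half-width of the acceptance window around the start
#'   (default 10 nt).
#' @param min_reads Minimum supporting reads (default 2, so a single
#'   spurious placement cannot flip a call).
#' @return Named character vector gene_id -> `"TS"`/`"nonTS"`.
#' @export
call_ts_transcripts <- function(placements, genes, window = 10L,
                                min_reads = 2L) {
  stopifnot(window >= 0L, min_reads >= 1L)
  known <- placements$scaffold %in% unique(genes$scaffold)
  if (any(!known)) {
    warning(sum(!known), " placement(s) on unknown scaffolds skipped")
    placements <- placements[known, , drop = FALSE]
  }
  calls <- stats::setNames(rep("nonTS", nrow(genes)), genes$gene_id)
  tss <- gene_tss(genes)
  key_g <- paste(genes$scaffold, genes$strand)
  by_key <- split(placements$five_prime_pos,
                  paste(placements$scaffold, placements$strand))
  for (k in names(by_key)) {
    pos <- sort(by_key[[k]])
    gi <- which(key_g == k)
    if (length(gi) == 0) next
    lo <- findInterval(tss[gi] - window - 1L, pos)
    hi <- findInterval(tss[gi] + window, pos)
    calls[gi][hi - lo >= min_reads] <- "TS"
  }
  calls
}

#' Write trans-splicing calls as TSV
#'
#' @param calls Named vector from [call_ts_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ts_calls <- function(calls, path) {
  tab <- data.frame(gene_id = names(calls), ts_status = unname(calls))
  tab <- tab[order(tab$gene_id), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
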