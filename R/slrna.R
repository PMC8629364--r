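# SL RNA gene discovery: exact seed search on both strands, followed by
# donor-site, Sm-site and hairpin-architecture validation. The structural
# check is a base-pair-maximization fold (Nussinov dynamic programming
# over Watson-Crick + GU pairs with a minimum hairpin loop); the
# rule for accepting a candidate is topological - at least three
# hairpin loops - not energetic.

PAIRABLE <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                           c("A", "C", "G", "U")))
  for (p in list(c("A", "U"), c("G", "C"), c("G", "U"))) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
})

#' Maximum base-pair fold of an RNA sequence
#'
#' Computes the maximum number of nested Watson-Crick + GU base pairs
#' with hairpin loops of at least `min_loop` unpaired nucleotides, by
#' Nussinov-style dynamic programming with a deterministic traceback
#' (at ties, leaving a base unpaired is preferred, then the smallest
#' pairing partner).
#'
#' @param seq RNA (or DNA; T is read as U) sequence.
#' @param min_loop Minimum number of nucleotides between the two bases of
#'   a pair (default 3, the steric minimum).
#' @return A list with `pairs` (integer count) and `structure`
#'   (dot-bracket string).
#' @export
#' @examples
#' fold_max_pairs("GGGAAACCC")$structure  # "(((...)))"
fold_max_pairs <- function(seq, min_loop = 3L) {
  stopifnot(nchar(seq) >= 1L, min_loop >= 0L)
  assert_nucleotides(seq, allow_n = FALSE, what = "fold input")
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(s)
  code <- match(s, c("A", "C", "G", "U"))
  N <- matrix(0L, n, n)
  val <- function(i, j) if (i > j || i > n || j < 1) 0L else N[i, j]
  if (n >= 2) {
    for (span in seq_len(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- if (i + 1L <= j) N[i + 1L, j] else 0L
        ks <- seq.int(i + min_loop + 1L, j)
        ks <- ks[ks <= j & ks >= i + min_loop + 1L]
        if (length(ks) > 0) {
          ok <- PAIRABLE[cbind(code[i], code[ks])]
          ks <- ks[ok]
          if (length(ks) > 0) {
            inner <- vapply(ks, function(k) {
              (if (i + 1L <= k - 1L) N[i + 1L, k - 1L] else 0L) + 1L +
                (if (k + 1L <= j) N[k + 1L, j] else 0L)
            }, integer(1))
            best <- max(best, inner)
          }
        }
        N[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  # iterative traceback with an explicit stack
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j) next
    if (N[i, j] == N[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    found <- FALSE
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (!PAIRABLE[code[i], code[k]]) next
      left <- if (i + 1L <= k - 1L) N[i + 1L, k - 1L] else 0L
      right <- if (k + 1L <= j) N[k + 1L, j] else 0L
      if (left + 1L + right == N[i, j]) {
        db[i] <- "("; db[k] <- ")"
        stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        found <- TRUE
        break
      }
    }
    if (!found) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  list(pairs = N[1, n] + 0L, structure = paste0(db, collapse = ""))
}

#' Count hairpin loops in a dot-bracket structure
#'
#' A hairpin loop is a base pair enclosing only unpaired positions.
#'
#' @param structure Well-formed dot-bracket string.
#' @return Integer hairpin count.
#' @export
#' @examples
#' count_hairpins("((..))..((...))")  # 2
count_hairpins <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop("structure contains characters other than '(', ')', '.'")
  }
  depth <- 0L; hairpins <- 0L; last_open <- FALSE
  for (ch in chars) {
    if (ch == "(") {
      depth <- depth + 1L
      last_open <- TRUE
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced dot-bracket structure")
      if (last_open) hairpins <- hairpins + 1L
      last_open <- FALSE
    }
  }
  if (depth != 0L) stop("unbalanced dot-bracket structure")
  hairpins
}

#' Find exact SL-seed occurrences in a genome
#'
#' Reports every exact occurrence of the SL sequence on either strand
#' (the minus strand is scanned with the reverse complement); overlapping
#' occurrences are all reported.
#'
#' @param genome A named `DNAStringSet` or FASTA path.
#' @param sl_seq Seed sequence (>= 8 nt).
#' @return A data.frame `scaffold`/`strand`/`seed_start` where
#'   `seed_start` is the 0-based forward-strand coordinate of the
#'   leftmost base of the matched interval.
#' @export
find_sl_seed_hits <- function(genome, sl_seq = mlig_sl_sequence()) {
  stopifnot(nchar(sl_seq) >= 8L)
  genome <- load_genome(genome)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") sl_seq else revcomp(sl_seq)
    m <- Biostrings::vmatchPattern(pat, genome)
    for (i in seq_along(m)) {
      ir <- m[[i]]
      if (length(ir) == 0) next
      hits[[length(hits) + 1L]] <- data.frame(
        scaffold = names(genome)[i], strand = strand,
        seed_start = IRanges::start(ir) - 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(scaffold = character(0), strand = character(0),
                      seed_start = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  res <- res[order(res$scaffold, res$seed_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  genome
}

#' Call SL RNA gene candidates
#'
#' For each exact seed hit, extracts the candidate sequence (seed start
#' through `candidate_length` in transcription orientation), checks for
#' the donor splice site immediately 3' of the seed, searches for an
#' Sm-binding-site word 3' of the donor, folds the candidate and counts
#' hairpin loops. A candidate is accepted iff the donor matches, an Sm
#' site is present, at least `min_hairpins` hairpins form, and - when an
#' annotation is supplied - the seed does not sit at the annotated 5'
#' end of a trans-spliced protein-coding gene (within `tss_window` bp),
#' which flags mRNA 5' ends masquerading as SL RNA loci.
#'
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param sl_seq SL seed sequence.
#' @param candidate_length Candidate gene length from the seed start
#'   (default 109 nt, the expected SL RNA gene size).
#' @param donor_pattern IUPAC donor-site pattern (default `"GTAAG"`;
#'   `"GTRAG"` matches the genome-wide donor consensus).
#' @param sm_pattern IUPAC Sm-site pattern over RNA letters (default
#'   `"RAUUUUNGR"`, a literature-standard Sm consensus; a package
#'   default, configurable).
#' @param min_hairpins Minimum hairpin loops (default 3).
#' @param genes Optional `gene_models` table for the coding-5'-end
#'   rejection.
#' @param tss_window Distance to a TS gene start that triggers rejection
#'   (default 50 bp).
#' @param min_loop Fold hairpin-loop minimum (default 3).
#' @return A data.frame with one row per seed hit: coordinates,
#'   `candidate_seq`, `donor_ok`, `sm_offset`, `sm_match`, `structure`,
#'   `hairpin_count`, `accepted`, `reason`.
#' @export
call_slrna_genes <- function(genome, sl_seq = mlig_sl_sequence(),
                             candidate_length = 109L,
                             donor_pattern = "GTAAG",
                             sm_pattern = "RAUUUUNGR",
                             min_hairpins = 3L, genes = NULL,
                             tss_window = 50L, min_loop = 3L) {
  stopifnot(candidate_length >= nchar(sl_seq) + 10L)
  genome <- load_genome(genome)
  hits <- find_sl_seed_hits(genome, sl_seq)
  slen <- nchar(sl_seq)
  ts_tss <- NULL
  if (!is.null(genes)) {
    ts <- genes[genes$ts_status == "TS", , drop = FALSE]
    ts_tss <- data.frame(scaffold = ts$scaffold, strand = ts$strand,
                         tss = gene_tss(ts), stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    chrom <- genome[[h$scaffold]]
    clen <- length(chrom)
    truncated <- FALSE
    if (h$strand == "+") {
      from <- h$seed_start + 1L
      to <- h$seed_start + candidate_length
      if (to > clen) { to <- clen; truncated <- TRUE }
      cand <- as.character(Biostrings::subseq(chrom, from, to))
      seed5 <- h$seed_start
    } else {
      to <- h$seed_start + slen
      from <- to - candidate_length + 1L
      if (from < 1L) { from <- 1L; truncated <- TRUE }
      cand <- revcomp(as.character(Biostrings::subseq(chrom, from, to)))
      seed5 <- h$seed_start + slen - 1L
    }
    if (truncated) {
      warning("candidate at ", h$scaffold, ":", h$seed_start,
              " truncated at scaffold end")
    }
    donor_ok <- iupac_match_at(cand, donor_pattern, slen + 1L)
    sm_region_start <- slen + nchar(donor_pattern) + 1L
    sm <- if (sm_region_start <= nchar(cand)) {
      iupac_find_first(substr(cand, sm_region_start, nchar(cand)), sm_pattern)
    } else NULL
    fold <- fold_max_pairs(cand, min_loop = min_loop)
    hp <- count_hairpins(fold$structure)
    near_tss <- FALSE
    if (!is.null(ts_tss) && nrow(ts_tss) > 0) {
      near_tss <- any(ts_tss$scaffold == h$scaffold &
                        ts_tss$strand == h$strand &
                        abs(ts_tss$tss - seed5) <= tss_window)
    }
    reason <- if (near_tss) "coding 5' end"
      else if (!donor_ok) "no donor site"
      else if (is.null(sm)) "no Sm site"
      else if (hp < min_hairpins) "too few hairpins"
      else "accepted"
    data.frame(
      scaffold = h$scaffold, strand = h$strand, seed_start = h$seed_start,
      candidate_seq = cand, donor_ok = donor_ok,
      sm_offset = if (is.null(sm)) NA_integer_ else
        sm_region_start + sm$start - 2L,       # 0-based within candidate
      sm_match = if (is.null(sm)) NA_character_ else sm$match,
      structure = fold$structure, hairpin_count = hp,
      accepted = reason == "accepted", reason = reason,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0) {
    return(data.frame(scaffold = character(0), strand = character(0),
                      seed_start = integer(0), candidate_seq = character(0),
                      donor_ok = logical(0), sm_offset = integer(0),
                      sm_match = character(0), structure = character(0),
                      hairpin_count = integer(0), accepted = logical(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
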