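# Junction-window extraction and discriminative motif discovery: exact
# k-mer enumeration scored with a one-sided Fisher exact test on
# sequence-containment counts, Bonferroni correction over the words
# tested, and greedy one-position IUPAC generalization - a deliberately
# small search in the spirit of discriminative tools like DREME.

SITE_TYPES <- c("cis_donor", "cis_acceptor", "trans_acceptor")

#' Extract splice-junction windows
#'
#' Retrieves genomic windows of `2 * flank` nt centered on splice
#' junctions, normalized to forward-transcription orientation (the
#' transcript's 5'->3' reads left to right; minus-strand genes are
#' reverse-complemented). `cis_donor` windows are centered on each
#' exon->intron boundary, `cis_acceptor` on each intron->exon boundary,
#' and `trans_acceptor` on the first-exon 5' boundary of trans-spliced
#' genes (outron upstream). Windows that would extend past a scaffold
#' edge are dropped with a warning.
#'
#' @param genes A `gene_models` data.frame.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param flank Flank size on each side of the junction (default 50).
#' @param site_type One of `"cis_donor"`, `"cis_acceptor"`,
#'   `"trans_acceptor"`.
#' @return A data.frame `site_type`/`gene_id`/`scaffold`/`strand`/
#'   `center` (0-based forward junction coordinate)/`seq`/`junction_at`
#'   (offset of the junction within `seq`, = `flank`).
#' @export
extract_junction_windows <- function(genes, genome, flank = 50L,
                                     site_type = SITE_TYPES) {
  site_type <- match.arg(site_type, SITE_TYPES)
  stopifnot(flank >= 1L)
  genome <- load_genome(genome)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    nex <- nrow(ex)
    centers <- switch(site_type,
      cis_donor = if (nex < 2) integer(0) else
        if (g$strand == "+") ex[-nex, 2] else ex[-1, 1],
      cis_acceptor = if (nex < 2) integer(0) else
        if (g$strand == "+") ex[-1, 1] else ex[-nex, 2],
      trans_acceptor = {
        if (g$ts_status != "TS") integer(0)
        else if (g$strand == "+") ex[1, 1] else ex[nex, 2]
      }
    )
    if (length(centers) == 0) next
    clen <- length(genome[[g$scaffold]])
    for (ct in centers) {
      lo <- ct - flank; hi <- ct + flank
      if (lo < 0L || hi > clen) { dropped <- dropped + 1L; next }
      s <- as.character(Biostrings::subseq(genome[[g$scaffold]],
                                           lo + 1L, hi))
      if (g$strand == "-") s <- revcomp(s)
      rows[[length(rows) + 1L]] <- data.frame(
        site_type = site_type, gene_id = g$gene_id, scaffold = g$scaffold,
        strand = g$strand, center = ct, seq = s, junction_at = flank,
        stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0) {
    warning(dropped, " window(s) clipped at scaffold edges were dropped")
  }
  if (length(rows) == 0) {
    return(data.frame(site_type = character(0), gene_id = character(0),
                      scaffold = character(0), strand = character(0),
                      center = integer(0), seq = character(0),
                      junction_at = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' One-sided Fisher exact enrichment p-value
#'
#' Upper-tail (enrichment) p-value from the 2x2 table of sequences
#' containing / not containing a word in a positive versus a background
#' set, computed from the hypergeometric distribution.
#'
#' @param pos_with,pos_total Positive-set counts.
#' @param bg_with,bg_total Background-set counts.
#' @return The p-value (vectorized over the arguments).
#' @export
#' @examples
#' fisher_enrichment(5, 5, 0, 5)  # 1/choose(10, 5) = 1/252
fisher_enrichment <- function(pos_with, pos_total, bg_with, bg_total) {
  if (any(c(pos_with, pos_total, bg_with, bg_total) < 0)) {
    stop("negative counts")
  }
  stopifnot(all(pos_with <= pos_total), all(bg_with <= bg_total))
  stats::phyper(pos_with - 1, pos_with + bg_with,
                (pos_total - pos_with) + (bg_total - bg_with),
                pos_total, lower.tail = FALSE)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Randomizes a sequence while preserving its exact dinucleotide
#' multiset (Altschul-Erikson Eulerian-path shuffle), the standard way
#' to build motif-search backgrounds.
#'
#' @param seq Nucleotide string.
#' @return A shuffled string with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n <= 2L) return(seq)
  verts <- unique(chars)
  if (length(verts) == 1L) return(seq)
  last <- chars[n]
  # edge list: from chars[i] to chars[i+1]
  edges <- split(chars[-1], chars[-n])
  repeat {
    # choose a random terminal edge for every vertex except the last
    # character; they must form a tree oriented toward `last`
    term <- vapply(verts, function(v) {
      if (v == last) NA_character_
      else {
        ee <- edges[[v]]
        ee[sample.int(length(ee), 1L)]
      }
    }, character(1))
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- term[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle the remaining edges per vertex, terminal edge goes last
  ordered <- lapply(verts, function(v) {
    ee <- edges[[v]]
    if (is.null(ee)) return(character(0))
    if (v != last) {
      drop1 <- match(term[[v]], ee)
      rest <- ee[-drop1]
      c(if (length(rest) > 0) rest[sample.int(length(rest))] else character(0),
        term[[v]])
    } else {
      ee[sample.int(length(ee))]
    }
  })
  names(ordered) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste0(out, collapse = "")
}

# Number of sequences containing each exact k-mer (ACGT only)
kmer_containment <- function(seqs, k) {
  per_seq <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, 1:(n - k + 1L), k:n)
    unique(km[!grepl("N", km, fixed = TRUE)])
  })
  tab <- table(unlist(per_seq))
  stats::setNames(as.integer(tab), names(tab))
}

# Sequences containing >= 1 occurrence of an IUPAC word
iupac_containment <- function(seqs, word) {
  sum(grepl(iupac_regex(word), seqs))
}

#' Discover enriched motifs in junction windows
#'
#' A simplified discriminative motif search: all exact words of each
#' length in `k_range` occurring in the positive windows are scored by a
#' one-sided Fisher exact test on sequence-containment counts against
#' the background (by default a per-sequence dinucleotide shuffle of the
#' positives), Bonferroni-corrected by the number of words tested. The
#' best word is greedily generalized by trying, at each position, each
#' two-letter IUPAC code and keeping changes that lower the p-value. A
#' motif is reported if its E-value is at most `e_cutoff`; its
#' occurrences are then masked and the search repeats, up to
#' `max_motifs` motifs.
#'
#' @param positives Character vector of positive window sequences.
#' @param background Character vector of background sequences, or `NULL`
#'   to build one by seeded dinucleotide shuffling of the positives.
#' @param k_range Length-2 integer vector `(k_min, k_max)` (default
#'   `c(3, 8)`).
#' @param max_motifs Maximum motifs to report (default 3).
#' @param e_cutoff E-value cutoff (default 0.05).
#' @param seed RNG seed for the shuffle (default 1).
#' @return A data.frame with one row per motif: `word`, `pos_with`,
#'   `pos_total`, `bg_with`, `bg_total`, `p_value`, `e_value`,
#'   `n_words_tested`, `pos_mode` (most frequent 0-based start offset in
#'   the positives).
#' @export
discover_motifs <- function(positives, background = NULL,
                            k_range = c(3L, 8L), max_motifs = 3L,
                            e_cutoff = 0.05, seed = 1L) {
  stopifnot(length(positives) > 0)
  if (k_range[2] > min(nchar(positives))) {
    stop("k_max exceeds the window length")
  }
  if (is.null(background)) {
    background <- with_seed(seed, vapply(positives, dinucleotide_shuffle,
                                         character(1), USE.NAMES = FALSE))
  }
  pos <- positives
  bg <- background
  results <- list()
  for (iter in seq_len(max_motifs)) {
    word_tabs <- lapply(seq(k_range[1], k_range[2]), function(k) {
      pw <- kmer_containment(pos, k)
      if (length(pw) == 0) return(NULL)
      bw <- kmer_containment(bg, k)
      data.frame(word = names(pw), pos_with = unname(pw),
                 bg_with = unname(bw[names(pw)]) %||% NA_integer_,
                 stringsAsFactors = FALSE)
    })
    words <- do.call(rbind, word_tabs)
    if (is.null(words) || nrow(words) == 0) break
    words$bg_with[is.na(words$bg_with)] <- 0L
    words$p <- fisher_enrichment(words$pos_with, length(pos),
                                 words$bg_with, length(bg))
    n_tested <- nrow(words)
    words <- words[order(words$p, words$word), , drop = FALSE]
    best <- words[1, ]
    w <- best$word
    best_p <- best$p
    # greedy IUPAC generalization, one pass over positions
    wc <- strsplit(w, "")[[1]]
    for (pos_i in seq_along(wc)) {
      orig <- wc[pos_i]
      for (code in names(IUPAC_PAIRS)) {
        if (!grepl(orig, IUPAC_PAIRS[[code]], fixed = TRUE)) next
        cand <- wc; cand[pos_i] <- code
        cand_word <- paste0(cand, collapse = "")
        p <- fisher_enrichment(iupac_containment(pos, cand_word), length(pos),
                               iupac_containment(bg, cand_word), length(bg))
        if (p < best_p) {
          best_p <- p
          wc[pos_i] <- code
        }
      }
    }
    w <- paste0(wc, collapse = "")
    e <- best_p * n_tested
    if (e > e_cutoff) break
    rex <- iupac_regex(w)
    pos_hit <- grepl(rex, pos)
    starts <- unlist(lapply(gregexpr(rex, pos[pos_hit]), function(m) {
      if (m[1] == -1L) integer(0) else as.integer(m) - 1L
    }))
    mode_tab <- table(starts)
    results[[length(results) + 1L]] <- data.frame(
      word = w, pos_with = sum(pos_hit), pos_total = length(pos),
      bg_with = sum(grepl(rex, bg)), bg_total = length(bg),
      p_value = best_p, e_value = e, n_words_tested = n_tested,
      pos_mode = as.integer(names(mode_tab)[which.max(mode_tab)]),
      stringsAsFactors = FALSE)
    # mask occurrences so the next iteration finds a different signal
    pos <- gsub(rex, strrep("N", nchar(w)), pos)
  }
  if (length(results) == 0) {
    return(data.frame(word = character(0), pos_with = integer(0),
                      pos_total = integer(0), bg_with = integer(0),
                      bg_total = integer(0), p_value = numeric(0),
                      e_value = numeric(0), n_words_tested = integer(0),
                      pos_mode = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  res
}
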