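# Operon inference from intergenic distances: adjacent same-strand gene
# pairs, repeat-adjusted gap lengths, mode detection on the distance
# distributions, and chaining under the 1-kb rule.

PAIR_CATEGORIES <- c("TS->TS", "nonTS->TS", "TS->nonTS", "nonTS->nonTS")

pair_category <- function(up_ts, down_ts) {
  up <- ifelse(up_ts == "TS", "TS", "nonTS")
  dn <- ifelse(down_ts == "TS", "TS", "nonTS")
  paste0(up, "->", dn)
}

#' Enumerate adjacent same-strand gene pairs
#'
#' Emits one pair per immediately adjacent same-strand gene duo on each
#' scaffold. A pair is suppressed when any opposite-strand gene's span
#' intersects the open interval between the two spans ("interrupted"),
#' and genes strictly nested inside another gene's span are skipped
#' entirely. Upstream/downstream are resolved by transcription
#' direction; `raw_distance = max(0, right.start - left.start_of_gap)`
#' in forward coordinates, so overlapping same-strand neighbours get
#' distance 0.
#'
#' @param genes A `gene_models` data.frame (its `ts_status` column
#'   provides the pair category).
#' @return A data.frame with columns `upstream_gene`, `downstream_gene`,
#'   `scaffold`, `strand`, `gap_start`, `gap_end`, `raw_distance`,
#'   `category`.
#' @export
adjacent_pairs <- function(genes) {
  out <- list()
  for (scaf in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == scaf, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    n <- nrow(g)
    if (n < 2) next
    # drop genes strictly nested inside another gene
    nested <- vapply(seq_len(n), function(i) {
      any(g$start <= g$start[i] & g$end >= g$end[i] &
            (g$start < g$start[i] | g$end > g$end[i]))
    }, logical(1))
    g <- g[!nested, , drop = FALSE]
    n <- nrow(g)
    for (s in c("+", "-")) {
      idx <- which(g$strand == s)
      if (length(idx) < 2) next
      opp <- g[g$strand != s, , drop = FALSE]
      for (k in seq_len(length(idx) - 1L)) {
        i <- idx[k]; j <- idx[k + 1L]
        gap_start <- g$end[i]; gap_end <- g$start[j]
        if (nrow(opp) > 0 && gap_end > gap_start &&
            any(opp$start < gap_end & opp$end > gap_start)) next
        raw <- max(0L, gap_end - gap_start)
        if (s == "+") { up <- i; dn <- j } else { up <- j; dn <- i }
        out[[length(out) + 1L]] <- data.frame(
          upstream_gene = g$gene_id[up], downstream_gene = g$gene_id[dn],
          scaffold = scaf, strand = s,
          gap_start = min(gap_start, gap_end),
          gap_end = max(gap_start, gap_end),
          raw_distance = raw,
          category = pair_category(g$ts_status[up], g$ts_status[dn]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(upstream_gene = character(0),
                      downstream_gene = character(0),
                      scaffold = character(0), strand = character(0),
                      gap_start = integer(0), gap_end = integer(0),
                      raw_distance = integer(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repeat-adjusted intergenic distances
#'
#' Subtracts from each pair's raw distance the number of bases of the
#' inter-gene interval covered by the union of repeat intervals
#' (overlapping repeats are merged first and clipped to the interval),
#' floored at 0.
#'
#' @param pairs Data.frame from [adjacent_pairs()].
#' @param repeats A `repeat_track` data.frame, or `NULL` for no
#'   adjustment.
#' @return `pairs` with an added integer column `adjusted_distance`.
#' @export
repeat_adjusted_distances <- function(pairs, repeats = NULL) {
  if (nrow(pairs) == 0) {
    pairs$adjusted_distance <- integer(0)
    return(pairs)
  }
  adj <- pairs$raw_distance
  if (!is.null(repeats) && nrow(repeats) > 0) {
    for (scaf in unique(pairs$scaffold)) {
      pi <- which(pairs$scaffold == scaf)
      rr <- repeats[repeats$scaffold == scaf, , drop = FALSE]
      if (nrow(rr) == 0) next
      rep_ir <- IRanges::reduce(IRanges::IRanges(rr$start + 1L, rr$end))
      gaps <- IRanges::IRanges(pairs$gap_start[pi] + 1L, pairs$gap_end[pi])
      cov <- vapply(seq_along(pi), function(q) {
        gp <- gaps[q]
        if (IRanges::width(gp) == 0) return(0L)
        hits <- IRanges::restrict(rep_ir, IRanges::start(gp), IRanges::end(gp))
        sum(IRanges::width(hits))
      }, integer(1))
      adj[pi] <- pmax(0L, pairs$raw_distance[pi] - cov)
    }
  }
  pairs$adjusted_distance <- as.integer(adj)
  pairs
}

#' Intergenic-distance distributions with mode detection
#'
#' Groups pair distances by category (optionally merging `nonTS->TS` and
#' `TS->nonTS` into one `"mixed"` group), smooths `log10(d + 1)` with a
#' Gaussian kernel at the Silverman bandwidth, and reports local density
#' maxima mapped back to bp, plus the valley (density minimum) between
#' the first two modes.
#'
#' @param pairs Data.frame from [repeat_adjusted_distances()] (or
#'   [adjacent_pairs()] when `use_adjusted = FALSE`).
#' @param use_adjusted Use `adjusted_distance` (default) or
#'   `raw_distance`.
#' @param merge_mixed Merge the two mixed-order categories (default
#'   `TRUE`).
#' @return A list of per-category lists with elements `category`,
#'   `distances`, `modes` (bp, ascending), `valley` (bp or `NULL`).
#' @export
distance_distributions <- function(pairs, use_adjusted = TRUE,
                                   merge_mixed = TRUE) {
  d <- if (use_adjusted) pairs$adjusted_distance else pairs$raw_distance
  cat <- pairs$category
  if (merge_mixed) {
    cat[cat %in% c("nonTS->TS", "TS->nonTS")] <- "mixed"
    cats <- c("TS->TS", "mixed", "nonTS->nonTS")
  } else {
    cats <- PAIR_CATEGORIES
  }
  lapply(cats, function(cc) {
    dd <- d[cat == cc]
    res <- list(category = cc, distances = dd, modes = numeric(0),
                valley = NULL)
    if (length(dd) < 2L || stats::sd(log10(dd + 1)) == 0) {
      if (length(dd) >= 2L) res$modes <- dd[1]  # all equal
      return(res)
    }
    x <- log10(dd + 1)
    dens <- stats::density(x, bw = "nrd0", n = 512)
    y <- dens$y
    is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE) &
      y > max(y) * 1e-6
    mx <- which(is_max)
    res$modes <- sort(10^dens$x[mx] - 1)
    if (length(mx) >= 2) {
      mx <- mx[order(dens$x[mx])]
      seg <- seq(mx[1], mx[2])
      vi <- seg[which.min(y[seg])]
      res$valley <- 10^dens$x[vi] - 1
    }
    res
  })
}

#' Chain genes into operons
#'
#' Scans each scaffold in transcription order per strand and links an
#' adjacent pair into the growing chain iff the pair survived the
#' adjacency rules, its adjusted distance is below `threshold`, and the
#' downstream gene is trans-spliced. A non-trans-spliced gene may only be
#' the chain's first member. Maximal chains of two or more genes are
#' emitted; each gene belongs to at most one operon.
#'
#' @param genes A `gene_models` data.frame.
#' @param ts_map Named vector gene_id -> `"TS"`/`"nonTS"`; defaults to
#'   the genes' `ts_status` column. Genes missing from the map are
#'   treated as nonTS with a warning.
#' @param repeats Optional `repeat_track` for distance adjustment.
#' @param threshold Linking threshold on the adjusted distance in bp
#'   (default 1000).
#' @return A data.frame with one row per operon: `operon_id`,
#'   `scaffold`, `strand`, `genes` (comma-separated in transcription
#'   order), `size`, `span_length`, `starts_nonTS`.
#' @export
call_operons <- function(genes, ts_map = NULL, repeats = NULL,
                         threshold = 1000L) {
  stopifnot(threshold > 0)
  if (is.null(ts_map)) {
    ts_map <- stats::setNames(genes$ts_status, genes$gene_id)
  }
  missing <- setdiff(genes$gene_id, names(ts_map))
  if (length(missing) > 0) {
    warning(length(missing), " gene(s) missing from ts_map; treated as nonTS")
    ts_map[missing] <- "nonTS"
  }
  is_ts <- stats::setNames(ts_map[genes$gene_id] == "TS", genes$gene_id)
  genes$ts_status <- ifelse(is_ts[genes$gene_id], "TS", "nonTS")
  pairs <- repeat_adjusted_distances(adjacent_pairs(genes), repeats)
  linkable <- pairs[pairs$adjusted_distance < threshold &
                      is_ts[pairs$downstream_gene], , drop = FALSE]
  link_key <- paste(linkable$upstream_gene, linkable$downstream_gene)
  chains <- list()
  for (scaf in unique(genes$scaffold)) {
    for (s in c("+", "-")) {
      g <- genes[genes$scaffold == scaf & genes$strand == s, , drop = FALSE]
      if (nrow(g) < 2) next
      ord <- order(g$start)
      if (s == "-") ord <- rev(ord)   # transcription order
      ids <- g$gene_id[ord]
      chain <- ids[1]
      flush <- function(chain) {
        if (length(chain) >= 2) chains[[length(chains) + 1L]] <<-
            list(scaffold = scaf, strand = s, genes = chain)
      }
      for (i in seq_len(length(ids) - 1L)) {
        if (paste(ids[i], ids[i + 1L]) %in% link_key) {
          chain <- c(chain, ids[i + 1L])
        } else {
          flush(chain)
          chain <- ids[i + 1L]
        }
      }
      flush(chain)
    }
  }
  if (length(chains) == 0) {
    return(data.frame(operon_id = character(0), scaffold = character(0),
                      strand = character(0), genes = character(0),
                      size = integer(0), span_length = integer(0),
                      starts_nonTS = logical(0), stringsAsFactors = FALSE))
  }
  gs <- stats::setNames(genes$start, genes$gene_id)
  ge <- stats::setNames(genes$end, genes$gene_id)
  res <- do.call(rbind, lapply(chains, function(ch) {
    data.frame(
      scaffold = ch$scaffold, strand = ch$strand,
      genes = paste(ch$genes, collapse = ","),
      size = length(ch$genes),
      span_length = max(ge[ch$genes]) - min(gs[ch$genes]),
      starts_nonTS = !is_ts[ch$genes[1]],
      stringsAsFactors = FALSE
    )
  }))
  res <- res[order(res$scaffold, vapply(strsplit(res$genes, ","), function(x)
    min(gs[x]), numeric(1))), , drop = FALSE]
  res <- cbind(operon_id = sprintf("operon%04d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Summarize called operons
#'
#' @param operons Data.frame from [call_operons()].
#' @param ts_map Named gene_id -> TS/nonTS vector (for the TS-gene
#'   denominator).
#' @param n_genes_total Total number of genes in the annotation.
#' @return A list: `size_hist` (named counts), `n_operons`,
#'   `genes_in_operons`, `nonts_starts`, `span_lengths`,
#'   `pct_all_genes_in_operons`, `pct_ts_genes_in_operons` (computed as
#'   (genes in operons - nonTS first genes) / total TS genes),
#'   `pct_operons_starting_nonts`.
#' @export
operon_summary <- function(operons, ts_map = NULL, n_genes_total = NA) {
  if (nrow(operons) == 0) {
    return(list(size_hist = integer(0), n_operons = 0L,
                genes_in_operons = 0L, nonts_starts = 0L,
                span_lengths = integer(0),
                pct_all_genes_in_operons = 0,
                pct_ts_genes_in_operons = 0,
                pct_operons_starting_nonts = 0))
  }
  genes_in <- sum(operons$size)
  nonts_starts <- sum(operons$starts_nonTS)
  ts_total <- if (!is.null(ts_map)) sum(ts_map == "TS") else NA_integer_
  list(
    size_hist = table(operons$size),
    n_operons = nrow(operons),
    genes_in_operons = genes_in,
    nonts_starts = nonts_starts,
    span_lengths = operons$span_length,
    pct_all_genes_in_operons =
      if (is.na(n_genes_total)) NA else pct_fraction(genes_in, n_genes_total, 1),
    pct_ts_genes_in_operons =
      if (is.na(ts_total)) NA else
        pct_fraction(genes_in - nonts_starts, ts_total, 1),
    pct_operons_starting_nonts = pct_fraction(nonts_starts, genes_in, 1)
  )
}

#' Write operons as TSV and GFF3
#'
#' @param operons Data.frame from [call_operons()].
#' @param genes The gene table (for span coordinates).
#' @param tsv_path,gff3_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_operons <- function(operons, genes, tsv_path = NULL, gff3_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(operons, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(gff3_path)) {
    gs <- stats::setNames(genes$start, genes$gene_id)
    ge <- stats::setNames(genes$end, genes$gene_id)
    con <- file(gff3_path, "w"); on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (i in seq_len(nrow(operons))) {
      o <- operons[i, ]
      ids <- strsplit(o$genes, ",")[[1]]
      writeLines(paste(o$scaffold, "sloperon", "operon",
                       min(gs[ids]) + 1L, max(ge[ids]), ".", o$strand, ".",
                       paste0("ID=", o$operon_id, ";genes=", o$genes),
                       sep = "\t"), con)
    }
  }
  invisible(c(tsv_path, gff3_path))
}
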