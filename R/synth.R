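# Synthetic dataset generator: a genome with planted gene neighborhoods
# (bimodal intergenic gaps: short lognormal gaps inside operons, long
# gaps elsewhere), repeat insertions inflating gaps, SL RNA gene copies,
# junction motifs, labeled genes, and SL-prefixed reads - everything the
# pipeline consumes, with full ground truth.

#' Synthetic dataset configuration
#'
#' Returns a validated configuration list for [generate_dataset()]. The
#' defaults emulate the structure the analysis assumes: ~30 % of genes
#' trans-spliced, ~30 % of genes inside operons with a ~100 bp
#' intra-operon gap mode, long (~5 kb mode) gaps between transcription
#' units, repeats inserted into 30 % of gaps, eight SL RNA gene copies,
#' and canonical GT..AG junction words.
#'
#' @param seed Mandatory RNG seed (integer).
#' @param n_scaffolds,n_genes Genome shape (defaults 20 scaffolds,
#'   2000 genes).
#' @param ts_fraction Fraction of genes trans-spliced (default 0.30).
#'   `0` disables operon planting and SL reads entirely.
#' @param operon_gene_fraction Fraction of genes inside operons
#'   (default 0.30).
#' @param operon_size_probs Named probability vector over operon sizes
#'   (default heavily favouring 2- and 3-gene operons).
#' @param nonts_start_prob Probability that an operon's first transcribed
#'   gene is non-trans-spliced (default 0.18).
#' @param intra_operon_gap,inter_gene_gap Lognormal gap parameters
#'   (`meanlog`, `sdlog`) in bp; defaults mode ~100 bp inside operons,
#'   ~5 kb between units.
#' @param repeat_insertion_rate Probability a gap receives a repeat
#'   insertion (default 0.3).
#' @param repeat_length Lognormal repeat-length parameters (default
#'   median 400 bp).
#' @param n_slrna_copies SL RNA gene copies to plant (default 8).
#' @param sl_seq The SL sequence (default [mlig_sl_sequence()]).
#' @param slrna_length Planted SL RNA gene length (default 109 nt).
#' @param reads_per_ts_gene SL-prefixed reads per trans-spliced gene
#'   (default 5).
#' @param body_reads_per_gene Non-SL reads from gene bodies (default 2).
#' @param read_length Read length (default 75 nt).
#' @param sl_truncation_range SL suffix lengths carried by reads,
#'   sampled uniformly (default 12..35 so partial-SL tagging is
#'   exercised).
#' @param donor_word,acceptor_word,trans_word Junction words planted at
#'   cis-donor, cis-acceptor and trans-acceptor (outron) junctions
#'   (defaults `GTAAG`, `CAG`, `TTTCAG`).
#' @param motif_plant_prob Planting probability per junction
#'   (default 0.9).
#' @param exon_count_probs Probabilities of 1..4 exons per gene.
#' @param exon_len_range,intron_len_range Uniform length ranges in bp.
#' @param cons_probs Conservation-class probabilities conditional on
#'   ts_status (defaults reflect a strong conservation bias among
#'   trans-spliced genes).
#' @param p_neoblast_ts_cons,p_neoblast_other,p_germline Cell-label
#'   planting probabilities.
#' @param plant_negative_controls Plant a donor-less SL RNA construct and
#'   an SL seed at a trans-spliced gene's 5' end (default `TRUE`).
#' @param max_scaffold_length Layout guard; exceeding it errors with a
#'   suggestion to shrink the gene count or gaps.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_scaffolds = 20L,
                         n_genes = 2000L,
                         ts_fraction = 0.30,
                         operon_gene_fraction = 0.30,
                         operon_size_probs = c("2" = 0.75, "3" = 0.18,
                                               "4" = 0.05, "5" = 0.015,
                                               "6" = 0.005),
                         nonts_start_prob = 0.18,
                         intra_operon_gap = list(meanlog = log(100),
                                                 sdlog = 0.5),
                         inter_gene_gap = list(meanlog = log(5000),
                                               sdlog = 0.6),
                         repeat_insertion_rate = 0.3,
                         repeat_length = list(meanlog = log(400),
                                              sdlog = 0.7),
                         n_slrna_copies = 8L,
                         sl_seq = mlig_sl_sequence(),
                         slrna_length = 109L,
                         reads_per_ts_gene = 5L,
                         body_reads_per_gene = 2L,
                         read_length = 75L,
                         sl_truncation_range = c(12L, 35L),
                         donor_word = "GTAAG",
                         acceptor_word = "CAG",
                         trans_word = "TTTCAG",
                         motif_plant_prob = 0.9,
                         exon_count_probs = c(0.30, 0.35, 0.25, 0.10),
                         exon_len_range = c(100L, 300L),
                         intron_len_range = c(80L, 400L),
                         cons_probs = list(
                           TS = c(conserved = 0.699,
                                  "non-conserved" = 0.243,
                                  "non-coding" = 0.058),
                           nonTS = c(conserved = 0.369,
                                     "non-conserved" = 0.429,
                                     "non-coding" = 0.202)),
                         p_neoblast_ts_cons = 0.08,
                         p_neoblast_other = 0.005,
                         p_germline = 0.02,
                         plant_negative_controls = TRUE,
                         max_scaffold_length = 5e7) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  props <- c(cfg$ts_fraction, cfg$operon_gene_fraction, cfg$nonts_start_prob,
             cfg$repeat_insertion_rate, cfg$motif_plant_prob,
             cfg$p_neoblast_ts_cons, cfg$p_neoblast_other, cfg$p_germline)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (abs(sum(cfg$operon_size_probs) - 1) > 1e-9) {
    stop("operon_size_probs must sum to 1")
  }
  if (any(as.integer(names(cfg$operon_size_probs)) < 2L)) {
    stop("operon sizes must be >= 2")
  }
  if (cfg$sl_truncation_range[1] < 1L ||
      cfg$sl_truncation_range[2] > nchar(cfg$sl_seq)) {
    stop("sl_truncation_range must lie within 1..nchar(sl_seq)")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Design a synthetic SL RNA gene construct
#'
#' Builds a sequence that starts with the SL exon, carries the donor
#' splice site immediately after it, contains the Sm-site word between
#' the designed second and third stems, and folds (by
#' [fold_max_pairs()]) into at least three hairpin loops; the fold is
#' asserted at construction time.
#'
#' @param sl_seq SL exon sequence.
#' @param donor Donor-site word placed right after the SL (default
#'   `"GTAAG"`).
#' @param sm_word Sm-site word (default `"AATTTTGGA"`, matching the
#'   `RAUUUUNGR` consensus). May be `""` to build a negative-control
#'   construct without an Sm site.
#' @param total_length Construct length (default 109 nt).
#' @return A DNA string of `total_length` characters.
#' @export
design_slrna_construct <- function(sl_seq = mlig_sl_sequence(),
                                   donor = "GTAAG",
                                   sm_word = "AATTTTGGA",
                                   total_length = 109L) {
  if (total_length < nchar(sl_seq) + 30L) {
    stop("total_length infeasible: need at least nchar(sl_seq) + 30")
  }
  stem2 <- "GGCAGCCG"; loop2 <- "TTTT"
  stem3 <- "GGGCCTCC"; loop3 <- "TCTT"
  fixed <- nchar(sl_seq) + nchar(donor) +
    (2L * nchar(stem2) + nchar(loop2)) + nchar(sm_word) +
    (2L * nchar(stem3) + nchar(loop3))
  flex <- total_length - fixed
  if (flex < 0L) {
    stop("cannot satisfy constraints at total_length = ", total_length,
         "; need at least ", fixed, " nt")
  }
  filler <- function(n) if (n <= 0L) "" else
    substr(strrep("ACA", ceiling(n / 3) + 1L), 1L, n)
  l1 <- flex %/% 4L; l2 <- flex %/% 4L; l3 <- flex %/% 4L
  tail_n <- flex - l1 - l2 - l3
  seq <- paste0(sl_seq, donor, filler(l1),
                stem2, loop2, revcomp(stem2), filler(l2),
                sm_word, filler(l3),
                stem3, loop3, revcomp(stem3), filler(tail_n))
  stopifnot(nchar(seq) == total_length)
  fold <- fold_max_pairs(seq)
  if (count_hairpins(fold$structure) < 3L) {
    stop("designed construct does not fold into three hairpins; ",
         "adjust stems or length")
  }
  seq
}

# write `word` (forward-strand letters) into char vector at 0-based
# forward interval [lo, lo + nchar(word))
plant_at <- function(chars, lo, word) {
  w <- strsplit(word, "")[[1]]
  if (lo < 0L || lo + length(w) > length(chars)) return(chars)
  chars[(lo + 1L):(lo + length(w))] <- w
  chars
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Deterministically (given the config seed) lays out genes per the gap
#' distributions, inserts repeats, plants junction motifs and SL RNA
#' gene copies (plus negative controls), simulates SL-prefixed and body
#' reads, and writes the standard files: `genome.fasta`, `genes.gff3`,
#' `repeats.bed`, `labels.tsv`, `reads.fastq`, `placements.tsv`, and
#' truth tables `truth_genes.tsv`, `truth_slrna.tsv`, `truth_gaps.tsv`,
#' `truth_reads.tsv`.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths`, the `genes` table, the
#'   `genome` (`DNAStringSet`), and `truth` tables.
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cfg <- config
  no_ts <- cfg$ts_fraction == 0
  op_frac <- if (no_ts) 0 else cfg$operon_gene_fraction

  ## ---- units: operons and singletons -------------------------------
  target_op <- round(cfg$n_genes * op_frac)
  sizes <- integer(0)
  while (sum(sizes) < target_op) {
    sizes <- c(sizes, as.integer(sample(names(cfg$operon_size_probs), 1L,
                                        prob = cfg$operon_size_probs)))
  }
  if (length(sizes) > 0 && sum(sizes) > target_op) {
    excess <- sum(sizes) - target_op
    last <- sizes[length(sizes)] - excess
    sizes <- sizes[-length(sizes)]
    if (last >= 2L) sizes <- c(sizes, last)
  }
  n_op_genes <- sum(sizes)
  n_single <- cfg$n_genes - n_op_genes
  units <- c(lapply(sizes, function(s) list(type = "operon", n = s)),
             replicate(n_single, list(type = "single", n = 1L),
                       simplify = FALSE))
  units <- units[sample.int(length(units))]

  ## ---- per-gene attributes -----------------------------------------
  gene_counter <- 0L
  op_counter <- 0L
  gene_rows <- list()
  gap_rows <- list()
  rep_rows <- list()
  scaffold_len <- integer(cfg$n_scaffolds)
  # split units over scaffolds in contiguous chunks
  chunk <- sort(rep_len(seq_len(cfg$n_scaffolds), length(units)))
  draw_gap <- function(par) max(10L, as.integer(round(stats::rlnorm(
    1, par$meanlog, par$sdlog))))
  for (sc in seq_len(cfg$n_scaffolds)) {
    scaf <- sprintf("scaf%03d", sc)
    cursor <- 500L
    sc_units <- units[chunk == sc]
    prev_gene <- NA_character_
    prev_intra <- FALSE
    for (u in sc_units) {
      strand <- sample(c("+", "-"), 1L)
      if (u$type == "operon") op_counter <- op_counter + 1L
      op_id <- if (u$type == "operon") {
        sprintf("true_operon%04d", op_counter)
      } else NA_character_
      first_nonts <- u$type == "operon" &&
        stats::runif(1) < cfg$nonts_start_prob
      for (gi in seq_len(u$n)) {
        # gap before this gene (inter-unit before gi == 1, intra inside)
        {
          intra <- gi > 1L
          par <- if (intra) cfg$intra_operon_gap else cfg$inter_gene_gap
          base <- draw_gap(par)
          rep_len_ins <- 0L
          rep_off <- NA_integer_
          if (stats::runif(1) < cfg$repeat_insertion_rate) {
            rep_len_ins <- max(20L, as.integer(round(stats::rlnorm(
              1, cfg$repeat_length$meanlog, cfg$repeat_length$sdlog))))
            rep_off <- sample.int(base + 1L, 1L) - 1L
            rep_rows[[length(rep_rows) + 1L]] <- data.frame(
              scaffold = scaf, start = cursor + rep_off,
              end = cursor + rep_off + rep_len_ins,
              stringsAsFactors = FALSE)
          }
          total_gap <- base + rep_len_ins
          if (!is.na(prev_gene)) {
            gap_rows[[length(gap_rows) + 1L]] <- data.frame(
              scaffold = scaf, left_gene = prev_gene,
              right_gene = sprintf("g%05d", gene_counter + 1L),
              category = if (intra) "intra" else "inter",
              base_gap = base, repeat_len = rep_len_ins,
              stringsAsFactors = FALSE)
          }
          cursor <- cursor + total_gap
        }
        gene_counter <- gene_counter + 1L
        gid <- sprintf("g%05d", gene_counter)
        nex <- sample(seq_along(cfg$exon_count_probs), 1L,
                      prob = cfg$exon_count_probs)
        ex_len <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], nex,
                         replace = TRUE)
        in_len <- if (nex > 1L) {
          sample(cfg$intron_len_range[1]:cfg$intron_len_range[2], nex - 1L,
                 replace = TRUE)
        } else integer(0)
        starts <- cursor + cumsum(c(0L, ex_len[-nex] + in_len))
        ends <- starts + ex_len
        # TS planting: operonic genes TS, except perhaps the first
        # transcribed gene; singles decided later against the quota
        first_tx <- if (strand == "+") gi == 1L else gi == u$n
        ts <- if (u$type == "operon") {
          if (first_tx && first_nonts) "nonTS" else "TS"
        } else "pending"
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gid, scaffold = scaf, strand = strand,
          start = cursor, end = ends[nex],
          ts_status = ts, operon_id = op_id %||% NA_character_,
          exon_str = paste(paste(starts, ends, sep = "-"), collapse = ","),
          stringsAsFactors = FALSE)
        cursor <- ends[nex]
      }
      prev_gene <- sprintf("g%05d", gene_counter)
    }
    cursor <- cursor + 500L
    if (cursor > cfg$max_scaffold_length) {
      stop("scaffold ", scaf, " exceeds max_scaffold_length; reduce ",
           "n_genes, gap sizes or increase n_scaffolds")
    }
    scaffold_len[sc] <- cursor
  }
  gdf <- do.call(rbind, gene_rows)

  ## ---- TS quota for singleton genes --------------------------------
  ts_target <- round(cfg$n_genes * cfg$ts_fraction)
  n_op_ts <- sum(gdf$ts_status == "TS")
  pending <- which(gdf$ts_status == "pending")
  if (no_ts) {
    gdf$ts_status[pending] <- "nonTS"
    gdf$ts_status[gdf$ts_status == "TS"] <- "nonTS"
  } else {
    need <- max(0L, min(length(pending), ts_target - n_op_ts))
    pick <- if (need > 0L) sample(pending, need) else integer(0)
    gdf$ts_status[pending] <- "nonTS"
    gdf$ts_status[pick] <- "TS"
  }

  ## ---- conservation and cell labels --------------------------------
  gdf$cons_class <- vapply(gdf$ts_status, function(ts) {
    p <- cfg$cons_probs[[if (ts == "TS") "TS" else "nonTS"]]
    sample(names(p), 1L, prob = p)
  }, character(1))
  p_neo <- ifelse(gdf$ts_status == "TS" & gdf$cons_class == "conserved",
                  cfg$p_neoblast_ts_cons, cfg$p_neoblast_other)
  u1 <- stats::runif(nrow(gdf))
  u2 <- stats::runif(nrow(gdf))
  gdf$cell_label <- ifelse(u1 < p_neo, "neoblast",
                           ifelse(u2 < cfg$p_germline, "germline", "none"))

  ## ---- gene table --------------------------------------------------
  exons <- lapply(strsplit(gdf$exon_str, ","), function(parts) {
    m <- do.call(rbind, strsplit(parts, "-"))
    cbind(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  })
  genes <- gene_models(gdf$gene_id, gdf$scaffold, gdf$strand, gdf$start,
                       gdf$end, exons, ts_status = gdf$ts_status,
                       cons_class = gdf$cons_class,
                       cell_label = gdf$cell_label)

  ## ---- genome sequence with planted words --------------------------
  chars_by_scaf <- lapply(seq_len(cfg$n_scaffolds), function(sc) {
    random_dna_chars(scaffold_len[sc])
  })
  names(chars_by_scaf) <- sprintf("scaf%03d", seq_len(cfg$n_scaffolds))
  dlen <- nchar(cfg$donor_word); alen <- nchar(cfg$acceptor_word)
  tlen <- nchar(cfg$trans_word)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ch <- chars_by_scaf[[g$scaffold]]
    ex <- g$exons[[1]]
    nex <- nrow(ex)
    if (nex > 1L) {
      if (g$strand == "+") {
        for (j in seq_len(nex - 1L)) {
          if (stats::runif(1) < cfg$motif_plant_prob)
            ch <- plant_at(ch, ex[j, 2], cfg$donor_word)
          if (stats::runif(1) < cfg$motif_plant_prob)
            ch <- plant_at(ch, ex[j + 1L, 1] - alen, cfg$acceptor_word)
        }
      } else {
        for (j in 2:nex) {
          if (stats::runif(1) < cfg$motif_plant_prob)
            ch <- plant_at(ch, ex[j, 1] - dlen, revcomp(cfg$donor_word))
          if (stats::runif(1) < cfg$motif_plant_prob)
            ch <- plant_at(ch, ex[j - 1L, 2], revcomp(cfg$acceptor_word))
        }
      }
    }
    if (g$ts_status == "TS" && stats::runif(1) < cfg$motif_plant_prob) {
      if (g$strand == "+") {
        ch <- plant_at(ch, g$start - tlen, cfg$trans_word)
      } else {
        ch <- plant_at(ch, g$end, revcomp(cfg$trans_word))
      }
    }
    chars_by_scaf[[g$scaffold]] <- ch
  }

  ## ---- SL RNA constructs and negative controls ---------------------
  construct <- design_slrna_construct(cfg$sl_seq, cfg$donor_word,
                                      total_length = cfg$slrna_length)
  slen <- nchar(cfg$sl_seq)
  gapdf <- do.call(rbind, gap_rows)
  slrna_rows <- list()
  host_gaps <- gapdf[gapdf$category == "inter" & gapdf$repeat_len == 0L &
                       gapdf$base_gap >= cfg$slrna_length + 400L, ,
                     drop = FALSE]
  n_controls <- if (cfg$plant_negative_controls) 1L else 0L
  need_gaps <- cfg$n_slrna_copies + n_controls
  if (nrow(host_gaps) < need_gaps) {
    stop("not enough large repeat-free gaps to host SL RNA copies; ",
         "increase n_genes or inter_gene_gap")
  }
  host_idx <- sample.int(nrow(host_gaps), need_gaps)
  gstart <- stats::setNames(genes$start, genes$gene_id)
  for (q in seq_len(need_gaps)) {
    hg <- host_gaps[host_idx[q], ]
    right_start <- gstart[[hg$right_gene]]
    pos <- right_start - hg$base_gap %/% 2L - cfg$slrna_length %/% 2L
    strand <- sample(c("+", "-"), 1L)
    this_seq <- if (q <= cfg$n_slrna_copies) construct else {
      # negative control: donor replaced by non-donor bases
      paste0(substr(construct, 1L, slen), strrep("A", 5L),
             substr(construct, slen + 6L, nchar(construct)))
    }
    word <- if (strand == "+") this_seq else revcomp(this_seq)
    chars_by_scaf[[hg$scaffold]] <- plant_at(chars_by_scaf[[hg$scaffold]],
                                             pos, word)
    seed_start <- if (strand == "+") pos else
      pos + cfg$slrna_length - slen
    slrna_rows[[length(slrna_rows) + 1L]] <- data.frame(
      scaffold = hg$scaffold, strand = strand, seed_start = seed_start,
      type = if (q <= cfg$n_slrna_copies) "positive" else "no_donor",
      stringsAsFactors = FALSE)
  }
  if (cfg$plant_negative_controls && !no_ts) {
    # an SL seed sitting exactly at a trans-spliced gene's 5' end:
    # the classic mis-annotation an annotation-aware caller must reject
    host <- genes[genes$ts_status == "TS" & genes$strand == "+", ,
                  drop = FALSE]
    host <- host[host$end - host$start > slen + 20L, , drop = FALSE]
    if (nrow(host) == 0L) {
      stop("no suitable trans-spliced host gene for the coding-5'-end ",
           "negative control")
    }
    hg <- host[sample.int(nrow(host), 1L), ]
    chars_by_scaf[[hg$scaffold]] <- plant_at(chars_by_scaf[[hg$scaffold]],
                                             hg$start, cfg$sl_seq)
    slrna_rows[[length(slrna_rows) + 1L]] <- data.frame(
      scaffold = hg$scaffold, strand = "+", seed_start = hg$start,
      type = "coding_5prime", stringsAsFactors = FALSE)
  }
  slrna_truth <- if (length(slrna_rows) > 0) do.call(rbind, slrna_rows) else
    data.frame(scaffold = character(0), strand = character(0),
               seed_start = integer(0), type = character(0))

  genome <- Biostrings::DNAStringSet(vapply(chars_by_scaf, paste0,
                                            character(1), collapse = ""))
  names(genome) <- names(chars_by_scaf)

  ## ---- reads -------------------------------------------------------
  read_rows <- list()
  read_seqs <- character(0)
  counter <- 0L
  tss <- gene_tss(genes)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- transcript_seq(g, genome)
    txlen <- nchar(tx)
    if (!no_ts && g$ts_status == "TS") {
      for (r in seq_len(cfg$reads_per_ts_gene)) {
        counter <- counter + 1L
        tr <- sample(cfg$sl_truncation_range[1]:cfg$sl_truncation_range[2],
                     1L)
        body_len <- min(cfg$read_length - tr, txlen)
        rs <- paste0(substr(cfg$sl_seq, slen - tr + 1L, slen),
                     substr(tx, 1L, body_len))
        rid <- sprintf("read%06d", counter)
        read_seqs[rid] <- rs
        read_rows[[length(read_rows) + 1L]] <- data.frame(
          read_id = rid, gene_id = g$gene_id, sl_overlap = tr,
          scaffold = g$scaffold, strand = g$strand,
          five_prime_pos = tss[i], stringsAsFactors = FALSE)
      }
    }
    if (cfg$body_reads_per_gene > 0L &&
        txlen >= 50L + cfg$read_length) {
      for (r in seq_len(cfg$body_reads_per_gene)) {
        counter <- counter + 1L
        off <- sample(50L:(txlen - cfg$read_length), 1L)
        rs <- substr(tx, off + 1L, off + cfg$read_length)
        rid <- sprintf("read%06d", counter)
        read_seqs[rid] <- rs
        read_rows[[length(read_rows) + 1L]] <- data.frame(
          read_id = rid, gene_id = g$gene_id, sl_overlap = 0L,
          scaffold = g$scaffold, strand = g$strand,
          five_prime_pos = tx_to_genome(g, off), stringsAsFactors = FALSE)
      }
    }
  }
  reads_truth <- if (length(read_rows) > 0) do.call(rbind, read_rows) else
    data.frame(read_id = character(0), gene_id = character(0),
               sl_overlap = integer(0), scaffold = character(0),
               strand = character(0), five_prime_pos = integer(0))

  ## ---- write files -------------------------------------------------
  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    genes = file.path(outdir, "genes.gff3"),
    repeats = file.path(outdir, "repeats.bed"),
    labels = file.path(outdir, "labels.tsv"),
    reads = file.path(outdir, "reads.fastq"),
    placements = file.path(outdir, "placements.tsv"),
    truth_genes = file.path(outdir, "truth_genes.tsv"),
    truth_slrna = file.path(outdir, "truth_slrna.tsv"),
    truth_gaps = file.path(outdir, "truth_gaps.tsv"),
    truth_reads = file.path(outdir, "truth_reads.tsv")
  )
  Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
  write_gene_gff3(genes, paths$genes)
  repeats <- if (length(rep_rows) > 0) {
    repeat_track_df <- do.call(rbind, rep_rows)
    repeat_track(repeat_track_df$scaffold, repeat_track_df$start,
                 repeat_track_df$end)
  } else repeat_track(character(0), integer(0), integer(0))
  write_repeat_bed(repeats, paths$repeats)
  write_label_table(genes, paths$labels)
  if (length(read_seqs) > 0) {
    dna <- Biostrings::DNAStringSet(unname(read_seqs))
    names(dna) <- names(read_seqs)
    qss <- Biostrings::QualityScaledDNAStringSet(
      dna, Biostrings::PhredQuality(strrep("I", nchar(read_seqs))))
    Biostrings::writeQualityScaledXStringSet(qss, paths$reads)
  } else {
    file.create(paths$reads)
  }
  utils::write.table(reads_truth[, c("read_id", "scaffold", "strand",
                                     "five_prime_pos")],
                     paths$placements, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_genes <- gdf[, c("gene_id", "ts_status", "operon_id")]
  truth_genes$ts_status <- genes$ts_status[match(truth_genes$gene_id,
                                                 genes$gene_id)]
  truth_genes$cons_class <- genes$cons_class[match(truth_genes$gene_id,
                                                   genes$gene_id)]
  truth_genes$cell_label <- genes$cell_label[match(truth_genes$gene_id,
                                                   genes$gene_id)]
  utils::write.table(truth_genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(slrna_truth, paths$truth_slrna, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gapdf, paths$truth_gaps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(reads_truth, paths$truth_reads, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, genes = genes, genome = genome,
                 repeats = repeats,
                 truth = list(genes = truth_genes, slrna = slrna_truth,
                              gaps = gapdf, reads = reads_truth)))
}
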