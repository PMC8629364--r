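# End-to-end orchestration: tag reads -> call trans-splicing ->
# distances -> operons -> SL RNA -> motifs -> enrichment, with a
# machine-readable JSON summary. Every summary number is recomputed from
# the per-stage tables, never invented here.

#' Build a pipeline run configuration
#'
#' @param genome Genome FASTA path.
#' @param annotation Gene annotation path (GFF3 or BED12).
#' @param repeats Optional repeat track path (BED or RepeatMasker .out).
#' @param reads Optional FASTQ of untrimmed reads.
#' @param placements Optional read 5'-end placement file (TSV or SAM).
#' @param labels Optional gene label TSV.
#' @param outdir Output directory.
#' @param sl_seq,min_overlap,window,min_reads SL tagging / TS calling
#'   parameters (see [match_sl_prefix()], [call_ts_transcripts()]).
#' @param threshold Operon linking threshold in bp (default 1000).
#' @param flank Junction window flank (default 50).
#' @param k_range,e_cutoff,max_motifs Motif search parameters.
#' @param slrna_length,donor_pattern,sm_pattern,min_hairpins SL RNA
#'   finder parameters.
#' @param seed Seed for the stochastic stages (motif background
#'   shuffle).
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome, annotation, repeats = NULL, reads = NULL,
                       placements = NULL, labels = NULL,
                       outdir = "sloperon_out",
                       sl_seq = mlig_sl_sequence(), min_overlap = 12L,
                       window = 10L, min_reads = 2L, threshold = 1000L,
                       flank = 50L, k_range = c(3L, 8L), e_cutoff = 0.05,
                       max_motifs = 3L, slrna_length = 109L,
                       donor_pattern = "GTAAG", sm_pattern = "RAUUUUNGR",
                       min_hairpins = 3L, seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("genome", "annotation", "repeats", "reads", "placements",
              "labels")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config path for '", p, "' does not exist: ", cfg[[p]])
    }
  }
  stopifnot(cfg$threshold > 0, cfg$window >= 0, cfg$min_reads >= 1,
            cfg$flank >= 1)
  class(cfg) <- "run_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes tag-reads, call-ts, intergenic distances, operon calling,
#' SL RNA discovery, motif discovery and enrichment on the configured
#' inputs, writing per-stage TSV/GFF3 outputs and a JSON summary into
#' the output directory. When a label table supplies ts_status it takes
#' precedence over read-derived calls (the number of conflicts is
#' logged); with no reads/placements the pipeline runs in a degraded,
#' labels-only mode with a logged notice.
#'
#' @param config A [run_config()].
#' @return The summary list (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[sloperon] ", ...)

  genome <- run_stage("load-genome", load_genome(config$genome))
  genes <- run_stage("load-annotation",
                     read_gene_annotation(config$annotation))
  repeats <- if (!is.null(config$repeats)) {
    run_stage("load-repeats", parse_repeat_track(config$repeats))
  } else NULL
  labels <- if (!is.null(config$labels)) {
    run_stage("load-labels", read_label_table(config$labels))
  } else NULL
  if (!is.null(labels)) genes <- attach_labels(genes, labels)

  ## ---- SL tagging and TS calling -----------------------------------
  read_calls <- NULL
  n_sl_reads <- 0L
  if (!is.null(config$reads) && !is.null(config$placements)) {
    tagged <- run_stage("tag-reads", tag_reads(
      config$reads, sl_seq = config$sl_seq,
      min_overlap = config$min_overlap,
      trimmed_fastq = file.path(config$outdir, "trimmed.fastq")))
    n_sl_reads <- nrow(tagged)
    log_msg(n_sl_reads, " SL-tagged reads")
    pl <- run_stage("load-placements", read_placements(config$placements))
    pl <- pl[pl$read_id %in% tagged$read_id, , drop = FALSE]
    read_calls <- run_stage("call-ts", call_ts_transcripts(
      pl, genes, window = config$window, min_reads = config$min_reads))
  } else {
    log_msg("no reads/placements supplied; TS status taken from labels only")
  }
  label_ts <- stats::setNames(genes$ts_status, genes$gene_id)
  have_label <- label_ts %in% c("TS", "nonTS")
  if (!is.null(read_calls)) {
    ts_map <- read_calls
    # explicit labels override read-derived calls
    conflicts <- sum(have_label &
                       label_ts[names(ts_map)] != ts_map, na.rm = TRUE)
    if (any(have_label)) {
      ts_map[have_label] <- label_ts[have_label]
      if (conflicts > 0) {
        log_msg(conflicts, " gene(s): label ts_status overrides read call")
      }
    }
  } else {
    ts_map <- ifelse(have_label, label_ts, "nonTS")
    names(ts_map) <- genes$gene_id
  }
  genes$ts_status <- unname(ts_map[genes$gene_id])
  write_ts_calls(ts_map, file.path(config$outdir, "ts_calls.tsv"))

  ## ---- distances and operons ---------------------------------------
  pairs <- run_stage("distances", repeat_adjusted_distances(
    adjacent_pairs(genes), repeats))
  utils::write.table(pairs, file.path(config$outdir, "distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dists <- run_stage("distance-modes",
                     distance_distributions(pairs, use_adjusted = TRUE,
                                            merge_mixed = TRUE))
  operons <- run_stage("operons", call_operons(
    genes, ts_map = ts_map, repeats = repeats,
    threshold = config$threshold))
  write_operons(operons, genes,
                tsv_path = file.path(config$outdir, "operons.tsv"),
                gff3_path = file.path(config$outdir, "operons.gff3"))
  osum <- operon_summary(operons, ts_map = ts_map,
                         n_genes_total = nrow(genes))

  ## ---- SL RNA ------------------------------------------------------
  slrna <- run_stage("slrna", call_slrna_genes(
    genome, sl_seq = config$sl_seq, candidate_length = config$slrna_length,
    donor_pattern = config$donor_pattern, sm_pattern = config$sm_pattern,
    min_hairpins = config$min_hairpins, genes = genes))
  utils::write.table(slrna, file.path(config$outdir, "slrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- motifs ------------------------------------------------------
  log_msg("motif search (seed ", config$seed, ")")
  top_motifs <- list()
  motif_tabs <- list()
  for (st in SITE_TYPES) {
    win <- run_stage(paste0("windows-", st), extract_junction_windows(
      genes, genome, flank = config$flank, site_type = st))
    if (nrow(win) == 0) next
    mot <- run_stage(paste0("motifs-", st), discover_motifs(
      win$seq, k_range = config$k_range, max_motifs = config$max_motifs,
      e_cutoff = config$e_cutoff, seed = config$seed))
    if (nrow(mot) > 0) {
      mot$site_type <- st
      motif_tabs[[st]] <- mot
      top_motifs[[st]] <- list(word = mot$word[1],
                               regions = mot$pos_with[1],
                               e_value = mot$e_value[1],
                               pos_mode = mot$pos_mode[1])
    }
  }
  if (length(motif_tabs) > 0) {
    utils::write.table(do.call(rbind, motif_tabs),
                       file.path(config$outdir, "motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- enrichment --------------------------------------------------
  xt <- conservation_crosstab(genes)
  utils::write.table(as.data.frame(xt),
                     file.path(config$outdir, "crosstab.tsv"),
                     sep = "\t", quote = FALSE)
  fracs <- crosstab_fractions(xt)
  neo <- genes$gene_id[genes$cell_label == "neoblast"]
  neo_fold <- NULL
  cons <- genes$cons_class == "conserved" & genes$ts_status %in%
    c("TS", "nonTS")
  sub_total <- sum(cons & genes$gene_id %in% neo)
  gen_total <- sum(cons)
  if (sub_total > 0 && gen_total > 0 &&
      sum(cons & genes$ts_status == "TS") > 0) {
    neo_fold <- fold_enrichment(
      sum(cons & genes$gene_id %in% neo & genes$ts_status == "TS"),
      sub_total,
      sum(cons & genes$ts_status == "TS"),
      gen_total)
  }

  ## ---- summary -----------------------------------------------------
  n_ts <- sum(ts_map == "TS")
  modes_of <- function(cat) {
    d <- Filter(function(x) x$category == cat, dists)
    if (length(d) == 0) return(numeric(0))
    round(d[[1]]$modes, 1)
  }
  summary <- list(
    seed = config$seed,
    n_genes = nrow(genes),
    n_sl_reads = n_sl_reads,
    ts_genes = n_ts,
    pct_ts_genes = pct_fraction(n_ts, nrow(genes), 1),
    genes_in_operons = osum$genes_in_operons,
    pct_all_genes_in_operons = osum$pct_all_genes_in_operons,
    pct_ts_genes_in_operons = osum$pct_ts_genes_in_operons,
    operons = osum$n_operons,
    operons_starting_nonts = osum$nonts_starts,
    pct_operons_starting_nonts = osum$pct_operons_starting_nonts,
    operon_size_hist = as.list(stats::setNames(
      as.integer(osum$size_hist), names(osum$size_hist))),
    ts_ts_distance_modes_bp = modes_of("TS->TS"),
    slrna_candidates = nrow(slrna),
    slrna_accepted = sum(slrna$accepted),
    top_motifs = top_motifs,
    conservation_pct = list(
      TS = as.list(fracs["TS", ]),
      nonTS = as.list(fracs["nonTS", ])),
    neoblast_conserved_fold_enrichment =
      if (is.null(neo_fold)) NULL else neo_fold$fold_2dp
  )
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
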