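# Gene models: a data.frame with one row per transcript/gene and a
# list-column of exon blocks. This is the central container every
# analysis module consumes.

TS_LEVELS   <- c("TS", "nonTS", "unknown")
CONS_LEVELS <- c("conserved", "non-conserved", "non-coding", "unknown")
CELL_LEVELS <- c("neoblast", "germline", "none")

#' Construct a gene-model table
#'
#' Builds the package's internal gene representation: one row per gene
#' (transcript span) with 0-based half-open coordinates on the forward
#' genomic strand and an `exons` list-column of two-column integer
#' matrices (start, end; 0-based half-open, disjoint, sorted by start).
#' Genes are sorted by (scaffold, start, gene_id).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param scaffold Character vector of scaffold names.
#' @param strand Character vector, `"+"` or `"-"`.
#' @param start,end Integer vectors, 0-based half-open span
#'   (first exon start to last exon end).
#' @param exons List of two-column matrices of exon blocks, or `NULL` to
#'   treat each gene as single-exon over its span.
#' @param ts_status,cons_class,cell_label Optional label vectors; default
#'   `"unknown"` / `"unknown"` / `"none"`.
#' @return A `data.frame` of class `gene_models`.
#' @export
gene_models <- function(gene_id, scaffold, strand, start, end,
                        exons = NULL,
                        ts_status = "unknown",
                        cons_class = "unknown",
                        cell_label = "none") {
  n <- length(gene_id)
  start <- as.integer(start); end <- as.integer(end)
  if (is.null(exons)) {
    exons <- Map(function(s, e) cbind(start = s, end = e), start, end)
  }
  exons <- lapply(exons, function(m) {
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    m[order(m[, 1]), , drop = FALSE]
  })
  df <- data.frame(
    gene_id = as.character(gene_id),
    scaffold = as.character(scaffold),
    strand = as.character(strand),
    start = start, end = end,
    ts_status = rep_len(as.character(ts_status), n),
    cons_class = rep_len(as.character(cons_class), n),
    cell_label = rep_len(as.character(cell_label), n),
    stringsAsFactors = FALSE
  )
  df$exons <- exons
  df <- df[order(df$scaffold, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  validate_gene_models(df)
  df
}

#' Validate a gene-model table
#'
#' Checks the coordinate invariants: `0 <= start < end`, every exon
#' within the gene span, exons pairwise disjoint, strand one of `+`/`-`,
#' unique gene ids.
#'
#' @param genes A `gene_models` data.frame.
#' @return The input, invisibly; errors on violation.
#' @export
validate_gene_models <- function(genes) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start < 0L) || any(genes$end <= genes$start)) {
    stop("gene coordinates must satisfy 0 <= start < end")
  }
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0L) stop("gene ", genes$gene_id[i], " has no exons")
    if (any(ex[, 1] >= ex[, 2])) {
      stop("gene ", genes$gene_id[i], ": exon with end <= start")
    }
    if (ex[1, 1] < genes$start[i] || ex[nrow(ex), 2] > genes$end[i]) {
      stop("gene ", genes$gene_id[i], ": exon outside gene span")
    }
    if (nrow(ex) > 1L && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop("gene ", genes$gene_id[i], ": overlapping exons")
    }
  }
  invisible(genes)
}

# 0-based genomic coordinate of a gene's 5' start (transcription start)
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Read a gene label table
#'
#' Reads a TSV with header `gene_id  ts_status  cons_class  cell_label`.
#' `ts_status` is one of TS/nonTS/unknown, `cons_class` one of
#' conserved/non-conserved/non-coding/unknown, `cell_label` one of
#' neoblast/germline/none.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the four label columns.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "ts_status", "cons_class", "cell_label")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("label table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id in label table: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  }
  check_levels <- function(x, lv, nm) {
    bad <- setdiff(unique(x), lv)
    if (length(bad) > 0) stop("invalid ", nm, " value(s): ",
                              paste(bad, collapse = ", "))
  }
  check_levels(tab$ts_status, TS_LEVELS, "ts_status")
  check_levels(tab$cons_class, CONS_LEVELS, "cons_class")
  check_levels(tab$cell_label, CELL_LEVELS, "cell_label")
  tab[need]
}

#' Attach labels from a side table to gene models
#'
#' Matching gene_ids receive the table's ts_status/cons_class/cell_label;
#' unmatched genes keep their current values. Label rows whose gene_id is
#' absent from the gene table are reported in a message and returned in
#' the `"unmatched_labels"` attribute.
#'
#' @param genes A `gene_models` data.frame.
#' @param labels A label data.frame (see [read_label_table()]).
#' @return The gene table with labels applied.
#' @export
attach_labels <- function(genes, labels) {
  if (anyDuplicated(labels$gene_id)) {
    stop("duplicate gene_id in label table")
  }
  idx <- match(genes$gene_id, labels$gene_id)
  hit <- !is.na(idx)
  genes$ts_status[hit]  <- labels$ts_status[idx[hit]]
  genes$cons_class[hit] <- labels$cons_class[idx[hit]]
  genes$cell_label[hit] <- labels$cell_label[idx[hit]]
  unmatched <- setdiff(labels$gene_id, genes$gene_id)
  if (length(unmatched) > 0) {
    message(length(unmatched), " label row(s) had no matching gene (e.g. ",
            unmatched[1], ")")
  }
  attr(genes, "unmatched_labels") <- unmatched
  genes
}

#' Write a gene label table
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(genes, path) {
  tab <- genes[order(genes$gene_id),
               c("gene_id", "ts_status", "cons_class", "cell_label")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Spliced transcript sequence of one gene row (character), reading the
# exons in transcription order. `genome` is a named DNAStringSet.
transcript_seq <- function(gene, genome) {
  chrom <- genome[[gene$scaffold]]
  ex <- gene$exons[[1]]
  parts <- vapply(seq_len(nrow(ex)), function(i) {
    as.character(Biostrings::subseq(chrom, ex[i, 1] + 1L, ex[i, 2]))
  }, character(1))
  s <- paste0(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

# Map a 0-based offset into the spliced transcript to the 0-based genomic
# coordinate of that base.
tx_to_genome <- function(gene, offset) {
  ex <- gene$exons[[1]]
  lens <- ex[, 2] - ex[, 1]
  if (gene$strand == "-") {
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    lens <- rev(lens)
  }
  if (offset < 0L || offset >= sum(lens)) stop("offset outside transcript")
  cum <- cumsum(lens)
  i <- which(offset < cum)[1]
  into <- offset - c(0L, cum)[i]
  if (gene$strand == "+") ex[i, 1] + into else ex[i, 2] - 1L - into
}
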