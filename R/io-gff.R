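# Annotation I/O. On-disk conventions: GFF3 is 1-based inclusive, BED is
# 0-based half-open, RepeatMasker .out is 1-based inclusive. Everything
# is converted to the internal 0-based half-open convention here and
# nowhere else. Writers emit deterministic (scaffold, start, gene_id)
# ordering.

# Cheap structural pre-validation so malformed records are reported with
# their line number before handing the file to rtracklayer.
prevalidate_tabular <- function(path, min_fields, numeric_fields,
                                comment = "#") {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, comment)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < min_fields) {
      stop("malformed record at line ", i, " of ", path,
           ": expected >= ", min_fields, " tab-separated fields")
    }
    for (j in numeric_fields) {
      if (is.na(suppressWarnings(as.integer(f[j])))) {
        stop("malformed record at line ", i, " of ", path,
             ": field ", j, " is not an integer")
      }
    }
  }
  invisible(lines)
}

#' Read gene annotation (GFF3 or BED12)
#'
#' Parses a gene/mRNA/exon GFF3 file or a BED12 file into a
#' [gene_models()] table. GFF3 coordinates (1-based inclusive) are
#' converted to the internal 0-based half-open convention; BED12 is
#' already 0-based half-open. Genes are returned sorted per scaffold by
#' start; all labels default to unknown/none (labels live in side
#' tables, see [attach_labels()]).
#'
#' @param path Annotation file path.
#' @param dialect `"auto"` (by extension), `"gff3"`, or `"bed12"`.
#' @return A `gene_models` data.frame.
#' @export
read_gene_annotation <- function(path, dialect = c("auto", "gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (dialect == "gff3") read_genes_gff3(path) else read_genes_bed12(path)
}

read_genes_gff3 <- function(path) {
  lines <- prevalidate_tabular(path, min_fields = 9,
                               numeric_fields = c(4, 5))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (any(df$end < df$start)) {
    stop("GFF3 record with end < start in ", path)
  }
  types <- as.character(df$type)
  is_gene <- types == "gene"
  is_mrna <- types %in% c("mRNA", "transcript")
  is_exon <- types == "exon"
  parent1 <- function(p) vapply(p, function(x)
    if (length(x) == 0) NA_character_ else x[[1]], character(1))
  if (!any(is_gene) && any(is_mrna)) {
    # transcript-only files: treat each mRNA as a gene
    is_gene <- is_mrna
    is_mrna <- rep(FALSE, length(types))
  }
  gene_rows <- df[is_gene, , drop = FALSE]
  if (nrow(gene_rows) == 0L) stop("no gene features found in ", path)
  # resolve exon -> gene, possibly via an mRNA level
  mrna2gene <- if (any(is_mrna)) {
    stats::setNames(parent1(df$Parent[is_mrna]), df$ID[is_mrna])
  } else character(0)
  exon_parent <- parent1(df$Parent[is_exon])
  exon_gene <- ifelse(exon_parent %in% names(mrna2gene),
                      mrna2gene[exon_parent], exon_parent)
  exon_df <- df[is_exon, , drop = FALSE]
  exons_by_gene <- split(seq_len(nrow(exon_df)), exon_gene)
  ids <- as.character(gene_rows$ID)
  exons <- lapply(ids, function(id) {
    rows <- exons_by_gene[[id]]
    if (is.null(rows)) {
      g <- gene_rows[gene_rows$ID == id, ]
      return(cbind(start = g$start - 1L, end = g$end))
    }
    ir <- IRanges::reduce(IRanges::IRanges(exon_df$start[rows],
                                           exon_df$end[rows]))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  gene_models(
    gene_id = ids,
    scaffold = as.character(gene_rows$seqnames),
    strand = as.character(gene_rows$strand),
    start = gene_rows$start - 1L,
    end = gene_rows$end,
    exons = exons
  )
}

read_genes_bed12 <- function(path) {
  prevalidate_tabular(path, min_fields = 3, numeric_fields = c(2, 3),
                      comment = "track")
  gr <- rtracklayer::import(path, format = "bed")
  st <- GenomicRanges::start(gr) - 1L   # back to BED 0-based
  en <- GenomicRanges::end(gr)
  if (any(en <= st)) stop("BED record with chromEnd <= chromStart in ", path)
  has_blocks <- !is.null(gr$blocks)
  exons <- lapply(seq_along(gr), function(i) {
    if (has_blocks && length(gr$blocks[[i]]) > 0) {
      b <- gr$blocks[[i]]  # 1-based relative to chromStart
      cbind(start = st[i] + IRanges::start(b) - 1L,
            end = st[i] + IRanges::end(b))
    } else {
      cbind(start = st[i], end = en[i])
    }
  })
  ids <- if (!is.null(gr$name)) as.character(gr$name) else
    paste0("gene", seq_along(gr))
  gene_models(
    gene_id = ids,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = st, end = en, exons = exons
  )
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon features with 1-based inclusive coordinates,
#' deterministically ordered by (scaffold, start, gene_id). Round-trips
#' through [read_gene_annotation()].
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  genes <- genes[order(genes$scaffold, genes$start, genes$gene_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(
      paste(g$scaffold, "sloperon", "gene", g$start + 1L, g$end, ".",
            g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$scaffold, "sloperon", "mRNA", g$start + 1L, g$end, ".",
            g$strand, ".", paste0("ID=", tid, ";Parent=", g$gene_id),
            sep = "\t"),
      vapply(seq_len(nrow(ex)), function(j) {
        paste(g$scaffold, "sloperon", "exon", ex[j, 1] + 1L, ex[j, 2], ".",
              g$strand, ".", paste0("Parent=", tid), sep = "\t")
      }, character(1))
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a repeat track (BED or RepeatMasker .out)
#'
#' Intervals are kept exactly as given (no merging at parse time) and
#' converted to 0-based half-open coordinates. Merging of overlapping
#' repeats happens later, inside [repeat_adjusted_distances()].
#'
#' @param path Repeat file path.
#' @param format `"auto"` (by extension), `"bed"`, or `"repeatmasker"`.
#' @return A data.frame with columns scaffold/start/end
#'   (class `repeat_track`).
#' @export
parse_repeat_track <- function(path, format = c("auto", "bed", "repeatmasker")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.out$", path, ignore.case = TRUE))
      "repeatmasker" else "bed"
  }
  if (format == "bed") {
    lines <- readLines(path)
    keep <- nzchar(lines) & !startsWith(lines, "#") &
      !startsWith(lines, "track")
    if (!any(keep)) {
      return(repeat_track(character(0), integer(0), integer(0)))
    }
    prevalidate_tabular(path, min_fields = 3, numeric_fields = c(2, 3),
                        comment = "track")
    gr <- rtracklayer::import(path, format = "bed")
    return(repeat_track(as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr) - 1L,
                        GenomicRanges::end(gr)))
  }
  # RepeatMasker .out: 3 header lines, whitespace-separated columns;
  # query = col 5, begin = col 6, end = col 7 (1-based inclusive)
  lines <- readLines(path)
  body <- grep("^\\s*\\d", lines)
  scaf <- character(0); st <- integer(0); en <- integer(0)
  for (i in body) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 7) stop("unparseable RepeatMasker record at line ", i,
                            " of ", path)
    b <- suppressWarnings(as.integer(f[6])); e <- suppressWarnings(as.integer(f[7]))
    if (is.na(b) || is.na(e)) stop("unparseable RepeatMasker record at line ",
                                   i, " of ", path)
    scaf <- c(scaf, f[5]); st <- c(st, b - 1L); en <- c(en, e)
  }
  repeat_track(scaf, st, en)
}

repeat_track <- function(scaffold, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("repeat interval with end <= start")
  df <- data.frame(scaffold = as.character(scaffold), start = start,
                   end = end, stringsAsFactors = FALSE)
  class(df) <- c("repeat_track", "data.frame")
  df
}

#' Write a repeat track as BED3
#'
#' @param repeats A `repeat_track` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(repeats, path) {
  repeats <- repeats[order(repeats$scaffold, repeats$start, repeats$end), ]
  writeLines(sprintf("%s\t%d\t%d", repeats$scaffold, repeats$start,
                     repeats$end), path)
  invisible(path)
}
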