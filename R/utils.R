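# Shared helpers: IUPAC degenerate-base handling, reverse complement,
# random sequence generation. All genomic coordinates inside the package
# are 0-based half-open on the forward strand; conversion happens only at
# I/O boundaries (see io-gff.R).

`%||%` <- function(x, y) if (is.null(x)) y else x

# DNA alphabet expansion of the IUPAC single-letter codes
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# Two-letter ambiguity codes, used by the greedy motif generalization
IUPAC_PAIRS <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' The Macrostomum lignano spliced-leader sequence
#'
#' Returns the 35-nt spliced-leader (SL) exon sequence that is
#' trans-spliced onto the 5' end of processed transcripts in
#' *M. lignano*. Used as the default seed/prefix throughout the package.
#'
#' @return A length-one character string (35 nt, DNA alphabet).
#' @export
#' @examples
#' nchar(mlig_sl_sequence())
mlig_sl_sequence <- function() {
  "CGGTCTCTTACTGCGAAGACTCAATTTATTGCATG"
}

# Convert an IUPAC word (DNA or RNA letters) to a plain regular expression.
# U is treated as T.
iupac_regex <- function(word) {
  chars <- strsplit(chartr("U", "T", toupper(word)), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  }
  paste0(vapply(chars, function(ch) {
    exp <- IUPAC_CODES[[ch]]
    if (nchar(exp) == 1L) exp else paste0("[", exp, "]")
  }, character(1)), collapse = "")
}

# Does `seq` match IUPAC `pattern` starting at 1-based position `at`?
iupac_match_at <- function(seq, pattern, at) {
  k <- nchar(pattern)
  if (at < 1L || at + k - 1L > nchar(seq)) return(FALSE)
  grepl(paste0("^", iupac_regex(pattern)), substr(seq, at, at + k - 1L))
}

# First occurrence (1-based start, matched string) of IUPAC `pattern`
# within `seq`, or NULL.
iupac_find_first <- function(seq, pattern) {
  if (nchar(pattern) == 0L) return(NULL)
  m <- regexpr(iupac_regex(pattern), seq)
  if (m[1] == -1L) return(NULL)
  list(start = as.integer(m[1]),
       match = substr(seq, m[1], m[1] + attr(m, "match.length") - 1L))
}

# Vectorized reverse complement on character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna_chars <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

assert_nucleotides <- function(seq, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTUNacgtun]*$" else "^[ACGTUacgtu]*$"
  if (!grepl(pat, seq)) {
    stop(what, " contains non-nucleotide characters")
  }
  invisible(TRUE)
}

# Percentage of num/den at the stated printed precision
#' Report a fraction as a percentage at printed precision
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal digits to round the percentage to.
#' @return `round(100 * num / den, digits)`.
#' @export
#' @examples
#' pct_fraction(21754, 71499, 0)  # 30
pct_fraction <- function(num, den, digits = 1) {
  stopifnot(den > 0)
  round(100 * num / den, digits)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (keeps library calls reproducible
# without trampling the session RNG).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
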