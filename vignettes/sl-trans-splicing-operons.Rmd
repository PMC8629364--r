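---
title: "Detecting SL trans-splicing and inferring operons: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting SL trans-splicing and inferring operons: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

In many lower eukaryotes — flatworms among them — a large fraction of
mRNAs begin with a short *spliced leader* (SL): a constant sequence
(35 nt in *Macrostomum lignano*) donated by a small nuclear SL RNA and
attached to the 5' end of pre-mRNAs by the spliceosome. SL
trans-splicing resolves *operons*: runs of adjacent, co-oriented genes
transcribed as one polycistronic pre-mRNA, in which every gene after
the first must be trans-spliced to become an independent mRNA. The
pre-mRNA region upstream of a trans-splice acceptor, removed during the
reaction, is called the *outron*.

`sloperon` implements the computational side of this biology as an
integrated, testable pipeline:

1. recognize SL-carrying reads, trim the SL, and call genes
   trans-spliced from trimmed-read 5'-end pileups at annotated
   transcription starts;
2. compute intergenic distances between co-oriented neighbours, subtract
   repeat coverage, and chain genes into operons under a distance
   threshold;
3. locate SL RNA gene copies by exact seed search plus donor-site,
   Sm-site and hairpin-structure validation;
4. find enriched junction motifs at cis-donor, cis-acceptor and
   trans-acceptor sites by a discriminative k-mer search;
5. cross-tabulate trans-splicing status against gene conservation and
   cell-type specificity.

A synthetic-genome generator with full planted truth makes every stage
verifiable without any external download.

## Coordinate contract

All genomic intervals inside the package are **0-based half-open on the
forward strand**. Conversion happens only at the I/O boundary: GFF3 and
RepeatMasker `.out` are 1-based inclusive on disk, BED is already
0-based half-open. A gene's span is its transcript span (first exon
start to last exon end); intergenic distances are measured between
these spans. Labels (trans-splicing status, conservation class,
cell-type specificity) live in side TSV tables, not in GFF3 attributes,
because in practice they originate from separate studies.

## Calling trans-spliced genes

`match_sl_prefix()` finds the longest SL *suffix* (at least
`min_overlap` nt) aligning ungapped to a read prefix, tolerating
`floor(overlap/12)` mismatches at the default stringency. The defaults
— `min_overlap = 12`, one mismatch per 12 matched nt — are package
choices: 12 nt keeps the random-match probability near
$4^{-12} \approx 6\times10^{-8}$ while accepting the partial SL
remnants that real library preparations leave on reads, and the
mismatch allowance absorbs ordinary sequencing error.

`call_ts_transcripts()` then marks a gene trans-spliced when at least
`min_reads = 2` strand-concordant trimmed-read 5' ends fall within
`window = 10` nt of its annotated transcription start. Two reads resist
singleton artifacts; the +/-10 nt window absorbs small annotation
imprecision without admitting gene-body hits. Both are exposed as
parameters.

## Operon inference

`adjacent_pairs()` emits immediately adjacent same-strand gene pairs,
suppressing pairs interrupted by an opposite-strand gene whose span
intersects the inter-gene interval (partial overlap counts — the
partial case is genuinely underdetermined and this is the conservative
reading). Genes strictly nested inside another gene are skipped
entirely; overlapping same-strand neighbours get distance 0 and remain
linkable, zero gap being the strongest possible adjacency signal.

`repeat_adjusted_distances()` subtracts from each raw distance the
number of bases covered by the union of repeat intervals (merged, then
clipped to the gap). Repeat insertions accumulate neutrally in operonic
intergenic regions, so the adjusted distance is the better estimate of
the ancestral gene spacing; empirically it is what restores the sharp
~100 bp mode between trans-spliced neighbours.

`distance_distributions()` smooths $\log_{10}(d+1)$ with a Gaussian
kernel at the Silverman bandwidth and reports local maxima mapped back
to bp, plus the valley between the first two modes. Working in log
space is essential because distances span four orders of magnitude;
ties between equal-density maxima break toward the smaller distance.

`call_operons()` applies the linking rule: scanning each scaffold in
transcription order per strand, a pair joins the growing chain iff it
survived the adjacency rules, its adjusted distance is below the
threshold (default 1000 bp, the fixed published rule; the data-driven
valley is reported alongside but deliberately not used unless
requested), and the downstream gene is trans-spliced. A
non-trans-spliced gene may only open a chain — biologically, the first
gene of an operon needs no trans-splicing because its 5' end is made by
capping. Chains are maximal and non-overlapping by construction, so a
gene belongs to at most one operon. For the summaries, the fraction of
trans-spliced genes in operons is `(genes in operons − non-TS first
genes) / total TS genes`.

The distance *plots* merge the two mixed-order categories
(`nonTS->TS`, `TS->nonTS`) into one "mixed" group, while operon
extension stays strictly order-sensitive; this reconciles the
three-category presentation of the distance distributions with the
ordered linking rule.

## SL RNA discovery

`find_sl_seed_hits()` reports every exact occurrence of the SL on
either strand. `call_slrna_genes()` extracts a candidate of
`candidate_length` (default 109 nt, the expected gene size) from each
seed in transcription orientation and accepts it iff

* the donor pattern (default `GTAAG`, configurable to `GTRAG`) sits
  immediately 3' of the SL,
* an Sm-site word matches 3' of the donor (default `RAUUUUNGR`, a
  literature-standard Sm consensus — a package default, flagged as
  such, since the exact site is configurable),
* the fold has at least three hairpin loops, and
* the seed does not coincide (within 50 bp) with the annotated 5' end
  of a trans-spliced protein-coding gene — the annotation-aware guard
  that catches mRNA 5' ends masquerading as SL RNA loci.

The structural check is `fold_max_pairs()`: Nussinov-style base-pair
maximization over Watson–Crick + GU pairs with a minimum hairpin loop
of 3 nt and a deterministic traceback (unpaired preferred at ties, then
the smallest partner). The choice of base-pair maximization over
free-energy folding is deliberate: what qualifies a candidate is
*topological* — the three-hairpin architecture with the SL in the first
hairpin — not energetic, and the dynamic program is exact,
dependency-free and deterministic. Its cost is that the maximum-pair
structure of an arbitrary ~100-nt sequence is not a thermodynamic
prediction; we only ever interpret its hairpin count.

## Motif discovery

`extract_junction_windows()` returns windows of `2*flank` nt (default
100) centered on each junction, normalized so the transcript's 5'→3'
direction reads left to right. `discover_motifs()` is a deliberately
small discriminative search: enumerate every exact word of length 3–8
present in the positives, score each by a one-sided Fisher exact test
on *sequence-containment* counts (a window counts once however many
occurrences it has — the "found in N regions" statistic), correct by
Bonferroni over the words tested, then greedily widen the best word one
position at a time through the two-letter IUPAC codes, keeping changes
that lower the p-value. Accepted motifs are masked out and the search
repeats. The default background is a seeded per-sequence
**dinucleotide shuffle** (Altschul–Erikson), which preserves each
window's dinucleotide multiset exactly.

This is not a full DREME reimplementation (no heap search over regular
expressions, no refinement pass), but it has the same statistic, the
same containment counting, and recovers the same *shape* of motif
(e.g. `GTRAG`-style generalizations). One practical caveat the tests
respect: a 3-nt word such as the acceptor `CAG` is nearly saturated in
100-bp windows, and a dinucleotide-preserving background retains most
of its trinucleotide content, so its enrichment only clears the E-value
cutoff once a few hundred windows are available.

## Enrichment statistics

`conservation_crosstab()` counts genes by trans-splicing status and
conservation class (conserved = detectable homology to human;
non-conserved = coding without such homology; non-coding otherwise),
excluding unknown labels from denominators. Fractions are reported to
one decimal and folds to two, matching conventional printed precision.
`fold_enrichment()` is the ratio of subset to genome-wide proportions;
`chi_square_gof()` is the plain goodness-of-fit statistic with the
upper-tail p from `pchisq`, and a 2×2 contingency wrapper is provided.
Neither test is tuned to reproduce any particular published p-value:
the exact contingency construction behind published figures of this
kind is often unrecoverable, so the package reports both generic forms
and leaves the choice to the analyst.

## The synthetic dataset

`generate_dataset()` plants, deterministically for a given seed:

* **gene neighborhoods** — ~30 % of genes inside operons whose
  internal gaps are lognormal with mode ~100 bp, all other gaps
  lognormal with mode ~5 kb, giving the bimodal adjusted-distance
  structure the method assumes;
* **repeats** — inserted into 30 % of gaps (lognormal lengths, median
  400 bp) and recorded in BED, so raw distances are inflated but
  adjusted distances recover the base gap;
* **trans-splicing** — operonic genes are trans-spliced except a
  fraction (18 %) of first genes; singleton genes fill the overall 30 %
  quota;
* **junction words** — `GTAAG` / `CAG` / `TTTCAG` written at donor,
  acceptor and outron-acceptor junctions with probability 0.9;
* **SL RNA loci** — eight copies of a designed 109-nt construct
  (SL + `GTAAG` + two engineered stems + Sm word) placed intergenically
  on random strands, plus two negative controls: a donor-less copy and
  an SL seed placed exactly at a trans-spliced gene's 5' end;
* **reads** — five SL-prefixed reads per trans-spliced gene with the
  carried SL suffix uniform over 12–35 nt (so partial-SL tagging is
  exercised), plus two body reads per gene, with 5'-end placements
  emitted as TSV (alignment is out of scope; the pipeline consumes
  placements).

Conservation and cell labels are planted conditionally on
trans-splicing status, so the enrichment stage has a real contrast to
find. What the generator does *not* emulate: sequencing error beyond an
optional uniform substitution rate, realistic repeat families,
expression-level variation, alternative isoforms, and genuinely
ambiguous gene models. Passing the planted-truth tests therefore
demonstrates the correctness of the algorithms under the stated
generative assumptions, not performance on real libraries.

Default problem sizes — 2000 genes on 20 scaffolds (~10 Mb), used by
the test suite and the acceptance script — are the package's chosen
balance between statistical resolution (enough windows for the 3-nt
acceptor word, enough pairs for stable modes) and a comfortable
single-CPU runtime.

## Numerical and degenerate-input choices

* Distance modes: density maxima below $10^{-6}$ of the peak are
  ignored; categories with fewer than two distances report no modes;
  an all-equal category reports its single value as the mode.
* `fold_max_pairs` traceback prefers leaving a base unpaired at ties,
  then the smallest pairing partner — one canonical structure per
  sequence.
* Candidates truncated at scaffold ends are folded as-is with a
  warning.
* Genes missing from a ts-status map are treated as non-trans-spliced
  with a warning; placements on unknown scaffolds are skipped with a
  warning.
* When both a label table and reads are supplied, explicit labels
  override read-derived trans-splicing calls (with a logged conflict
  count): curated annotations are taken as the better evidence, and
  this also reproduces the labels-first path of reanalysis studies.

## Known limitations

* The operon caller is a single left-to-right scan: it cannot represent
  overlapping or nested operon structures.
* Base-pair maximization over-pairs relative to thermodynamic folding;
  hairpin counts from it are a liberal structural screen.
* The motif search reports degenerate words, not position weight
  matrices, and its Bonferroni correction is conservative.
* The printed-count arithmetic helpers assume the published counts are
  internally consistent; one published fold (2.13) appears to be a
  truncation of the exact 2.1351, which the package rounds to 2.14.
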