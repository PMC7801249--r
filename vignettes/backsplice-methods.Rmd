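---
title: "Detecting plant circular RNAs from chiastic split reads"
author: "backsplice maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting plant circular RNAs from chiastic split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backsplice)
options(backsplice.verbose = FALSE)
```

# The problem

Circular RNAs (circRNAs) arise by back-splicing: a downstream splice
donor is joined to an upstream splice acceptor, producing a covalently
closed circle. In RNA-seq data the only direct evidence for a circle
is a read spanning the back-splice junction (BSJ). When such a read is
mapped to the linear genome by a chimeric-aware aligner it is split
into two segments in *chiastic* order: the part that comes first in
the read maps *downstream* of the part that comes second (mirrored on
the minus strand). Plant genomes complicate this picture: circRNAs are
comparatively short, gene families are highly duplicated (so split
mappings are easily spurious), and a non-negligible fraction of
introns use the minor (U12) spliceosome with AT-AC boundaries rather
than the major-class GT-AG/GC-AG signals.

`backsplice` detects plant circRNAs from split-read alignments (SAM)
and carries the calls through to functional hypotheses: miRNA binding
sites on the circles, circRNA--mRNA pairs that share miRNAs more often
than chance (candidate competing endogenous RNAs, ceRNAs), an
exportable circRNA--miRNA--mRNA network, and GO terms enriched among
each circle's ceRNA partners.

# Detection model

## Chiastic geometry and strict segment screening

Every read end with exactly two aligned segments (after per-segment
screening) is tested for chiastic order on one chromosome and strand.
Reads with more than two mapped segments are excluded -- a single
back-splice yields exactly two segments -- and up to 5 bp of
read-coordinate overlap between segments is tolerated, since aligners
often re-align a few bases on both sides of the split. Segments must
have at most 2 mismatches and an alignment score of at least 0.8 times
the aligned segment length; these strict criteria guard against the
false splits that repetitive plant gene families produce. Reads whose
two segments map to different strands are discarded as artifactual
chimeras. The candidate interval runs from the acceptor (lower
coordinate, stored as `start`) to the donor (`end`), 1-based
inclusive; all coordinates in the package are 1-based inclusive, with
BED conversion only in the writers.

## Plant-specific screening

Candidates pooled by (chromosome, start, end, strand) are then passed
through:

* **Length thresholds.** Genomic spans above 100 kb are removed; spans
  above 20 kb are kept but flagged `long`. The thresholds reflect the
  short length distribution of plant circRNAs and are applied to the
  genomic span -- the quantity known before any annotation -- while the
  spliced length is reported separately on the isoform table.
* **Splice signals.** The donor/acceptor dinucleotide context is
  classified as GT-AG, GC-AG (U2 spliceosome) or AT-AC (U12 minor
  spliceosome). Together these account for essentially all plant
  splice sites.
* **Site adjustment.** Alternative donor/acceptor usage clusters
  within a few bases of canonical sites, so a candidate with no signal
  is searched over acceptor/donor offsets within a 5 bp window
  (increasing total shift; ties broken by signal priority GT-AG >
  GC-AG > AT-AC, then by the smaller donor shift). Reads whose raw
  sites adjust to the same key are pooled.
* **Annotation anchoring and complementarity.** Signal and annotation
  are treated as complementary evidence: a candidate whose boundaries
  match exon boundaries of one transcript (within 5 bp, same strand)
  is accepted even with signal class `none`, and this anchoring is
  checked *before* any site adjustment. This ordering matters: a
  genuine junction whose flanks mix splicing classes (e.g. an AT-AC
  donor intron with a GT-AG acceptor intron reads as `none`) would
  otherwise be dragged toward a spurious nearby dinucleotide pair by
  the adjustment search.
* **Strand resolution.** Sequencing libraries are effectively
  unstranded at the cDNA level, so junction reads from the
  second strand align with flipped strand. A candidate with no signal
  on its alignment strand but an exact canonical signal on the
  opposite strand is flipped (flag `strand_flipped`). Exact signals
  are trusted over adjusted ones: resolution order is own-strand
  signal, annotation anchor, opposite-strand signal, own-strand
  adjustment, opposite-strand adjustment.
* **Paired-end consistency.** For paired data the mate of a junction
  read must map inside the (5 bp padded) circle interval on the
  opposite strand; a candidate needs at least one such read. Mates may
  themselves wrap the seam. Single-end data pass vacuously.
* **Read support.** At least 2 junction reads by default. The
  threshold is our choice (the method's inputs do not pin it); it is
  the smallest value that rules out singleton mapping artifacts.

## Verification against a junction pseudo-reference

Candidates are re-tested directly against the raw reads. For each
candidate a pseudo-reference entry is built: the last *f* bases of the
circle followed by its first *f* bases (reverse-complemented for minus
candidates), with *f* = min(flank, circle span) so the junction
sequence never wraps. The natural flank is the read length -- a
junction-spanning read cannot need more. A read verifies an entry if,
in either orientation, it aligns across the seam with at least 10
bases on each side and at most 2 mismatches inside the seam-centered
20 bp window; anchoring uses exact 20-mer seeds drawn from the
seam-spanning region of the entry, followed by ungapped comparison.
The original workflow re-runs the external aligner for this step; the
package instead ships this internal seed-and-extend matcher so that
verification is self-contained and testable without any external
binary -- the contract (seam-spanning alignment, anchor and mismatch
caps) is what matters, and the thresholds are all configurable.
Candidates with at least 2 verified reads become circRNAs.

Restricting the mismatch count to the seam window is deliberate: for
an exonic circle whose boundary exon is shorter than the read, the
distal part of a junction read comes from the *next* exon of the
spliced circle and would mismatch the genomic flank; the seam window
(anchored in the boundary exons) is the part every true junction read
must match.

## Full-length sequences

For exonic circRNAs (boundaries matching exon boundaries of a
transcript within 5 bp), each matching transcript contributes one
isoform: its exons inside the interval, spliced and
reverse-complemented as needed. Distinct exon chains give distinct
isoforms; we emit one isoform per distinct chain rather than a merged
exon union, since transcripts sharing boundary exons but differing
internally are exactly the isoform ambiguity a downstream user wants
to see. Intronic and intergenic circles (and exonic ones with no exon
inside the interval, flagged `genomic_fallback`) get the genomic span.
Alternative splicing *within* circRNAs is out of scope.

# miRNA interaction model

Plant miRNAs direct cleavage through near-perfect pairing. Sites are
scored with the standard plant penalty convention: mismatch 1, G:U
wobble 0.5, bulged nucleotide 1, all doubled over miRNA positions
2--13, minimised over alignments with at most one bulge of up to 5 nt
per side (dynamic program, with a brute-force enumeration as the test
oracle). A site is reported below a score cutoff of 3. circRNA
targets are scanned on the circularised sequence (the site may wrap
the BSJ seam; wrapped hits are de-duplicated by modular position).

Endogenous target mimics (miRNA sponges) are called by three rules:
(R1) perfect Watson--Crick pairing at miRNA positions 2--8; (R2) a
single bulge of 1--5 unpaired target nucleotides opposite miRNA
positions 9--11 -- the bulge that blocks cleavage -- and no other
bulge; (R3) at most 4 combined mismatches plus G:U pairs elsewhere.
These encode the standard endogenous-target-mimic criteria of the
plant literature; the exact rule set of any particular tool is not
published as a formula, so every constant is exposed in
`mirnaParams()` and the rules should be read as our documented,
configurable encoding. A cleavage call at coordinates identical to a
mimic call is suppressed (the bulge blocks cleavage), making the
classification exclusive per site.

# ceRNA pairs, network, GO

For a circRNA hit by $K$ of the $N$ scanned miRNAs and an mRNA hit by
$n$ of them, the number of shared miRNAs $k$ is tested against the
hypergeometric upper tail $P(X \ge k)$, computed in log space from
`lchoose` for stability. The test is applied per pair (the method
description leaves pooling unspecified; per-pair testing is the
conservative reading), p-values are Benjamini--Hochberg adjusted
across all tested pairs -- the original names no correction; BH at
$q \le 0.05$ is the field default and is configurable to none or
Bonferroni -- and retained pairs define the circRNA--miRNA--mRNA
network (edges `binds` and `targets`, exportable as Cytoscape-loadable
SIF or TSV with deterministic ordering). The miRNA universe $N$
defaults to the distinct miRNAs in the input FASTA and can be
overridden for species-level universes.

Functions are assigned per circRNA by GO enrichment of its ceRNA
partners against the background of all annotated genes, again
hypergeometric with per-circRNA BH adjustment; with an OBO ontology
(only `id`, `name`, `is_a` are parsed) annotations are propagated to
ancestors first.

# The simulator: what it emulates, and what it does not

`simulateBenchmark()` generates the package's calibrated benchmark:

* a random multi-gene genome (default 4 x 500 kb chromosomes, 500
  non-overlapping single-transcript genes, 4--8 exons of 80--300 bp,
  introns 60--200 bp, random strands). Every intron is written with
  canonical boundary dinucleotides on the transcribed strand (5%
  GC-AG and 2% AT-AC by default, the rest GT-AG), and terminal exon
  boundaries also receive GT/AG context so that any exon-boundary
  pair is a signal-bearing back-splice site;
* 200 circRNAs, one per sampled multi-exon transcript, each a pair of
  exon boundaries with spliced length of at least the read length
  plus 20 (so a junction read cannot wrap the circle twice);
* 6000 BSJ fragments (the benchmark's read budget) distributed
  multinomially with a floor of 2 per circle -- totals are fixed but
  per-circle depth is not, so the multinomial is the least-informative
  choice -- as paired-end 100 bp reads. Read 1 spans the seam with at
  least 10 bases each side; fragment lengths are N(250, 25) truncated
  to the circle, and mates are drawn from inside the circle (possibly
  wrapping the seam themselves);
* 6000 linear background fragments from the non-circle transcripts;
* uniform per-base substitution errors (0 by default; the benchmark's
  error regime uses 0.5%).

Two outputs make the pipeline testable with no aligner: FASTQ reads
for end-to-end runs through a real mapper, and a truth-derived SAM in
which the simulator plays an idealised chimeric-aware spliced aligner
-- primary plus hard-clipped supplementary records with `SA`, `NM` and
`AS` tags, `N` operations across introns, and colinear split records
for background reads that span an exon junction with at least 15 bases
on both sides. `AS` is modelled as aligned length minus 5 per
mismatch, mirroring a BWA-like penalty. Everything is byte-
deterministic under a seed.

What the simulator does *not* emulate -- and hence what passing the
benchmark does not show about real data: real plant genome composition
(repeats, gene-family paralogy, GC structure), indels and
quality-dependent errors, alignment ambiguity from a real mapper
(the truth-derived SAM has no mismapping), expression-level variation
beyond the multinomial, and intra-circRNA alternative splicing.
Accuracy on the benchmark is therefore an upper bound with respect to
mapping noise, while the geometry, screening, verification and
bookkeeping it exercises are exactly the production code paths.

# Numerical and design choices

* Tie-breaks in site adjustment are fully deterministic (total shift,
  then signal priority, then smaller and then signed donor offset,
  then acceptor offset).
* Junctions at chromosome edges get signal `none` rather than an
  exception; degenerate inputs (empty candidate sets, empty pair
  lists, circles with no partners) propagate as empty results.
* `hypergeomSF` sums the tail in log space with a log-sum-exp guard;
  exhaustive enumeration over all parameters with $N \le 60$ agrees
  to $10^{-9}$ (see the test suite).
* Some split-read circRNA callers rank split mappings with a
  maximum-likelihood multiple-seed-matching estimator whose internals
  are not published; this package instead uses the deterministic
  chiastic-geometry test plus the strict per-segment thresholds, with
  the observable contract (the benchmark accuracy) as the design
  target.
* T and U are treated as identical; all sequences are normalised to
  the DNA alphabet on input.
* Problem sizes in the test suite are scaled for a desktop run: the
  full benchmark (2 Mb genome, 200 circles, 12,000 fragments) runs in
  about three minutes; unit tests use 60--120 kb genomes with tens of
  circles.

# Known limitations

* The detector consumes text SAM (at benchmark scale this is
  deliberate -- no binary parsing); BAM/CRAM inputs should be
  converted upstream.
* The miRNA scanner is exact but quadratic in target length times
  miRNA count; it is meant for circRNA/mRNA-scale inputs, not
  genome-wide scans.
* Fusion (inter-chromosomal) circRNAs, rolling-circle concatemers,
  degradome evidence and thermodynamic site scoring are out of scope.

# A worked run

```{r benchmark, eval = FALSE}
res <- runBenchmark(simParams(errorRate = 0.005), seed = 101)
res$metrics
```

The acceptance script (`scripts/acceptance.R`) reruns exactly this
computation from scratch for an error regime and an error-free regime
and writes the metrics as JSON.
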