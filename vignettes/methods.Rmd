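---
title: "Methods: assembly diffing, effect classification and kinetics summaries in straindelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly diffing, effect classification and kinetics summaries in straindelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straindelta)
```

straindelta compares two near-identical assembled bacterial genomes and
summarizes what the differences do: a classified variant table, a
direct-repeat signature for deletions, motif-level methylome summaries from
SMRT kinetics, and regulatory-locus statistics.  This vignette records the
models and procedures, the parameters that matter, the numerical choices, and
the limits of what the synthetic data can demonstrate.

## Assembly-level variant calling

Read-level resequencing pipelines call variants by mapping reads to a
reference.  When both strains are available as closed assemblies, the same
information can be extracted by comparing the assemblies directly, which is
what `call_variants()` does:

1. **Anchoring.** Every `k`-mer occurring exactly once in *each* genome is an
   anchor (`find_anchors()`).  The default `k = 31` is long enough that
   essentially all positions of an AT-rich desk-scale chromosome are unique,
   and short enough to tile the gaps between nearby variants.  `k` must be at
   least 11; raise it for genomes with long exact repeats.
2. **Chaining.** The maximum set of anchors strictly increasing in both
   coordinates is kept — a longest-increasing-subsequence computation on the
   alternate coordinate after sorting by the reference coordinate
   (`chain_anchors()`), ties resolved toward the smaller alternate offset.
   Anchors displaced by rearrangement drop out here.  Chained anchors are
   then thinned to a non-overlapping tiling so every inter-anchor gap is
   well-defined on both genomes.
3. **Gap alignment.** Each gap is aligned end-to-end under unit edit cost
   (match 0, mismatch −1, gap base −1).  The implementation is a three-state
   Gotoh DP with an *infinitesimal* gap-opening penalty (−1/1024).  The
   opening penalty never changes which scripts are optimal under unit cost
   (total openings are far too few to accumulate one cost unit); it exists
   only to resolve ties among equal-cost scripts in favour of contiguous
   indel runs, so a 24-bp deletion is reported as one deletion rather than an
   arbitrary equal-cost fragmentation.  Remaining ties break deterministically:
   match/mismatch over gap, deletion over insertion, gap extension over gap
   opening.
4. **Normalization.** The edit script becomes VCF-style calls: substitutions
   as single bases, indels carrying one anchor base and left-aligned by the
   standard shift rule (`normalize_variant()`, idempotent).  Applying all
   calls to the reference reconstructs the alternate sequence exactly, and
   the suite enforces this round trip on every tested pair.

**Circular genomes.** Two closed assemblies of the same chromosome may start
at different rotations.  When both inputs are circular and the first chained
anchor sits off the main diagonal, the alternate sequence is rotated so the
anchor becomes diagonal and anchoring is redone; reported coordinates always
stay in the reference frame.  Variants whose footprint spans the reference
origin itself are outside scope.

**Degenerate inputs.** No unique shared `k`-mer (for instance a purely
periodic sequence) raises an explicit "too divergent or too repetitive"
error.  Inter-anchor gaps longer than `max_gap` (default 50 kb) abort with a
structural-variation error rather than attempting an alignment that the
unit-cost model cannot interpret.

## Effect classification

`classify_variant()` maps a call onto the (non-overlapping) CDS annotations
and classifies it:

* substitutions: the affected codon is read on the coding strand (reverse
  complement for minus-strand genes) and translated with the standard
  genetic code; identical residues are **silent**, a new stop is **nonsense**,
  and anything else is **conservative** iff the BLOSUM62 entry for the
  residue pair is positive, otherwise **nonconservative**;
* deletions wholly inside a CDS: **in-frame** iff the length is divisible by
  3, else **frameshift**; deletions spanning a CDS boundary are conservatively
  filed as frameshift with a warning;
* insertions in a CDS follow the same divisibility rule (`inframe_insertion`
  / `frameshift`) — the class exists for completeness even though the
  generator never plants insertions;
* anything outside every CDS is **intergenic**.

The BLOSUM62 sign rule deserves a note: published variant tables rarely state
a quantitative criterion for "conservative", and hand-curated tables are not
always internally consistent.  A fixed, published matrix makes the partition
reproducible, and the synthetic generator plants its quotas under the same
rule, so recovery checks are self-consistent by construction.  Start codons
are treated as ordinary codons for effect calling; no planted variant targets
position 1.

**Residue ranges.** For an in-frame deletion, `residue_range()` translates
the reference and mutant CDS and reports the first and last deleted residues
after the maximal common prefix.  This protein-level convention matters for
repeat-flanked deletions: when the deleted segment begins with the same bases
that follow it, the nucleotide-level and protein-level placements differ by
the repeat overlap, and the maximal-prefix rule gives the canonical
(left-most protein change) answer for plus- and minus-strand genes alike.

**Direct repeats.** `flanking_repeat()` computes the maximal `m` with
`genome[s, s+m) == genome[s+d, s+d+m)` for a left-aligned deletion — brute
force over `m`, checked in the suite against an independent scan.  A repeat
length of several bases is the classic footprint of homologous recombination
between direct repeats, which removes the intervening spacer and one repeat
copy.

## Synthetic data: what it emulates and what it does not

The generator stands in for unreleased raw data; its defaults *are* the study
conditions of the package's acceptance checks and were fixed before any
measurements were taken.

* **Reference** (`generate_reference()`): a circular chromosome of
  configurable length and GC (default profile: 200 kb at GC 0.30 — a
  desk-scale stand-in for a ~4.35-Mb, ~30 %-GC clostridial chromosome, small
  enough for a full run in seconds yet with enough codons for every quota),
  carrying non-overlapping CDSs on both strands (default 150 genes of mean
  length 900 bp, lengths normal on the codon scale, floored at 60 codons).
  CDSs are built codon-by-codon from a stop-free pool at codon probabilities
  induced by the base composition, so "ATG start, stop end, no internal
  stop" holds by construction, not by rejection.  Intergenic spacers are
  i.i.d. at the profile GC.  Excluding the three AT-rich stop codons nudges
  coding GC up by well under a percentage point, comfortably inside the
  ±0.02 tolerance the suite checks at 10 kb.
* **Variant planting** (`plant_variants()`): substitutions are drawn by
  rejection sampling — pick a gene (length-weighted) or intergenic position,
  a codon away from start/stop, a random alternative base, classify with the
  *same* classifier used downstream, and accept only on class match, capped
  at 10,000 attempts per variant (bounded runtime with a clear failure
  naming the class).  Planted positions keep ≥ 150 bp separation, stay clear
  of the deletion construct and the sequence ends, so every call is resolved
  independently by the anchored diff.  The default quota mirrors the
  partition 10 intergenic / 14 silent / 14 conservative / 27 nonconservative /
  1 nonsense, plus the deletion: 67 variants.
* **The deletion construct**: the reference receives, in frame, one guard
  base, the deleted sequence (`repeat+spacer`, 24 bp by default), a second
  repeat copy and a padding codon; the mutant then loses `repeat+spacer`.
  Guard base and padding codon are chosen deterministically so that neither
  reading frame gains a stop, the deletion cannot left-shift out of the
  construct, and the repeat cannot extend beyond its nominal length.  The
  default profile plants the segment at codon 232, which places the
  protein-level deleted range at residues 235–242 (the repeat prefix aligns
  the three junction codons).  In-frame planting requires
  `|deleted| + |repeat| ≡ 2 (mod 3)`; other phases raise an error rather
  than silently shifting the construct.
* **Kinetics** (`simulate_kinetics()`): one IPD ratio per position and
  strand, log-normal with the *arithmetic* mean set by the most specific
  cytosine context (defaults: first C of `CGCG` 1.25, second C 1.11, `CG`
  0.89, other C 0.86, background 1.00) because downstream summaries report
  plain averages (`mu = log(m) − sigma²/2`).  The dispersion
  `lognormal_sigma = 0.25` is a model assumption, not a measured value — no
  dispersion accompanies the published averages this profile mirrors.
  Modification QVs are normal (modified mean 86, unmodified mean 5, sd 8,
  truncated at zero) around a call threshold of 30; each duplex motif site is
  methylated with its motif's detection fraction (defaults: the five m6A
  motifs of `default_m6a_motifs()` at 99.65 / 99.61 / 99.03 / 99.14 /
  97.10 %), and a methylated site draws the modified QV on every
  motif-bearing strand.  Coverage is Poisson with mean 58 and is carried but
  never filtered on — the summaries report mean coverages and no cutoff is
  applied by default.
* **The kinetics stand-in genome** (`kinetics_profile()`) is 600 kb of
  balanced composition (GC 0.5).  The choice is deliberate: cytosine-context
  recovery needs thousands of `CGCG` sites (the two-standard-error check is
  meaningless with dozens), and an AT-rich 200-kb sequence carries only
  ~100.  At GC 0.5, ~2,300 `CGCG` duplex sites give ~4,700 first-C strand
  observations; with sd ≈ 0.32 that makes the standard error of the group
  mean ≈ 0.005.

What passing these checks shows — and does not.  The generator produces
i.i.d. composition, clean assemblies, no sequencing error, no repeats beyond
the planted one, and kinetics that follow the model exactly.  Recovery
therefore demonstrates the *correctness of the algorithms under their stated
assumptions*, not robustness to misassembly, low complexity regions,
context-dependent IPD beyond the four cytosine groups, or partial
methylation heterogeneity in real data.  Published exact p-values from raw
kinetics are functions of data that is not available; the package's Welch
comparison is a direction-and-significance check (the default conditions
reject the `CGCG`-vs-background null far below 1e−4), never a numeric
reproduction.

## Methylome conventions

* **Site counting.** A motif's genomic count is the number of *duplex
  footprints* carrying the motif on at least one strand.  A palindromic
  motif (`GATC`) therefore counts once per site, and a motif and its partner
  (IUPAC-aware reverse complement, `partner_motif()`, an involution)
  summarize the identical site set — both properties match how motif tables
  are conventionally printed.
* **Detection.** A site is detected when the modification QV at the
  modified-position base reaches the threshold (default 30, a configuration
  choice, as is the overspecification minimum count of 30) on any
  motif-bearing strand.  With zero genomic sites the summary is returned
  flagged with `NA` means rather than silent NaNs.
* **Cytosine contexts are mutually exclusive**: `C_other` excludes C
  followed by G; `CG_firstC` excludes `CGCG` occurrences; a C that is both
  a first C of one `CGCG` and the second C of an overlapping one counts as
  first C.  Without exclusion, the background group would contain the very
  sites being tested.  Context statistics pool both strands; contexts are
  read 5'→3' per strand, so `CGCG` (self-reverse-complementary) contributes
  a first-C observation on each strand of every site.

## Locus comparison conventions

* 0A-box scans use the consensus `5'-TGNCGAA-3'` on either strand within a
  300-bp upstream window by default; no promoter window convention is
  standard, so the window is exposed as configuration.  Upstream is 5' of
  the gene on its own strand; hits must lie wholly inside the window.
* Intergenic gaps are bases strictly between consecutive genes
  (`next_start − prev_end − 1`), order-invariant, erroring on overlap.
* Percent identity is identical columns over total alignment columns (gaps
  in the denominator), from end-to-end alignment with DNA +1/−1/−2 or
  protein BLOSUM62/−8.  Identity conventions differ across the literature by
  several points depending on denominator and gap handling, so values should
  be compared across sequences under this one convention rather than against
  numbers computed under unknown ones.  Arguments are canonically ordered
  before aligning so the reported identity is symmetric even when co-optimal
  alignments disagree.

## Numerical and design choices

* Coordinates are 0-based half-open internally and 1-based inclusive in all
  outputs (VCF, GFF3; BED is 0-based half-open as required).
* All randomness flows through explicit integer seeds; identical profile and
  seed give byte-identical outputs, which the suite verifies.
* The Welch test accepts summary statistics `(n, mean, sd)` so it can be
  driven from context summaries without retaining per-position vectors; both
  variances zero is handled explicitly (p = 1 on equal means, p = 0 flagged
  degenerate otherwise; n < 2 is an error).
* Alignment kernels live in C++ (Rcpp) because the deterministic tie-break
  order is part of the contract and a fixed implementation is easier to
  guarantee than a wrapped third-party aligner; pure-R DP oracles in the
  test suite check scores independently.
* Overlapping gene models are rejected at load time; codon mapping assumes a
  unique gene per position, which the generator guarantees and typical
  bacterial CDS sets satisfy after de-duplication.

## Problem sizes

The suites and the acceptance script run the default conditions end to end:
a 3-kb worked-example fixture, the 200-kb strain pair with 67 planted
variants, and 600 kb of simulated kinetics (1.2 M position–strand records).
These sizes were chosen so a complete run takes seconds on a single core
while leaving every statistical check comfortably powered; all of them scale
linearly if larger stand-ins are wanted.

## Known limitations

* No read-level simulation (FASTQ/BAM), sequencing-error model, plasmids or
  multi-replicon genomes.
* No structural-variant or rearrangement calling; long inter-anchor gaps
  fail loudly instead.
* Motif analysis summarizes *given* motifs; de novo motif discovery from
  kinetics is out of scope.
* Variants spanning the circular origin of the reference are not called.
* m4C/m5C chemistry is not modelled beyond the generic context-mean
  mechanism.
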