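# straindelta

Toolkit for asking, of two near-identical assembled bacterial genomes —
typically a parent strain and a laboratory-evolved or mutagenized daughter —
*what changed, what it does to the proteome, and what the accompanying SMRT
kinetics say about the methylome*.  It grew out of resequencing studies of
solventogenic *Clostridium* strains, where a handful of point mutations and a
single recombination-mediated deletion in a master regulator can explain a
selected phenotype, but all of its parts are organism-agnostic.

The package covers five connected analyses:

1. **Assembly-level variant calling** (`call_variants`).  Instead of mapping
   reads, the two assemblies are compared directly: *k*-mers unique in both
   genomes act as anchors, a longest-increasing-subsequence chain keeps the
   collinear subset, and each inter-anchor gap is globally aligned by
   unit-cost edit distance (Gotoh three-state DP with deterministic
   tie-breaks).  The edit script becomes left-aligned, parsimonious VCF-style
   calls; applying them to the reference reconstructs the alternate genome
   exactly.
2. **Codon-aware effect classification** (`classify_variant`).  Substitutions
   in a CDS are translated on the coding strand with the standard genetic
   code and partitioned into *silent*, *nonsense* (new stop), *conservative*
   (BLOSUM62 score > 0) or *nonconservative* (score ≤ 0); deletions are
   *in-frame* iff their length is divisible by 3.  Shorthand follows the
   field's notation: `A267V`, `Q641*`, `Silent`, `Del. 235–242`.
3. **Direct-repeat deletion signatures** (`flanking_repeat`).  For a deletion
   of *d* bases starting at offset *s*, the flanking repeat length is
   max{ *m* : genome[*s*, *s*+*m*) = genome[*s*+*d*, *s*+*d*+*m*) } — the
   footprint of homologous recombination between two short direct repeats
   that collapsed to one copy.
4. **Methylome summaries from SMRT kinetics** (`scan_motif`, `motif_summary`,
   `context_mean_ipd`, `welch_t`).  IUPAC degenerate motifs are enumerated on
   both strands (circular-aware); per-motif detection percentages, mean
   modification QV and coverage mirror the usual motif-table layout; cytosine
   interpulse-duration (IPD) ratios are compared across mutually exclusive
   contexts (first/second C of `CGCG`, `CG`, other `C`) with Welch
   heteroscedastic *t*-tests,
   *t* = (m₁−m₂)/√(s₁²/n₁+s₂²/n₂) with Welch–Satterthwaite degrees of
   freedom.
5. **Regulatory locus comparison** (`scan_0a_boxes`, `intergenic_gaps`,
   `pairwise_identity`).  Spo0A-binding sites (0A box, `5'-TGNCGAA-3'`) are
   scanned upstream of genes; operon tightness is read off intergenic gaps;
   percent identity comes from global DNA (match +1 / mismatch −1 / gap −2)
   or protein (BLOSUM62, gap −8) alignment.

Because the raw sequencing data such studies rely on is typically not
deposited, the package includes a first-class **synthetic-data generator**
(`generate_reference`, `plant_variants`, `simulate_kinetics`): seeded,
profile-driven genomes with stop-free CDSs, a planted substitution mix whose
classes are enforced by rejection sampling against the package's own
classifier, one repeat-flanked in-frame deletion, and log-normal IPD kinetics
with context-dependent means.  Every downstream analysis is therefore
testable end to end with no downloads.

## Worked example

The canonical deletion case: a reference CDS carrying
`ATACCATAAATAAATTATTTGGAT` followed by a second copy of its 8-bp prefix
`ATACCATA`, and a mutant with the 24-mer removed.

```r
library(straindelta)

fx <- spo0a_fixture()
calls <- call_variants(fx$reference, fx$mutant, k = 31)
calls
#>           chrom pos                       ref alt     type
#> 1 synthetic_ref 461 AATACCATAAATAAATTATTTGGAT   A deletion

flanking_repeat(fx$reference, calls[1, ], fx$annotations)
#> $repeat_length
#> [1] 8
#> $repeat_sequence
#> [1] "ATACCATA"
#> $in_frame
#> [1] TRUE
#> $deleted_residue_range
#> [1] 103 110
```

One deletion call of 24 bp, flanked by the 8-bp direct repeat, removing eight
residues in frame — the recombination signature the repeat analysis is built
to detect.

The default strain-pair profile (200 kb, GC 0.30, 150 genes) plants 66
substitutions plus the deletion and recovers them exactly:

```r
sim   <- simulate_strain_pair(default_strain_profile())
calls <- call_variants(sim$reference, sim$mutant)
eff   <- classify_variants(calls, sim$annotations, sim$reference)
summarize_effects(eff)
#>        intergenic            silent      conservative   nonconservative
#>                10                14                14                27
#>          nonsense  inframe_deletion inframe_insertion        frameshift
#>                 1                 1                 0                 0
```

Simulated kinetics recover the configured cytosine-context IPD means, and the
elevated first-C-of-`CGCG` signal separates decisively from background
cytosines:

```r
kp <- kinetics_profile(seed = 7)
context_mean_ipd(kp$genome, kp$track, "CGCG_firstC")$mean   # ~1.25
context_mean_ipd(kp$genome, kp$track, "C_other")$mean       # ~0.86
welch_t(context_mean_ipd(kp$genome, kp$track, "CGCG_firstC"),
        context_mean_ipd(kp$genome, kp$track, "C_other"))
#> Welch two-sample t-test: t = 82.86, df = 4718.18, p (two-sided) = 0

print(motif_summary(kp$genome, default_m6a_motifs()$GATC, kp$track))
#> <motif_summary> GATC: 2279/2293 sites detected (99.39%), mean QV 85.8,
#>   mean coverage 58.0, partner GATC
```

A thin shell interface wraps the same functions
(`exec/straindelta simulate|diff|effects|methylome|loci|run`), and
`run_pipeline()` drives all stages into a report directory with the effective
configuration echoed alongside.

## Package layout

- `R/` — one file per analysis module (synthetic data, genome diff, variant
  effects, methylome, locus comparison, pipeline).
- `src/` — the Gotoh alignment and LIS chaining kernels (Rcpp).
- `vignettes/methods.Rmd` — the model, its assumptions, all tunable
  parameters, and what the synthetic data does and does not emulate.
- `tests/testthat/` — unit, property and end-to-end suites with independent
  pure-R DP and statistics oracles.
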