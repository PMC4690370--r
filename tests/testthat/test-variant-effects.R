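# small hand-built gene fixtures -------------------------------------------

# genome with one plus-strand gene: ATG <codons> TAA, flanked by fixed pads
make_gene_genome <- function(codons, pad = "GGTTCCAAGGTTCCAA") {
  cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  seq <- paste0(pad, cds, pad)
  list(genome = genome_record("g", seq, topology = "linear"),
       ann = gene_annotations("g1", nchar(pad) + 1L, nchar(pad) + nchar(cds),
                              "+", "test protein"),
       cds_start = nchar(pad) + 1L)
}

sub_call <- function(genome, pos, alt) {
  data.frame(chrom = genome$id, pos = pos, ref = substr(genome$seq, pos, pos),
             alt = alt, type = "substitution", stringsAsFactors = FALSE)
}

test_that("coding substitutions produce residue-accurate shorthand", {
  # codon 2 GCT (Ala); second base C->T gives GTT (Val): A2V, nonconservative
  fx <- make_gene_genome(c("GCT", "CAA"))
  pos <- fx$cds_start + 4L
  eff <- classify_variant(sub_call(fx$genome, pos, "T"), fx$ann, fx$genome)
  expect_identical(eff$shorthand, "A2V")
  expect_identical(eff$effect_class, "nonconservative")  # BLOSUM62(A,V) = 0
  expect_identical(eff$gene_id, "g1")
  expect_equal(eff$aa_position, 2L)
  # third-position synonymous change GCT->GCC stays alanine: silent
  eff2 <- classify_variant(sub_call(fx$genome, fx$cds_start + 5L, "C"),
                           fx$ann, fx$genome)
  expect_identical(eff2$effect_class, "silent")
  expect_identical(eff2$shorthand, "Silent")
  # CAA (Gln) -> TAA at codon 3: premature stop, Q3*
  eff3 <- classify_variant(sub_call(fx$genome, fx$cds_start + 6L, "T"),
                           fx$ann, fx$genome)
  expect_identical(eff3$effect_class, "nonsense")
  expect_identical(eff3$shorthand, "Q3*")
  # GTT (Val) -> ATT (Ile) is conservative: BLOSUM62(V,I) = 3 > 0
  fx4 <- make_gene_genome(c("GTT"))
  eff4 <- classify_variant(sub_call(fx4$genome, fx4$cds_start + 3L, "A"),
                           fx4$ann, fx4$genome)
  expect_identical(eff4$effect_class, "conservative")
  expect_identical(eff4$shorthand, "V2I")
  # outside any CDS: intergenic
  eff5 <- classify_variant(sub_call(fx$genome, 2L, "A"), fx$ann, fx$genome)
  expect_identical(eff5$effect_class, "intergenic")
  expect_true(is.na(eff5$gene_id))
  # out of bounds errors
  expect_error(classify_variant(data.frame(chrom = "g", pos = 10000L,
                                           ref = "A", alt = "C",
                                           type = "substitution"),
                                fx$ann, fx$genome),
               "bounds")
})

test_that("every synonymous single-base codon change is silent (exhaustive)", {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  n_checked <- 0L
  for (cod in codons) {
    if (gc_tab[[cod]] == "*") next
    fx <- make_gene_genome(c(cod))
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cod, p, p))) {
        alt_cod <- cod
        substr(alt_cod, p, p) <- b
        eff <- classify_variant(sub_call(fx$genome, fx$cds_start + 2L + p, b),
                                fx$ann, fx$genome)
        if (gc_tab[[alt_cod]] == gc_tab[[cod]]) {
          expect_identical(eff$effect_class, "silent")
          n_checked <- n_checked + 1L
        } else {
          expect_false(eff$effect_class == "silent")
        }
      }
    }
  }
  expect_gt(n_checked, 100L)   # the synonymous pairs really were exercised
})

test_that("classification is strand-symmetric", {
  set.seed(10)
  for (rep in 1:20) {
    codons <- sample_plus <- NULL
    cods <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
    codons <- sample(cods, 5, replace = TRUE)
    fx <- make_gene_genome(codons)
    L <- nchar(fx$genome$seq)
    # mirrored construct: reverse-complement genome, gene on minus strand
    g_rc <- genome_record("g", revcomp_str <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(fx$genome$seq))),
      topology = "linear")
    ann_rc <- gene_annotations("g1", L - fx$ann$end + 1L,
                               L - fx$ann$start + 1L, "-", "test protein")
    pos <- fx$cds_start + 3L + sample(0:(3 * 5 - 1), 1)   # inside codons 2..6
    alt <- sample(setdiff(c("A", "C", "G", "T"),
                          substr(fx$genome$seq, pos, pos)), 1)
    eff_plus <- classify_variant(sub_call(fx$genome, pos, alt), fx$ann,
                                 fx$genome)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pos_rc <- L - pos + 1L
    eff_minus <- classify_variant(sub_call(g_rc, pos_rc, unname(comp[alt])),
                                  ann_rc, g_rc)
    expect_identical(eff_minus$effect_class, eff_plus$effect_class)
    expect_identical(eff_minus$shorthand, eff_plus$shorthand)
  }
})

test_that("effect summaries partition their input", {
  empty <- summarize_effects(data.frame(effect_class = character(0)))
  expect_true(all(empty == 0L))
  set.seed(11)
  prof <- generator_profile(genome_length = 30000L, gc_fraction = 0.30,
                            n_genes = 15L, mean_gene_length = 900L,
                            substitution_quota = c(intergenic = 3L, silent = 3L,
                                                   conservative = 3L,
                                                   nonconservative = 3L),
                            seed = 12L)
  sim <- simulate_strain_pair(prof)
  calls <- call_variants(sim$reference, sim$mutant)
  eff <- classify_variants(calls, sim$annotations, sim$reference)
  counts <- summarize_effects(eff)
  expect_equal(sum(counts), nrow(eff))
  expect_equal(unname(counts[c("intergenic", "silent", "conservative",
                               "nonconservative")]),
               rep(3L, 4))
})

test_that("flanking repeats match the brute-force scan", {
  # canonical worked example: deleted allele + repeat + non-matching base
  fx <- spo0a_fixture()
  del <- call_variants(fx$reference, fx$mutant)[1, ]
  sig <- flanking_repeat(fx$reference, del, fx$annotations)
  expect_equal(sig$repeat_length, 8L)
  expect_identical(sig$repeat_sequence, "ATACCATA")
  expect_true(sig$in_frame)
  expect_equal(sig$deleted_residue_range[2] - sig$deleted_residue_range[1] + 1L,
               8L)
  # deleted segment AAA followed by GGG: no repeat
  g <- genome_record("g", "TTTTCAAAGGGTTTT", topology = "linear")
  call <- data.frame(chrom = "g", pos = 5L, ref = "CAAA", alt = "C",
                     type = "deletion")
  sig2 <- flanking_repeat(g, call)
  expect_equal(sig2$repeat_length, 0L)
  expect_identical(sig2$repeat_sequence, "")
  # randomized deletions against the exhaustive-m oracle
  set.seed(13)
  for (rep in 1:40) {
    seq <- rand_seq(300, gc = 0.4)
    s <- sample(10:200, 1); d <- sample(1:30, 1)
    g3 <- genome_record("g", seq, topology = "linear")
    call3 <- data.frame(chrom = "g", pos = s,
                        ref = substr(seq, s, s + d), alt = substr(seq, s, s),
                        type = "deletion")
    expect_equal(flanking_repeat(g3, call3)$repeat_length,
                 repeat_len_oracle(seq, s, d))
  }
  # non-deletions are rejected
  expect_error(flanking_repeat(g, data.frame(chrom = "g", pos = 2L, ref = "T",
                                             alt = "A", type = "substitution")),
               "deletion")
})

test_that("residue ranges are exact for codon-aligned and minus-strand deletions", {
  # 24-base codon-aligned deletion starting at codon 5 removes residues 5..12
  codons <- c("GCT", "CAA", "GTT", "AAA", "CCT", "GAA", "TTC", "GGA", "CAT",
              "ATC", "TGG", "AGA", "CTT", "AAG")
  fx <- make_gene_genome(codons)
  s <- fx$cds_start + 4 * 3L   # first base of codon 5 (after ATG + 3 codons)
  del24 <- data.frame(chrom = "g", pos = s - 1L,
                      ref = substr(fx$genome$seq, s - 1L, s + 23L),
                      alt = substr(fx$genome$seq, s - 1L, s - 1L),
                      type = "deletion")
  expect_equal(residue_range(del24, fx$ann[1, ], fx$genome), c(5L, 12L))
  # 3-base deletion of codon 2 (first codon after ATG) reports (2, 2)
  del3 <- data.frame(chrom = "g", pos = fx$cds_start + 2L,
                     ref = substr(fx$genome$seq, fx$cds_start + 2L,
                                  fx$cds_start + 5L),
                     alt = substr(fx$genome$seq, fx$cds_start + 2L,
                                  fx$cds_start + 2L),
                     type = "deletion")
  expect_equal(residue_range(del3, fx$ann[1, ], fx$genome), c(2L, 2L))
  # minus-strand gene: verified against a translate-and-diff oracle
  L <- nchar(fx$genome$seq)
  g_rc <- genome_record("g", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fx$genome$seq))), topology = "linear")
  ann_rc <- gene_annotations("g1", L - fx$ann$end + 1L, L - fx$ann$start + 1L,
                             "-", "test protein")
  s_rc <- L - (s + 23L) + 1L       # genomic start of the mirrored 24-mer
  del_rc <- data.frame(chrom = "g", pos = s_rc - 1L,
                       ref = substr(g_rc$seq, s_rc - 1L, s_rc + 23L),
                       alt = substr(g_rc$seq, s_rc - 1L, s_rc - 1L),
                       type = "deletion")
  rr <- residue_range(del_rc, ann_rc[1, ], g_rc)
  # oracle: translate reference and mutant coding sequences and diff
  ref_aa <- strsplit(translate_cds(cds_sequence(g_rc, ann_rc[1, ])), "")[[1]]
  mut_seq <- apply_variants(g_rc, del_rc)
  mut_ann <- ann_rc; mut_ann$end <- ann_rc$end - 24L
  mut_aa <- strsplit(translate_cds(cds_sequence(
    genome_record("g", mut_seq, topology = "linear"), mut_ann[1, ])), "")[[1]]
  pre <- 0L
  while (pre < length(mut_aa) && ref_aa[pre + 1] == mut_aa[pre + 1]) pre <- pre + 1L
  expect_equal(rr, c(pre + 1L, pre + 8L))
  expect_equal(rr[2] - rr[1] + 1L, 8L)
  # frameshift deletions have no residue range
  fs <- data.frame(chrom = "g", pos = s, ref = substr(fx$genome$seq, s, s + 4L),
                   alt = substr(fx$genome$seq, s, s), type = "deletion")
  expect_error(residue_range(fs, fx$ann[1, ], fx$genome), "frameshift")
})

test_that("deletions spanning a CDS boundary are frameshift with a warning", {
  fx <- make_gene_genome(c("GCT", "CAA"))
  p <- fx$ann$end - 2L
  call <- data.frame(chrom = "g", pos = p,
                     ref = substr(fx$genome$seq, p, p + 5L),
                     alt = substr(fx$genome$seq, p, p), type = "deletion")
  expect_warning(eff <- classify_variant(call, fx$ann, fx$genome),
                 "CDS boundary")
  expect_identical(eff$effect_class, "frameshift")
})
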