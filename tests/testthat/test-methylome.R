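test_that("motif scanning finds palindromic sites on both strands", {
  g <- genome_record("g", "GATCGATC", topology = "linear")
  hits <- scan_motif(g, iupac_motif("GATC", 2L, "m6A"))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$position, c(1L, 5L))
  # palindrome: reverse-strand matches cover the same footprints
  rev <- hits[hits$strand == "-", ]
  expect_equal(sort(rev$position - 4L + 1L), fwd$position)
  # invalid IUPAC characters error
  expect_error(iupac_motif("GAXC"), "invalid IUPAC")
})

test_that("motif counts on random sequence match the composition expectation", {
  set.seed(20)
  L <- 200000L
  g <- genome_record("g", rand_seq(L, gc = 0.30), topology = "linear")
  hits <- scan_motif(g, iupac_motif("GRTAAAG", 6L, "m6A"))
  # per-position probability: G R T A A A G with p(G)=p(C)=0.15, p(A)=p(T)=0.35
  p <- 0.15 * (0.15 + 0.35) * 0.35 * 0.35^3 * 0.15
  expected <- 2 * L * p                   # both strands
  sd3 <- 3 * sqrt(2 * L * p * (1 - p))
  expect_lt(abs(nrow(hits) - expected), sd3)
})

test_that("forward scan of a motif equals forward scan of its partner on the reverse complement", {
  set.seed(21)
  g <- genome_record("g", rand_seq(20000, gc = 0.4), topology = "linear")
  g_rc <- genome_record("g", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$seq))), topology = "linear")
  for (pat in c("GATC", "AAGNNNNNCTCC", "TGNCGAA", "CAAAAAR")) {
    m <- iupac_motif(pat)
    n_fwd <- sum(scan_motif(g, m)$strand == "+")
    n_partner_rc <- sum(scan_motif(g_rc, partner_motif(m))$strand == "+")
    expect_equal(n_fwd, n_partner_rc)
    # full mirror property: site sets reflect
    hits <- scan_motif(g, m)
    hits_rc <- scan_motif(g_rc, m)
    L <- nchar(g$seq)
    mirrored <- sort(L - hits$position + 1L)
    expect_equal(sort(hits_rc$position), mirrored)
  }
})

test_that("partner motifs complement IUPAC-aware and are an involution", {
  expect_identical(partner_motif(iupac_motif("AAGNNNNNCTCC", 2L))$pattern,
                   "GGAGNNNNNCTT")
  expect_identical(partner_motif(iupac_motif("GATC", 2L))$pattern, "GATC")
  expect_identical(partner_motif(iupac_motif("TGNCGAA", 1L))$pattern,
                   "TTCGNCA")
  # modified position remaps
  expect_equal(partner_motif(iupac_motif("AAGNNNNNCTCC", 2L))$modified_position,
               11L)
  # involution over assorted degenerate patterns
  for (pat in c("GRTAAAG", "CAAAAAR", "MNNNCGCGAANANT", "CGCGNNNANNNTNNANA",
                "GATC", "TGNCGAA", "BDHVKMSWRY")) {
    m <- iupac_motif(pat, 1L)
    expect_identical(partner_motif(partner_motif(m))$pattern, m$pattern)
  }
})

test_that("circular genomes find motifs across the origin", {
  # GATC split across the origin: ...GA | TC...
  set.seed(22)
  g <- genome_record("c", paste0("TC", rand_seq(60, gc = 0.2), "GA"))
  hits <- scan_motif(g, iupac_motif("GATC", 2L))
  expect_true(63L %in% hits$position[hits$strand == "+"])
  lin <- genome_record("l", g$seq, topology = "linear")
  hits_lin <- scan_motif(lin, iupac_motif("GATC", 2L))
  expect_false(63L %in% hits_lin$position[hits_lin$strand == "+"])
})

test_that("motif summaries count duplex sites and recover detection fractions", {
  set.seed(23)
  g <- genome_record("g", rand_seq(120000, gc = 0.5), topology = "linear")
  model <- kinetics_model()
  motif <- default_m6a_motifs()$GATC
  track <- simulate_kinetics(g, model, motifs = list(motif), seed = 30L)
  ms <- motif_summary(g, motif, track, qv_threshold = model$qv_call_threshold)
  # duplex-site convention: a palindromic motif counts once per footprint,
  # i.e. exactly the forward-strand occurrence count
  n_fwd <- sum(scan_motif(g, motif)$strand == "+")
  expect_equal(ms$n_genome, n_fwd)
  # its partner (itself) summarizes the same sites
  expect_identical(ms$partner, "GATC")
  # detection fraction recovery within 3 binomial SE
  f <- attr(motif, "detection_fraction")
  se <- sqrt(f * (1 - f) / ms$n_genome)
  expect_lt(abs(ms$pct_detected / 100 - f), 3 * se + 0.005)
  # all sites above threshold -> 100 %
  hot <- track
  hot$mod_qv[] <- 99
  expect_equal(motif_summary(g, motif, hot)$pct_detected, 100)
  # a motif absent from the genome yields a flagged zero-count summary
  none <- motif_summary(g, iupac_motif("ACGTACGTACGTACGTACGTA", 1L), track)
  expect_true(none$flagged)
  expect_equal(none$n_genome, 0L)
  expect_true(is.na(none$pct_detected))
})

test_that("a non-palindromic motif and its partner summarize identical duplex site sets", {
  set.seed(24)
  g <- genome_record("g", rand_seq(150000, gc = 0.4), topology = "linear")
  tr <- simulate_kinetics(g, kinetics_model(), motifs = list(), seed = 31L)
  m <- iupac_motif("AAGNNNNNCTCC", 2L, "m6A")
  s1 <- motif_summary(g, m, tr)
  s2 <- motif_summary(g, partner_motif(m), tr)
  expect_equal(s1$n_genome, s2$n_genome)
})

test_that("overspecification flags rare long motifs but not common short ones", {
  set.seed(25)
  g <- genome_record("g", rand_seq(200000, gc = 0.30), topology = "linear")
  # a 17-base highly specified pattern: expected count ~ 2e5 * 4^-17 << 1
  long <- overspecification_check(g, iupac_motif("CGCGAATTCCGGATCGA", 1L),
                                  min_count = 30L)
  expect_true(long$flagged)
  # GATC on >= 10 kb of typical composition is plentiful
  short <- overspecification_check(g, iupac_motif("GATC", 2L), min_count = 30L)
  expect_false(short$flagged)
  # duplex-site expectation at GC 0.30: 2e5 * (0.35*0.15)^2 ~ 550
  expect_gt(short$n_genome, 300L)
  # min_count 0 never flags
  expect_false(overspecification_check(g, iupac_motif("CGCGAATTCCGGATCGA", 1L),
                                       min_count = 0L)$flagged)
})

test_that("cytosine context groups are exclusive and strand-complete", {
  # single CGCG: its reverse complement is itself, so the first-C group holds
  # the forward first C and the reverse-strand first C
  g <- genome_record("g", "AATTCGCGAATT", topology = "linear")
  cm <- straindelta:::.context_matrix(g)
  # forward strand: C at 5 is CGCG first C; C at 7 is CGCG second C
  expect_equal(which(cm[, 1] == 3L), 5L)
  expect_equal(which(cm[, 1] == 4L), 7L)
  # reverse strand mirrors: genomic position 8 is the reverse first C
  expect_equal(which(cm[, 2] == 3L), 8L)
  expect_equal(which(cm[, 2] == 4L), 6L)
  tr <- ipd_track(matrix(1, 12, 2), matrix(0, 12, 2), matrix(50, 12, 2))
  s <- context_mean_ipd(g, tr, "CGCG_firstC")
  expect_equal(s$n, 2L)
  expect_equal(s$mean, 1.0)
  expect_equal(s$sd, 0)
  # constant track: every non-empty context has mean 1, sd 0
  g2 <- genome_record("g", "ACGACCGCGTCCA", topology = "linear")
  tr2 <- ipd_track(matrix(1, 13, 2), matrix(0, 13, 2), matrix(50, 13, 2))
  for (cx in c("C_other", "CG_firstC", "CGCG_firstC")) {
    s2 <- context_mean_ipd(g2, tr2, cx)
    expect_equal(s2$mean, 1.0)
    expect_equal(s2$sd, 0)
  }
  # exclusivity: a CG inside CGCG is not counted as CG_firstC
  expect_equal(sum(cm == 2L), sum(cm[, 1] == 2L) + sum(cm[, 2] == 2L))
  expect_false(any(which(cm[, 1] == 2L) %in% c(5L, 7L)))
})

test_that("Welch statistics match the closed form and an independent oracle", {
  # identical groups: t = 0, p = 1
  w0 <- welch_t(c(10, 1.0, 0.2), c(10, 1.0, 0.2))
  expect_equal(w0$t_statistic, 0)
  expect_equal(w0$p_two_sided, 1)
  # worked numeric example, computed independently from the formula:
  # se = sqrt(2.5/5 + 10/5) = sqrt(2.5); t = -3/1.5811 = -1.8974
  # df = 2.5^2 / (0.5^2/4 + 2^2/4) = 5.8824
  w <- welch_t(c(5, 3, sqrt(2.5)), c(5, 6, sqrt(10)))
  expect_equal(w$t_statistic, -1.897367, tolerance = 1e-6)
  expect_equal(w$degrees_freedom, 5.882353, tolerance = 1e-6)
  # 1000 random summary inputs against stats::t.test on the raw samples
  set.seed(26)
  for (rep in 1:1000) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    x <- rnorm(n1, runif(1, -2, 2), runif(1, 0.2, 3))
    y <- rnorm(n2, runif(1, -2, 2), runif(1, 0.2, 3))
    got <- welch_t(c(n1, mean(x), sd(x)), c(n2, mean(y), sd(y)))
    want <- welch_oracle(x, y)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
    expect_equal(got$degrees_freedom, want$df, tolerance = 1e-10)
    expect_equal(got$p_two_sided, want$p, tolerance = 1e-10)
  }
  # p is monotone non-increasing as both n grow, means and sds fixed
  ps <- vapply(c(5, 10, 20, 40, 80), function(n)
    welch_t(c(n, 1.0, 0.3), c(n, 1.1, 0.4))$p_two_sided, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # degenerate and invalid inputs
  expect_error(welch_t(c(1, 0, 0), c(5, 1, 1)), "n >= 2")
  wd <- welch_t(c(5, 1, 0), c(5, 1, 0))
  expect_true(wd$degenerate)
  expect_equal(wd$p_two_sided, 1)
  wd2 <- welch_t(c(5, 2, 0), c(5, 1, 0))
  expect_equal(wd2$p_two_sided, 0)
})

test_that("motif BED export uses 0-based half-open footprints", {
  g <- genome_record("g", "AAGATCAA", topology = "linear")
  path <- withr::local_tempfile(fileext = ".bed")
  write_motif_sites_bed(g, iupac_motif("GATC", 2L), path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, c(2L, 2L))      # both strands, same footprint
  expect_equal(bed$V3, c(6L, 6L))
  expect_setequal(bed$V6, c("+", "-"))
})
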