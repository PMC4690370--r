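## ---------------------------------------------------------------------------
## Methylome analyses over SMRT kinetics: degenerate-motif site enumeration,
## per-motif detection summaries, overspecification diagnostics, cytosine
## context IPD statistics and Welch heteroscedastic t-tests.
## ---------------------------------------------------------------------------

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Construct an IUPAC degenerate motif
#'
#' @param pattern Motif string over IUPAC nucleotide codes (e.g. `"GATC"`,
#'   `"AAGNNNNNCTCC"`).
#' @param modified_position 1-based offset of the methylated base within the
#'   pattern.
#' @param modification_type Label, e.g. `"m6A"`, `"m4C"`, `"unknown"`.
#' @return An `iupac_motif` list.
#' @export
iupac_motif <- function(pattern, modified_position = 1L,
                        modification_type = "unknown") {
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("motif pattern must be non-empty")
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_COMPLEMENT))
  if (length(bad))
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  modified_position <- as.integer(modified_position)
  if (modified_position < 1L || modified_position > nchar(pattern))
    stop("modified_position outside the pattern")
  structure(list(pattern = pattern, modified_position = modified_position,
                 modification_type = modification_type),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("<iupac_motif> %s (%s at position %d)\n", x$pattern,
              x$modification_type, x$modified_position))
  invisible(x)
}

#' Reverse-complement partner of a degenerate motif
#'
#' The partner motif is the recognition sequence seen on the opposite strand:
#' the IUPAC-aware reverse complement, with the modified position remapped to
#' `length - position + 1`.  Applying the operation twice returns the original
#' motif.
#'
#' @param motif An [iupac_motif()].
#' @return The partner [iupac_motif()].
#' @export
partner_motif <- function(motif) {
  ch <- strsplit(motif$pattern, "")[[1]]
  rc <- paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
  iupac_motif(rc, nchar(motif$pattern) - motif$modified_position + 1L,
              motif$modification_type)
}

#' Scan a genome for a degenerate motif on both strands
#'
#' Positions are the 1-based genomic coordinate of the motif's first base as
#' read 5'-to-3' on the matching strand (so a minus-strand hit's coordinate is
#' the rightmost base of its footprint).  Circular genomes wrap across the
#' origin.  `N` matches any base; other IUPAC codes match their standard sets.
#'
#' @param genome A [genome_record()].
#' @param motif An [iupac_motif()] (a plain pattern string is accepted).
#' @return Data.frame `position`, `strand`, sorted by position within strand.
#' @export
scan_motif <- function(genome, motif) {
  if (is.character(motif)) motif <- iupac_motif(motif)
  w <- nchar(motif$pattern)
  L <- nchar(genome$seq)
  subj <- genome$seq
  if (genome$topology == "circular" && w > 1L)
    subj <- paste0(subj, substr(genome$seq, 1L, w - 1L))
  pat <- Biostrings::DNAString(motif$pattern)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat,
                                                    Biostrings::DNAString(subj),
                                                    fixed = FALSE))
  fwd <- fwd[fwd <= L]
  rsubj <- revcomp(subj)
  rev_q <- Biostrings::start(Biostrings::matchPattern(pat,
                                                      Biostrings::DNAString(rsubj),
                                                      fixed = FALSE))
  Ls <- nchar(subj)
  rev_pos <- Ls - rev_q + 1L                 # genomic coord of first motif base
  if (genome$topology == "circular")
    rev_pos <- ((rev_pos - 1L) %% L) + 1L
  rev_pos <- sort(unique(rev_pos))
  ## a wrap duplicate can arise on circular genomes when the extended subject
  ## re-finds the same physical site; unique() above collapses it
  rbind(
    if (length(fwd)) data.frame(position = fwd, strand = "+") else NULL,
    if (length(rev_pos)) data.frame(position = rev_pos, strand = "-") else NULL)
}

## genomic coordinate of a hit's modified base (strand-aware, circular-safe)
.modified_coord <- function(hits, motif, L) {
  off <- motif$modified_position - 1L
  p <- ifelse(hits$strand == "+", hits$position + off, hits$position - off)
  ((p - 1L) %% L) + 1L
}

## leftmost genomic coordinate of each hit's footprint (duplex site key)
.footprint_key <- function(hits, w, L) {
  p <- ifelse(hits$strand == "+", hits$position, hits$position - w + 1L)
  ((p - 1L) %% L) + 1L
}

#' Summarize a methylation motif against a kinetics track
#'
#' Sites are duplex footprints carrying the motif on at least one strand
#' (palindromic motifs therefore count once per site, and a motif and its
#' partner summarize the same site set).  A site is detected when the
#' modification QV at the modified-position base reaches `qv_threshold` on any
#' motif-bearing strand.
#'
#' @param genome A [genome_record()].
#' @param motif An [iupac_motif()].
#' @param track An [ipd_track()] covering the genome.
#' @param qv_threshold Modification-QV call threshold (default 30).
#' @return A `motif_summary` list: `motif`, `n_genome`, `n_detected`,
#'   `pct_detected`, `mean_qv` (over detected site records), `mean_coverage`,
#'   `partner`, `flagged` (`TRUE` when the motif has no genomic site).
#' @export
motif_summary <- function(genome, motif, track, qv_threshold = 30) {
  if (is.character(motif)) motif <- iupac_motif(motif)
  L <- nchar(genome$seq)
  stopifnot(inherits(track, "ipd_track"), track$length == L)
  hits <- scan_motif(genome, motif)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(structure(list(motif = motif, n_genome = 0L, n_detected = 0L,
                          pct_detected = NA_real_, mean_qv = NA_real_,
                          mean_coverage = NA_real_,
                          partner = partner_motif(motif)$pattern,
                          flagged = TRUE), class = "motif_summary"))
  }
  key <- .footprint_key(hits, nchar(motif$pattern), L)
  mc <- .modified_coord(hits, motif, L)
  si <- ifelse(hits$strand == "+", 1L, 2L)
  qv <- track$mod_qv[cbind(mc, si)]
  cov <- track$coverage[cbind(mc, si)]
  det_site <- tapply(qv >= qv_threshold, key, any)
  n_genome <- length(det_site)
  n_detected <- sum(det_site)
  structure(list(motif = motif, n_genome = n_genome, n_detected = n_detected,
                 pct_detected = 100 * n_detected / n_genome,
                 mean_qv = if (any(qv >= qv_threshold))
                   mean(qv[qv >= qv_threshold]) else NA_real_,
                 mean_coverage = mean(cov),
                 partner = partner_motif(motif)$pattern,
                 flagged = FALSE),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat(sprintf("<motif_summary> %s: %d/%d sites detected (%.2f%%), mean QV %.1f, mean coverage %.1f, partner %s%s\n",
              x$motif$pattern, x$n_detected, x$n_genome,
              ifelse(is.na(x$pct_detected), NA, x$pct_detected),
              x$mean_qv, x$mean_coverage, x$partner,
              if (x$flagged) " [flagged: no sites]" else ""))
  invisible(x)
}

#' Flag overspecified modification motifs
#'
#' Motif callers occasionally report very long, highly specified recognition
#' sequences whose genomic occurrence count is too small to be a plausible
#' restriction-modification target; such motifs are flagged.
#'
#' @param genome A [genome_record()].
#' @param motif An [iupac_motif()] or pattern string.
#' @param min_count Minimum plausible site count (default 30).
#' @return List `n_genome`, `flagged` (`TRUE` iff `n_genome < min_count`).
#' @export
overspecification_check <- function(genome, motif, min_count = 30L) {
  if (is.character(motif)) motif <- iupac_motif(motif)
  hits <- scan_motif(genome, motif)
  n <- if (is.null(hits)) 0L else
    length(unique(.footprint_key(hits, nchar(motif$pattern), nchar(genome$seq))))
  list(n_genome = n, flagged = n < min_count)
}

## cytosine context codes; priority CGCG first C > CGCG second C > CG > other C
CYTOSINE_CONTEXTS <- c("C_other", "CG_firstC", "CGCG_firstC", "CGCG_secondC")

## per-position context codes for one strand reading (0 = non-cytosine)
.context_codes <- function(chars, circular) {
  L <- length(chars)
  at <- function(i) chars[((i - 1L) %% L) + 1L]
  idx <- seq_len(L)
  if (!circular) {
    get <- function(off) { p <- idx + off; out <- rep("", L)
      ok <- p >= 1L & p <= L; out[ok] <- chars[p[ok]]; out }
  } else {
    get <- function(off) at(idx + off)
  }
  p1 <- get(1L); p2 <- get(2L); p3 <- get(3L)
  m1 <- get(-1L); m2 <- get(-2L)
  isC <- chars == "C"
  code <- integer(L)
  cgcg1 <- isC & p1 == "G" & p2 == "C" & p3 == "G"
  cgcg2 <- isC & m2 == "C" & m1 == "G" & p1 == "G"
  cg <- isC & p1 == "G"
  code[isC] <- 1L                                    # C_other
  code[cg] <- 2L                                     # CG first C
  code[cgcg2 & !cgcg1] <- 4L                         # CGCG second C
  code[cgcg1] <- 3L                                  # CGCG first C
  code
}

## both-strand context code matrix (columns: +, -)
.context_matrix <- function(genome) {
  chars <- strsplit(genome$seq, "")[[1]]
  circ <- genome$topology == "circular"
  fwd <- .context_codes(chars, circ)
  comp <- c(A = "T", C = "G", G = "C", T = "A")[chars]
  rev_codes <- .context_codes(rev(unname(comp)), circ)
  cbind(fwd, rev(rev_codes))
}

#' Mean IPD ratio by cytosine context
#'
#' Contexts are read 5'-to-3' on each strand and are mutually exclusive:
#' `CGCG_firstC` (first C of a CGCG), `CGCG_secondC`, `CG_firstC` (C followed
#' by G, outside CGCG) and `C_other` (any other C).  Statistics pool both
#' strands.
#'
#' @param genome A [genome_record()].
#' @param track An [ipd_track()].
#' @param context One of `"C_other"`, `"CG_firstC"`, `"CGCG_firstC"`,
#'   `"CGCG_secondC"`.
#' @return List `n`, `mean`, `sd` of the IPD ratios in the context group.
#' @export
context_mean_ipd <- function(genome, track, context) {
  context <- match.arg(context, CYTOSINE_CONTEXTS)
  stopifnot(inherits(track, "ipd_track"), track$length == nchar(genome$seq))
  code <- match(context, CYTOSINE_CONTEXTS)
  cm <- .context_matrix(genome)
  sel <- cm == code
  vals <- track$ipd[sel]
  if (length(vals) == 0L)
    stop("empty context group: no '", context, "' positions in this genome")
  list(n = length(vals), mean = mean(vals), sd = stats::sd(vals))
}

#' Welch heteroscedastic two-sample t-test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value from the t distribution.  Accepts the
#' `(n, mean, sd)` summaries produced by [context_mean_ipd()].
#'
#' @param a,b Group summaries: lists or numeric vectors `(n, mean, sd)`.
#' @return A `welch_result` list: `t_statistic`, `degrees_freedom`,
#'   `p_two_sided`, `group_stats`, and `degenerate` (`TRUE` when both
#'   variances are zero).
#' @export
welch_t <- function(a, b) {
  g <- function(x) {
    x <- unlist(x)[1:3]
    list(n = as.numeric(x[[1]]), mean = as.numeric(x[[2]]),
         sd = as.numeric(x[[3]]))
  }
  a <- g(a); b <- g(b)
  if (a$n < 2 || b$n < 2) stop("welch_t requires n >= 2 in both groups")
  if (a$sd < 0 || b$sd < 0) stop("standard deviations must be non-negative")
  if (a$sd == 0 && b$sd == 0) {
    equal <- isTRUE(all.equal(a$mean, b$mean))
    return(structure(list(t_statistic = if (equal) 0 else Inf * sign(a$mean - b$mean),
                          degrees_freedom = a$n + b$n - 2,
                          p_two_sided = if (equal) 1 else 0,
                          group_stats = list(a = a, b = b),
                          degenerate = TRUE),
                     class = "welch_result"))
  }
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(t_statistic = t, degrees_freedom = df, p_two_sided = p,
                 group_stats = list(a = a, b = b), degenerate = FALSE),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.2f, p (two-sided) = %.3g%s\n",
              x$t_statistic, x$degrees_freedom, x$p_two_sided,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' The five native methylation motifs used as simulation defaults
#'
#' N6-methyladenine recognition motifs of the organism's
#' restriction-modification systems with their default per-site detection
#' fractions (proportion of genomic sites called modified).
#'
#' @return Named list of [iupac_motif()] objects with a `detection_fraction`
#'   attribute on each.
#' @export
default_m6a_motifs <- function() {
  mk <- function(p, mp, f) {
    m <- iupac_motif(p, mp, "m6A"); attr(m, "detection_fraction") <- f; m
  }
  list(GRTAAAG      = mk("GRTAAAG", 6L, 0.9965),
       AAGNNNNNCTCC = mk("AAGNNNNNCTCC", 2L, 0.9961),
       GGAGNNNNNCTT = mk("GGAGNNNNNCTT", 3L, 0.9903),
       GATC         = mk("GATC", 2L, 0.9914),
       CAAAAAR      = mk("CAAAAAR", 6L, 0.9710))
}

#' Export motif sites as BED
#'
#' 0-based half-open intervals with strand, one line per strand hit.
#'
#' @param genome A [genome_record()].
#' @param motif An [iupac_motif()] or pattern.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motif_sites_bed <- function(genome, motif, path) {
  if (is.character(motif)) motif <- iupac_motif(motif)
  hits <- scan_motif(genome, motif)
  w <- nchar(motif$pattern); L <- nchar(genome$seq)
  if (is.null(hits) || nrow(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  left <- .footprint_key(hits, w, L)
  gr <- GenomicRanges::GRanges(genome$id,
                               IRanges::IRanges(start = left,
                                                width = pmin(w, L - left + 1L)),
                               strand = hits$strand)
  S4Vectors::mcols(gr)$name <- motif$pattern
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a per-motif methylome report
#'
#' @param summaries List of [motif_summary()] results.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_methylome_tsv <- function(summaries, path) {
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(motif = s$motif$pattern,
               modified_position = s$motif$modified_position,
               type = s$motif$modification_type,
               pct_detected = round(s$pct_detected, 2),
               n_detected = s$n_detected, n_genome = s$n_genome,
               mean_qv = round(s$mean_qv, 1),
               mean_coverage = round(s$mean_coverage, 1),
               partner = s$partner, stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
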