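## ---------------------------------------------------------------------------
## Synthetic genome / truth-set generator.
##
## The generator emulates the inputs the downstream analyses assume: an AT-rich
## circular chromosome with non-overlapping CDSs on both strands, and a mutant
## derived from it by a configured mix of substitutions by effect class plus a
## single in-frame deletion flanked by a direct repeat (the recombination
## signature: the reference carries repeat+spacer+repeat, the mutant keeps one
## repeat copy).  CDSs are built codon-by-codon from a stop-free codon pool so
## the no-internal-stop invariant holds by construction; intergenic spacers are
## i.i.d. at the profile GC.
## ---------------------------------------------------------------------------

#' Generator profile for synthetic genomes
#'
#' @param genome_length Chromosome length in bases.
#' @param gc_fraction Target GC proportion in `[0, 1]`.
#' @param n_genes Number of non-overlapping CDSs to place (both strands).
#' @param mean_gene_length Mean CDS length in bases (rounded to codons).
#' @param substitution_quota Named integer vector of planted substitution
#'   counts per effect class; allowed names: `intergenic`, `silent`,
#'   `conservative`, `nonconservative`, `nonsense`.
#' @param deletion_spec `NULL`, or a list with `deleted_sequence` (the bases
#'   removed from the mutant; a positive multiple of 3), `repeat_sequence`
#'   (direct repeat; must be a prefix of `deleted_sequence`),
#'   `target_codon` (codon index containing the first deleted base; because
#'   the repeat is a prefix of the deleted sequence, the protein-level
#'   (maximal-common-prefix) deleted residue range starts a few codons later)
#'   and optional `target_gene` (gene id; chosen automatically when `NULL`).
#' @param seed Integer RNG seed; a fixed seed makes all outputs byte-identical.
#' @return A `generator_profile` list.
#' @seealso [default_strain_profile()] for the default strain-comparison profile.
#' @export
generator_profile <- function(genome_length, gc_fraction, n_genes,
                              mean_gene_length,
                              substitution_quota = c(intergenic = 0L, silent = 0L,
                                                     conservative = 0L,
                                                     nonconservative = 0L,
                                                     nonsense = 0L),
                              deletion_spec = NULL, seed = 1L) {
  stopifnot(genome_length >= 100, gc_fraction > 0, gc_fraction < 1,
            n_genes >= 0, mean_gene_length %% 3 == 0 || n_genes == 0)
  allowed <- c("intergenic", "silent", "conservative", "nonconservative", "nonsense")
  if (length(substitution_quota) && is.null(names(substitution_quota)))
    stop("substitution_quota must be named")
  if (!all(names(substitution_quota) %in% allowed))
    stop("unknown effect class in quota: ",
         paste(setdiff(names(substitution_quota), allowed), collapse = ", "))
  quota <- setNames(integer(length(allowed)), allowed)
  quota[names(substitution_quota)] <- as.integer(substitution_quota)
  if (any(quota < 0)) stop("substitution quotas must be non-negative")
  if (!is.null(deletion_spec)) {
    ds <- deletion_spec
    stopifnot(is.list(ds), !is.null(ds$deleted_sequence), !is.null(ds$repeat_sequence))
    ds$deleted_sequence <- toupper(ds$deleted_sequence)
    ds$repeat_sequence <- toupper(ds$repeat_sequence)
    d <- nchar(ds$deleted_sequence)
    if (d == 0L || d %% 3L != 0L)
      stop("deleted_sequence length must be a positive multiple of 3")
    if (!startsWith(ds$deleted_sequence, ds$repeat_sequence))
      stop("repeat_sequence must be a prefix of deleted_sequence")
    if (is.null(ds$target_codon)) ds$target_codon <- 232L
    if (is.null(ds$target_gene)) ds$target_gene <- NULL
    deletion_spec <- ds
  }
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
                 mean_gene_length = as.integer(mean_gene_length),
                 substitution_quota = quota, deletion_spec = deletion_spec,
                 seed = as.integer(seed)),
            class = "generator_profile")
}

#' Default strain-comparison profile
#'
#' A desk-scale stand-in for a 4.35-Mb, ~30%-GC clostridial chromosome:
#' 200 kb at GC 0.30 with 150 genes of mean length 900 bp, a planted
#' substitution mix of 10 intergenic / 14 silent / 14 conservative /
#' 27 nonconservative / 1 nonsense, and one 24-bp in-frame deletion whose
#' removed allele `ATACCATAAATAAATTATTTGGAT` is flanked in the reference by
#' the 8-bp direct repeat `ATACCATA`, removing residues 235-242 of the target
#' gene.  67 variants in total.
#'
#' @param seed RNG seed (default 42).
#' @return A [generator_profile()].
#' @export
default_strain_profile <- function(seed = 42L) {
  generator_profile(
    genome_length = 200000L, gc_fraction = 0.30, n_genes = 150L,
    mean_gene_length = 900L,
    substitution_quota = c(intergenic = 10L, silent = 14L, conservative = 14L,
                           nonconservative = 27L, nonsense = 1L),
    ## planting the deleted segment at codon 232 makes the protein-level
    ## deleted residue range 235-242 (the 8-bp repeat prefix aligns the first
    ## three junction codons)
    deletion_spec = list(deleted_sequence = "ATACCATAAATAAATTATTTGGAT",
                         repeat_sequence = "ATACCATA",
                         target_codon = 232L),
    seed = seed)
}

## codon pools -----------------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

codon_probs <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cods <- all_codons()
  w <- vapply(strsplit(cods, ""), function(ch) prod(p[ch]), numeric(1))
  setNames(w, cods)
}

sample_codons <- function(n, gc, exclude_stops = TRUE) {
  w <- codon_probs(gc)
  if (exclude_stops) w <- w[setdiff(names(w), STOP_CODONS)]
  sample(names(w), n, replace = TRUE, prob = w)
}

## reference construction ------------------------------------------------------

#' Generate a synthetic reference genome with gene annotations
#'
#' Gene lengths are drawn around `mean_gene_length` (normal on the codon
#' scale, floored at 60 codons); each CDS begins `ATG`, ends a stop codon and
#' contains no internal stop.  Strands are assigned at random.  When the
#' profile has a `deletion_spec`, the direct-repeat construct
#' (repeat+spacer+repeat) is written in-frame into a sufficiently long
#' plus-strand CDS so that the later deletion removes `repeat+spacer` and
#' leaves one repeat copy; the target residue window is padded so neither the
#' reference nor the mutant reading frame gains a stop codon.
#'
#' @param profile A [generator_profile()].
#' @return `list(genome = genome_record, annotations = data.frame)`.
#' @export
generate_reference <- function(profile) {
  stopifnot(inherits(profile, "generator_profile"))
  set.seed(profile$seed)
  L <- profile$genome_length
  n <- profile$n_genes
  if (n == 0L) {
    genome <- genome_record("synthetic_ref", random_dna(L, profile$gc_fraction))
    return(list(genome = genome,
                annotations = gene_annotations(character(0), integer(0),
                                               integer(0), character(0),
                                               character(0))))
  }
  mean_cod <- profile$mean_gene_length %/% 3L
  ncod <- pmax(60L, as.integer(round(rnorm(n, mean_cod, mean_cod / 6))))
  if (!is.null(profile$deletion_spec)) {
    ## make sure at least one gene can host the repeat construct at the
    ## requested codon (construct needs target_codon + d/3 + 3 codons)
    need <- .deletion_min_codons(profile$deletion_spec)
    if (max(ncod) < need) ncod[which.max(ncod)] <- need + 10L
  }
  glen <- ncod * 3L
  total_coding <- sum(glen)
  spare <- L - total_coding
  min_spacer <- 20L
  if (spare < (n + 1L) * min_spacer)
    stop("infeasible geometry: ", n, " genes totalling ", total_coding,
         " bases cannot be placed in a ", L, "-base genome without overlap")
  ## split the intergenic budget into n+1 spacers via uniform breaks
  extra <- spare - (n + 1L) * min_spacer
  cuts <- sort(c(0L, sample.int(extra + 1L, n, replace = TRUE) - 1L, extra))
  spacers <- min_spacer + diff(cuts)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  gc <- profile$gc_fraction
  pieces <- character(2L * n + 1L)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- random_dna(spacers[i], gc)
    pos <- pos + spacers[i]
    body <- paste(sample_codons(ncod[i] - 2L, gc), collapse = "")
    stop_cod <- sample(STOP_CODONS, 1L,
                       prob = codon_probs(gc)[STOP_CODONS] /
                         sum(codon_probs(gc)[STOP_CODONS]))
    cds <- paste0("ATG", body, stop_cod)
    pieces[2L * i] <- if (strands[i] == "-") revcomp(cds) else cds
    starts[i] <- pos + 1L
    ends[i] <- pos + glen[i]
    pos <- pos + glen[i]
  }
  pieces[2L * n + 1L] <- random_dna(spacers[n + 1L], gc)
  seq <- paste(pieces, collapse = "")
  ann <- gene_annotations(sprintf("gene_%04d", seq_len(n)), starts, ends,
                          strands, genome_length = L)
  genome <- genome_record("synthetic_ref", seq)
  if (!is.null(profile$deletion_spec)) {
    emb <- .embed_deletion_construct(genome, ann, profile$deletion_spec)
    genome <- emb$genome
  }
  list(genome = genome, annotations = ann)
}

## Minimum codons a host gene needs: construct spans codons c..c+n_constr and
## we keep a stop-codon margin.
.deletion_min_codons <- function(ds) {
  d <- nchar(ds$deleted_sequence); r <- nchar(ds$repeat_sequence)
  c0 <- ds$target_codon                            # construct starts at codon c0
  c0 + (1L + d + r + 3L + 2L) %/% 3L + 4L
}

## Deterministically choose the host gene and genomic coordinates for the
## direct-repeat construct, and return the strings to write.
##
## Layout (in-frame on a plus-strand gene): one base P1 at codon position 1 of
## codon c0 = target_codon - 1, then deleted_sequence (repeat+spacer) starting
## at codon position 2, then one more repeat copy, then a padding codon Q.
## Requires |repeat| == 2 (mod 3) so the construct ends on a codon boundary.
## P1 is chosen so the deletion cannot left-shift past the construct
## (P1 != last base of deleted_sequence) and cannot create a stop (P1 != T);
## Q's first base breaks repeat extension beyond |repeat|.  The deleted
## residues are then codons target_codon .. target_codon + d/3 - 1 (the hybrid
## codon formed across the junction re-creates the residue at codon c0 because
## the repeat is a prefix of the deleted sequence).
.deletion_site <- function(ann, ds) {
  d <- nchar(ds$deleted_sequence); r <- nchar(ds$repeat_sequence)
  if ((d + r) %% 3L != 2L)
    stop("unsupported repeat phase: need |deleted| + |repeat| == 2 (mod 3) ",
         "for in-frame planting")
  need <- .deletion_min_codons(ds)
  cand <- ann[ann$strand == "+" & (ann$end - ann$start + 1L) / 3L >= need, ,
              drop = FALSE]
  if (!is.null(ds$target_gene))
    cand <- cand[cand$gene_id == ds$target_gene, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("infeasible deletion_spec: no plus-strand gene long enough to host ",
         "the repeat construct")
  gene <- cand[1L, ]
  c0 <- ds$target_codon
  if (c0 < 2L) stop("target_codon must be >= 2 (cannot overwrite the start codon)")
  p1_off <- (c0 - 1L) * 3L + 1L                    # gene offset (1-based) of P1
  s_gene <- p1_off + 1L                            # offset of first deleted base
  ds_last <- substr(ds$deleted_sequence, d, d)
  p1 <- setdiff(c("A", "C", "G"), ds_last)[1L]
  after <- substr(ds$deleted_sequence, r + 1L, r + 1L)
  q_pool <- c("GGC", "GCC", "GAC", "CTG", "CAC", "AGC", "TCC")
  q <- q_pool[substr(q_pool, 1L, 1L) != after][1L]
  construct <- paste0(p1, ds$deleted_sequence, ds$repeat_sequence, q)
  ## reading-frame check: no stop codon may appear in the reference construct
  ## frame (P1 at codon position 1) or in the post-deletion frame
  ref_frame <- construct
  mut_frame <- paste0(p1, ds$repeat_sequence, q)
  for (fr in list(ref_frame, mut_frame)) {
    cods <- substring(fr, seq(1L, nchar(fr) - 2L, 3L), seq(3L, nchar(fr), 3L))
    if (any(cods %in% STOP_CODONS))
      stop("deletion_spec would introduce an in-frame stop codon; ",
           "choose a different deleted_sequence or target_codon")
  }
  g_p1 <- gene$start + p1_off - 1L                 # genomic coordinate of P1
  list(gene_id = gene$gene_id,
       construct = construct,
       construct_start = g_p1,                     # genomic, 1-based
       del_start = g_p1 + 1L,                      # first deleted base
       del_len = d)
}

.embed_deletion_construct <- function(genome, ann, ds) {
  site <- .deletion_site(ann, ds)
  seq <- genome$seq
  a <- site$construct_start
  b <- a + nchar(site$construct) - 1L
  stopifnot(b <= nchar(seq))
  seq <- paste0(substr(seq, 1L, a - 1L), site$construct,
                substr(seq, b + 1L, nchar(seq)))
  genome$seq <- seq
  list(genome = genome, site = site)
}

## variant planting ------------------------------------------------------------

#' Plant a truth set of variants into a synthetic reference
#'
#' Substitutions are placed by rejection sampling against the same effect
#' classifier used downstream ([classify_variant()]), so each truth record's
#' planted class is consistent by construction; candidates are kept at least
#' 150 bp apart (and clear of the deletion construct) so every call is
#' resolved independently by the anchored diff.  The in-frame deletion removes
#' `repeat+spacer` from the construct [generate_reference()] embedded, leaving
#' one repeat copy in the mutant.
#'
#' @param genome Reference [genome_record()] from [generate_reference()].
#' @param annotations Matching annotation data.frame.
#' @param profile The same [generator_profile()].
#' @param max_attempts Rejection-sampling cap per variant (default 10000).
#' @return `list(mutant = genome_record, truth = data.frame)` where `truth`
#'   has columns `position`, `ref_allele`, `alt_allele`, `planted_class`
#'   (VCF-style: indels carry one anchor base).
#' @export
plant_variants <- function(genome, annotations, profile, max_attempts = 10000L) {
  stopifnot(inherits(profile, "generator_profile"))
  set.seed((profile$seed %% 2000000000L) + 1L)
  L <- nchar(genome$seq)
  quota <- profile$substitution_quota
  margin <- 150L
  used <- integer(0)                 # occupied positions (separation control)
  blocked <- integer(0)
  site <- NULL
  if (!is.null(profile$deletion_spec)) {
    site <- .deletion_site(annotations, profile$deletion_spec)
    blocked <- seq(site$construct_start - 60L,
                   site$construct_start + nchar(site$construct) + 60L)
  }
  edge <- 100L                       # keep clear of the linear sequence ends
  ok_pos <- function(p, span = 1L) {
    pts <- seq(p, p + span - 1L)
    all(pts > edge) && all(pts < L - edge) &&
      !any(pts %in% blocked) &&
      (length(used) == 0L || min(abs(outer(pts, used, "-"))) >= margin)
  }
  coding_mask <- rep(FALSE, L)
  for (i in seq_len(nrow(annotations)))
    coding_mask[annotations$start[i]:annotations$end[i]] <- TRUE
  truth <- list()
  bases <- c("A", "C", "G", "T")
  plant_one <- function(class) {
    for (attempt in seq_len(max_attempts)) {
      if (class == "intergenic") {
        p <- sample.int(L, 1L)
        if (coding_mask[p] || !ok_pos(p)) next
      } else {
        if (nrow(annotations) == 0L)
          stop("could not plant a '", class,
               "' substitution: the genome has no genes")
        gi <- sample.int(nrow(annotations), 1L,
                         prob = annotations$end - annotations$start + 1L)
        gene <- annotations[gi, ]
        ncods <- (gene$end - gene$start + 1L) %/% 3L
        if (ncods < 4L) next
        cod <- sample(2:(ncods - 1L), 1L)          # skip start and stop codons
        off <- (cod - 1L) * 3L + sample.int(3L, 1L)  # 1-based offset in gene
        p <- if (gene$strand == "+") gene$start + off - 1L else gene$end - off + 1L
        if (!ok_pos(p)) next
      }
      ref <- substr(genome$seq, p, p)
      alt <- sample(setdiff(bases, ref), 1L)
      call <- data.frame(chrom = genome$id, pos = p, ref = ref, alt = alt,
                         type = "substitution", stringsAsFactors = FALSE)
      eff <- classify_variant(call, annotations, genome)
      if (eff$effect_class == class) {
        used <<- c(used, p)
        return(call)
      }
    }
    stop("could not plant a '", class, "' substitution after ", max_attempts,
         " attempts")
  }
  for (class in names(quota)) {
    for (i in seq_len(quota[[class]])) {
      call <- plant_one(class)
      truth[[length(truth) + 1L]] <-
        data.frame(position = call$pos, ref_allele = call$ref,
                   alt_allele = call$alt, planted_class = class,
                   stringsAsFactors = FALSE)
    }
  }
  if (!is.null(site)) {
    anchor_pos <- site$del_start - 1L
    ref_allele <- substr(genome$seq, anchor_pos, site$del_start + site$del_len - 1L)
    truth[[length(truth) + 1L]] <-
      data.frame(position = anchor_pos, ref_allele = ref_allele,
                 alt_allele = substr(genome$seq, anchor_pos, anchor_pos),
                 planted_class = "inframe_deletion", stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  calls <- data.frame(chrom = genome$id, pos = truth$position,
                      ref = truth$ref_allele, alt = truth$alt_allele,
                      type = ifelse(nchar(truth$ref_allele) >
                                      nchar(truth$alt_allele),
                                    "deletion", "substitution"),
                      stringsAsFactors = FALSE)
  mutant <- genome
  mutant$seq <- apply_variants(genome, calls)
  mutant$id <- paste0(genome$id, "_mutant")
  list(mutant = mutant, truth = truth)
}

#' Run the full synthetic generation for a profile
#'
#' Convenience wrapper: [generate_reference()] then [plant_variants()].
#'
#' @param profile A [generator_profile()].
#' @return `list(reference, annotations, mutant, truth)`.
#' @export
simulate_strain_pair <- function(profile) {
  ref <- generate_reference(profile)
  pv <- plant_variants(ref$genome, ref$annotations, profile)
  list(reference = ref$genome, annotations = ref$annotations,
       mutant = pv$mutant, truth = pv$truth)
}

## truth-set output ------------------------------------------------------------

#' Write a truth set (or any variant table) as a minimal VCF
#'
#' Substitutions are written as SNVs; deletions VCF-style with their anchor
#' base already part of the alleles.
#'
#' @param truth Data.frame with `position`, `ref_allele`, `alt_allele` (a
#'   `planted_class` column, if present, is carried in INFO).
#' @param genome The reference [genome_record()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, genome, path) {
  info <- if ("planted_class" %in% names(truth))
    paste0("CLASS=", truth$planted_class) else rep(".", nrow(truth))
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", genome$id, nchar(genome$seq)),
             "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Planted effect class\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", genome$id,
                     truth$position, truth$ref_allele, truth$alt_allele, info))
  writeLines(lines, path)
  invisible(path)
}
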