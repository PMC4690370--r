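## ---------------------------------------------------------------------------
## Codon-aware variant effect classification.
##
## Substitutions inside a CDS are translated on the coding strand with the
## standard genetic code.  Identical residues are silent; a new stop codon is
## nonsense; otherwise the replacement is conservative iff its BLOSUM62 score
## is positive (a reproducible, published operationalization of "biochemically
## similar"), else nonconservative.  Deletions in a CDS are in-frame iff their
## length is divisible by 3, else frameshift; deletions spanning a CDS
## boundary are conservatively filed as frameshift with a warning.
## ---------------------------------------------------------------------------

EFFECT_CLASSES <- c("intergenic", "silent", "conservative", "nonconservative",
                    "nonsense", "inframe_deletion", "inframe_insertion",
                    "frameshift")

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

genetic_code <- function() Biostrings::GENETIC_CODE

## gene containing a 1-based position, or NULL
.gene_at <- function(annotations, pos) {
  hit <- which(annotations$start <= pos & annotations$end >= pos)
  if (length(hit) == 0L) return(NULL)
  annotations[hit[1L], ]
}

## codon/residue mapping of a genomic position within a gene (coding strand)
.codon_of <- function(gene, pos) {
  cp <- if (gene$strand == "+") pos - gene$start + 1L else gene$end - pos + 1L
  list(residue = (cp - 1L) %/% 3L + 1L, codon_pos = (cp - 1L) %% 3L + 1L)
}

## coding-strand codon at residue index
.codon_seq <- function(genome, gene, residue) {
  off <- (residue - 1L) * 3L
  if (gene$strand == "+") {
    subseq_str(genome$seq, gene$start + off, gene$start + off + 2L)
  } else {
    revcomp(subseq_str(genome$seq, gene$end - off - 2L, gene$end - off))
  }
}

#' Classify a variant call against gene models
#'
#' @param call One-row call data.frame (`chrom`, `pos`, `ref`, `alt`) as
#'   produced by [call_variants()]; must be normalized and consistent with
#'   `genome`.
#' @param annotations CDS annotation data.frame ([gene_annotations()]).
#' @param genome Reference [genome_record()].
#' @return A one-row data.frame: `gene_id` (NA for intergenic), `product`,
#'   `effect_class`, `aa_ref`, `aa_alt`, `aa_position` (coding substitutions
#'   only) and `shorthand` (`"A267V"`, `"Q641*"`, `"Silent"`,
#'   `"Del. 235`–`242"`, ...).
#' @export
classify_variant <- function(call, annotations, genome) {
  L <- nchar(genome$seq)
  if (call$pos < 1L || call$pos + nchar(call$ref) - 1L > L)
    stop("variant outside genome bounds")
  if (substr(genome$seq, call$pos, call$pos + nchar(call$ref) - 1L) != call$ref)
    stop("variant ref allele does not match the genome")
  out <- data.frame(gene_id = NA_character_, product = NA_character_,
                    effect_class = NA_character_, aa_ref = NA_character_,
                    aa_alt = NA_character_, aa_position = NA_integer_,
                    shorthand = NA_character_, stringsAsFactors = FALSE)
  is_sub <- nchar(call$ref) == 1L && nchar(call$alt) == 1L
  if (is_sub) {
    gene <- .gene_at(annotations, call$pos)
    if (is.null(gene)) {
      out$effect_class <- "intergenic"; out$shorthand <- "No CDS"
      return(out)
    }
    out$gene_id <- gene$gene_id; out$product <- gene$product
    cm <- .codon_of(gene, call$pos)
    ref_codon <- .codon_seq(genome, gene, cm$residue)
    base_alt <- if (gene$strand == "+") call$alt else revcomp(call$alt)
    alt_codon <- ref_codon
    substr(alt_codon, cm$codon_pos, cm$codon_pos) <- base_alt
    gc_tab <- genetic_code()
    aa_ref <- unname(gc_tab[[ref_codon]]); aa_alt <- unname(gc_tab[[alt_codon]])
    out$aa_ref <- aa_ref; out$aa_alt <- aa_alt; out$aa_position <- cm$residue
    if (aa_ref == aa_alt) {
      out$effect_class <- "silent"; out$shorthand <- "Silent"
    } else if (aa_alt == "*") {
      out$effect_class <- "nonsense"
      out$shorthand <- sprintf("%s%d*", aa_ref, cm$residue)
    } else if (aa_ref == "*") {
      ## stop-loss: read-through extends the protein; biochemically drastic
      out$effect_class <- "nonconservative"
      out$shorthand <- sprintf("*%d%s", cm$residue, aa_alt)
    } else {
      b62 <- .blosum62()
      out$effect_class <- if (b62[aa_ref, aa_alt] > 0) "conservative"
                          else "nonconservative"
      out$shorthand <- sprintf("%s%d%s", aa_ref, cm$residue, aa_alt)
    }
    return(out)
  }
  ## indel (VCF-style: shared anchor base at call$pos)
  is_del <- nchar(call$ref) > nchar(call$alt)
  seg_len <- abs(nchar(call$ref) - nchar(call$alt))
  if (is_del) {
    first <- call$pos + 1L; last <- call$pos + seg_len
  } else {
    first <- call$pos + 1L; last <- call$pos    # zero-width in the reference
  }
  genes_in <- which(annotations$start <= last & annotations$end >= first)
  if (is_del) {
    if (length(genes_in) == 0L) {
      out$effect_class <- "intergenic"; out$shorthand <- "No CDS"
      return(out)
    }
    gene <- annotations[genes_in[1L], ]
    out$gene_id <- gene$gene_id; out$product <- gene$product
    within <- length(genes_in) == 1L && first >= gene$start && last <= gene$end
    if (!within) {
      warning("deletion spans a CDS boundary; classified as frameshift")
      out$effect_class <- "frameshift"
      out$shorthand <- sprintf("Del. %d bp (CDS boundary)", seg_len)
      return(out)
    }
    if (seg_len %% 3L != 0L) {
      out$effect_class <- "frameshift"
      out$shorthand <- sprintf("Frameshift del. %d bp", seg_len)
      return(out)
    }
    out$effect_class <- "inframe_deletion"
    rr <- residue_range(call, gene, genome)
    out$aa_position <- rr[1L]
    out$shorthand <- sprintf("Del. %d–%d", rr[1L], rr[2L])
    return(out)
  }
  ## insertion
  gene <- .gene_at(annotations, call$pos)
  if (is.null(gene) ||
      call$pos >= gene$end) {  # inserted bases fall after the CDS
    out$effect_class <- "intergenic"; out$shorthand <- "No CDS"
    return(out)
  }
  out$gene_id <- gene$gene_id; out$product <- gene$product
  if (seg_len %% 3L == 0L) {
    out$effect_class <- "inframe_insertion"
    out$shorthand <- sprintf("Ins. %d bp", seg_len)
  } else {
    out$effect_class <- "frameshift"
    out$shorthand <- sprintf("Frameshift ins. %d bp", seg_len)
  }
  out
}

#' Classify a table of variant calls
#'
#' @param calls Call data.frame.
#' @inheritParams classify_variant
#' @return Calls with the effect columns of [classify_variant()] appended.
#' @export
classify_variants <- function(calls, annotations, genome) {
  if (nrow(calls) == 0L)
    return(cbind(calls, classify_variant(
      data.frame(chrom = genome$id, pos = 1L,
                 ref = substr(genome$seq, 1, 1),
                 alt = substr(genome$seq, 1, 1)), annotations, genome)[0, ]))
  eff <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
    classify_variant(calls[i, , drop = FALSE], annotations, genome)))
  cbind(calls, eff)
}

#' Tally effect classes
#'
#' @param effects Data.frame with an `effect_class` column.
#' @return Named integer vector over all effect classes (zero-filled); counts
#'   always sum to `nrow(effects)`.
#' @export
summarize_effects <- function(effects) {
  counts <- setNames(integer(length(EFFECT_CLASSES)), EFFECT_CLASSES)
  if (nrow(effects) > 0L) {
    tab <- table(factor(effects$effect_class, levels = EFFECT_CLASSES))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Direct-repeat signature flanking a deletion
#'
#' For a left-aligned deletion removing `d` bases starting at 0-based offset
#' `s`, the flanking repeat length is the largest `m` with
#' `genome[s, s+m) == genome[s+d, s+d+m)` - i.e. the deleted segment begins
#' with the same bases that immediately follow it, the signature of a
#' homologous-recombination (direct-repeat-mediated) deletion that collapsed
#' two repeat copies into one.
#'
#' @param genome Reference [genome_record()].
#' @param deletion One-row deletion call (VCF-style, normalized).
#' @param annotations Optional annotation data.frame; when supplied and the
#'   deletion lies wholly within a CDS, `in_frame` and the deleted residue
#'   range are filled in.
#' @return List with `repeat_length`, `repeat_sequence`, `in_frame`,
#'   `deleted_residue_range` (or `NULL`).
#' @export
flanking_repeat <- function(genome, deletion, annotations = NULL) {
  if (nchar(deletion$ref) <= nchar(deletion$alt))
    stop("flanking_repeat requires a deletion call")
  d <- nchar(deletion$ref) - nchar(deletion$alt)
  s <- deletion$pos                     # 0-based start of deleted segment
                                        # (pos is the 1-based anchor base)
  L <- nchar(genome$seq)
  m <- 0L
  while (s + d + m < L &&
         substr(genome$seq, s + 1L + m, s + 1L + m) ==
         substr(genome$seq, s + d + 1L + m, s + d + 1L + m))
    m <- m + 1L
  res <- list(repeat_length = m,
              repeat_sequence = if (m > 0L) substr(genome$seq, s + 1L, s + m)
                                else "",
              in_frame = FALSE, deleted_residue_range = NULL)
  if (!is.null(annotations)) {
    first <- s + 1L; last <- s + d
    hit <- which(annotations$start <= first & annotations$end >= last)
    if (length(hit) == 1L && d %% 3L == 0L) {
      res$in_frame <- TRUE
      res$deleted_residue_range <-
        residue_range(deletion, annotations[hit, ], genome)
    }
  }
  res
}

#' Deleted residue range of an in-frame deletion
#'
#' Translates the reference and mutant CDS and reports the 1-based indices of
#' the first and last deleted residues (maximal common prefix, then
#' `length/3` residues).  Works for deletions that do not start on a codon
#' boundary (the junction forms a hybrid codon) and for minus-strand genes.
#'
#' @param deletion One-row deletion call (VCF-style anchor base included).
#' @param gene One annotation row wholly containing the deletion.
#' @param genome Reference [genome_record()].
#' @return Integer vector `c(first, last)`.
#' @export
residue_range <- function(deletion, gene, genome) {
  d <- nchar(deletion$ref) - nchar(deletion$alt)
  if (d <= 0L) stop("not a deletion")
  if (d %% 3L != 0L) stop("frameshift deletion has no residue range")
  first <- deletion$pos + 1L; last <- deletion$pos + d
  if (first < gene$start || last > gene$end)
    stop("deletion not wholly within the CDS")
  ref_cds <- cds_sequence(genome, gene)
  mut_genome <- genome
  mut_genome$seq <- apply_variants(genome, deletion)
  mut_gene <- gene
  if (gene$strand == "+") {
    mut_gene$end <- gene$end - d
  } else {
    ## on the minus strand the CDS keeps its genomic end; the start moves
    mut_gene$end <- gene$end - d
  }
  mut_cds <- cds_sequence(mut_genome, mut_gene)
  ref_aa <- strsplit(translate_cds(ref_cds), "")[[1]]
  mut_aa <- strsplit(translate_cds(mut_cds), "")[[1]]
  n_del <- d %/% 3L
  pre <- 0L
  while (pre < length(mut_aa) && ref_aa[pre + 1L] == mut_aa[pre + 1L])
    pre <- pre + 1L
  c(pre + 1L, pre + n_del)
}

#' Write a classified variant report
#'
#' One row per variant: locus (position), mutation type, CDS product,
#' shorthand and effect class.
#'
#' @param effects Output of [classify_variants()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_effects_tsv <- function(effects, path) {
  tab <- data.frame(locus = effects$pos,
                    mut_type = c(substitution = "Sub.", deletion = "Del.",
                                 insertion = "Ins.")[effects$type],
                    cds_product = ifelse(is.na(effects$product), "No CDS",
                                         effects$product),
                    mutation = effects$shorthand,
                    class = effects$effect_class,
                    ref = effects$ref, var = effects$alt,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
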