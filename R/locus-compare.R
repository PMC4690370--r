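## ---------------------------------------------------------------------------
## Regulatory / comparative locus analyses: Spo0A-box (0A box) promoter
## scanning, intergenic-gap reports, and pairwise percent identity.
## ---------------------------------------------------------------------------

ZERO_A_BOX <- "TGNCGAA"

#' Scan for 0A boxes upstream of genes
#'
#' Finds all matches of the Spo0A-binding consensus `5'-TGNCGAA-3'` on either
#' strand whose footprint lies within `window` bases upstream of a gene's
#' translational start (upstream is 5' of the gene on its own strand).
#' `distance_upstream` is measured from the gene start to the box base nearest
#' the gene boundary on the genomic axis facing the gene, i.e. for a
#' plus-strand gene `start - footprint_start`, mirrored for minus-strand
#' genes.
#'
#' @param genome A [genome_record()].
#' @param annotations CDS annotation data.frame.
#' @param window Upstream window in bases (default 300).
#' @param motif Box consensus (default `"TGNCGAA"`).
#' @return Data.frame `gene_id`, `box_position` (1-based genomic coordinate of
#'   the footprint's leftmost base), `strand_of_match`, `distance_upstream`.
#' @export
scan_0a_boxes <- function(genome, annotations, window = 300L,
                          motif = ZERO_A_BOX) {
  stopifnot(window > 0)
  m <- iupac_motif(motif)
  w <- nchar(m$pattern)
  L <- nchar(genome$seq)
  hits <- scan_motif(genome, m)
  out <- list()
  if (!is.null(hits) && nrow(hits) > 0L) {
    left <- .footprint_key(hits, w, L)
    right <- left + w - 1L                     # footprints wrapping the origin
    ok <- right <= L                           # are skipped for windowing
    left <- left[ok]; right <- right[ok]; strands <- hits$strand[ok]
    for (i in seq_len(nrow(annotations))) {
      gene <- annotations[i, ]
      if (gene$strand == "+") {
        lo <- max(1L, gene$start - window); hi <- gene$start - 1L
        sel <- left >= lo & right <= hi
        if (any(sel))
          out[[length(out) + 1L]] <-
            data.frame(gene_id = gene$gene_id, box_position = left[sel],
                       strand_of_match = strands[sel],
                       distance_upstream = gene$start - left[sel],
                       stringsAsFactors = FALSE)
      } else {
        lo <- gene$end + 1L; hi <- min(L, gene$end + window)
        sel <- left >= lo & right <= hi
        if (any(sel))
          out[[length(out) + 1L]] <-
            data.frame(gene_id = gene$gene_id, box_position = left[sel],
                       strand_of_match = strands[sel],
                       distance_upstream = right[sel] - gene$end,
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), box_position = integer(0),
                      strand_of_match = character(0),
                      distance_upstream = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gaps between consecutive genes
#'
#' For genes sorted by start, the gap is the number of bases strictly between
#' one gene's end and the next gene's start
#' (`next_start - previous_end - 1`); small gaps indicate tight, operon-like
#' organization.  Input order does not matter; overlapping annotations are an
#' error.
#'
#' @param annotations CDS annotation data.frame.
#' @return Data.frame `gene_left`, `gene_right`, `gap`.
#' @export
intergenic_gaps <- function(annotations) {
  ann <- annotations[order(annotations$start), , drop = FALSE]
  if (nrow(ann) > 1L && any(ann$start[-1L] <= ann$end[-nrow(ann)]))
    stop("overlapping annotations")
  if (nrow(ann) < 2L)
    return(data.frame(gene_left = character(0), gene_right = character(0),
                      gap = integer(0), stringsAsFactors = FALSE))
  n <- nrow(ann)
  data.frame(gene_left = ann$gene_id[-n], gene_right = ann$gene_id[-1L],
             gap = ann$start[-1L] - ann$end[-n] - 1L,
             stringsAsFactors = FALSE)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Pairwise percent identity by global alignment
#'
#' End-to-end (Needleman-Wunsch) alignment with linear gap penalties.  DNA:
#' match +1, mismatch -1, gap -2.  Protein: BLOSUM62, gap -8.  Identity is
#' the number of identical columns over the total alignment length (gap
#' columns count in the denominator), times 100.
#'
#' @param a,b Sequences (character scalars).
#' @param alphabet `"dna"` or `"protein"`.
#' @return List `pct_identity`, `alignment_length`, `score`.
#' @export
pairwise_identity <- function(a, b, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (alphabet == "dna") {
    letters_ok <- c("A", "C", "G", "T")
    S <- matrix(-1, 4, 4, dimnames = list(letters_ok, letters_ok))
    diag(S) <- 1
    gap <- -2
  } else {
    letters_ok <- AA20
    S <- .blosum62()[AA20, AA20]
    gap <- -8
  }
  ## canonical argument order makes the reported identity symmetric even
  ## when co-optimal alignments exist (tie-breaks are orientation-dependent)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  ach <- strsplit(a, "")[[1]]; bch <- strsplit(b, "")[[1]]
  if (!all(ach %in% letters_ok) || !all(bch %in% letters_ok))
    stop("sequence contains characters outside the ", alphabet, " alphabet")
  ai <- match(ach, letters_ok); bi <- match(bch, letters_ok)
  aln <- nw_align_cpp(ai, bi, S, gap)
  ncol_aln <- length(aln$a_idx)
  both <- aln$a_idx > 0 & aln$b_idx > 0
  ident <- sum(both & ach[ifelse(both, aln$a_idx, 1L)] ==
                 bch[ifelse(both, aln$b_idx, 1L)])
  list(pct_identity = 100 * ident / ncol_aln,
       alignment_length = ncol_aln, score = aln$score)
}
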