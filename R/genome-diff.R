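## ---------------------------------------------------------------------------
## Assembly-level variant calling between two near-identical genomes.
##
## Instead of read mapping, the two assemblies are compared directly: k-mers
## unique in both genomes serve as anchors, a longest-increasing-subsequence
## chain keeps the collinear subset, and the short gaps between anchors are
## globally aligned by unit-cost edit distance with a deterministic traceback.
## The resulting edit script is converted to normalized, left-aligned variant
## calls (VCF conventions: substitutions as single bases, indels with one
## anchor base).
## ---------------------------------------------------------------------------

#' Find unique shared k-mer anchors between two genomes
#'
#' An anchor is a k-mer occurring exactly once in each genome.  Offsets are
#' 0-based; the list is sorted by `ref_pos`.
#'
#' @param ref,alt [genome_record()] objects.
#' @param k Anchor length in bases (`k >= 11`; default 31).
#' @return Data.frame with columns `ref_pos`, `alt_pos`, `length`.
#' @export
find_anchors <- function(ref, alt, k = 31L) {
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11")
  if (nchar(ref$seq) <= k || nchar(alt$seq) <= k)
    stop("both sequences must be longer than k")
  ref_km <- .kmers(ref$seq, k)
  alt_km <- .kmers(alt$seq, k)
  ref_uni <- !(duplicated(ref_km) | duplicated(ref_km, fromLast = TRUE))
  alt_uni <- !(duplicated(alt_km) | duplicated(alt_km, fromLast = TRUE))
  alt_pos_of <- match(ref_km, alt_km)
  keep <- ref_uni & !is.na(alt_pos_of) & alt_uni[ifelse(is.na(alt_pos_of), 1L,
                                                        alt_pos_of)]
  if (!any(keep))
    stop("no unique shared anchors: genomes too divergent or too repetitive")
  out <- data.frame(ref_pos = which(keep) - 1L,
                    alt_pos = alt_pos_of[keep] - 1L,
                    length = k)
  out[order(out$ref_pos), , drop = FALSE]
}

.kmers <- function(seq, k) {
  n <- nchar(seq)
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Chain anchors to the maximal collinear subset
#'
#' Returns the maximum-cardinality subset strictly increasing in both
#' `ref_pos` and `alt_pos` (longest increasing subsequence on `alt_pos` after
#' sorting by `ref_pos`); ties resolve toward smaller `alt_pos`.
#'
#' @param anchors Data.frame from [find_anchors()].
#' @return The chained subset, same columns.
#' @export
chain_anchors <- function(anchors) {
  if (nrow(anchors) == 0L) return(anchors)
  anchors <- anchors[order(anchors$ref_pos), , drop = FALSE]
  keep <- lis_cpp(as.integer(anchors$alt_pos))
  out <- anchors[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call variants between two assembled genomes
#'
#' Anchors the genomes on unique shared k-mers, chains them, and aligns every
#' inter-anchor gap by unit-cost edit distance (tie-breaks: mismatch over
#' indel; deletion before insertion).  For circular genomes whose assemblies
#' start at different origins, `alt` is rotated so the first chained anchor
#' lies on the main diagonal before calling.  Applying the returned calls to
#' `ref` reconstructs `alt` exactly.
#'
#' @param ref,alt [genome_record()] objects.
#' @param k Anchor k-mer size (default 31).
#' @param max_gap Inter-anchor gaps longer than this abort with a
#'   structural-variation error (default 50000).
#' @return Data.frame of calls: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `type` (`substitution`/`insertion`/`deletion`), left-aligned and
#'   parsimonious, sorted by position.
#' @export
call_variants <- function(ref, alt, k = 31L, max_gap = 50000L) {
  anchors <- chain_anchors(find_anchors(ref, alt, k))
  if (ref$topology == "circular" && alt$topology == "circular") {
    shift <- anchors$alt_pos[1L] - anchors$ref_pos[1L]
    if (shift != 0L) {
      n <- nchar(alt$seq)
      shift <- ((shift %% n) + n) %% n
      if (shift != 0L) {
        alt$seq <- paste0(substr(alt$seq, shift + 1L, n),
                          substr(alt$seq, 1L, shift))
        anchors <- chain_anchors(find_anchors(ref, alt, k))
      }
    }
  }
  ## thin to a non-overlapping tiling so every inter-anchor gap is
  ## non-negative on both genomes
  keep <- logical(nrow(anchors))
  last_r <- -k; last_a <- -k
  for (i in seq_len(nrow(anchors))) {
    if (anchors$ref_pos[i] >= last_r + k && anchors$alt_pos[i] >= last_a + k) {
      keep[i] <- TRUE
      last_r <- anchors$ref_pos[i]; last_a <- anchors$alt_pos[i]
    }
  }
  anchors <- anchors[keep, , drop = FALSE]
  nr <- nchar(ref$seq); na <- nchar(alt$seq)
  ## gap boundaries (0-based half-open) including the leading/trailing segments
  rs <- c(0L, anchors$ref_pos + k); re <- c(anchors$ref_pos, nr)
  as_ <- c(0L, anchors$alt_pos + k); ae <- c(anchors$alt_pos, na)
  calls <- list()
  for (g in seq_along(rs)) {
    rseg <- if (re[g] > rs[g]) substr(ref$seq, rs[g] + 1L, re[g]) else ""
    aseg <- if (ae[g] > as_[g]) substr(alt$seq, as_[g] + 1L, ae[g]) else ""
    if (identical(rseg, aseg)) next
    if (nchar(rseg) > max_gap || nchar(aseg) > max_gap)
      stop("inter-anchor gap exceeds ", max_gap,
           " bases: likely structural variation, not handled")
    calls[[length(calls) + 1L]] <-
      .gap_to_calls(rseg, aseg, rs[g], ref$seq, ref$id)
  }
  if (length(calls) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)
EDIT_S <- local({
  m <- matrix(-1, 4, 4); diag(m) <- 0; m
})

## Align one inter-anchor gap and convert the edit script to VCF-style calls.
## gap_off: 0-based offset of the gap's first ref base in the full genome.
.gap_to_calls <- function(rseg, aseg, gap_off, ref_seq, chrom) {
  ra <- unname(DNA_CODE[strsplit(rseg, "")[[1]]])
  ba <- unname(DNA_CODE[strsplit(aseg, "")[[1]]])
  if (length(ra) == 0L) {
    aln <- list(a_idx = rep(0L, length(ba)), b_idx = seq_along(ba))
  } else if (length(ba) == 0L) {
    aln <- list(a_idx = seq_along(ra), b_idx = rep(0L, length(ra)))
  } else {
    ## unit-cost edit distance; the infinitesimal opening penalty only breaks
    ## ties among equal-cost scripts in favour of contiguous indel runs
    aln <- nw_align_cpp(ra, ba, EDIT_S, -1, gap_open = -1 / 1024)
  }
  ai <- aln$a_idx; bi <- aln$b_idx
  rch <- strsplit(rseg, "")[[1]]; ach <- strsplit(aseg, "")[[1]]
  op <- character(length(ai))
  op[ai > 0 & bi > 0] <- ifelse(rch[ai[ai > 0 & bi > 0]] ==
                                  ach[bi[ai > 0 & bi > 0]], "M", "X")
  op[ai > 0 & bi == 0] <- "D"
  op[ai == 0 & bi > 0] <- "I"
  calls <- list()
  i <- 1L
  while (i <= length(op)) {
    if (op[i] == "M") { i <- i + 1L; next }
    if (op[i] == "X") {
      pos <- gap_off + ai[i]
      calls[[length(calls) + 1L]] <-
        data.frame(chrom = chrom, pos = pos, ref = rch[ai[i]],
                   alt = ach[bi[i]], type = "substitution",
                   stringsAsFactors = FALSE)
      i <- i + 1L
    } else {
      kind <- op[i]
      j <- i
      while (j < length(op) && op[j + 1L] == kind) j <- j + 1L
      if (kind == "D") {
        seg <- paste(rch[ai[i:j]], collapse = "")
        first_ref <- gap_off + ai[i]            # 1-based first deleted base
        anchor <- first_ref - 1L
        if (anchor >= 1L) {
          call <- data.frame(chrom = chrom, pos = anchor,
                             ref = paste0(substr(ref_seq, anchor, anchor), seg),
                             alt = substr(ref_seq, anchor, anchor),
                             type = "deletion", stringsAsFactors = FALSE)
        } else {
          nxt <- first_ref + nchar(seg)
          call <- data.frame(chrom = chrom, pos = 1L,
                             ref = paste0(seg, substr(ref_seq, nxt, nxt)),
                             alt = substr(ref_seq, nxt, nxt),
                             type = "deletion", stringsAsFactors = FALSE)
        }
      } else {
        seg <- paste(ach[bi[i:j]], collapse = "")
        prev <- which(ai[1:i] > 0)              # last ref base consumed before run
        anchor <- if (length(prev)) gap_off + ai[max(prev)] else gap_off
        if (anchor >= 1L) {
          call <- data.frame(chrom = chrom, pos = anchor,
                             ref = substr(ref_seq, anchor, anchor),
                             alt = paste0(substr(ref_seq, anchor, anchor), seg),
                             type = "insertion", stringsAsFactors = FALSE)
        } else {
          call <- data.frame(chrom = chrom, pos = 1L,
                             ref = substr(ref_seq, 1L, 1L),
                             alt = paste0(seg, substr(ref_seq, 1L, 1L)),
                             type = "insertion", stringsAsFactors = FALSE)
        }
      }
      calls[[length(calls) + 1L]] <-
        normalize_variant(call, genome_record(chrom, ref_seq))
      i <- j + 1L
    }
  }
  if (length(calls) == 0L) return(NULL)
  do.call(rbind, calls)
}

#' Left-align (normalize) an indel call
#'
#' Standard VCF left-alignment: the indel is shifted left while the base
#' preceding it equals the repeated end base.  Substitutions and already
#' left-aligned calls pass through unchanged; the operation is idempotent and
#' preserves the ref-to-alt transformation.
#'
#' @param call One-row call data.frame (`chrom`, `pos`, `ref`, `alt`, `type`).
#' @param genome The reference [genome_record()] the call refers to.
#' @return The normalized call.
#' @export
normalize_variant <- function(call, genome) {
  seq <- genome$seq
  if (substr(seq, call$pos, call$pos + nchar(call$ref) - 1L) != call$ref)
    stop("call is inconsistent with the reference sequence at position ",
         call$pos)
  if (nchar(call$ref) == nchar(call$alt)) return(call)
  base_at <- function(p) substr(seq, p, p)
  if (nchar(call$ref) > nchar(call$alt)) {       # deletion; alleles anchor+seg/anchor
    seg <- substr(call$ref, 2L, nchar(call$ref))
    d <- nchar(seg)
    pos <- call$pos
    while (pos > 1L && base_at(pos) == base_at(pos + d)) pos <- pos - 1L
    call$pos <- pos
    call$ref <- substr(seq, pos, pos + d)
    call$alt <- base_at(pos)
  } else {                                       # insertion
    seg <- substr(call$alt, 2L, nchar(call$alt))
    pos <- call$pos
    while (pos > 1L && substr(seg, nchar(seg), nchar(seg)) == base_at(pos)) {
      seg <- paste0(base_at(pos), substr(seg, 1L, nchar(seg) - 1L))
      pos <- pos - 1L
    }
    call$pos <- pos
    call$ref <- base_at(pos)
    call$alt <- paste0(base_at(pos), seg)
  }
  call
}

#' Apply variant calls to a reference sequence
#'
#' Reconstructs the alternate sequence from a reference and a set of
#' non-overlapping VCF-style calls.
#'
#' @param genome Reference [genome_record()].
#' @param calls Call data.frame (as from [call_variants()]).
#' @return The alternate sequence (character scalar).
#' @export
apply_variants <- function(genome, calls) {
  seq <- genome$seq
  if (nrow(calls) == 0L) return(seq)
  calls <- calls[order(calls$pos, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(calls))) {
    p <- calls$pos[i]; r <- calls$ref[i]; a <- calls$alt[i]
    if (substr(seq, p, p + nchar(r) - 1L) != r)
      stop("call at position ", p, " does not match the reference")
    seq <- paste0(substr(seq, 1L, p - 1L), a,
                  substr(seq, p + nchar(r), nchar(seq)))
  }
  seq
}

#' Write variant calls as a minimal VCF
#'
#' @param calls Call data.frame.
#' @param genome Reference [genome_record()] (contig line).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(calls, genome, path) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", genome$id, nchar(genome$seq)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) > 0L)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                              calls$chrom, calls$pos, calls$ref, calls$alt))
  writeLines(lines, path)
  invisible(path)
}

#' Read variant calls from a (minimal) VCF
#'
#' Parses CHROM/POS/REF/ALT of a single-sample, single-allele VCF into the
#' call data.frame used across the package.
#'
#' @param path VCF file.
#' @return Call data.frame (`chrom`, `pos`, `ref`, `alt`, `type`).
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t")
  data.frame(chrom = vapply(f, `[[`, "", 1L),
             pos = as.integer(vapply(f, `[[`, "", 2L)),
             ref = vapply(f, `[[`, "", 4L),
             alt = vapply(f, `[[`, "", 5L),
             type = {
               r <- nchar(vapply(f, `[[`, "", 4L))
               a <- nchar(vapply(f, `[[`, "", 5L))
               ifelse(r == a, "substitution",
                      ifelse(r > a, "deletion", "insertion"))
             },
             stringsAsFactors = FALSE)
}
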