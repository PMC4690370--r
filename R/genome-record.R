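#' Construct a genome record
#'
#' A genome record is a single named DNA sequence (alphabet `A/C/G/T`) with a
#' topology flag.  Bacterial chromosomes are circular; the topology matters for
#' motif scanning (matches may wrap across the arbitrary FASTA origin) and for
#' the rotation step of [call_variants()].
#'
#' @param id Sequence name (used as the VCF/GFF contig name).
#' @param sequence Character scalar over `A`, `C`, `G`, `T` (case-insensitive).
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `genome_record` with fields `id`, `seq`,
#'   `topology`.
#' @export
#' @examples
#' g <- genome_record("chr", "ACGTACGT")
#' nchar(g)
genome_record <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    stop("genome sequence must be non-empty")
  if (grepl("[^ACGT]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T}")
  structure(list(id = id, seq = sequence, topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, GC %.3f\n",
              x$id, format(nchar(x$seq), big.mark = ","), x$topology,
              gc_fraction(x)))
  invisible(x)
}

#' @export
nchar.genome_record <- function(x, ...) nchar(x$seq)

#' GC fraction of a genome record
#' @param genome A [genome_record()].
#' @return Proportion of G+C bases.
#' @export
gc_fraction <- function(genome) {
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(genome$seq))
  sum(counts[c("G", "C")]) / nchar(genome$seq)
}

## string-level helpers used throughout (sequences are plain R strings; heavy
## lifting goes through Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

subseq_str <- function(seq, start, end) substr(seq, start, end)

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Read the first sequence of a FASTA file as a genome record
#'
#' @param path FASTA file.
#' @param topology Topology to assign (FASTA carries none).
#' @return A [genome_record()].
#' @export
read_genome_fasta <- function(path, topology = "circular") {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  genome_record(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]),
                topology = topology)
}

#' Write a genome record to FASTA
#'
#' @param genome A [genome_record()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
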