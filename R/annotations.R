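#' Build and validate a CDS annotation table
#'
#' Gene models are held as a plain data.frame with one row per CDS:
#' `gene_id`, `start`, `end` (1-based inclusive), `strand` (`+`/`-`) and
#' `product`.  CDS lengths must be divisible by 3 and annotations must not
#' overlap; overlapping gene models are rejected at load time because every
#' downstream codon mapping assumes a unique gene per position.
#'
#' @param gene_id,start,end,strand,product Parallel vectors, one entry per CDS.
#' @param genome_length Optional genome length for bounds checking.
#' @return A validated annotation data.frame, sorted by `start`.
#' @export
gene_annotations <- function(gene_id, start, end, strand,
                             product = rep("hypothetical protein", length(gene_id)),
                             genome_length = NULL) {
  ann <- data.frame(gene_id = as.character(gene_id),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    product = as.character(product),
                    stringsAsFactors = FALSE)
  validate_annotations(ann, genome_length = genome_length)
}

#' @rdname gene_annotations
#' @param ann An annotation data.frame.
#' @export
validate_annotations <- function(ann, genome_length = NULL) {
  req <- c("gene_id", "start", "end", "strand", "product")
  if (!all(req %in% names(ann)))
    stop("annotations need columns: ", paste(req, collapse = ", "))
  if (nrow(ann) == 0L) return(ann)
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotations")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(ann$start < 1L) || any(ann$end < ann$start))
    stop("invalid CDS coordinates (need 1 <= start <= end)")
  if (!is.null(genome_length) && any(ann$end > genome_length))
    stop("CDS extends beyond genome length")
  len <- ann$end - ann$start + 1L
  if (any(len %% 3L != 0L)) stop("CDS length not divisible by 3: ",
                                 paste(ann$gene_id[len %% 3L != 0L], collapse = ", "))
  ann <- ann[order(ann$start), , drop = FALSE]
  if (nrow(ann) > 1L && any(ann$start[-1L] <= ann$end[-nrow(ann)]))
    stop("overlapping annotations are not supported")
  rownames(ann) <- NULL
  ann
}

#' Extract the coding-strand sequence of a CDS
#'
#' @param genome A [genome_record()].
#' @param gene One annotation row.
#' @return Coding-strand DNA string (reverse-complemented for `-` genes).
#' @export
cds_sequence <- function(genome, gene) {
  s <- subseq_str(genome$seq, gene$start, gene$end)
  if (gene$strand == "-") revcomp(s) else s
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds Coding-strand DNA string, length divisible by 3.
#' @return Amino-acid string (`*` for stop codons).
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3L == 0L)
  if (nchar(cds) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "error"))
}

#' Read CDS annotations from GFF3
#'
#' Keeps `CDS` features (falling back to all features if none are typed CDS),
#' taking `ID` as the gene id and `product` when present.
#'
#' @param path GFF3 file.
#' @param genome_length Optional bounds check.
#' @return Annotation data.frame (see [gene_annotations()]).
#' @export
read_annotations_gff3 <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "CDS"))
    gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    sprintf("cds_%05d", seq_along(gr))
  prod <- if ("product" %in% names(mc)) as.character(mc$product) else
    rep("hypothetical protein", length(gr))
  prod[is.na(prod)] <- "hypothetical protein"
  gene_annotations(ids, GenomicRanges::start(gr), GenomicRanges::end(gr),
                   as.character(GenomicRanges::strand(gr)), prod,
                   genome_length = genome_length)
}

#' Write CDS annotations as GFF3
#'
#' @param ann Annotation data.frame.
#' @param genome The [genome_record()] the coordinates refer to.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(ann, genome, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  S4Vectors::mcols(gr)$product <- ann$product
  GenomeInfoDb::seqlengths(gr) <- nchar(genome$seq)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
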