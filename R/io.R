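#' Read a genome FASTA
#'
#' Loads a genome into a [Biostrings::DNAStringSet]. Sequence names are
#' truncated at the first whitespace so they match GFF3/BED seqids.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation and returns the exon features with their
#' transcript (`Parent`) and gene identifiers resolved. Transcript features
#' may be typed `mRNA` or `transcript`; exons attach to them via `Parent`.
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges` of exons with metadata columns `transcript_id` and
#'   `gene_id`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  tx <- gr[typ %in% c("mRNA", "transcript")]
  tx_gene <- vapply(as.list(tx$Parent), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))
  names(tx_gene) <- tx$ID
  ex <- gr[typ == "exon"]
  if (length(ex) == 0) stop("annotation contains no exon features")
  ex_tx <- vapply(as.list(ex$Parent), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))
  out <- GenomicRanges::granges(ex)
  S4Vectors::mcols(out)$transcript_id <- ex_tx
  S4Vectors::mcols(out)$gene_id <- unname(tx_gene[ex_tx])
  out
}

## ---- coding-axis helpers -------------------------------------------------
##
## All tandem-acceptor arithmetic is done on the "coding axis": for a +
## strand feature, coding coordinates equal genomic coordinates and the
## contig sequence is used as is; for a - strand feature, the contig is
## reverse-complemented and position g maps to L - g + 1 (L = contig
## length). This collapses both strands onto one code path; results are
## mapped back to genomic coordinates at the end.

coding_pos <- function(g, strand, contig_len) {
  ifelse(strand == "+", g, contig_len - g + 1L)
}

genomic_pos <- coding_pos  # the map is its own inverse

## Character vector of contig sequences keyed by "seqid|strand", with -
## strand entries reverse-complemented. Computed lazily per call site.
coding_contigs <- function(genome, seqids, strands) {
  keys <- unique(paste(seqids, strands, sep = "|"))
  out <- vector("list", length(keys))
  names(out) <- keys
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sq <- parts[1]
    if (!sq %in% names(genome)) {
      stop("seqid '", sq, "' not present in the genome FASTA")
    }
    s <- genome[[sq]]
    if (parts[2] == "-") s <- Biostrings::reverseComplement(s)
    out[[k]] <- as.character(s)
  }
  out
}

## substring on the coding contig, padding out-of-range positions with 'X'
coding_substr <- function(contig, from, to) {
  n <- nchar(contig)
  left <- max(0L, 1L - from)
  right <- max(0L, to - n)
  lo <- max(from, 1L)
  hi <- min(to, n)
  core <- if (lo > hi) "" else substr(contig, lo, hi)
  out <- paste0(strrep("X", min(left, to - from + 1L)), core,
                strrep("X", min(right, to - from + 1L - left)))
  stopifnot(nchar(out) == to - from + 1L)
  out
}
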