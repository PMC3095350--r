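#' Extract introns from annotated gene models
#'
#' Every gap between two consecutive exons of a transcript becomes one
#' intron. Ordinals count from the transcription start (1-based), i.e. in
#' genomic order for `+` transcripts and reverse genomic order for `-`
#' transcripts. Introns whose coding-strand sequence does not end in the
#' canonical acceptor `AG` are kept but flagged (`canonical_acceptor =
#' FALSE`); downstream scanning skips them.
#'
#' @param annotation Exon `GRanges` from [read_annotation()], or a GFF3 path.
#' @param genome `DNAStringSet` from [read_genome()], or a FASTA path.
#' @return A data.frame of class `nagnag_introns` with one row per intron:
#'   `gene_id`, `transcript_id`, `seqid`, `start`, `end` (1-based inclusive
#'   genomic), `strand`, `ordinal`, `upstream_exon_len`,
#'   `downstream_exon_len`, `canonical_acceptor`.
#' @export
extract_introns <- function(annotation, genome) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(genome)) genome <- read_genome(genome)
  ex <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation),
    end = GenomicRanges::end(annotation),
    strand = as.character(GenomicRanges::strand(annotation)),
    transcript_id = annotation$transcript_id,
    gene_id = annotation$gene_id,
    stringsAsFactors = FALSE
  )
  missing_sq <- setdiff(unique(ex$seqid), names(genome))
  if (length(missing_sq) > 0) {
    stop("seqid(s) missing from genome FASTA: ",
         paste(missing_sq, collapse = ", "))
  }
  pieces <- lapply(split(ex, ex$transcript_id), function(tx) {
    tx <- tx[order(tx$start), ]
    n <- nrow(tx)
    if (n < 2) return(NULL)
    if (any(tx$start[-1] <= tx$end[-n])) {
      stop("overlapping exons in transcript ", tx$transcript_id[1])
    }
    ivs <- data.frame(
      gene_id = tx$gene_id[1],
      transcript_id = tx$transcript_id[1],
      seqid = tx$seqid[1],
      start = tx$end[-n] + 1L,
      end = tx$start[-1] - 1L,
      strand = tx$strand[1],
      upstream_exon_len = (tx$end - tx$start + 1L)[-n],
      downstream_exon_len = (tx$end - tx$start + 1L)[-1],
      stringsAsFactors = FALSE
    )
    if (tx$strand[1] == "-") {
      ivs <- ivs[rev(seq_len(n - 1L)), ]
      # on - strand the transcription-downstream exon is the genomic-left one
      tmp <- ivs$upstream_exon_len
      ivs$upstream_exon_len <- ivs$downstream_exon_len
      ivs$downstream_exon_len <- tmp
    }
    ivs$ordinal <- seq_len(n - 1L)
    ivs
  })
  introns <- do.call(rbind, pieces)
  if (is.null(introns)) {
    introns <- data.frame(gene_id = character(), transcript_id = character(),
                          seqid = character(), start = integer(),
                          end = integer(), strand = character(),
                          upstream_exon_len = integer(),
                          downstream_exon_len = integer(),
                          ordinal = integer(), stringsAsFactors = FALSE)
  }
  rownames(introns) <- NULL
  if (nrow(introns) > 0 && any(introns$end < introns$start + 3L)) {
    stop("intron shorter than 4 nt encountered; malformed annotation")
  }
  # canonical acceptor: coding-strand intron sequence ends in AG
  introns$canonical_acceptor <- vapply(seq_len(nrow(introns)), function(i) {
    sq <- genome[[introns$seqid[i]]]
    if (introns$strand[i] == "+") {
      as.character(Biostrings::subseq(sq, introns$end[i] - 1L,
                                      introns$end[i])) == "AG"
    } else {
      # AG on the minus strand reads CT on the plus strand
      as.character(Biostrings::subseq(sq, introns$start[i],
                                      introns$start[i] + 1L)) == "CT"
    }
  }, logical(1))
  class(introns) <- c("nagnag_introns", "data.frame")
  introns
}

#' Scan annotated acceptors for NAGNAG tandem motifs
#'
#' For each canonical intron, looks for a second `AG` three nucleotides
#' upstream of the annotated acceptor `AG` (annotated acceptor is then the
#' distal one; the motif lies entirely in the intron) or three nucleotides
#' downstream, i.e. at exon positions +2/+3 (annotated acceptor proximal;
#' the second `NAG` is exonic). If both configurations are present
#' (`NAGNAGNAG`) each adjacent `AG` pair is emitted as its own site. Sites
#' whose `N` positions are not plain `A`/`C`/`G`/`T` are skipped, as are
#' sites whose motif would extend beyond the contig. Sites shared by several
#' transcripts are deduplicated on (seqid, strand, proximal junction),
#' keeping the lowest-ordinal transcript as representative.
#'
#' Junction coordinates are genomic positions of the last intronic base of
#' each acceptor `AG`; on the coding axis the distal junction is always the
#' proximal junction plus three.
#'
#' @param introns Output of [extract_introns()].
#' @param genome `DNAStringSet` or FASTA path.
#' @return A data.frame of class `nagnag_sites`: `site_id`, `seqid`,
#'   `strand`, `intron_start`, `intron_end`, `proximal_junction`,
#'   `distal_junction`, `motif`, `annotated_acceptor`, `gene_id`,
#'   `transcript_id`, `ordinal`, `upstream_exon_len`, `downstream_exon_len`.
#' @export
scan_nagnag_sites <- function(introns, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  introns <- introns[introns$canonical_acceptor, , drop = FALSE]
  contigs <- coding_contigs(genome, introns$seqid, introns$strand)
  lens <- vapply(genome, length, integer(1))
  rows <- list()
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    key <- paste(it$seqid, it$strand, sep = "|")
    ctg <- contigs[[key]]
    L <- lens[[it$seqid]]
    # intron bounds on the coding axis
    if (it$strand == "+") {
      ce <- it$end
    } else {
      ce <- L - it$start + 1L
    }
    cs <- ce - (it$end - it$start)
    emit <- function(p, annotated) {
      # p = coding position of the proximal junction (last base of first AG)
      motif <- coding_substr(ctg, p - 2L, p + 3L)
      if (grepl("X", motif, fixed = TRUE)) {
        warning("NAGNAG context beyond contig boundary near ", it$seqid,
                ":", p, "; site skipped")
        return(NULL)
      }
      n1 <- substr(motif, 1L, 1L)
      n2 <- substr(motif, 4L, 4L)
      if (!n1 %in% c("A", "C", "G", "T") || !n2 %in% c("A", "C", "G", "T")) {
        return(NULL)
      }
      stopifnot(substr(motif, 2L, 3L) == "AG", substr(motif, 5L, 6L) == "AG")
      gp <- genomic_pos(p, it$strand, L)
      gd <- genomic_pos(p + 3L, it$strand, L)
      data.frame(
        site_id = paste(it$seqid, it$strand, gp, sep = ":"),
        seqid = it$seqid, strand = it$strand,
        intron_start = it$start, intron_end = it$end,
        proximal_junction = gp, distal_junction = gd,
        motif = motif, annotated_acceptor = annotated,
        gene_id = it$gene_id, transcript_id = it$transcript_id,
        ordinal = it$ordinal,
        upstream_exon_len = it$upstream_exon_len,
        downstream_exon_len = it$downstream_exon_len,
        stringsAsFactors = FALSE
      )
    }
    # upstream AG: motif entirely intronic, annotated acceptor = distal
    if (ce - 4L >= cs && substr(ctg, ce - 4L, ce - 3L) == "AG") {
      rows[[length(rows) + 1L]] <- emit(ce - 3L, "distal")
    }
    # downstream AG at exon positions +2/+3: annotated acceptor = proximal
    # (the exonic NAG must lie inside the downstream exon)
    if (ce + 3L <= nchar(ctg) && it$downstream_exon_len >= 3L &&
        substr(ctg, ce + 2L, ce + 3L) == "AG") {
      rows[[length(rows) + 1L]] <- emit(ce, "proximal")
    }
  }
  sites <- do.call(rbind, rows)
  if (is.null(sites)) {
    sites <- data.frame(site_id = character(), seqid = character(),
                        strand = character(), intron_start = integer(),
                        intron_end = integer(), proximal_junction = integer(),
                        distal_junction = integer(), motif = character(),
                        annotated_acceptor = character(),
                        gene_id = character(), transcript_id = character(),
                        ordinal = integer(), upstream_exon_len = integer(),
                        downstream_exon_len = integer(),
                        stringsAsFactors = FALSE)
  }
  # deduplicate across transcripts: keep lowest ordinal per physical site
  sites <- sites[order(sites$site_id, sites$ordinal), , drop = FALSE]
  sites <- sites[!duplicated(sites$site_id), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("nagnag_sites", "data.frame")
  sites
}

#' Extract the 49-nt context around each NAGNAG site
#'
#' The context is assembled 5'->3' on mRNA sense from four blocks: the last
#' 3 nt of the upstream exon (positions 1-3), the 30 intronic nt immediately
#' upstream of the motif (4-33), the 6-nt NAGNAG motif (34-39), and the
#' 10 nt downstream of the motif (40-49). Positions a short flank cannot
#' supply (intron shorter than the 30-nt window, upstream exon < 3 nt,
#' downstream exon < 10 nt, or contig edge) are padded with the sentinel
#' letter `X`. Reverse-strand sites are reverse-complemented before storage.
#'
#' @param sites Output of [scan_nagnag_sites()].
#' @param genome `DNAStringSet` or FASTA path.
#' @return A data.frame of class `nagnag_contexts`: `site_id`, `seq49`, and
#'   the block offsets `exon_block`, `intron_block`, `motif_block`,
#'   `down_block` (1-based start positions within `seq49`).
#' @export
extract_context <- function(sites, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  contigs <- coding_contigs(genome, sites$seqid, sites$strand)
  lens <- vapply(genome, length, integer(1))
  seq49 <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    ctg <- contigs[[paste(st$seqid, st$strand, sep = "|")]]
    L <- lens[[st$seqid]]
    p <- coding_pos(st$proximal_junction, st$strand, L)
    ce <- if (st$strand == "+") st$intron_end else L - st$intron_start + 1L
    cs <- ce - (st$intron_end - st$intron_start)
    # upstream exon: last 3 nt before the intron (X-padded if exon < 3 nt)
    exon3 <- coding_substr(ctg, cs - 3L, cs - 1L)
    if (st$upstream_exon_len < 3L) {
      keep <- st$upstream_exon_len
      exon3 <- paste0(strrep("X", 3L - keep),
                      substr(exon3, 3L - keep + 1L, 3L))
    }
    # 30 intronic nt immediately 5' of the motif; exonic/absent -> X
    ipos <- (p - 32L):(p - 3L)
    ichars <- strsplit(coding_substr(ctg, p - 32L, p - 3L), "")[[1]]
    ichars[ipos < cs] <- "X"
    intron30 <- paste(ichars, collapse = "")
    motif <- coding_substr(ctg, p - 2L, p + 3L)
    # 10 nt downstream of the motif, clipped to the downstream exon
    dpos <- (p + 4L):(p + 13L)
    dchars <- strsplit(coding_substr(ctg, p + 4L, p + 13L), "")[[1]]
    dchars[dpos > ce + st$downstream_exon_len] <- "X"
    down10 <- paste(dchars, collapse = "")
    ctx <- paste0(exon3, intron30, motif, down10)
    stopifnot(nchar(ctx) == 49L, substr(ctx, 34L, 39L) == st$motif)
    seq49[i] <- ctx
  }
  out <- data.frame(site_id = sites$site_id, seq49 = seq49,
                    exon_block = 1L, intron_block = 4L, motif_block = 34L,
                    down_block = 40L, stringsAsFactors = FALSE)
  class(out) <- c("nagnag_contexts", "data.frame")
  out
}

#' Write the sites table as TSV
#' @param sites Output of [scan_nagnag_sites()].
#' @param path Output file.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write context sequences as FASTA
#'
#' Contexts may contain the sentinel letter `X`, so they are written as
#' plain (B-string) FASTA records, one 49-mer per site.
#' @param contexts Output of [extract_context()].
#' @param path Output file.
#' @export
write_contexts_fasta <- function(contexts, path) {
  bs <- Biostrings::BStringSet(contexts$seq49)
  names(bs) <- contexts$site_id
  Biostrings::writeXStringSet(bs, path)
  invisible(path)
}
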