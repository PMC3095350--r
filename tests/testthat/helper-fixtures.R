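# In-code fixtures: tiny genomes, annotations and alignments assembled from
# explicit strings so expected coordinates can be hand-checked.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}

# minimal hand-written GFF3: exons is a list of transcripts, each a list
# with seqid, strand, gene, and a matrix/data.frame of exon start/end
write_gff3 <- function(transcripts, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (nm in names(transcripts)) {
    tx <- transcripts[[nm]]
    ex <- tx$exons
    lines <- c(lines,
      sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              tx$seqid, min(ex[, 1]), max(ex[, 2]), tx$strand, tx$gene),
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              tx$seqid, min(ex[, 1]), max(ex[, 2]), tx$strand, nm, tx$gene),
      sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              tx$seqid, ex[, 1], ex[, 2], tx$strand, nm))
  }
  writeLines(lines, path)
  path
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# A 80-nt contig with one two-exon gene on the + strand carrying a CAGCAG
# tandem whose annotated acceptor is the distal AG:
#   exon1: 1-10, intron: 11-50 (donor GT, last 6 nt CAGCAG), exon2: 51-80
#   proximal junction 47, distal junction 50
tandem_fixture <- function(strand = "+") {
  exon1 <- "ATGGCCAAAT"
  intron_body <- "GTAAGTTTCTCTCTTTTCCCTTTCTTTCTC"  # 30 nt, no stray AG run
  intron <- paste0(intron_body, "TTCC", "CAGCAG")   # 40 nt
  exon2 <- "TTTCCGGAATCATGCTGATCGATCGGATCC"          # 30 nt, no AG at +2/+3
  contig <- paste0(exon1, intron, exon2)
  stopifnot(nchar(contig) == 80)
  if (strand == "+") {
    genome <- write_fasta(list(chr1 = contig))
    exons <- rbind(c(1, 10), c(51, 80))
  } else {
    genome <- write_fasta(list(chr1 = revcomp(contig)))
    exons <- rbind(c(1, 30), c(71, 80))
  }
  gff <- write_gff3(list(t1 = list(seqid = "chr1", strand = strand,
                                   gene = "g1", exons = exons)))
  list(genome = genome, gff = gff, contig = contig,
       proximal = if (strand == "+") 47L else 34L,
       distal = if (strand == "+") 50L else 31L)
}

# build a splice_alignments table from a list of block matrices
make_alignments <- function(blocks, read_id = NULL, identity = 1,
                            coverage = 1, pool = "sanger",
                            seqid = "chr1", strand = "+") {
  n <- length(blocks)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  nagnag:::new_alignments(
    read_id = read_id, seqid = rep_len(seqid, n),
    strand = rep_len(strand, n),
    blocks = lapply(blocks, function(m) {
      m <- matrix(as.integer(m), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
      m[order(m[, 1]), , drop = FALSE]
    }),
    identity = rep_len(identity, n), coverage = rep_len(coverage, n),
    pool = rep_len(pool, n))
}

# evidence_counts constructor for label/summary tests
make_counts <- function(n_E, n_I, site_id = NULL) {
  if (is.null(site_id)) site_id <- sprintf("s%05d", seq_along(n_E))
  out <- data.frame(site_id = site_id, n_E = as.integer(n_E),
                    n_I = as.integer(n_I), stringsAsFactors = FALSE)
  class(out) <- c("evidence_counts", "data.frame")
  out
}

# sites stub with motifs, enough for summarize_labels()
make_sites_stub <- function(site_id, motif) {
  data.frame(site_id = site_id, motif = motif, stringsAsFactors = FALSE)
}

# independent scanner oracle: regex over the 9-nt window spanning both
# possible AG placements around each annotated acceptor
oracle_scan <- function(introns, genome) {
  hits <- list()
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    if (!it$canonical_acceptor) next
    ctg <- as.character(genome[[it$seqid]])
    L <- nchar(ctg)
    if (it$strand == "-") ctg <- revcomp(ctg)
    ce <- if (it$strand == "+") it$end else L - it$start + 1L
    w <- substr(ctg, ce - 5L, ce + 3L)
    if (nchar(w) < 9) w <- formatC(w, width = 9)  # off-contig: no match
    add <- function(p_cod) {
      gp <- if (it$strand == "+") p_cod else L - p_cod + 1L
      hits[[length(hits) + 1L]] <<- paste(it$seqid, it$strand, gp,
                                          sep = ":")
    }
    if (grepl("^[ACGT]AG[ACGT]AG", w)) add(ce - 3L)
    if (it$downstream_exon_len >= 3L &&
        grepl("^[ACGT]AG[ACGT]AG", substr(w, 4L, 9L))) add(ce)
  }
  sort(unique(unlist(hits)))
}

# labelled feature data for classifier tests: one categorical column
toy_vectors <- function(letters_by_class) {
  labels <- rep(names(letters_by_class),
                vapply(letters_by_class, length, integer(1)))
  data.frame(site_id = sprintf("s%03d", seq_along(labels)),
             N1 = unlist(letters_by_class, use.names = FALSE),
             stringsAsFactors = FALSE) -> df
  list(vectors = df, labels = labels)
}
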