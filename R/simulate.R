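#' Configuration for the synthetic NAGNAG data generator
#'
#' Defaults describe a small but realistic study: multi-exon genes on both
#' strands, a class mixture matching the observed E/I/EI proportions of
#' EST-covered tandem acceptors, class-dependent sequence signal (the
#' acceptor actually used keeps a favourable C/T before its AG while the
#' unused acceptor is degraded towards the rarely functional GAG; the
#' polypyrimidine tract is stronger where both acceptors are active), and
#' a junction-read model with controllable depth, minor-isoform fraction
#' and decoy alignments that each violate exactly one filter.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes.
#' @param introns_per_gene Introns per gene.
#' @param exon_len,intron_len Length ranges (min, max) in nt.
#' @param p_nagnag Fraction of acceptors carrying a NAGNAG tandem.
#' @param class_mix Named mixture over E, I, EI (sums to 1).
#' @param signal Signal strength in `[0, 1]`; 0 makes sequence composition
#'   class-independent (null control), 1 is the full default signal.
#' @param n_strong,n_weak,n_alt Letter distributions of the N position of a
#'   used (strong) and unused (degraded towards the rarely functional GAG)
#'   acceptor of a constitutive site, and of both N positions of an
#'   alternative (EI) site, where the pyrimidine preference C > T > A > G is
#'   most pronounced.
#' @param ppt_prob Per-class pyrimidine probability of the 20-nt
#'   polypyrimidine-tract window.
#' @param ppt_null Pyrimidine probability when `signal = 0`.
#' @param background Genome background base frequencies.
#' @param read_mean Mean junction reads per covered site.
#' @param covered_fraction Fraction of planted sites receiving any reads.
#' @param minor_frac Range of the EI minor-isoform fraction.
#' @param identity_range,coverage_range Quality ranges of genuine reads.
#' @param decoy_frac Decoy alignments as a fraction of genuine reads.
#' @param pool Evidence pool label of the generated reads.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 40L,
                       introns_per_gene = 3L,
                       exon_len = c(80L, 160L),
                       intron_len = c(70L, 140L),
                       p_nagnag = 0.7,
                       class_mix = c(E = 0.536, I = 0.405, EI = 0.059),
                       signal = 1,
                       n_strong = c(A = 0.20, C = 0.40, G = 0.06, T = 0.34),
                       n_weak = c(A = 0.20, C = 0.07, G = 0.65, T = 0.08),
                       n_alt = c(A = 0.06, C = 0.52, G = 0.02, T = 0.40),
                       ppt_prob = c(E = 0.52, I = 0.62, EI = 0.78),
                       ppt_null = 0.5,
                       background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       read_mean = 15,
                       covered_fraction = 0.95,
                       minor_frac = c(0.15, 0.45),
                       identity_range = c(0.96, 1),
                       coverage_range = c(0.92, 1),
                       decoy_frac = 0.1,
                       pool = "sanger") {
  class_mix <- class_mix[c("E", "I", "EI")]
  stopifnot(abs(sum(class_mix) - 1) < 1e-9, signal >= 0, signal <= 1,
            p_nagnag >= 0, p_nagnag <= 1, read_mean > 0,
            intron_len[1] >= 45L, exon_len[1] >= 20L)
  structure(as.list(environment()), class = "sim_config")
}

sample_bases <- function(n, prob) {
  sample(BASES, n, replace = TRUE, prob = prob[BASES])
}

## mix a class-specific distribution with the null distribution
mix_dist <- function(p_class, p_null, s) s * p_class + (1 - s) * p_null

ppt_window <- function(n, p_y) {
  # pyrimidine with probability p_y (C/T equally), else purine (A/G equally)
  pick <- stats::runif(n) < p_y
  out <- character(n)
  out[pick] <- sample(c("C", "T"), sum(pick), replace = TRUE)
  out[!pick] <- sample(c("A", "G"), sum(!pick), replace = TRUE)
  out
}

#' Sample context sequences with class-dependent signal
#'
#' Draws 49-nt NAGNAG contexts for a given splicing class under the
#' configured signal: the N of a used acceptor favours C/T (C > T > A > G),
#' the N of an unused acceptor drifts towards G (GAG acceptors are rarely
#' functional), and the 20-nt upstream window carries a class-dependent
#' pyrimidine bias. At `signal = 0` all classes share one distribution.
#'
#' @param class One of `E`, `I`, `EI`.
#' @param config A [sim_config()].
#' @param n Number of contexts to draw.
#' @return Character vector of `n` 49-mers (motif at positions 34-39).
#' @export
plant_class_signal <- function(class, config = sim_config(), n = 1L) {
  stopifnot(class %in% NB_CLASSES)
  s <- config$signal
  null_n <- c(A = .25, C = .25, G = .25, T = .25)
  p_n1 <- mix_dist(switch(class, E = config$n_strong, I = config$n_weak,
                          EI = config$n_alt), null_n, s)
  p_n2 <- mix_dist(switch(class, E = config$n_weak, I = config$n_strong,
                          EI = config$n_alt), null_n, s)
  p_y <- config$ppt_null + s * (config$ppt_prob[[class]] - config$ppt_null)
  bg <- config$background
  vapply(seq_len(n), function(i) {
    exon3 <- sample_bases(3L, bg)
    up10 <- sample_bases(10L, bg)
    ppt <- ppt_window(20L, p_y)
    n1 <- sample_bases(1L, p_n1)
    n2 <- sample_bases(1L, p_n2)
    down10 <- sample_bases(10L, bg)
    # keep the planted tandem unambiguous: no third AG adjacent to either
    # end of the motif; the constraint is applied identically to every
    # class so the null (zero-signal) generator stays class-exchangeable
    while (paste0(ppt[19], ppt[20]) == "AG") {
      ppt[19:20] <- ppt_window(2L, p_y)
    }
    while (paste0(down10[2], down10[3]) == "AG") {
      down10[2:3] <- sample_bases(2L, bg)
    }
    paste(c(exon3, up10, ppt, n1, "A", "G", n2, "A", "G", down10),
          collapse = "")
  }, character(1))
}

#' Sample labelled contexts for classifier experiments
#'
#' Convenience wrapper drawing `n_per_class` contexts for each splicing
#' class under a configuration's signal, without building a genome.
#'
#' @param n_per_class Contexts per class (single number or named vector
#'   over E, I, EI).
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to `config$seed`).
#' @return A list with `contexts` (a `nagnag_contexts` data.frame) and
#'   `labels` (character vector).
#' @export
simulate_contexts <- function(n_per_class, config = sim_config(),
                              seed = config$seed) {
  set.seed(seed)
  if (length(n_per_class) == 1) {
    n_per_class <- stats::setNames(rep(n_per_class, 3), NB_CLASSES)
  }
  seqs <- character(0); labels <- character(0)
  for (cl in NB_CLASSES) {
    seqs <- c(seqs, plant_class_signal(cl, config, n_per_class[[cl]]))
    labels <- c(labels, rep(cl, n_per_class[[cl]]))
  }
  contexts <- data.frame(
    site_id = sprintf("sim:%s:%d", labels, seq_along(seqs)),
    seq49 = seqs, exon_block = 1L, intron_block = 4L, motif_block = 34L,
    down_block = 40L, stringsAsFactors = FALSE)
  class(contexts) <- c("nagnag_contexts", "data.frame")
  list(contexts = contexts, labels = labels)
}

## read-count model: every covered EI site gets at least one read per
## variant, so a pure-EI configuration is labelled EI by construction
draw_site_reads <- function(class, config) {
  if (stats::runif(1) > config$covered_fraction) {
    return(c(n_E = 0L, n_I = 0L))
  }
  n <- if (class == "EI") {
    2L + stats::rpois(1, max(config$read_mean - 2, 0))
  } else {
    1L + stats::rpois(1, max(config$read_mean - 1, 0))
  }
  if (class == "E") return(c(n_E = n, n_I = 0L))
  if (class == "I") return(c(n_E = 0L, n_I = n))
  f <- stats::runif(1, config$minor_frac[1], config$minor_frac[2])
  minor <- min(max(1L, stats::rbinom(1, n, f)), n - 1L)
  if (stats::runif(1) < 0.5) c(n_E = n - minor, n_I = minor)
  else c(n_E = minor, n_I = n - minor)
}

#' Generate a synthetic genome, annotation, alignments and truth table
#'
#' Builds multi-exon genes on both strands along one chromosome, plants
#' NAGNAG tandem acceptors of known class with [plant_class_signal()]'s
#' sequence signal, emits junction-spanning spliced alignments at the
#' configured depths (BED12 with identity/coverage/pool extra columns),
#' adds decoy alignments that each violate exactly one filtering rule, and
#' records per-site truth. Output is deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list with paths `genome`, `annotation`, `alignments`, `truth`,
#'   `config`, and the in-memory `truth` data.frame.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("sim")) {
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bg <- config$background
  chrom_parts <- character(0)
  offset <- 0L
  spacer <- function(n) paste(sample_bases(n, bg), collapse = "")
  genes <- list(); truth <- list(); reads <- list()
  read_n <- 0L
  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    tx_id <- sprintf("%s.1", gene_id)
    strand <- sample(c("+", "-"), 1)
    n_ex <- config$introns_per_gene + 1L
    ex_len <- sample(config$exon_len[1]:config$exon_len[2], n_ex,
                     replace = TRUE)
    in_len <- sample(config$intron_len[1]:config$intron_len[2],
                     config$introns_per_gene, replace = TRUE)
    has_site <- stats::runif(config$introns_per_gene) < config$p_nagnag
    cls <- sample(NB_CLASSES, config$introns_per_gene, replace = TRUE,
                  prob = config$class_mix)
    # assemble the gene on its coding axis
    exons <- lapply(ex_len, function(l) sample_bases(l, bg))
    introns <- list()
    ctxs <- character(config$introns_per_gene)
    for (k in seq_len(config$introns_per_gene)) {
      iv <- sample_bases(in_len[k], bg)
      iv[1:2] <- c("G", "T")  # donor
      if (has_site[k]) {
        ctx <- plant_class_signal(cls[k], config, 1L)
        ctxs[k] <- ctx
        chars <- strsplit(ctx, "")[[1]]
        exons[[k]][(ex_len[k] - 2L):ex_len[k]] <- chars[1:3]
        if (cls[k] == "E") {
          # annotated acceptor proximal: intron ends ...NAG, exonic NAG
          iv[(in_len[k] - 32L):in_len[k]] <- chars[4:36]
          exons[[k + 1L]][1:13] <- chars[37:49]
        } else {
          # annotated acceptor distal: whole motif intronic
          iv[(in_len[k] - 35L):in_len[k]] <- chars[4:39]
          exons[[k + 1L]][1:10] <- chars[40:49]
        }
      } else {
        # constitutive acceptor with no tandem: ...[not-AG] N A G / exon
        tail5 <- c(sample_bases(2L, bg), sample_bases(1L, bg), "A", "G")
        while (paste0(tail5[1], tail5[2]) == "AG") {
          tail5[1:2] <- sample_bases(2L, bg)
        }
        iv[(in_len[k] - 4L):in_len[k]] <- tail5
        while (paste0(exons[[k + 1L]][2], exons[[k + 1L]][3]) == "AG") {
          exons[[k + 1L]][2:3] <- sample_bases(2L, bg)
        }
      }
      introns[[k]] <- iv
    }
    gene_seq <- character(0)
    ex_coords <- matrix(0L, n_ex, 2)  # gene-local coding coords
    pos <- 0L
    for (k in seq_len(n_ex)) {
      ex_coords[k, ] <- c(pos + 1L, pos + ex_len[k])
      gene_seq <- c(gene_seq, exons[[k]])
      pos <- pos + ex_len[k]
      if (k <= config$introns_per_gene) {
        gene_seq <- c(gene_seq, introns[[k]])
        pos <- pos + in_len[k]
      }
    }
    G <- pos
    gap <- spacer(sample(200:400, 1))
    chrom_parts <- c(chrom_parts, gap)
    offset <- offset + nchar(gap)
    gene_str <- paste(gene_seq, collapse = "")
    if (strand == "-") {
      gene_str <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_str)))
    }
    chrom_parts <- c(chrom_parts, gene_str)
    force(offset)
    to_genomic <- function(c1, c2) {
      if (strand == "+") c(offset + c1, offset + c2)
      else c(offset + G - c2 + 1L, offset + G - c1 + 1L)
    }
    genes[[g]] <- list(gene_id = gene_id, tx_id = tx_id, strand = strand,
                       exons = t(apply(ex_coords, 1, function(r)
                         to_genomic(r[1], r[2]))))
    # truth + reads per planted site
    for (k in seq_len(config$introns_per_gene)) {
      if (!has_site[k]) next
      intron_ce <- ex_coords[k, 2] + in_len[k]  # gene-local coding
      cs <- ex_coords[k, 2] + 1L
      p_cod <- if (cls[k] == "E") intron_ce else intron_ce - 3L
      jp <- to_genomic(p_cod, p_cod)[1]
      jd <- if (strand == "+") jp + 3L else jp - 3L
      cnt <- draw_site_reads(cls[k], config)
      site_id <- paste("chr1", strand, jp, sep = ":")
      truth[[length(truth) + 1L]] <- data.frame(
        site_id = site_id, gene_id = gene_id, transcript_id = tx_id,
        ordinal = k, class = cls[k],
        annotated_acceptor = if (cls[k] == "E") "proximal" else "distal",
        motif = substr(ctxs[k], 34, 39),
        proximal_junction = jp, distal_junction = jd,
        n_E_true = cnt[["n_E"]], n_I_true = cnt[["n_I"]],
        stringsAsFactors = FALSE)
      for (variant in c("E", "I")) {
        nv <- cnt[[paste0("n_", variant)]]
        if (nv == 0) next
        j_cod <- if (variant == "E") p_cod else p_cod + 3L
        for (r in seq_len(nv)) {
          w1 <- sample(40:min(70L, ex_len[k] - 5L), 1)
          dn_max <- (intron_ce - j_cod) + ex_len[k + 1L]
          w2 <- sample(40:min(70L, dn_max - 5L), 1)
          b1 <- to_genomic(cs - w1, cs - 1L)
          b2 <- to_genomic(j_cod + 1L, j_cod + w2)
          m <- rbind(b1, b2)
          m <- m[order(m[, 1]), , drop = FALSE]
          colnames(m) <- c("start", "end")
          read_n <- read_n + 1L
          reads[[read_n]] <- list(
            read_id = sprintf("read%05d:%s:%s", read_n, site_id, variant),
            blocks = m,
            identity = stats::runif(1, config$identity_range[1],
                                    config$identity_range[2]),
            coverage = stats::runif(1, config$coverage_range[1],
                                    config$coverage_range[2]))
        }
      }
    }
    offset <- offset + G
  }
  tail_gap <- spacer(300L)
  chrom_parts <- c(chrom_parts, tail_gap)
  chrom <- paste(chrom_parts, collapse = "")
  # decoys: each violates exactly one rule
  n_decoy <- round(config$decoy_frac * read_n)
  truth_df <- do.call(rbind, truth)
  decoys <- list()
  if (n_decoy > 0 && !is.null(truth_df) && nrow(truth_df) > 0) {
    # the oversized-intron decoy jumps past every gene into the trailing
    # spacer, so its gap boundaries can never coincide with a junction
    far <- max(nchar(chrom), 21000L) + 100L
    chrom <- paste0(chrom, spacer(far + 200L - nchar(chrom)))
    types <- rep_len(c("single_exon", "low_identity", "low_coverage",
                       "big_gap", "boundary_end"), n_decoy)
    for (i in seq_len(n_decoy)) {
      ty <- types[i]
      st <- truth_df[sample(nrow(truth_df), 1), ]
      jp <- st$proximal_junction
      id <- sprintf("decoy%04d:%s", i, ty)
      dk <- switch(ty,
        single_exon = list(read_id = id,
          blocks = cbind(start = jp + 20L, end = jp + 90L),
          identity = 1, coverage = 1),
        low_identity = list(read_id = id,
          blocks = rbind(cbind(start = jp - 120L, end = jp - 60L),
                         cbind(start = jp + 1L, end = jp + 50L)),
          identity = 0.90, coverage = 1),
        low_coverage = list(read_id = id,
          blocks = rbind(cbind(start = jp - 120L, end = jp - 60L),
                         cbind(start = jp + 1L, end = jp + 50L)),
          identity = 1, coverage = 0.80),
        big_gap = list(read_id = id,
          blocks = rbind(cbind(start = 10L, end = 60L),
                         cbind(start = far, end = far + 60L)),
          identity = 1, coverage = 1),
        boundary_end = list(read_id = id,
          # genuine-looking spliced read whose terminal block *ends* at the
          # junction instead of spanning it; its gap sits strictly inside
          # the flanking exon/intron body, away from any junction
          blocks = rbind(cbind(start = jp - 160L, end = jp - 140L),
                         cbind(start = jp - 100L, end = jp)),
          identity = 1, coverage = 1))
      decoys[[i]] <- dk
    }
  }
  all_reads <- c(reads, decoys)
  aln <- new_alignments(
    read_id = vapply(all_reads, `[[`, character(1), "read_id"),
    seqid = "chr1", strand = "+",
    blocks = lapply(all_reads, `[[`, "blocks"),
    identity = vapply(all_reads, `[[`, numeric(1), "identity"),
    coverage = vapply(all_reads, `[[`, numeric(1), "coverage"),
    pool = config$pool)
  # write outputs
  paths <- list(genome = file.path(dir, "genome.fa"),
                annotation = file.path(dir, "annotation.gff3"),
                alignments = file.path(dir, "alignments.bed"),
                truth = file.path(dir, "truth.tsv"),
                config = file.path(dir, "config.json"))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  Biostrings::writeXStringSet(genome, paths$genome)
  write_sim_gff3(genes, paths$annotation)
  write_bed12(aln, paths$alignments)
  if (is.null(truth_df)) truth_df <- data.frame()
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  c(paths, list(truth_table = truth_df))
}

## GFF3 writer for the simulated gene models (gene/mRNA/exon with ID/Parent)
write_sim_gff3 <- function(genes, path) {
  grl <- lapply(genes, function(g) {
    ex <- g$exons
    n_ex <- nrow(ex)
    gr <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(min(ex[, 1]), min(ex[, 1]), ex[, 1]),
                       c(max(ex[, 2]), max(ex[, 2]), ex[, 2])),
      strand = g$strand)
    gr$type <- c("gene", "mRNA", rep("exon", n_ex))
    gr$ID <- c(g$gene_id, g$tx_id,
               paste0(g$tx_id, ".exon", seq_len(n_ex)))
    gr$Parent <- IRanges::CharacterList(
      c(list(character(0)), list(g$gene_id),
        rep(list(g$tx_id), n_ex)))
    gr
  })
  gr <- do.call(c, grl)
  gr$type <- factor(gr$type, levels = c("gene", "mRNA", "exon"))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write spliced alignments as BED12 (+ identity/coverage/pool columns)
#'
#' The inverse of [read_alignments_bed12()]'s dialect: standard BED12 with
#' three extra columns.
#' @param alignments A `splice_alignments` data.frame.
#' @param path Output file.
#' @export
write_bed12 <- function(alignments, path) {
  rows <- vapply(seq_len(nrow(alignments)), function(i) {
    m <- alignments$blocks[[i]]
    cs <- m[1, 1] - 1L  # BED is 0-based half-open
    ce <- m[nrow(m), 2]
    sizes <- paste(m[, 2] - m[, 1] + 1L, collapse = ",")
    starts <- paste(m[, 1] - 1L - cs, collapse = ",")
    paste(alignments$seqid[i], cs, ce, alignments$read_id[i], 0,
          alignments$strand[i], cs, ce, "0,0,0", nrow(m), sizes, starts,
          alignments$identity[i], alignments$coverage[i],
          alignments$pool[i], sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
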