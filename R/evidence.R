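#' Alignment filter parameters
#'
#' Quality thresholds applied to spliced alignments before junction-support
#' counting: minimum alignment identity, minimum fraction of the read
#' aligned, maximum intron (block gap) length, and the slack within which an
#' alignment *terminus* at a junction disqualifies that alignment at that
#' site (an alignment merely ending at an exon boundary does not witness a
#' splice).
#'
#' @param min_identity Minimum identity fraction (default 0.95).
#' @param min_read_coverage Minimum aligned fraction of the read (default 0.90).
#' @param max_intron Maximum block-gap length in nt (default 20000).
#' @param boundary_slack Terminus-to-junction distance in nt within which an
#'   alignment is ignored at a site (default 3).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_identity = 0.95, min_read_coverage = 0.90,
                          max_intron = 20000L, boundary_slack = 3L) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_read_coverage >= 0, min_read_coverage <= 1,
            max_intron > 0, boundary_slack >= 0)
  structure(list(min_identity = min_identity,
                 min_read_coverage = min_read_coverage,
                 max_intron = as.integer(max_intron),
                 boundary_slack = as.integer(boundary_slack)),
            class = "filter_params")
}

new_alignments <- function(read_id, seqid, strand, blocks, identity,
                           coverage, pool) {
  out <- data.frame(read_id = read_id, seqid = seqid, strand = strand,
                    identity = identity, coverage = coverage, pool = pool,
                    stringsAsFactors = FALSE)
  out$blocks <- blocks  # list of 2-column (start, end) matrices, sorted
  class(out) <- c("splice_alignments", "data.frame")
  out
}

#' Read spliced alignments from BED12
#'
#' Blocks come from the standard BED12 `blockSizes`/`blockStarts` fields.
#' Alignment identity, read coverage and evidence pool travel in optional
#' extra columns 13-15 (`identity`, `coverage`, `pool`); when absent they
#' default to 1.0, 1.0 and the `pool` argument.
#'
#' @param path BED12 (or BED12+3) file.
#' @param pool Default evidence pool label (default "sanger").
#' @return A `splice_alignments` data.frame.
#' @export
read_alignments_bed12 <- function(path, pool = "sanger") {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  extra <- character(0)
  if (length(first) >= 13) extra <- c(identity = "numeric")
  if (length(first) >= 14) extra <- c(extra, coverage = "numeric")
  if (length(first) >= 15) extra <- c(extra, pool = "character")
  gr <- rtracklayer::import(path, format = "bed", extraCols = extra)
  blocks <- gr$blocks  # IRangesList, relative to alignment start
  abs_blocks <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    m <- cbind(start = GenomicRanges::start(gr)[i] + IRanges::start(b) - 1L,
               end = GenomicRanges::start(gr)[i] + IRanges::end(b) - 1L)
    m[order(m[, 1]), , drop = FALSE]
  })
  new_alignments(
    read_id = gr$name,
    seqid = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    blocks = abs_blocks,
    identity = if ("identity" %in% names(S4Vectors::mcols(gr)))
      gr$identity else 1.0,
    coverage = if ("coverage" %in% names(S4Vectors::mcols(gr)))
      gr$coverage else 1.0,
    pool = if ("pool" %in% names(S4Vectors::mcols(gr))) gr$pool else pool
  )
}

#' Read spliced alignments from GFF3 match features
#'
#' Accepts GFF3 alignment features (`match`, `cDNA_match`, `EST_match`,
#' `match_part`): rows sharing one `ID` (or pointing at it via `Parent`)
#' form the blocks of one alignment. Optional attributes `identity`,
#' `coverage` and `pool` are honoured.
#'
#' @inheritParams read_alignments_bed12
#' @export
read_alignments_gff3 <- function(path, pool = "sanger") {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gr <- gr[typ %in% c("match", "cDNA_match", "EST_match", "match_part")]
  parent <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(as.list(gr$Parent), function(p)
      if (length(p) == 0) NA_character_ else p[[1]], character(1))
  } else rep(NA_character_, length(gr))
  grp <- ifelse(is.na(parent), gr$ID, parent)
  idx_all <- split(seq_along(gr), grp)
  # blocks come from match_part children when present; attributes live on
  # whichever row of the group carries them
  idx <- lapply(idx_all, function(ii) {
    kids <- ii[as.character(gr$type[ii]) == "match_part"]
    if (length(kids) > 0) kids else ii
  })
  get_attr <- function(ii, key, default) {
    if (key %in% names(S4Vectors::mcols(gr))) {
      v <- S4Vectors::mcols(gr)[[key]][ii]
      v <- v[!is.na(v)]
      if (length(v) > 0) return(as(v[1], class(default)))
    }
    default
  }
  new_alignments(
    read_id = names(idx),
    seqid = vapply(idx, function(ii)
      as.character(GenomicRanges::seqnames(gr)[ii[1]]), character(1)),
    strand = vapply(idx, function(ii)
      as.character(GenomicRanges::strand(gr)[ii[1]]), character(1)),
    blocks = lapply(idx, function(ii) {
      m <- cbind(start = GenomicRanges::start(gr)[ii],
                 end = GenomicRanges::end(gr)[ii])
      m[order(m[, 1]), , drop = FALSE]
    }),
    identity = vapply(idx_all, get_attr, numeric(1), key = "identity",
                      default = 1.0),
    coverage = vapply(idx_all, get_attr, numeric(1), key = "coverage",
                      default = 1.0),
    pool = vapply(idx_all, get_attr, character(1), key = "pool",
                  default = pool)
  )
}

#' Read spliced alignments from the package's TSV dialect
#'
#' Tab-separated with header
#' `read_id  seqid  strand  blocks  identity  coverage  pool`, where
#' `blocks` is `start-end;start-end;...` in 1-based inclusive genomic
#' coordinates.
#'
#' @param path TSV file.
#' @return A `splice_alignments` data.frame.
#' @export
read_alignments_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(read_id = "character",
                                          seqid = "character",
                                          strand = "character",
                                          blocks = "character",
                                          pool = "character"))
  blocks <- lapply(strsplit(tab$blocks, ";", fixed = TRUE), function(b) {
    m <- do.call(rbind, lapply(strsplit(b, "-", fixed = TRUE), as.integer))
    colnames(m) <- c("start", "end")
    m[order(m[, 1]), , drop = FALSE]
  })
  new_alignments(tab$read_id, tab$seqid, tab$strand, blocks,
                 tab$identity, tab$coverage, tab$pool)
}

#' Write spliced alignments in the TSV dialect
#' @param alignments A `splice_alignments` data.frame.
#' @param path Output file.
#' @export
write_alignments_tsv <- function(alignments, path) {
  tab <- data.frame(
    read_id = alignments$read_id, seqid = alignments$seqid,
    strand = alignments$strand,
    blocks = vapply(alignments$blocks, function(m)
      paste(paste0(m[, 1], "-", m[, 2]), collapse = ";"), character(1)),
    identity = alignments$identity, coverage = alignments$coverage,
    pool = alignments$pool, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter spliced alignments on quality and structure
#'
#' Retains only multi-block alignments with `identity >= min_identity`,
#' `read_coverage >= min_read_coverage`, and every block gap at most
#' `max_intron` nt. Single-exon (one-block) alignments cannot witness a
#' splice junction and are discarded. Alignments with missing quality
#' fields are rejected.
#'
#' @param alignments A `splice_alignments` data.frame.
#' @param params A [filter_params()] object.
#' @param keep_reasons If `TRUE`, attach a `rejected` attribute listing the
#'   discarded read ids and the first failing rule.
#' @return The retained alignments.
#' @export
filter_alignments <- function(alignments, params = filter_params(),
                              keep_reasons = FALSE) {
  n_blocks <- vapply(alignments$blocks, nrow, integer(1))
  max_gap <- vapply(alignments$blocks, function(m) {
    if (nrow(m) < 2) return(0L)
    max(m[-1, 1] - m[-nrow(m), 2] - 1L)
  }, integer(1))
  reason <- rep(NA_character_, nrow(alignments))
  reason[is.na(alignments$identity) | is.na(alignments$coverage)] <-
    "missing_quality"
  reason[is.na(reason) & n_blocks < 2] <- "single_exon"
  reason[is.na(reason) & alignments$identity < params$min_identity] <-
    "low_identity"
  reason[is.na(reason) & alignments$coverage < params$min_read_coverage] <-
    "low_coverage"
  reason[is.na(reason) & max_gap > params$max_intron] <- "oversized_intron"
  keep <- is.na(reason)
  out <- alignments[keep, , drop = FALSE]
  class(out) <- class(alignments)
  if (keep_reasons) {
    attr(out, "rejected") <- data.frame(
      read_id = alignments$read_id[!keep], reason = reason[!keep],
      stringsAsFactors = FALSE)
  }
  out
}

#' Count junction support for the two acceptors of each site
#'
#' An alignment supports the E (proximal) variant of a site when one of its
#' block gaps ends exactly at the proximal junction, and the I (distal)
#' variant when a gap ends exactly at the distal junction ("ends" on the
#' coding axis: for `-` strand sites the genomic gap start is compared).
#' Alignments whose terminal boundary lies within `boundary_slack` nt of
#' either junction contribute nothing at that site; each read counts at most
#' once per site.
#'
#' @param sites Output of [scan_nagnag_sites()].
#' @param alignments Pre-filtered alignments (see [filter_alignments()]).
#' @param params A [filter_params()] object (for `boundary_slack`).
#' @return A data.frame of class `evidence_counts`: `site_id`, `n_E`, `n_I`,
#'   plus per-pool columns `n_E_<pool>` / `n_I_<pool>`.
#' @export
count_acceptor_support <- function(sites, alignments,
                                   params = filter_params()) {
  pools <- sort(unique(alignments$pool))
  n <- nrow(sites)
  n_E <- integer(n); n_I <- integer(n)
  pool_E <- matrix(0L, n, length(pools), dimnames = list(NULL, pools))
  pool_I <- matrix(0L, n, length(pools), dimnames = list(NULL, pools))
  by_seqid <- split(seq_len(nrow(alignments)), alignments$seqid)
  gap_ends <- lapply(alignments$blocks, function(m) {
    if (nrow(m) < 2) return(cbind(start = integer(0), end = integer(0)))
    cbind(start = m[-nrow(m), 2] + 1L, end = m[-1, 1] - 1L)
  })
  term <- t(vapply(alignments$blocks, function(m)
    c(m[1, 1], m[nrow(m), 2]), integer(2)))
  for (i in seq_len(n)) {
    st <- sites[i, ]
    cand <- by_seqid[[st$seqid]]
    if (is.null(cand)) next
    jp <- st$proximal_junction; jd <- st$distal_junction
    near <- abs(term[cand, 1] - jp) <= params$boundary_slack |
      abs(term[cand, 2] - jp) <= params$boundary_slack |
      abs(term[cand, 1] - jd) <= params$boundary_slack |
      abs(term[cand, 2] - jd) <= params$boundary_slack
    cand <- cand[!near]
    if (length(cand) == 0) next
    side <- if (st$strand == "+") "end" else "start"
    hits_p <- vapply(gap_ends[cand], function(g) any(g[, side] == jp),
                     logical(1))
    hits_d <- vapply(gap_ends[cand], function(g) any(g[, side] == jd),
                     logical(1))
    # a read counts once per site; a single read cannot splice at both AGs
    e_reads <- unique(alignments$read_id[cand[hits_p]])
    i_reads <- setdiff(unique(alignments$read_id[cand[hits_d]]), e_reads)
    n_E[i] <- length(e_reads)
    n_I[i] <- length(i_reads)
    for (pl in pools) {
      in_pool <- alignments$read_id[cand][alignments$pool[cand] == pl]
      pool_E[i, pl] <- sum(e_reads %in% in_pool)
      pool_I[i, pl] <- sum(i_reads %in% in_pool)
    }
  }
  out <- data.frame(site_id = sites$site_id, n_E = n_E, n_I = n_I,
                    stringsAsFactors = FALSE)
  for (pl in pools) {
    out[[paste0("n_E_", pl)]] <- pool_E[, pl]
    out[[paste0("n_I_", pl)]] <- pool_I[, pl]
  }
  class(out) <- c("evidence_counts", "data.frame")
  out
}

#' Assign observed splicing labels from evidence counts
#'
#' `E` when only the proximal acceptor has support, `I` when only the
#' distal, `EI` when both (alternative splicing), `uncovered` when neither.
#'
#' @param counts An `evidence_counts` data.frame.
#' @return The input with an `observed` column added.
#' @export
label_sites <- function(counts) {
  if (any(counts$n_E < 0 | counts$n_I < 0)) stop("negative evidence counts")
  counts$observed <- ifelse(
    counts$n_E > 0 & counts$n_I > 0, "EI",
    ifelse(counts$n_E > 0, "E", ifelse(counts$n_I > 0, "I", "uncovered")))
  counts
}

#' Training-set selection criteria
#'
#' A site is a constitutive training example (class E or I) when one
#' variant has at least `min_constitutive_reads` supporting reads and the
#' other has none; it is an alternative (EI) training example when both
#' variants have at least `min_reads_per_variant` reads and the minor
#' variant carries at least `min_minor_fraction` of the total.
#'
#' @param min_constitutive_reads Default 10.
#' @param min_reads_per_variant Default 2.
#' @param min_minor_fraction Default 0.10.
#' @return A list of class `training_criteria`.
#' @export
training_criteria <- function(min_constitutive_reads = 10L,
                              min_reads_per_variant = 2L,
                              min_minor_fraction = 0.10) {
  stopifnot(min_constitutive_reads > 0, min_reads_per_variant > 0,
            min_minor_fraction > 0)
  structure(list(min_constitutive_reads = as.integer(min_constitutive_reads),
                 min_reads_per_variant = as.integer(min_reads_per_variant),
                 min_minor_fraction = min_minor_fraction),
            class = "training_criteria")
}

#' Select high-confidence training examples
#'
#' @param counts A labelled `evidence_counts` data.frame (see
#'   [label_sites()]; the `observed` column is added if missing).
#' @param criteria A [training_criteria()] object.
#' @return The input with a `training_class` column (`E`, `I`, `EI`, or
#'   `none` for sites that go to the test/prediction pool).
#' @export
select_training_set <- function(counts, criteria = training_criteria()) {
  if (!"observed" %in% names(counts)) counts <- label_sites(counts)
  total <- counts$n_E + counts$n_I
  minor <- pmin(counts$n_E, counts$n_I)
  tc <- rep("none", nrow(counts))
  tc[counts$n_E >= criteria$min_constitutive_reads & counts$n_I == 0] <- "E"
  tc[counts$n_I >= criteria$min_constitutive_reads & counts$n_E == 0] <- "I"
  ei <- minor >= criteria$min_reads_per_variant &
    total > 0 & minor / total >= criteria$min_minor_fraction
  tc[ei] <- "EI"
  counts$training_class <- tc
  counts
}

#' Merge two evidence pools for the same sites
#'
#' Element-wise sum of the per-acceptor counts; per-pool breakdown columns
#' are preserved (and summed where both tables carry the same pool).
#'
#' @param a,b `evidence_counts` data.frames over the same `site_id` set.
#' @return A merged `evidence_counts` data.frame.
#' @export
merge_evidence <- function(a, b) {
  if (!setequal(a$site_id, b$site_id)) {
    stop("evidence tables cover different site_id sets; cannot merge")
  }
  b <- b[match(a$site_id, b$site_id), , drop = FALSE]
  out <- data.frame(site_id = a$site_id,
                    n_E = a$n_E + b$n_E, n_I = a$n_I + b$n_I,
                    stringsAsFactors = FALSE)
  pool_cols <- function(x) grep("^n_[EI]_", names(x), value = TRUE)
  for (cl in union(pool_cols(a), pool_cols(b))) {
    out[[cl]] <- (if (cl %in% names(a)) a[[cl]] else 0L) +
      (if (cl %in% names(b)) b[[cl]] else 0L)
  }
  class(out) <- c("evidence_counts", "data.frame")
  out
}

#' Round half away from zero
#'
#' Tally percentages are reported with conventional round-half-up (so
#' 0.05 -> 0.1), not banker's rounding.
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarize site labels
#'
#' Tallies covered sites by observed label, with percentages (round-half-up
#' to one decimal), the GAG-containing subset (sites whose motif has a `G`
#' immediately before either acceptor `AG`), and per-pool breakdowns when
#' pool columns are present.
#'
#' @param labels A labelled `evidence_counts` data.frame.
#' @param sites The matching `nagnag_sites` table (for motifs).
#' @return A list of class `nagnag_summary`.
#' @export
summarize_labels <- function(labels, sites) {
  if (!"observed" %in% names(labels)) labels <- label_sites(labels)
  m <- match(labels$site_id, sites$site_id)
  motif <- sites$motif[m]
  covered <- labels$observed != "uncovered"
  tally <- function(obs) {
    n <- sum(obs != "uncovered")
    cnt <- c(EI = sum(obs == "EI"), E = sum(obs == "E"), I = sum(obs == "I"))
    pct <- if (n > 0) round_half_up(100 * cnt / n, 1) else cnt * NA_real_
    list(covered = n, counts = cnt, pct = pct)
  }
  is_gag <- substr(motif, 1, 1) == "G" | substr(motif, 4, 4) == "G"
  gag <- tally(labels$observed[covered & is_gag])
  out <- list(
    overall = tally(labels$observed),
    gag = gag,
    n_sites = nrow(labels),
    n_uncovered = sum(!covered)
  )
  pools <- unique(sub("^n_E_", "", grep("^n_E_", names(labels), value = TRUE)))
  if (length(pools) > 1) {
    out$per_pool <- lapply(stats::setNames(pools, pools), function(pl) {
      pe <- labels[[paste0("n_E_", pl)]]
      pi <- labels[[paste0("n_I_", pl)]]
      obs <- ifelse(pe > 0 & pi > 0, "EI",
                    ifelse(pe > 0, "E", ifelse(pi > 0, "I", "uncovered")))
      tally(obs)
    })
  }
  class(out) <- "nagnag_summary"
  out
}

#' @export
print.nagnag_summary <- function(x, ...) {
  cat("NAGNAG coverage summary\n")
  cat(sprintf("  sites: %d (covered %d, uncovered %d)\n",
              x$n_sites, x$overall$covered, x$n_uncovered))
  for (cl in c("EI", "E", "I")) {
    cat(sprintf("  %-2s form: %d (%.1f%%)\n", cl,
                x$overall$counts[[cl]], x$overall$pct[[cl]]))
  }
  cat(sprintf("  GAG-containing covered: %d, of which alternative %d (%.1f%%)\n",
              x$gag$covered, x$gag$counts[["EI"]], x$gag$pct[["EI"]]))
  if (!is.null(x$per_pool)) {
    for (pl in names(x$per_pool)) {
      t <- x$per_pool[[pl]]
      cat(sprintf("  pool %s: covered %d, EI %d (%.1f%%), E %d, I %d\n", pl,
                  t$covered, t$counts[["EI"]], t$pct[["EI"]],
                  t$counts[["E"]], t$counts[["I"]]))
    }
  }
  invisible(x)
}

#' Write a per-site evidence table as TSV
#' @param counts A (possibly labelled) `evidence_counts` data.frame.
#' @param path Output file.
#' @export
write_evidence_tsv <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-site evidence table written by [write_evidence_tsv()]
#' @param path TSV file.
#' @return An `evidence_counts` data.frame.
#' @export
read_evidence_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(site_id = "character"))
  class(out) <- c("evidence_counts", "data.frame")
  out
}
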