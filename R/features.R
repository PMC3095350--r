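BASES <- c("A", "C", "G", "T")

## fixed positions inside the 49-nt context
CTX_EXON <- 1:3        # last 3 nt of the upstream exon
CTX_PPT <- 14:33       # the 20 intronic nt immediately 5' of the motif
CTX_MOTIF <- 34:39     # N1 A G N2 A G
CTX_DOWN <- 40:42      # first 3 nt downstream of the motif
# 23-nt acceptor windows (-20..+3 around a junction, acceptor AG at -2/-1):
# proximal junction = context position 36, distal = 39
CTX_WIN_PROX <- 17:39
CTX_WIN_DIST <- 20:42

#' Names of the 31 predictors
#'
#' 28 positional nucleotide features (last 3 exonic nt, the 20 intronic nt
#' upstream of the motif, the two Ns of the NAGNAG, 3 nt downstream) plus
#' `y_content` and the two acceptor-strength scores.
#' @return Character vector of length 31.
#' @export
feature_names <- function() {
  c("exon_m3", "exon_m2", "exon_m1",
    paste0("up_m", 20:1),
    "N1", "N2",
    paste0("down_p", 1:3),
    "y_content", "score_E", "score_I")
}

#' Names of the reduced 5-feature view
#'
#' The Ns of the NAGNAG, the two intronic positions immediately upstream,
#' and the position immediately downstream — the minimal neighbourhood that
#' still predicts splicing outcome well across species.
#' @return Character vector of length 5.
#' @export
reduced_feature_names <- function() {
  c("N1", "N2", "up_m1", "up_m2", "down_p1")
}

ctx_chars <- function(contexts) {
  if (nrow(contexts) == 0) return(matrix(character(0), 0, 49))
  m <- do.call(rbind, strsplit(contexts$seq49, ""))
  stopifnot(ncol(m) == 49L)
  m
}

#' Pyrimidine content of the polypyrimidine-tract window
#'
#' Counts C/T among the 20 intronic nucleotides immediately upstream of the
#' NAGNAG (context positions 14-33), a proxy for polypyrimidine-tract
#' strength. Windows containing the sentinel `X` yield `NA`.
#'
#' @param contexts A `nagnag_contexts` data.frame (or character vector of
#'   49-mers).
#' @return Integer vector in `[0, 20]`, `NA` where the window is padded.
#' @export
compute_y_content <- function(contexts) {
  if (is.character(contexts)) contexts <- data.frame(seq49 = contexts)
  m <- ctx_chars(contexts)[, CTX_PPT, drop = FALSE]
  y <- rowSums(m == "C" | m == "T")
  y[rowSums(m == "X") > 0] <- NA_integer_
  as.integer(y)
}

#' Slice the 23-nt acceptor window for one junction
#'
#' @param contexts A `nagnag_contexts` data.frame.
#' @param which `"proximal"` or `"distal"`.
#' @return Character vector of 23-mers (positions -20..+3 of the junction,
#'   acceptor AG at -2/-1).
#' @export
acceptor_windows <- function(contexts, which = c("proximal", "distal")) {
  which <- match.arg(which)
  rng <- if (which == "proximal") CTX_WIN_PROX else CTX_WIN_DIST
  substr(contexts$seq49, rng[1], rng[length(rng)])
}

#' Genome mononucleotide frequencies
#' @param genome A `DNAStringSet` or FASTA path.
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
base_frequencies <- function(genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  cnt <- colSums(Biostrings::letterFrequency(genome, BASES))
  cnt / sum(cnt)
}

#' Train the position-specific acceptor strength model
#'
#' A 23-position log-odds matrix over the acceptor neighbourhood
#' (-20..+3, acceptor AG fixed at -2/-1): per-position base probabilities
#' with an add-one pseudocount, divided by background frequencies and
#' log2-transformed. Trained on the acceptor windows of constitutive
#' training sites; scoring a window sums the per-position log-odds, so a
#' background-distributed sequence scores about zero and the consensus
#' scores maximally.
#'
#' @param windows Character vector of 23-mers (see [acceptor_windows()]).
#' @param background Named base frequencies (default uniform).
#' @param pseudocount Add-k smoothing constant (default 1).
#' @return A list of class `acceptor_pwm` with elements `log_odds` (4 x 23),
#'   `probs`, `background`, `pseudocount`, `n`.
#' @export
train_acceptor_pwm <- function(windows,
                               background = c(A = .25, C = .25,
                                              G = .25, T = .25),
                               pseudocount = 1) {
  windows <- windows[!grepl("X", windows, fixed = TRUE)]
  if (length(windows) == 0) stop("no sentinel-free training windows")
  if (length(windows) < 50) {
    warning("fewer than 50 training windows; acceptor model may be noisy")
  }
  stopifnot(all(nchar(windows) == 23L))
  background <- background[BASES] / sum(background[BASES])
  m <- do.call(rbind, strsplit(windows, ""))
  counts <- vapply(seq_len(23L), function(j)
    tabulate(factor(m[, j], levels = BASES), 4L), integer(4))
  rownames(counts) <- BASES
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
  structure(list(log_odds = log2(probs / background), probs = probs,
                 background = background, pseudocount = pseudocount,
                 n = length(windows)),
            class = "acceptor_pwm")
}

#' Score acceptor windows against the trained model
#'
#' @param pwm An `acceptor_pwm`.
#' @param windows Character vector of 23-mers, or a `nagnag_contexts`
#'   data.frame combined with `which`.
#' @param which When `windows` is a contexts table: which junction to score.
#' @return Numeric log2-odds scores; `NA` where a window contains `X`.
#' @export
score_acceptor <- function(pwm, windows, which = c("proximal", "distal")) {
  if (is.data.frame(windows)) {
    windows <- acceptor_windows(windows, match.arg(which))
  }
  stopifnot(all(nchar(windows) == 23L))
  m <- do.call(rbind, strsplit(windows, ""))
  scores <- vapply(seq_len(nrow(m)), function(i) {
    idx <- match(m[i, ], BASES)
    if (anyNA(idx)) return(NA_real_)
    sum(pwm$log_odds[cbind(idx, seq_len(23L))])
  }, numeric(1))
  scores
}

#' Extract the 31-feature representation of each site
#'
#' 28 positional letters (exon -3..-1, intron -20..-1, N1, N2, exon
#' +1..+3 relative to the motif), the pyrimidine count of the -20..-1
#' window (`y_content`), and the acceptor-strength scores of the proximal
#' (`score_E`) and distal (`score_I`) junctions. Sites with a sentinel `X`
#' at any feature position are excluded and reported via the `excluded`
#' attribute.
#'
#' @param contexts A `nagnag_contexts` data.frame.
#' @param pwm An `acceptor_pwm` for the strength scores (optional; omitted
#'   scores are `NA`).
#' @return A data.frame of class `feature_vectors`: `site_id` plus the 31
#'   predictor columns of [feature_names()]. Attribute `excluded` lists the
#'   dropped site ids.
#' @export
extract_feature_vectors <- function(contexts, pwm = NULL) {
  m <- ctx_chars(contexts)
  feat_pos <- c(CTX_EXON, CTX_PPT, CTX_MOTIF[c(1, 4)], CTX_DOWN)
  ok <- rowSums(m[, feat_pos, drop = FALSE] == "X") == 0
  excluded <- contexts$site_id[!ok]
  m <- m[ok, , drop = FALSE]
  out <- data.frame(site_id = contexts$site_id[ok], stringsAsFactors = FALSE)
  letters <- stats::setNames(feat_pos, feature_names()[1:28])
  for (nm in names(letters)) out[[nm]] <- m[, letters[[nm]]]
  kept <- contexts[ok, , drop = FALSE]
  out$y_content <- compute_y_content(kept)
  if (!is.null(pwm)) {
    out$score_E <- score_acceptor(pwm, kept, "proximal")
    out$score_I <- score_acceptor(pwm, kept, "distal")
  } else {
    out$score_E <- rep(NA_real_, nrow(out))
    out$score_I <- rep(NA_real_, nrow(out))
  }
  attr(out, "excluded") <- excluded
  class(out) <- c("feature_vectors", "data.frame")
  out
}

#' Restrict feature vectors to the reduced 5-feature view
#' @param vectors A `feature_vectors` data.frame.
#' @return The same rows with only `site_id` and the five predictors of
#'   [reduced_feature_names()].
#' @export
reduced_features <- function(vectors) {
  out <- vectors[, c("site_id", reduced_feature_names()), drop = FALSE]
  class(out) <- class(vectors)
  out
}

#' Per-position base composition of context sequences
#'
#' The frequency matrix behind a sequence logo: for each of the 49 context
#' positions, the fraction of A/C/G/T among the selected sites (sentinel
#' letters are ignored position-wise).
#'
#' @param contexts A `nagnag_contexts` data.frame.
#' @param labels Optional vector of class labels aligned with `contexts`.
#' @param subset Optional label value to restrict to (e.g. `"EI"`).
#' @return A 49 x 4 matrix of frequencies with attribute `n` (sites used).
#' @export
composition_matrix <- function(contexts, labels = NULL, subset = NULL) {
  if (!is.null(subset)) {
    stopifnot(!is.null(labels), length(labels) == nrow(contexts))
    contexts <- contexts[labels == subset, , drop = FALSE]
  }
  stopifnot(nrow(contexts) >= 1)
  m <- ctx_chars(contexts)
  freq <- t(vapply(seq_len(49L), function(j) {
    cnt <- tabulate(factor(m[, j], levels = BASES), 4L)
    if (sum(cnt) == 0) rep(NA_real_, 4) else cnt / sum(cnt)
  }, numeric(4)))
  colnames(freq) <- BASES
  attr(freq, "n") <- nrow(m)
  freq
}

#' Serialize an acceptor model as JSON
#' @param pwm An `acceptor_pwm`.
#' @param path Output file.
#' @export
write_pwm_json <- function(pwm, path) {
  jsonlite::write_json(
    list(log_odds = pwm$log_odds, probs = pwm$probs,
         background = as.list(pwm$background),
         pseudocount = pwm$pseudocount, n = pwm$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an acceptor model written by [write_pwm_json()]
#' @param path JSON file.
#' @return An `acceptor_pwm`.
#' @export
read_pwm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lo <- as.matrix(x$log_odds); rownames(lo) <- BASES
  pr <- as.matrix(x$probs); rownames(pr) <- BASES
  structure(list(log_odds = lo, probs = pr,
                 background = unlist(x$background),
                 pseudocount = x$pseudocount, n = x$n),
            class = "acceptor_pwm")
}

#' Write feature vectors as TSV
#' @param vectors A `feature_vectors` data.frame (a `label` column, if
#'   present, is preserved).
#' @param path Output file.
#' @export
write_features_tsv <- function(vectors, path) {
  utils::write.table(as.data.frame(vectors), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read feature vectors written by [write_features_tsv()]
#' @param path TSV file.
#' @return A `feature_vectors` data.frame.
#' @export
read_features_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(site_id = "character"))
  for (nm in intersect(feature_names()[1:28], names(out))) {
    out[[nm]] <- as.character(out[[nm]])
  }
  class(out) <- c("feature_vectors", "data.frame")
  out
}
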