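#' Pipeline configuration
#'
#' Bundles input paths and stage parameters for [run_pipeline()]. All input
#' files must exist; outputs are written under `out_dir` and are never
#' overwritten unless `overwrite = TRUE`.
#'
#' @param genome Genome FASTA path.
#' @param annotation GFF3 gene-model path.
#' @param alignments Named list/vector of alignment files; names are pool
#'   labels. Formats are inferred from extension (`.bed` BED12, `.gff3`/
#'   `.gff` GFF3 match features, `.tsv` the TSV dialect).
#' @param out_dir Output directory.
#' @param filter A [filter_params()] object.
#' @param criteria A [training_criteria()] object.
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param smoothing Laplace pseudocount for the classifier.
#' @param reduced Use the reduced 5-feature view throughout.
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, alignments, out_dir,
                            filter = filter_params(),
                            criteria = training_criteria(),
                            folds = 10, seed = 1L, smoothing = 1,
                            reduced = FALSE, overwrite = FALSE) {
  for (p in c(genome, annotation, unlist(alignments))) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  if (is.null(names(alignments))) {
    names(alignments) <- paste0("pool", seq_along(alignments))
  }
  structure(list(genome = genome, annotation = annotation,
                 alignments = as.list(alignments), out_dir = out_dir,
                 filter = filter, criteria = criteria, folds = folds,
                 seed = as.integer(seed), smoothing = smoothing,
                 reduced = reduced, overwrite = overwrite),
            class = "pipeline_config")
}

read_alignments_auto <- function(path, pool) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         bed = read_alignments_bed12(path, pool = pool),
         gff = ,
         gff3 = read_alignments_gff3(path, pool = pool),
         tsv = read_alignments_tsv(path),
         stop("cannot infer alignment format from extension: ", path))
}

#' Run the full NAGNAG pipeline
#'
#' Chains the stages: intron extraction and NAGNAG scanning, context
#' extraction, alignment filtering and junction-support counting per
#' evidence pool, pool merging, observed labelling and training-set
#' selection, acceptor-model training on constitutive training sites,
#' feature extraction, naive Bayes fitting with stratified
#' cross-validation, and genome-wide posterior prediction. Each stage's
#' table is written under `out_dir`, and a JSON manifest records
#' parameters, seed and per-stage row counts.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly a list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) > 0 && !config$overwrite) {
    stop("output directory not empty (use overwrite = TRUE): ", out)
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  genome <- stage("read_genome", read_genome(config$genome))
  introns <- stage("extract_introns",
                   extract_introns(config$annotation, genome))
  sites <- stage("scan_nagnag_sites", scan_nagnag_sites(introns, genome))
  contexts <- stage("extract_context", extract_context(sites, genome))
  write_sites_tsv(sites, file.path(out, "sites.tsv"))
  write_contexts_fasta(contexts, file.path(out, "contexts.fa"))

  counts_by_pool <- stage("evidence", lapply(
    stats::setNames(names(config$alignments), names(config$alignments)),
    function(pool) {
      aln <- read_alignments_auto(config$alignments[[pool]], pool)
      aln <- filter_alignments(aln, config$filter)
      count_acceptor_support(sites, aln, config$filter)
    }))
  counts <- Reduce(merge_evidence, counts_by_pool)
  labelled <- select_training_set(label_sites(counts), config$criteria)
  write_evidence_tsv(labelled, file.path(out, "evidence.tsv"))
  summary <- summarize_labels(labelled, sites)
  writeLines(utils::capture.output(print(summary)),
             file.path(out, "summary.txt"))

  pwm <- stage("acceptor_pwm", {
    const <- labelled$training_class %in% c("E", "I")
    ctx_const <- contexts[match(labelled$site_id[const], contexts$site_id), ]
    used <- ifelse(labelled$training_class[const] == "E",
                   "proximal", "distal")
    wins <- ifelse(used == "proximal",
                   acceptor_windows(ctx_const, "proximal"),
                   acceptor_windows(ctx_const, "distal"))
    suppressWarnings(
      train_acceptor_pwm(wins, background = base_frequencies(genome)))
  })
  write_pwm_json(pwm, file.path(out, "acceptor_pwm.json"))

  vectors <- stage("features", extract_feature_vectors(contexts, pwm))
  if (config$reduced) vectors <- reduced_features(vectors)
  write_features_tsv(vectors, file.path(out, "features.tsv"))

  train_idx <- match(labelled$site_id[labelled$training_class != "none"],
                     vectors$site_id)
  keep <- !is.na(train_idx)
  train_vec <- vectors[train_idx[keep], , drop = FALSE]
  train_lab <- labelled$training_class[labelled$training_class != "none"][keep]
  model <- stage("fit", fit_naive_bayes(train_vec, train_lab,
                                        smoothing = config$smoothing))
  write_model_json(model, file.path(out, "model.json"))
  cv <- stage("crossval", cross_validate(train_vec, train_lab,
                                         k = config$folds,
                                         seed = config$seed,
                                         smoothing = config$smoothing))
  utils::write.table(
    data.frame(class = names(cv$auc), auc = as.numeric(cv$auc),
               scheme = cv$scheme, seed = config$seed),
    file.path(out, "crossval.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ig <- rank_information_gain(train_vec, train_lab)
  utils::write.table(as.data.frame(ig), file.path(out, "info_gain.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  post <- stage("predict", compute_posterior(model, vectors))
  post$predicted <- predict_class(post)
  utils::write.table(post, file.path(out, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- c("sites.tsv", "contexts.fa", "evidence.tsv", "summary.txt",
               "acceptor_pwm.json", "features.tsv", "model.json",
               "crossval.tsv", "info_gain.tsv", "predictions.tsv")
  manifest <- list(
    package = "nagnag",
    version = as.character(utils::packageVersion("nagnag")),
    inputs = list(genome = config$genome, annotation = config$annotation,
                  alignments = config$alignments),
    params = list(filter = unclass(config$filter),
                  criteria = unclass(config$criteria),
                  folds = config$folds, seed = config$seed,
                  smoothing = config$smoothing, reduced = config$reduced),
    counts = list(introns = nrow(introns), sites = nrow(sites),
                  covered = sum(labelled$observed != "uncovered"),
                  training = sum(labelled$training_class != "none"),
                  features = nrow(vectors)),
    auc = as.list(cv$auc),
    outputs = as.list(tools::md5sum(file.path(out, outputs)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
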