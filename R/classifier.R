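NB_CLASSES <- c("E", "I", "EI")  # fixed order; also the tie-break order

nb_split_cols <- function(vectors) {
  cols <- setdiff(names(vectors), c("site_id", "label"))
  is_num <- vapply(vectors[cols], is.numeric, logical(1))
  list(categorical = cols[!is_num], numeric = cols[is_num])
}

#' Fit the three-class naive Bayes splice-outcome model
#'
#' Class priors are the training frequencies. Each categorical
#' (nucleotide) feature gets a Laplace-smoothed class-conditional table
#' over A/C/G/T; each numeric feature (`y_content`, `score_E`, `score_I`)
#' gets a class-conditional Gaussian with a variance floor so that
#' within-class constant features cannot produce a zero variance.
#'
#' @param vectors A `feature_vectors` data.frame (any subset of columns; the
#'   model records which features it saw).
#' @param labels Class labels in `E`, `I`, `EI`, aligned with `vectors`.
#' @param smoothing Laplace pseudocount for categorical tables (default 1).
#' @param var_floor Minimum Gaussian variance (default 1e-9).
#' @return A list of class `nagnag_nb`.
#' @export
fit_naive_bayes <- function(vectors, labels, smoothing = 1,
                            var_floor = 1e-9) {
  stopifnot(length(labels) == nrow(vectors))
  labels <- as.character(labels)
  missing <- setdiff(NB_CLASSES, unique(labels))
  if (length(missing) > 0) {
    stop("training set lacks class(es): ", paste(missing, collapse = ", "))
  }
  if (!all(labels %in% NB_CLASSES)) stop("labels must be E, I or EI")
  cols <- nb_split_cols(vectors)
  n_c <- table(factor(labels, levels = NB_CLASSES))
  cat_tables <- lapply(stats::setNames(cols$categorical, cols$categorical),
                       function(f) {
    tab <- table(factor(vectors[[f]], levels = BASES),
                 factor(labels, levels = NB_CLASSES))
    sweep(tab + smoothing, 2, colSums(tab + smoothing), "/")
  })
  gauss <- lapply(stats::setNames(cols$numeric, cols$numeric), function(f) {
    x <- vectors[[f]]
    t(vapply(NB_CLASSES, function(cl) {
      v <- x[labels == cl & !is.na(x)]
      mu <- mean(v)
      s2 <- if (length(v) > 1) stats::var(v) else 0
      c(mean = mu, var = max(s2, var_floor))
    }, numeric(2)))
  })
  structure(list(classes = NB_CLASSES,
                 log_prior = log(as.numeric(n_c) / sum(n_c)),
                 cat_tables = cat_tables, gauss = gauss,
                 smoothing = smoothing, var_floor = var_floor,
                 n = length(labels)),
            class = "nagnag_nb")
}

#' Class posteriors under a fitted model
#'
#' Bayes rule in log space with log-sum-exp normalization. Features that
#' are `NA` for a site simply drop their likelihood term.
#'
#' @param model A `nagnag_nb` model.
#' @param vectors A `feature_vectors` data.frame carrying at least the
#'   features the model was fitted on.
#' @return A data.frame of class `class_posterior`: `site_id` (when
#'   available), `p_E`, `p_I`, `p_EI`, rows summing to 1.
#' @export
compute_posterior <- function(model, vectors) {
  feats <- c(names(model$cat_tables), names(model$gauss))
  absent <- setdiff(feats, names(vectors))
  if (length(absent) > 0) {
    stop("feature schema mismatch; vectors lack: ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(vectors)
  logp <- matrix(rep(model$log_prior, each = n), n, 3,
                 dimnames = list(NULL, model$classes))
  for (f in names(model$cat_tables)) {
    tab <- log(unclass(model$cat_tables[[f]]))
    idx <- match(vectors[[f]], BASES)
    ok <- !is.na(idx)
    logp[ok, ] <- logp[ok, , drop = FALSE] + tab[idx[ok], , drop = FALSE]
  }
  for (f in names(model$gauss)) {
    par <- model$gauss[[f]]
    x <- vectors[[f]]
    ok <- !is.na(x)
    for (k in seq_along(model$classes)) {
      cl <- model$classes[k]
      logp[ok, k] <- logp[ok, k] +
        stats::dnorm(x[ok], par[cl, "mean"], sqrt(par[cl, "var"]), log = TRUE)
    }
  }
  mx <- apply(logp, 1, max)
  post <- exp(logp - mx)
  post <- post / rowSums(post)
  out <- data.frame(p_E = post[, "E"], p_I = post[, "I"],
                    p_EI = post[, "EI"])
  if ("site_id" %in% names(vectors)) {
    out <- cbind(site_id = vectors$site_id, out)
  }
  class(out) <- c("class_posterior", "data.frame")
  out
}

#' Predicted class from posteriors
#'
#' Argmax of the posterior; exact ties break in the fixed order
#' E > I > EI.
#'
#' @param posterior A `class_posterior` data.frame.
#' @return Character vector of predicted classes.
#' @export
predict_class <- function(posterior) {
  p <- as.matrix(posterior[, c("p_E", "p_I", "p_EI"), drop = FALSE])
  NB_CLASSES[apply(p, 1, which.max)]
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney statistic with midrank tie handling: the probability
#' that a random positive scores above a random negative (+ half the tie
#' probability).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) positive indicator.
#' @return AUC in `[0, 1]`.
#' @export
compute_roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need at least one positive and one negative")
  r <- rank(scores)  # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation with per-class ROC/AUC
#'
#' Splits each class into `k` seeded folds (or leave-one-out), trains on
#' the out-of-fold data, pools the held-out posteriors, and reports a
#' one-vs-rest AUC per class.
#'
#' @param vectors A `feature_vectors` data.frame.
#' @param labels Class labels aligned with `vectors`.
#' @param k Number of folds (2, 5 or 10 are customary); ignored when
#'   `loo = TRUE`.
#' @param loo Leave-one-out instead of k-fold.
#' @param seed Integer seed for fold assignment (mandatory for k-fold).
#' @param smoothing,var_floor Passed to [fit_naive_bayes()].
#' @return A list of class `nagnag_cv`: `auc` (named E/I/EI), `posteriors`,
#'   `labels`, `predicted`, `folds`, `scheme`, `seed`.
#' @export
cross_validate <- function(vectors, labels, k = 10, loo = FALSE,
                           seed = NULL, smoothing = 1, var_floor = 1e-9) {
  labels <- as.character(labels)
  n <- nrow(vectors)
  if (loo) {
    folds <- seq_len(n)
  } else {
    if (is.null(seed)) stop("k-fold cross-validation requires a seed")
    small <- names(which(table(labels) < k))
    if (length(small) > 0) {
      stop("class(es) ", paste(small, collapse = ", "), " have fewer than ",
           k, " members; use a smaller k")
    }
    folds <- integer(n)
    set.seed(seed)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  post <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("p_E", "p_I", "p_EI")))
  for (f in unique(folds)) {
    fit <- fit_naive_bayes(vectors[folds != f, , drop = FALSE],
                           labels[folds != f], smoothing, var_floor)
    p <- compute_posterior(fit, vectors[folds == f, , drop = FALSE])
    post[folds == f, ] <- as.matrix(p[, c("p_E", "p_I", "p_EI")])
  }
  auc <- vapply(stats::setNames(NB_CLASSES, NB_CLASSES), function(cl) {
    compute_roc_auc(post[, paste0("p_", cl)], labels == cl)
  }, numeric(1))
  posteriors <- as.data.frame(post)
  if ("site_id" %in% names(vectors)) {
    posteriors <- cbind(site_id = vectors$site_id, posteriors)
  }
  class(posteriors) <- c("class_posterior", "data.frame")
  structure(list(auc = auc, posteriors = posteriors, labels = labels,
                 predicted = predict_class(posteriors), folds = folds,
                 scheme = if (loo) "leave-one-out" else paste0(k, "-fold"),
                 seed = seed),
            class = "nagnag_cv")
}

#' @export
print.nagnag_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation (n = %d)\n", x$scheme, length(x$labels)))
  for (cl in names(x$auc)) {
    cat(sprintf("  AUC %-2s (one-vs-rest): %.3f\n", cl, x$auc[[cl]]))
  }
  acc <- mean(x$predicted == x$labels)
  cat(sprintf("  accuracy: %.3f\n", acc))
  invisible(x)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rank features by information gain
#'
#' Information gain of a feature is the reduction in class entropy given
#' the feature, `H(Class) - H(Class | Feature)`, in bits. Numeric features
#' are discretized into equal-frequency bins first.
#'
#' @param vectors A `feature_vectors` data.frame.
#' @param labels Class labels aligned with `vectors`.
#' @param numeric_bins Number of equal-frequency bins (default 10).
#' @return A data.frame of class `feature_ranking`, sorted by decreasing
#'   gain, with attribute `class_entropy`.
#' @export
rank_information_gain <- function(vectors, labels, numeric_bins = 10) {
  labels <- as.character(labels)
  cols <- nb_split_cols(vectors)
  h_class <- entropy_bits(table(labels) / length(labels))
  ig_one <- function(f) {
    x <- vectors[[f]]
    if (is.numeric(x)) {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
                                                    numeric_bins + 1),
                                   na.rm = TRUE, names = FALSE))
      if (length(br) < 2) return(0)
      x <- cut(x, breaks = br, include.lowest = TRUE)
    }
    ok <- !is.na(x)
    x <- x[ok]; y <- labels[ok]
    if (length(x) == 0) return(0)
    h_y <- entropy_bits(table(y) / length(y))
    h_cond <- sum(vapply(split(y, x), function(yy) {
      length(yy) / length(y) * entropy_bits(table(yy) / length(yy))
    }, numeric(1)))
    h_y - h_cond
  }
  feats <- c(cols$categorical, cols$numeric)
  out <- data.frame(feature = feats,
                    info_gain = vapply(feats, ig_one, numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$info_gain), ]
  rownames(out) <- NULL
  attr(out, "class_entropy") <- h_class
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Predict with a model trained on another dataset
#'
#' Applies a fitted model to feature vectors from a different source
#' without refitting (cross-species transfer). With `reduced = TRUE` the
#' model must have been fitted on the 5-feature view of
#' [reduced_feature_names()].
#'
#' @param model A `nagnag_nb` model.
#' @param vectors Feature vectors from the target dataset.
#' @param reduced Assert the reduced 5-feature schema.
#' @return A `class_posterior` data.frame.
#' @export
transfer_predict <- function(model, vectors, reduced = FALSE) {
  feats <- c(names(model$cat_tables), names(model$gauss))
  if (reduced && !setequal(feats, reduced_feature_names())) {
    stop("reduced = TRUE requires a model fitted on the 5-feature view")
  }
  compute_posterior(model, vectors)
}

#' Serialize a fitted model as JSON
#' @param model A `nagnag_nb` model.
#' @param path Output file.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(classes = model$classes, log_prior = model$log_prior,
         cat_tables = lapply(model$cat_tables, function(t)
           as.data.frame.matrix(unclass(t))),
         gauss = lapply(model$gauss, as.data.frame),
         smoothing = model$smoothing, var_floor = model$var_floor,
         n = model$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#' @param path JSON file.
#' @return A `nagnag_nb` model.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat_tables <- lapply(x$cat_tables, function(t) {
    m <- as.matrix(t); rownames(m) <- BASES; m
  })
  gauss <- lapply(x$gauss, function(g) {
    m <- as.matrix(g); rownames(m) <- x$classes; m
  })
  structure(list(classes = x$classes, log_prior = x$log_prior,
                 cat_tables = cat_tables, gauss = gauss,
                 smoothing = x$smoothing, var_floor = x$var_floor, n = x$n),
            class = "nagnag_nb")
}
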