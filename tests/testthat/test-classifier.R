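# naive Bayes fitting, posteriors, ROC/AUC, cross-validation, information
# gain, transfer prediction

uniform_model <- function(priors) {
  structure(list(
    classes = c("E", "I", "EI"), log_prior = log(priors),
    cat_tables = list(N1 = matrix(0.25, 4, 3,
                                  dimnames = list(c("A", "C", "G", "T"),
                                                  c("E", "I", "EI")))),
    gauss = list(), smoothing = 1, var_floor = 1e-9, n = 0),
    class = "nagnag_nb")
}

test_that("fitting recovers priors and hand-counted conditional tables", {
  toy <- toy_vectors(list(E = c("A", "A"), I = c("C", "C"),
                          EI = c("A", "C")))
  fit <- fit_naive_bayes(toy$vectors, toy$labels)
  expect_equal(exp(fit$log_prior), rep(1 / 3, 3))
  # hand computation: (count + 1) / (n_class + 4)
  tab <- fit$cat_tables$N1
  expect_equal(unname(tab["A", "E"]), 3 / 6)
  expect_equal(unname(tab["C", "E"]), 1 / 6)
  expect_equal(unname(tab["A", "I"]), 1 / 6)
  expect_equal(unname(tab["A", "EI"]), 2 / 6)
  expect_true(all(tab > 0))
  expect_equal(unname(colSums(tab)), rep(1, 3))

  # missing class is a hard error naming it
  expect_error(
    fit_naive_bayes(toy$vectors[1:4, ], toy$labels[1:4]), "EI")

  # within-class constant numeric feature gets the variance floor
  v <- toy$vectors
  v$y_content <- c(5, 5, 7, 7, 6, 8)
  fit2 <- fit_naive_bayes(v, toy$labels)
  expect_equal(unname(fit2$gauss$y_content["E", "var"]), 1e-9)
  expect_equal(unname(fit2$gauss$y_content["E", "mean"]), 5)
})

test_that("posteriors follow Bayes rule and normalize", {
  # uninformative likelihoods: posterior equals the prior
  m <- uniform_model(c(0.5, 0.3, 0.2))
  post <- compute_posterior(m, data.frame(N1 = "A"))
  expect_equal(unlist(post[1, c("p_E", "p_I", "p_EI")], use.names = FALSE),
               c(0.5, 0.3, 0.2))

  # one-feature model vs hand Bayes computation
  toy <- toy_vectors(list(E = c("A", "A"), I = c("C", "C"),
                          EI = c("A", "C")))
  fit <- fit_naive_bayes(toy$vectors, toy$labels)
  post_a <- compute_posterior(fit, data.frame(N1 = "A"))
  # P(c|A) prop. to (1/3) * P(A|c) = (1/3) * (1/2, 1/6, 1/3)
  hand <- c(1 / 2, 1 / 6, 1 / 3) / sum(c(1 / 2, 1 / 6, 1 / 3))
  expect_equal(unlist(post_a[1, c("p_E", "p_I", "p_EI")],
                      use.names = FALSE), hand)

  # normalization holds for random 31-feature vectors without underflow
  sim <- simulate_contexts(40, sim_config(seed = 51))
  pwm <- train_acceptor_pwm(acceptor_windows(sim$contexts, "proximal"))
  fv <- extract_feature_vectors(sim$contexts, pwm)
  fit31 <- fit_naive_bayes(fv, sim$labels)
  p <- compute_posterior(fit31, fv)
  expect_true(all(abs(rowSums(p[, c("p_E", "p_I", "p_EI")]) - 1) < 1e-9))
  expect_true(all(is.finite(as.matrix(p[, c("p_E", "p_I", "p_EI")]))))

  # NA features drop their likelihood term rather than propagating
  fv_na <- fv[1, ]
  fv_na$y_content <- NA_integer_
  expect_false(anyNA(compute_posterior(fit31, fv_na)[, -1]))

  expect_error(compute_posterior(fit31, fv[, 1:10]), "schema")
})

test_that("posteriors agree with an independent naive Bayes oracle", {
  skip_if_not_installed("e1071")
  sim <- simulate_contexts(60, sim_config(seed = 52))
  fv <- extract_feature_vectors(sim$contexts)  # categorical letters only
  cols <- feature_names()[1:28]
  X <- fv[, cols]
  X[] <- lapply(X, factor, levels = c("A", "C", "G", "T"))
  y <- factor(sim$labels)
  ref <- e1071::naiveBayes(X, y, laplace = 1)
  ref_post <- predict(ref, X, type = "raw")
  fit <- fit_naive_bayes(fv[, c("site_id", cols)], sim$labels)
  post <- compute_posterior(fit, fv)
  expect_equal(unname(post$p_E), unname(ref_post[, "E"]), tolerance = 1e-9)
  expect_equal(unname(post$p_I), unname(ref_post[, "I"]), tolerance = 1e-9)
  expect_equal(unname(post$p_EI), unname(ref_post[, "EI"]),
               tolerance = 1e-9)
})

test_that("class prediction takes the argmax with fixed tie order", {
  post <- data.frame(p_E = c(0.1, 1 / 3, 0.2), p_I = c(0.1, 1 / 3, 0.6),
                     p_EI = c(0.8, 1 / 3, 0.2))
  expect_equal(predict_class(post), c("EI", "E", "I"))
  # single-feature model agrees with exhaustive Bayes enumeration
  toy <- toy_vectors(list(E = c("A", "A", "A"), I = c("C", "C"),
                          EI = c("G", "T")))
  fit <- fit_naive_bayes(toy$vectors, toy$labels)
  for (b in c("A", "C", "G", "T")) {
    scores <- log(c(3, 2, 2) / 7) + log(fit$cat_tables$N1[b, ])
    expected <- c("E", "I", "EI")[which.max(scores)]
    got <- predict_class(compute_posterior(fit, data.frame(N1 = b)))
    expect_equal(got, expected)
  }
})

test_that("rank AUC matches pair enumeration and known endpoints", {
  expect_equal(compute_roc_auc(c(0.9, 0.8, 0.1, 0.2),
                               c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(compute_roc_auc(rep(0.4, 6), c(1, 1, 0, 0, 0, 1)), 0.5)
  expect_equal(compute_roc_auc(c(0.9, 0.4, 0.5, 0.1),
                               c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(compute_roc_auc(1:3, c(TRUE, TRUE, TRUE)), "positive")

  # property: midrank AUC equals exhaustive positive-negative comparison
  pair_auc <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(7)
  for (i in 1:25) {
    s <- sample(seq(0, 1, 0.05), 30, replace = TRUE)  # ties guaranteed
    l <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(.4, .6))
    if (!any(l) || all(l)) next
    expect_equal(compute_roc_auc(s, l), pair_auc(s, l))
  }
})

test_that("rank AUC equals trapezoidal ROC area (pROC oracle)", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:5) {
    s <- c(rnorm(40, 1), rnorm(60))
    l <- rep(c(TRUE, FALSE), c(40, 60))
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(compute_roc_auc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("cross-validation separates separable data and not shuffled", {
  toy <- toy_vectors(list(E = rep("A", 20), I = rep("C", 20),
                          EI = rep("G", 20)))
  cv <- cross_validate(toy$vectors, toy$labels, k = 5, seed = 1)
  expect_equal(unname(cv$auc), rep(1, 3))
  expect_equal(cv$scheme, "5-fold")

  # leave-one-out is deterministic (no seed needed)
  cv_loo <- cross_validate(toy$vectors, toy$labels, loo = TRUE)
  expect_equal(unname(cv_loo$auc), rep(1, 3))

  # label shuffling destroys the signal
  sim <- simulate_contexts(100, sim_config(seed = 53))
  fv <- extract_feature_vectors(sim$contexts)
  set.seed(3)
  shuffled <- sample(sim$labels)
  cv_null <- cross_validate(fv, shuffled, k = 5, seed = 2)
  expect_true(all(abs(cv_null$auc - 0.5) < 0.1))

  # class smaller than the fold count is refused with advice
  expect_error(cross_validate(toy$vectors[1:25, ], toy$labels[1:25],
                              k = 10, seed = 1), "smaller k")
  expect_error(cross_validate(toy$vectors, toy$labels, k = 5), "seed")
})

test_that("information gain matches hand-worked entropies", {
  # feature identical to a balanced binary label carries the full bit
  v <- data.frame(f = rep(c("A", "C"), each = 10))
  lab <- rep(c("E", "I"), each = 10)
  ig <- rank_information_gain(v, lab)
  expect_equal(ig$info_gain[ig$feature == "f"], 1.0)
  expect_equal(attr(ig, "class_entropy"), 1.0)

  # constant feature carries nothing
  v$const <- "A"
  ig2 <- rank_information_gain(v, lab)
  expect_equal(ig2$info_gain[ig2$feature == "const"], 0)

  # labels (E,E,I,I), feature (A,A,A,C):
  # IG = 1 - 0.75 * H(1/3, 2/3) = 0.31127...
  v3 <- data.frame(f = c("A", "A", "A", "C"))
  ig3 <- rank_information_gain(v3, c("E", "E", "I", "I"))
  hand <- 1 - 0.75 * (-(1 / 3) * log2(1 / 3) - (2 / 3) * log2(2 / 3))
  expect_equal(ig3$info_gain, hand, tolerance = 1e-10)
  expect_equal(round(hand, 4), 0.3113)

  # bounds and relabeling invariance
  sim <- simulate_contexts(80, sim_config(seed = 54))
  fv <- extract_feature_vectors(sim$contexts)
  igs <- rank_information_gain(fv, sim$labels)
  h <- attr(igs, "class_entropy")
  expect_true(all(igs$info_gain >= -1e-12 & igs$info_gain <= h + 1e-12))
  relab <- fv
  relab$N1 <- chartr("ACGT", "TGCA", relab$N1)
  igs2 <- rank_information_gain(relab, sim$labels)
  expect_equal(igs2$info_gain[igs2$feature == "N1"],
               igs$info_gain[igs$feature == "N1"])
})

test_that("numeric features are discretized for information gain", {
  set.seed(6)
  lab <- rep(c("E", "I"), each = 50)
  v <- data.frame(x = c(rnorm(50, 0), rnorm(50, 5)))
  ig <- rank_information_gain(v, lab, numeric_bins = 10)
  expect_gt(ig$info_gain[1], 0.8)   # near-perfectly separating
  v$noise <- rnorm(100)
  ig2 <- rank_information_gain(v, lab)
  expect_lt(ig2$info_gain[ig2$feature == "noise"], 0.25)
})

test_that("transfer prediction reuses a model without refitting", {
  sim_a <- simulate_contexts(80, sim_config(seed = 55))
  sim_b <- simulate_contexts(40, sim_config(seed = 56))
  fv_a <- extract_feature_vectors(sim_a$contexts)
  fv_b <- extract_feature_vectors(sim_b$contexts)
  fit <- fit_naive_bayes(fv_a, sim_a$labels)
  # A = B: identical to in-domain posteriors
  expect_equal(transfer_predict(fit, fv_a), compute_posterior(fit, fv_a))

  # reduced view restricts to exactly 5 predictors and transfers signal
  red_a <- reduced_features(fv_a)
  fit_red <- fit_naive_bayes(red_a, sim_a$labels)
  expect_length(c(names(fit_red$cat_tables), names(fit_red$gauss)), 5L)
  post_b <- transfer_predict(fit_red, reduced_features(fv_b),
                             reduced = TRUE)
  for (cl in c("E", "I", "EI")) {
    auc <- compute_roc_auc(post_b[[paste0("p_", cl)]], sim_b$labels == cl)
    expect_gt(auc, 0.6)  # above a shuffled baseline
  }
  # full model does not satisfy the reduced schema assertion
  expect_error(transfer_predict(fit, fv_b, reduced = TRUE), "5-feature")
})

test_that("model JSON serialization round-trips posteriors exactly", {
  sim <- simulate_contexts(50, sim_config(seed = 57))
  pwm <- train_acceptor_pwm(acceptor_windows(sim$contexts, "proximal"))
  fv <- extract_feature_vectors(sim$contexts, pwm)
  fit <- fit_naive_bayes(fv, sim$labels)
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(compute_posterior(back, fv), compute_posterior(fit, fv),
               tolerance = 1e-12)
})
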