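test_that("training separates a separable toy set and stores scaling", {
  toy <- toy_features(delta = 4)
  model <- meth_train(toy$features, toy$labels, seed = 3)
  expect_s3_class(model, "meth_model")
  pred <- predict(model, toy$features)
  expect_equal(mean(pred == toy$labels), 1)
  # scaling maps training features into [0, 1]
  ms <- methsc:::scale_features(toy$features, model$scaling)
  expect_gte(min(ms), 0)
  expect_lte(max(ms), 1)
  expect_error(meth_train(toy$features, rep(1L, nrow(toy$features))),
               "classes|class")
})

test_that("confusion metrics follow the defining formulas", {
  # symmetric confusion: TP = FN = TN = FP = 25
  scores <- rep(c(1, -1), each = 50)
  labels <- rep(c(1L, 0L, 1L, 0L), each = 25)
  ev <- methsc:::eval_from_scores(scores, labels)
  expect_equal(c(ev$TP, ev$FP, ev$TN, ev$FN), c(25, 25, 25, 25))
  expect_equal(ev$acc, 0.5)
  expect_equal(ev$mcc, 0)
  expect_equal(ev$sens, 0.5)
  expect_equal(ev$spec, 0.5)

  # perfect predictions
  ev <- methsc:::eval_from_scores(c(2, 3, -1, -4), c(1L, 1L, 0L, 0L))
  expect_equal(c(ev$sens, ev$spec, ev$acc, ev$mcc, ev$auc), rep(1, 5))

  # enumerated confusion matrices against hand formulas
  withr::with_seed(17, {
    for (rep in 1:20) {
      counts <- sample(0:30, 4, replace = TRUE)
      tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
      if (tp + fn == 0 || tn + fp == 0) next
      scores <- c(rep(1, tp + fp), rep(-1, tn + fn))
      labels <- c(rep(1L, tp), rep(0L, fp), rep(0L, tn), rep(1L, fn))
      ev <- methsc:::eval_from_scores(scores, labels)
      expect_equal(ev$sens, tp / (tp + fn))
      expect_equal(ev$spec, tn / (tn + fp))
      expect_equal(ev$acc, (tp + tn) / sum(counts))
      den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den == 0) {
        expect_equal(ev$mcc, 0)
        expect_true(ev$mcc_degenerate)
      } else {
        expect_equal(ev$mcc, (tp * tn - fp * fn) / den)
        expect_gte(ev$mcc, -1)
        expect_lte(ev$mcc, 1)
      }
    }
  })
})

test_that("rank AUC matches the O(n^2) pairwise oracle, with ties", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      n <- 200
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      scores <- round(rnorm(n, mean = labels), 1)  # rounding creates ties
      expect_equal(methsc:::rank_auc(scores, labels),
                   oracle_auc(scores, labels))
    }
  })
})

test_that("rank AUC agrees with an established ROC implementation", {
  withr::with_seed(59, {
    labels <- rbinom(120, 1, 0.5)
    scores <- round(rnorm(120, labels), 1)
    expect_equal(
      methsc:::rank_auc(scores, labels),
      as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                     direction = "<")))
    )
  })
})

test_that("rank AUC equals trapezoidal integration of the ROC points", {
  withr::with_seed(29, {
    labels <- rbinom(300, 1, 0.4)
    scores <- round(rnorm(300, labels), 1)
    ev <- methsc:::eval_from_scores(scores, labels)
    r <- ev$roc_points
    trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
    expect_equal(ev$auc, trap, tolerance = 1e-9)
  })
})

test_that("evaluation is order-invariant and label-flip antisymmetric", {
  withr::with_seed(31, {
    labels <- rbinom(150, 1, 0.5)
    scores <- rnorm(150, labels)
    ev <- methsc:::eval_from_scores(scores, labels)
    perm <- sample(150)
    ev2 <- methsc:::eval_from_scores(scores[perm], labels[perm])
    expect_equal(ev[c("TP", "TN", "FP", "FN", "auc", "mcc")],
                 ev2[c("TP", "TN", "FP", "FN", "auc", "mcc")])
    # exchanging the class roles (flip labels and scores) swaps sens/spec
    swap <- methsc:::eval_from_scores(-scores, 1L - labels)
    expect_equal(swap$sens, ev$spec)
    expect_equal(swap$spec, ev$sens)
    expect_equal(swap$mcc, ev$mcc)
    expect_equal(swap$auc, ev$auc)
    # flipping labels alone negates MCC
    neg <- methsc:::eval_from_scores(scores, 1L - labels)
    expect_equal(neg$mcc, -ev$mcc)
  })
})

test_that("cross-validation is stratified, pooled, and deterministic", {
  toy <- toy_features(n_per_class = 50, delta = 3)
  cv <- cross_validate(toy$features, toy$labels, folds = 5, seed = 5)
  expect_equal(cv$TP + cv$TN + cv$FP + cv$FN, 100)
  expect_length(cv$per_fold, 5)
  fold <- attr(cv, "fold")
  for (cl in 0:1) {
    sizes <- table(fold[toy$labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  cv2 <- cross_validate(toy$features, toy$labels, folds = 5, seed = 5)
  expect_equal(glance(cv), glance(cv2))
  expect_gte(cv$acc, 0.95)  # separable data
  expect_error(cross_validate(toy$features, toy$labels, folds = 60),
               "folds")
})

test_that("cross-validated AUC is null under label permutation", {
  toy <- toy_features(n_per_class = 100, delta = 3)
  perm <- withr::with_seed(41, sample(toy$labels))
  cv <- cross_validate(toy$features, perm, folds = 5, seed = 5)
  n1 <- sum(perm == 1); n0 <- sum(perm == 0)
  sd_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(cv$auc - 0.5), 3 * sd_null)
})

test_that("importance is normalized, splits collinear pairs, buries noise", {
  toy <- toy_features(n_per_class = 50, delta = 3, informative = 2,
                      total = 4)
  # duplicated informative feature
  m <- cbind(toy$features, f1dup = toy$features[, "f1"])
  imp <- feature_importance(m, toy$labels, resamples = 5, seed = 9)
  expect_equal(sum(imp$mean), 1, tolerance = 1e-8)
  r1 <- imp$rank[imp$feature == "f1"]
  r2 <- imp$rank[imp$feature == "f1dup"]
  expect_equal(abs(unname(r1 - r2)), 1)  # adjacent ranks
  expect_equal(unname(imp$mean[imp$feature == "f1"]),
               unname(imp$mean[imp$feature == "f1dup"]), tolerance = 0.1)
  # the pure-noise columns rank behind the informative ones
  informative_ranks <- imp$rank[imp$feature %in% c("f1", "f1dup", "f2")]
  noise_ranks <- imp$rank[imp$feature %in% c("f3", "f4")]
  expect_lt(max(informative_ranks), min(noise_ranks))
})

test_that("single-resample importance equals normalized |w| of one fit", {
  toy <- toy_features(n_per_class = 40, delta = 2)
  imp <- feature_importance(toy$features, toy$labels, resamples = 1,
                            seed = 13)
  expect_equal(sum(imp$mean), 1, tolerance = 1e-8)
  expect_true(all(is.na(imp$sd) | imp$sd == 0))
})

test_that("class distribution test matches the hand Welch formula", {
  x <- c(4.1, 5.2, 6.3)        # class 1
  y <- c(1.0, 2.5, 2.0)        # class 0
  res <- class_distribution_test(c(x, y), c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(res$t_statistic, oracle_welch_t(x, y))
  expect_equal(res$p_value,
               stats::t.test(x, y)$p.value)
  expect_equal(res$variance_pos, var(x))
  expect_equal(res$variance_neg, var(y))

  # degenerate: both classes constant
  res0 <- class_distribution_test(rep(1, 6), rep(c(1L, 0L), 3))
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p_value))
})

test_that("class distribution test has power on a 2-SD shift", {
  hits <- withr::with_seed(47, {
    sum(replicate(20, {
      x <- rnorm(100, 2)
      y <- rnorm(100, 0)
      class_distribution_test(c(x, y),
                              rep(c(1L, 0L), each = 100))$p_value < 0.01
    }))
  })
  expect_equal(hits, 20)
})

test_that("model bundles round-trip through JSON with identical predictions", {
  toy <- toy_features()
  model <- meth_train(toy$features, toy$labels, C = 2, seed = 7)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_meth_model(model, tmp)
  back <- read_meth_model(tmp)
  expect_equal(back$weights, model$weights)
  expect_equal(back$bias, model$bias)
  expect_equal(predict(back, toy$features, type = "decision"),
               predict(model, toy$features, type = "decision"))
})

test_that("balanced subsampling draws the requested class sizes", {
  d <- tibble::tibble(label = rep(c(0L, 1L), c(30, 70)), x = 1:100)
  sub <- subsample_balanced(d, 25, seed = 3)
  expect_equal(as.integer(table(sub$label)), c(25L, 25L))
  expect_error(subsample_balanced(d, 40), "n_per_class")
})

test_that("tidiers expose weights and per-fold metrics", {
  toy <- toy_features()
  model <- meth_train(toy$features, toy$labels)
  td <- tidy(model)
  expect_equal(nrow(td), ncol(toy$features))
  expect_equal(sum(td$importance), 1)
  expect_equal(glance(model)$n_train, nrow(toy$features))

  cv <- cross_validate(toy$features, toy$labels, folds = 4, seed = 2)
  expect_equal(nrow(tidy(cv)), 4)
  expect_equal(nrow(glance(cv)), 1)
  expect_equal(sum(tidy(cv)$TP), cv$TP)
})
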