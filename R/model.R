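# Coerce a feature input (tibble possibly with metadata columns, or matrix)
# to a numeric matrix restricted to the 72 canonical features when present,
# otherwise to all numeric columns.
as_feature_matrix <- function(features, expected = NULL) {
  if (is.matrix(features)) {
    m <- features
  } else if (is.data.frame(features)) {
    nm <- if (!is.null(expected)) expected else
      intersect(c(feature_names(), names(features)), names(features))
    nm <- intersect(nm, names(features))
    if (is.null(expected)) {
      # keep only numeric columns, drop obvious metadata
      nm <- setdiff(nm, c("label", "chrom", "center_position", "stage"))
      nm <- nm[vapply(features[nm], is.numeric, logical(1))]
    }
    if (length(nm) == 0L) abort("No numeric feature columns found.")
    m <- as.matrix(features[, nm, drop = FALSE])
  } else {
    abort("`features` must be a data frame or numeric matrix.")
  }
  if (!is.null(expected) && !identical(colnames(m), expected)) {
    missing <- setdiff(expected, colnames(m))
    if (length(missing) > 0L) {
      abort(sprintf("Missing feature columns: %s ...",
                    paste(utils::head(missing, 5L), collapse = ", ")))
    }
    m <- m[, expected, drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}

check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) abort("`labels` length must match feature rows.")
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be binary 0/1.")
  if (length(unique(labels)) < 2L) {
    abort("Both classes must be present in `labels`.")
  }
  labels
}

#' Train a linear-kernel SVM methylation classifier
#'
#' Fits per-feature min-max scaling on the training data (mapping each
#' training feature into `[0, 1]`), then trains a linear-kernel C-SVM via
#' LibSVM (through \pkg{e1071}) and extracts the primal weight vector. The
#' returned bundle carries everything needed to reproduce predictions:
#' weights and bias, scaling parameters, feature ordering, window size and
#' SC point specification, and training metadata.
#'
#' @param features Feature matrix or tibble (one row per window; columns
#'   from [feature_names()], extra metadata columns are ignored).
#' @param labels Binary vector, 1 = methylated, 0 = unmethylated.
#' @param C Soft-margin cost (default 1).
#' @param seed Integer seed recorded in the bundle (the linear C-SVM fit
#'   itself is deterministic).
#' @param sc_spec Optional [sc_spec()] recorded for provenance.
#' @return An object of class `meth_model`.
#' @export
meth_train <- function(features, labels, C = 1.0, seed = 1L, sc_spec = NULL) {
  m <- as_feature_matrix(features)
  labels <- check_labels(labels, nrow(m))
  if (min(table(labels)) < 2L) abort("Need >= 2 samples per class.")
  scaling <- list(min = apply(m, 2L, min), max = apply(m, 2L, max))
  ms <- scale_features(m, scaling)
  y <- factor(labels, levels = c(1L, 0L))  # positive class first
  fit <- with_seed(seed, e1071::svm(
    x = ms, y = y, kernel = "linear", cost = C, scale = FALSE
  ))
  w <- drop(t(fit$coefs) %*% fit$SV)
  names(w) <- colnames(ms)
  structure(
    list(
      weights = w,
      bias = -fit$rho,
      scaling = scaling,
      feature_names = colnames(ms),
      window_size = if (!is.null(sc_spec)) sc_spec$window_size else NA_integer_,
      sc_spec = sc_spec,
      C = C,
      seed = seed,
      n_train = nrow(ms),
      svm = fit,
      trained = format(Sys.time(), "%Y-%m-%d")
    ),
    class = "meth_model"
  )
}

scale_features <- function(m, scaling) {
  rng <- scaling$max - scaling$min
  rng[rng == 0] <- 1  # constant training feature -> mapped to 0
  sweep(sweep(m, 2L, scaling$min, "-"), 2L, rng, "/")
}

#' @export
print.meth_model <- function(x, ...) {
  cat(sprintf(
    "<meth_model> linear-kernel SVM, %d features, C = %g, n_train = %d\n",
    length(x$weights), x$C, x$n_train
  ))
  top <- utils::head(sort(abs(x$weights), decreasing = TRUE), 5L)
  cat("  top |w|:", paste(sprintf("%s=%.3f", names(top), top),
                          collapse = " "), "\n")
  invisible(x)
}

#' Predict methylation status or decision values
#'
#' @param object A `meth_model`.
#' @param features Feature matrix or tibble.
#' @param type `"class"` for binary 0/1 predictions at decision threshold
#'   0, `"decision"` for signed distances to the separating hyperplane.
#' @param ... Unused.
#' @return Numeric vector (0/1 or decision values).
#' @export
predict.meth_model <- function(object, features,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  m <- as_feature_matrix(features, expected = object$feature_names)
  ms <- scale_features(m, object$scaling)
  dec <- drop(ms %*% object$weights) + object$bias
  if (type == "decision") dec else as.integer(dec > 0)
}

#' Serialize / restore a trained model
#'
#' The bundle is written as plain JSON: weights, bias, scaling, feature
#' ordering, window size, SC point indices and training metadata. The
#' underlying LibSVM object is not serialized; predictions only need the
#' primal weights.
#'
#' @param model A `meth_model`.
#' @param path File path.
#' @return `path` invisibly; `read_meth_model()` returns a `meth_model`.
#' @export
write_meth_model <- function(model, path) {
  obj <- model[c("weights", "bias", "scaling", "feature_names",
                 "window_size", "C", "seed", "n_train", "trained")]
  obj$sc_feature_indices <- if (!is.null(model$sc_spec)) {
    model$sc_spec$feature_indices
  } else {
    NULL
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_meth_model
#' @export
read_meth_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    weights = stats::setNames(as.numeric(obj$weights), obj$feature_names),
    bias = obj$bias,
    scaling = list(
      min = stats::setNames(as.numeric(obj$scaling$min), obj$feature_names),
      max = stats::setNames(as.numeric(obj$scaling$max), obj$feature_names)
    ),
    feature_names = obj$feature_names,
    window_size = obj$window_size,
    sc_spec = NULL,
    C = obj$C,
    seed = obj$seed,
    n_train = obj$n_train,
    svm = NULL,
    trained = obj$trained
  )
  if (!is.null(obj$sc_feature_indices) && !is.na(model$window_size)) {
    sp <- try(sc_spec(model$window_size), silent = TRUE)
    if (!inherits(sp, "try-error") &&
        identical(sp$feature_indices, as.integer(obj$sc_feature_indices))) {
      model$sc_spec <- sp
    }
  }
  structure(model, class = "meth_model")
}

# Confusion counts and Eq.-style metrics from scores (decision values) and
# truth labels; threshold 0.
eval_from_scores <- function(scores, labels) {
  pred <- as.integer(scores > 0)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  denom <- sqrt(as.numeric(tp + fn)) * sqrt(as.numeric(tp + fp)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc_flag <- denom == 0
  mcc <- if (mcc_flag) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  auc <- rank_auc(scores, labels)
  structure(
    list(
      TP = tp, TN = tn, FP = fp, FN = fn,
      sens = sens, spec = spec, acc = acc, mcc = mcc,
      mcc_degenerate = mcc_flag,
      auc = auc,
      roc_points = roc_points(scores, labels),
      per_fold = NULL
    ),
    class = "meth_eval"
  )
}

# Rank (Mann-Whitney) AUC with midranks for ties.
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve points (FPR, TPR) over the distinct decision thresholds.
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last point per tied block
  tibble(
    fpr = c(0, fp[keep] / n0),
    tpr = c(0, tp[keep] / n1)
  )
}

#' Evaluate a trained model
#'
#' Scores `features` with the model (signed distance to the hyperplane),
#' thresholds at 0 to form the confusion matrix, and reports sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, the Matthews
#' correlation coefficient, and rank-based (Mann-Whitney) AUC over the
#' decision values, plus the ROC points. An MCC whose denominator is zero
#' is reported as 0 and flagged (`mcc_degenerate`).
#'
#' @param model A `meth_model`.
#' @param features Feature matrix or tibble.
#' @param labels Binary truth vector.
#' @return An object of class `meth_eval`.
#' @export
meth_evaluate <- function(model, features, labels) {
  scores <- predict(model, features, type = "decision")
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    abort("`labels` length must match feature rows.")
  }
  eval_from_scores(scores, labels)
}

#' @export
print.meth_eval <- function(x, ...) {
  cat(sprintf(
    "<meth_eval> n = %d  TP %d  TN %d  FP %d  FN %d\n",
    x$TP + x$TN + x$FP + x$FN, x$TP, x$TN, x$FP, x$FN
  ))
  cat(sprintf(
    "  Sens %.4f  Spec %.4f  ACC %.4f  MCC %.4f  AUC %.4f\n",
    x$sens, x$spec, x$acc, x$mcc, x$auc
  ))
  if (!is.null(x$per_fold)) {
    cat(sprintf("  pooled over %d folds\n", length(x$per_fold)))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into `folds` stratified folds (per-class fold sizes
#' differ by at most one), trains on each training split — min-max scaling
#' refitted within the split, no leakage — and pools held-out confusion
#' counts and decision values into a single report; per-fold reports are
#' attached as `per_fold`.
#'
#' @param features Feature matrix or tibble.
#' @param labels Binary vector.
#' @param folds Number of folds (default 10).
#' @param C Soft-margin cost.
#' @param seed Seed controlling the fold assignment.
#' @return A `meth_eval` with `per_fold` populated and the fold assignment
#'   attached as attribute `fold`.
#' @export
cross_validate <- function(features, labels, folds = 10L, C = 1.0,
                           seed = 1L) {
  m <- as_feature_matrix(features)
  labels <- check_labels(labels, nrow(m))
  folds <- check_count(folds, "folds", min = 2L)
  if (min(table(labels)) < folds) {
    abort("Each class must have at least `folds` members.")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  scores <- numeric(length(labels))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- meth_train(m[tr, , drop = FALSE], labels[tr], C = C, seed = seed)
    scores[!tr] <- predict(model, m[!tr, , drop = FALSE], type = "decision")
    per_fold[[f]] <- eval_from_scores(scores[!tr], labels[!tr])
  }
  out <- eval_from_scores(scores, labels)
  out$per_fold <- per_fold
  attr(out, "fold") <- fold
  out
}

#' Feature importance by normalized SVM coefficients
#'
#' For each of `resamples` bootstrap resamples of the training rows, fits
#' the linear SVM and records the normalized absolute primal coefficients
#' `|w_j| / sum_j |w_j|` (which sum to 1 per resample). Reports per-feature
#' mean and standard deviation across resamples and the rank order by mean
#' importance (1 = most important).
#'
#' @param features Feature matrix or tibble.
#' @param labels Binary vector.
#' @param resamples Number of bootstrap resamples (default 30).
#' @param C Soft-margin cost.
#' @param seed Seed for the resampling.
#' @return A tibble `feature`, `mean`, `sd`, `rank`, in the canonical
#'   feature order.
#' @export
feature_importance <- function(features, labels, resamples = 30L, C = 1.0,
                               seed = 1L) {
  m <- as_feature_matrix(features)
  labels <- check_labels(labels, nrow(m))
  resamples <- check_count(resamples, "resamples")
  n <- nrow(m)
  imp <- with_seed(seed, {
    vapply(seq_len(resamples), function(r) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L &&
            min(table(labels[idx])) >= 2L) break
      }
      model <- meth_train(m[idx, , drop = FALSE], labels[idx], C = C)
      w <- abs(model$weights)
      w / sum(w)
    }, numeric(ncol(m)))
  })
  means <- rowMeans(imp)
  tibble(
    feature = colnames(m),
    mean = means,
    sd = apply(imp, 1L, stats::sd),
    rank = rank(-means, ties.method = "first")
  )
}

#' Compare a feature's distribution between classes
#'
#' Two-sample t-test (Welch) of one feature column between methylated and
#' unmethylated samples, plus the per-class variances — used to ask whether
#' e.g. the first sequence-complexity features separate the classes and
#' which class is more variable.
#'
#' @param feature_column Numeric vector of one feature.
#' @param labels Binary vector (1 = methylated).
#' @param var_equal Pool variances (classic two-sample t) instead of Welch.
#' @return A one-row tibble: `t_statistic`, `p_value`, `variance_pos`,
#'   `variance_neg`, `degenerate` (TRUE when both classes are constant, in
#'   which case the p-value is NA).
#' @export
class_distribution_test <- function(feature_column, labels,
                                    var_equal = FALSE) {
  labels <- as.integer(labels)
  x <- feature_column[labels == 1L]
  y <- feature_column[labels == 0L]
  if (length(x) < 2L || length(y) < 2L) {
    abort("Need >= 2 samples per class.")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(tibble(
      t_statistic = NA_real_, p_value = NA_real_,
      variance_pos = vx, variance_neg = vy, degenerate = TRUE
    ))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  tibble(
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    variance_pos = vx,
    variance_neg = vy,
    degenerate = FALSE
  )
}

#' Balanced subsample of a labelled feature table
#'
#' Draws `n_per_class` rows from each class without replacement —
#' the protocol used to build matched training / independent-test sets.
#'
#' @param data Tibble with a `label` column.
#' @param n_per_class Rows to keep per class.
#' @param seed Seed for the draw.
#' @return The subsampled tibble, rows in original order.
#' @export
subsample_balanced <- function(data, n_per_class, seed = 1L) {
  if (!"label" %in% names(data)) abort("`data` needs a `label` column.")
  counts <- table(data$label)
  if (any(counts < n_per_class)) {
    abort(sprintf("Smallest class has %d rows < n_per_class = %d.",
                  min(counts), n_per_class))
  }
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), data$label), function(idx) {
      sample(idx, n_per_class)
    }))
  })
  data[sort(keep), , drop = FALSE]
}
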