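#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained methylation model
#'
#' One row per feature: the raw primal weight, its absolute value, and the
#' normalized absolute coefficient (`|w| / sum |w|`, the single-fit
#' importance score).
#'
#' @param x A `meth_model`.
#' @param ... Unused.
#' @return A tibble `feature`, `weight`, `abs_weight`, `importance`.
#' @export
tidy.meth_model <- function(x, ...) {
  w <- x$weights
  tibble(
    feature = names(w),
    weight = unname(w),
    abs_weight = abs(unname(w)),
    importance = abs(unname(w)) / sum(abs(w))
  )
}

#' @rdname tidy.meth_model
#' @return `glance()`: a one-row tibble `n_features`, `n_train`, `C`,
#'   `bias`, `window_size`, `seed`.
#' @export
glance.meth_model <- function(x, ...) {
  tibble(
    n_features = length(x$weights),
    n_train = x$n_train,
    C = x$C,
    bias = x$bias,
    window_size = x$window_size,
    seed = x$seed
  )
}

eval_row <- function(e) {
  tibble(
    TP = e$TP, TN = e$TN, FP = e$FP, FN = e$FN,
    sens = e$sens, spec = e$spec, acc = e$acc, mcc = e$mcc, auc = e$auc
  )
}

#' Tidy an evaluation report
#'
#' For a cross-validation report, one row per fold; for a plain
#' evaluation, a single row. `glance()` always returns the single pooled
#' row.
#'
#' @param x A `meth_eval`.
#' @param ... Unused.
#' @return A tibble with columns `fold` (tidy only), `TP`, `TN`, `FP`,
#'   `FN`, `sens`, `spec`, `acc`, `mcc`, `auc`.
#' @export
tidy.meth_eval <- function(x, ...) {
  if (is.null(x$per_fold)) {
    return(dplyr::bind_cols(tibble(fold = NA_integer_), eval_row(x)))
  }
  dplyr::bind_rows(lapply(seq_along(x$per_fold), function(f) {
    dplyr::bind_cols(tibble(fold = f), eval_row(x$per_fold[[f]]))
  }))
}

#' @rdname tidy.meth_eval
#' @export
glance.meth_eval <- function(x, ...) {
  eval_row(x)
}
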