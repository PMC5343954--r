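#' Subword complexity function of a DNA sequence
#'
#' Counts, for each length `n = 1..n_max`, the number of distinct subwords
#' (factors) of length `n` occurring in `seq`. Overlapping occurrences of the
#' same subword are collapsed; counting is on the given strand only. The
#' value at `n = 1` is the number of distinct letters present; if
#' `n_max = nchar(seq)` the final value is always 1 (the sequence itself).
#'
#' For a fully repetitive sequence the complexity function is identically 1;
#' for a maximally diverse sequence it grows as `4^n` until the window length
#' caps it at `L - n + 1`.
#'
#' @param seq A single DNA string over A/C/G/T (case-insensitive).
#' @param n_max Largest subword length to evaluate; must not exceed
#'   `nchar(seq)`.
#' @return Integer vector of length `n_max`; element `n` is the number of
#'   distinct length-`n` subwords.
#' @examples
#' complexity_function("CAGATGTACA", 10)
#' complexity_function("AAAA", 4)
#' @export
complexity_function <- function(seq, n_max = nchar(seq)) {
  s <- check_dna(seq)
  L <- nchar(s)
  n_max <- check_count(n_max, "n_max")
  if (n_max > L) {
    abort(sprintf("`n_max` (%d) exceeds sequence length (%d).", n_max, L))
  }
  vapply(seq_len(n_max), function(n) {
    length(unique(substring(s, 1:(L - n + 1L), n:L)))
  }, integer(1))
}

#' Complexity profile of a DNA window
#'
#' Computes the subword complexity function together with its first and
#' second discrete differences and the detected exponentially increasing
#' part (EIP). The second difference attached to point `k` is
#' `p(k+2) - 2 p(k+1) + p(k)`; the EIP is the longest contiguous run of
#' points with non-zero second difference (ties broken towards the earliest
#' run), and its last point (`eip_last`) is the anchor used to place the
#' sequence-complexity features.
#'
#' @param seq A single DNA string over A/C/G/T.
#' @param n_max Largest subword length to evaluate (default: full length,
#'   capped at 64 — the informative part of the curve for windows up to a
#'   kilobase lies well below that).
#' @return An object of class `complexity_profile`: a list with elements
#'   `sequence_length`, `p`, `d1`, `d2`, `eip_first`, `eip_last`,
#'   `degenerate`.
#' @seealso [complexity_function()], [detect_eip()], [sc_features()]
#' @export
complexity_profile <- function(seq, n_max = min(nchar(seq), 64L)) {
  s <- check_dna(seq)
  p <- complexity_function(s, n_max)
  prof <- structure(
    list(
      sequence_length = nchar(s),
      p = p,
      d1 = if (length(p) >= 2L) diff(p) else integer(0),
      d2 = if (length(p) >= 3L) diff(p, differences = 2L) else integer(0),
      eip_first = NA_integer_,
      eip_last = NA_integer_,
      degenerate = FALSE
    ),
    class = "complexity_profile"
  )
  if (length(prof$d2) >= 1L) {
    eip <- detect_eip(prof)
    prof$eip_first <- eip[["eip_first"]]
    prof$eip_last <- eip[["eip_last"]]
    prof$degenerate <- attr(eip, "degenerate")
  }
  prof
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat(sprintf(
    "<complexity_profile> L = %d, n_max = %d\n", x$sequence_length, length(x$p)
  ))
  cat("  p:", paste(utils::head(x$p, 12L), collapse = " "),
      if (length(x$p) > 12L) "..." else "", "\n")
  if (x$degenerate) {
    cat("  EIP: degenerate (all second differences zero)\n")
  } else {
    cat(sprintf("  EIP: points %d..%d\n", x$eip_first, x$eip_last))
  }
  invisible(x)
}

#' Detect the exponentially increasing part of a complexity profile
#'
#' Applies two discrete difference operations to the complexity function and
#' returns the maximal-length contiguous run of point indices with non-zero
#' second difference. Within that run the complexity function is still
#' curving, i.e. growing (or saturating) non-linearly — the exponentially
#' increasing part. Ties between equally long runs go to the earliest run.
#'
#' @param profile A `complexity_profile` with at least one second-difference
#'   entry (`n_max >= 3`).
#' @return Named integer vector `c(eip_first, eip_last)` in complexity-point
#'   indices, with attribute `degenerate` set to `TRUE` when every second
#'   difference is zero (e.g. a homopolymer), in which case `(1, 1)` is
#'   returned.
#' @export
detect_eip <- function(profile) {
  if (!inherits(profile, "complexity_profile")) {
    abort("`profile` must be a complexity_profile.")
  }
  d2 <- profile$d2
  if (length(d2) < 1L) {
    abort("detect_eip() needs a profile computed to n_max >= 3.")
  }
  nz <- d2 != 0L
  if (!any(nz)) {
    return(structure(
      c(eip_first = 1L, eip_last = 1L), degenerate = TRUE
    ))
  }
  r <- rle(nz)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]  # which.max -> earliest on ties
  structure(
    c(eip_first = starts[best], eip_last = ends[best]),
    degenerate = FALSE
  )
}

#' Entropy point of a window size
#'
#' The entropy point `n0` of a window of length `L` is the unique integer
#' satisfying `4^n0 + n0 - 1 < L <= 4^(n0+1) + (n0+1) - 1`: the largest
#' subword length at which a sequence of length `L` could still display all
#' `4^n0` subwords, so the natural point at which to read off a finite-length
#' estimate of topological entropy.
#'
#' @param window_size Window length in bases (>= 2).
#' @return The entropy point, a non-negative integer.
#' @examples
#' entropy_point(100) # 3
#' entropy_point(500) # 4
#' @export
entropy_point <- function(window_size) {
  L <- check_count(window_size, "window_size", min = 2L)
  n0 <- 0L
  while (4^(n0 + 1) + (n0 + 1) - 1 < L) {
    n0 <- n0 + 1L
  }
  # now L <= 4^(n0+1) + n0; the lower bound holds by construction
  stopifnot(4^n0 + n0 - 1 < L)
  n0
}

#' Topological entropy estimate of a finite DNA window
#'
#' Topological entropy is the asymptotic exponential growth rate of the
#' subword complexity function, normalized by base-4 logarithms so that a
#' maximally diverse DNA sequence has entropy 1 and a homopolymer entropy 0.
#' Two finite-sequence estimators are provided: `"koslicki"` evaluates
#' `log4 p(n0) / n0` at the entropy point `n0` alone; `"jin"` averages
#' `log4 p(i) / i` over the `k` points ending at `n0` (i.e.
#' `i = n0 - k + 1, ..., n0`), using the points immediately preceding the
#' entropy point as additional evidence.
#'
#' @param profile A `complexity_profile` computed at least to the entropy
#'   point of its window size.
#' @param estimator `"koslicki"` or `"jin"`.
#' @param k Number of points averaged by the `"jin"` estimator (default 3).
#' @return A single number in `[0, 1]`.
#' @export
topological_entropy <- function(profile, estimator = c("koslicki", "jin"),
                                k = 3L) {
  if (!inherits(profile, "complexity_profile")) {
    abort("`profile` must be a complexity_profile.")
  }
  estimator <- match.arg(estimator)
  n0 <- entropy_point(profile$sequence_length)
  if (n0 < 1L) {
    abort("Window too short: entropy point is 0.")
  }
  if (estimator == "koslicki") {
    if (length(profile$p) < n0) {
      abort(sprintf("Profile must be computed to n0 = %d.", n0))
    }
    return(log(profile$p[n0], base = 4) / n0)
  }
  k <- check_count(k, "k")
  idx <- (n0 - k + 1L):n0
  if (idx[1] < 1L) {
    abort(sprintf(
      "Invalid parameter: jin estimator needs n0 >= k (n0 = %d, k = %d).",
      n0, k
    ))
  }
  if (length(profile$p) < n0) {
    abort(sprintf("Profile must be computed to n0 = %d.", n0))
  }
  mean(log(profile$p[idx], base = 4) / idx)
}

# window size -> 7 complexity-point indices used as SC features
SC_FEATURE_TABLE <- list(
  `100` = 1:7, `200` = 2:8, `300` = 2:8, `400` = 3:9, `500` = 4:10,
  `600` = 4:10, `700` = 4:10, `800` = 4:10, `900` = 5:11
)

#' Specify which complexity points become SC features
#'
#' The 7 sequence-complexity (SC) features of a window are the values of the
#' subword complexity function at 7 consecutive points covering its
#' exponentially increasing part. In `"fixed-table"` mode the interval is
#' looked up from the built-in calibration covering window sizes 100–900 bp
#' (e.g. points 1–7 at 100 bp, points 4–10 at 600 bp). In `"dynamic"` mode
#' the interval is recalibrated from a corpus of windows: the last EIP point
#' is recorded for each corpus window and the interval is the 7 points ending
#' at the median (median ties round down).
#'
#' @param window_size Window length in bases.
#' @param mode `"fixed-table"` or `"dynamic"`.
#' @param corpus In dynamic mode, a character vector of calibration DNA
#'   windows of length `window_size` (typically ~100 windows).
#' @return An object of class `sc_spec`: list with `window_size`, `n0`,
#'   `feature_indices` (7 consecutive integers), `mode`.
#' @examples
#' sc_spec(600)$feature_indices # 4:10
#' @export
sc_spec <- function(window_size, mode = c("fixed-table", "dynamic"),
                    corpus = NULL) {
  window_size <- check_count(window_size, "window_size", min = 2L)
  mode <- match.arg(mode)
  if (mode == "fixed-table") {
    key <- as.character(window_size)
    if (!key %in% names(SC_FEATURE_TABLE)) {
      abort(sprintf(
        paste0(
          "Unsupported window size %d for fixed-table mode (supported: %s); ",
          "use mode = \"dynamic\" with a calibration corpus."
        ),
        window_size, paste(names(SC_FEATURE_TABLE), collapse = ", ")
      ))
    }
    idx <- SC_FEATURE_TABLE[[key]]
  } else {
    if (is.null(corpus) || length(corpus) < 1L) {
      abort("Dynamic mode needs a non-empty calibration `corpus`.")
    }
    lens <- nchar(corpus)
    if (any(lens != window_size)) {
      abort("All calibration windows must have length `window_size`.")
    }
    lp <- vapply(corpus, function(s) {
      complexity_profile(s)$eip_last
    }, integer(1), USE.NAMES = FALSE)
    m <- floor(stats::median(lp))
    if (m < 7L) m <- 7L  # interval must start at point >= 1
    idx <- (m - 6L):m
  }
  structure(
    list(
      window_size = window_size,
      n0 = entropy_point(window_size),
      feature_indices = as.integer(idx),
      mode = mode
    ),
    class = "sc_spec"
  )
}

#' @export
print.sc_spec <- function(x, ...) {
  cat(sprintf(
    "<sc_spec> window %d bp, n0 = %d, SC points %d..%d (%s)\n",
    x$window_size, x$n0, min(x$feature_indices), max(x$feature_indices),
    x$mode
  ))
  invisible(x)
}

#' Sequence-complexity features of one window
#'
#' Reads the subword complexity function of `seq` at the 7 points given by
#' `spec$feature_indices` (SC-1 ... SC-7).
#'
#' @param seq DNA string whose length equals `spec$window_size`.
#' @param spec An [sc_spec()].
#' @return Named integer vector of length 7 (`SC1`..`SC7`).
#' @export
sc_features <- function(seq, spec) {
  if (!inherits(spec, "sc_spec")) abort("`spec` must be an sc_spec.")
  s <- check_dna(seq)
  if (nchar(s) != spec$window_size) {
    abort(sprintf(
      "Sequence length (%d) does not match spec window size (%d).",
      nchar(s), spec$window_size
    ))
  }
  idx <- spec$feature_indices
  p <- complexity_function(s, max(idx))
  stats::setNames(p[idx], paste0("SC", 1:7))
}

#' Complexity summary table for a set of sequences
#'
#' Tidy per-sequence summary of the complexity machinery: entropy point,
#' EIP bounds, both topological entropy estimates, and the complexity
#' function values up to `n_max`.
#'
#' @param seqs Character vector of DNA strings (optionally named), or a
#'   data frame with columns `id` and `sequence`.
#' @param n_max Largest subword length profiled (default
#'   `min(L, max SC index + 4)` per sequence, capped at 64).
#' @param k Points averaged by the jin estimator.
#' @return A tibble with one row per sequence: `id`, `length`, `n0`,
#'   `eip_first`, `eip_last`, `degenerate`, `h_koslicki`, `h_jin`, and a
#'   list-column `p` holding the complexity function.
#' @export
complexity_table <- function(seqs, n_max = NULL, k = 3L) {
  if (is.data.frame(seqs)) {
    ids <- as.character(seqs$id)
    seqs <- as.character(seqs$sequence)
  } else {
    ids <- if (!is.null(names(seqs))) names(seqs) else
      paste0("seq", seq_along(seqs))
    seqs <- as.character(seqs)
  }
  rows <- purrr::map2(seqs, ids, function(s, id) {
    nm <- if (is.null(n_max)) min(nchar(s), 64L) else n_max
    prof <- complexity_profile(s, n_max = nm)
    n0 <- entropy_point(nchar(s))
    hk <- if (n0 >= 1L) topological_entropy(prof, "koslicki") else NA_real_
    hj <- if (n0 >= k) topological_entropy(prof, "jin", k = k) else NA_real_
    tibble(
      id = id, length = nchar(s), n0 = n0,
      eip_first = prof$eip_first, eip_last = prof$eip_last,
      degenerate = prof$degenerate,
      h_koslicki = hk, h_jin = hj,
      p = list(prof$p)
    )
  })
  dplyr::bind_rows(rows)
}
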