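# Independent oracles, written before the implementations they check and
# deliberately kept on different code paths (explicit loops, hash sets,
# O(n^2) enumeration).

# Brute-force subword complexity: collect every substring of each length
# into a hash-set environment, one substring at a time.
oracle_complexity <- function(seq, n_max) {
  L <- nchar(seq)
  out <- integer(n_max)
  for (n in seq_len(n_max)) {
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(L - n + 1L)) {
      assign(substr(seq, i, i + n - 1L), TRUE, envir = seen)
    }
    out[n] <- length(ls(seen))
  }
  out
}

# Exhaustive scan over all contiguous runs of non-zero second differences;
# returns c(first, last) of the longest (earliest on ties) run.
oracle_eip <- function(p) {
  d2 <- integer(length(p) - 2L)
  for (k in seq_along(d2)) {
    d2[k] <- p[k + 2L] - 2L * p[k + 1L] + p[k]
  }
  best <- c(1L, 1L)
  best_len <- 0L
  for (a in seq_along(d2)) {
    for (b in a:length(d2)) {
      if (all(d2[a:b] != 0L) && (b - a + 1L) > best_len) {
        best <- c(a, b)
        best_len <- b - a + 1L
      }
    }
  }
  if (best_len == 0L) NULL else best
}

# O(n^2) pairwise concordance AUC: ties count 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Welch two-sample t statistic from first principles.
oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
}

# Wilcoxon rank-sum statistic W (number of (x, y) pairs with x > y,
# ties 1/2) -- the statistic wilcox.test() reports for x vs y.
oracle_rank_sum_W <- function(x, y) {
  w <- 0
  for (a in x) {
    for (b in y) {
      w <- w + (a > b) + 0.5 * (a == b)
    }
  }
  w
}

# All-pairs greedy clustering in input order with no prescreen: a window
# joins the first earlier representative with identity >= threshold.
oracle_greedy_cluster <- function(seqs, threshold) {
  L <- nchar(seqs[1])
  reps <- integer(0)
  for (i in seq_along(seqs)) {
    dup <- FALSE
    for (j in reps) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      if (sum(a == b) / L >= threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) reps <- c(reps, i)
  }
  reps
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Order-3 de Bruijn-like sequence over ACGT via the prefer-largest greedy
# construction: contains every 3-mer exactly once (verified at build time),
# so p(1) = 4, p(2) = 16, p(3) = 64.
debruijn3 <- function() {
  k <- 3L
  s <- c("A", "A", "A")
  seen <- new.env(parent = emptyenv())
  assign("AAA", TRUE, envir = seen)
  while (length(s) < 4^k + k - 1L) {
    added <- FALSE
    for (b in c("T", "G", "C", "A")) {
      cand <- paste0(paste(utils::tail(s, k - 1L), collapse = ""), b)
      if (!exists(cand, envir = seen)) {
        assign(cand, TRUE, envir = seen)
        s <- c(s, b)
        added <- TRUE
        break
      }
    }
    if (!added) stop("de Bruijn construction stalled")
  }
  out <- paste(s, collapse = "")
  stopifnot(length(ls(seen)) == 64L)
  out
}
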