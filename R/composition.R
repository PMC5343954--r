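# 64 trinucleotides in lexicographic order AAA, AAC, ..., TTT
TRINUCLEOTIDES <- {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b3 = b, b2 = b, b1 = b)[, 3:1], 1L, paste0, collapse = "")
}

#' Feature names of the 72-dimensional window encoding
#'
#' Ordered labels: the 64 trinucleotides `AAA`..`TTT`, then `GC`, then
#' `SC1`..`SC7`. This ordering is fixed, serialized with every trained
#' model, and shared by every feature matrix the package produces.
#'
#' @return Character vector of length 72.
#' @export
feature_names <- function() {
  c(TRINUCLEOTIDES, "GC", paste0("SC", 1:7))
}

#' Overlapping trinucleotide frequencies
#'
#' Counts the `L - 2` overlapping trinucleotides of `seq` on the given
#' strand and normalizes each count by `L - 2`, returning the 64 frequencies
#' in lexicographic order. Frequencies sum to 1 for any pure-ACGT input.
#'
#' @param seq DNA string, length >= 3, pure A/C/G/T.
#' @return Named numeric vector of length 64.
#' @examples
#' trinucleotide_frequency("AAAA")["AAA"] # 1
#' @export
trinucleotide_frequency <- function(seq) {
  s <- check_dna(seq)
  L <- nchar(s)
  if (L < 3L) abort("`seq` must have at least 3 bases.")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(s), width = 3L
  )
  counts[TRINUCLEOTIDES] / (L - 2L)
}

#' GC content
#'
#' Fraction of G and C bases in the window: `(G + C) / L`.
#'
#' @param seq DNA string, length >= 1.
#' @return A number in `[0, 1]`.
#' @examples
#' gc_content("CAGATGTACA") # 0.4
#' @export
gc_content <- function(seq) {
  s <- check_dna(seq)
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAString(s), letters = c("G", "C")
  )
  sum(counts) / nchar(s)
}

#' Encode one window as a 72-dimensional feature vector
#'
#' Concatenates, in fixed order, 64 trinucleotide frequencies, GC content,
#' and the 7 sequence-complexity features given by `sc_spec`. Features are
#' computed on the plus strand as given; the encoding is deliberately not
#' reverse-complement symmetric.
#'
#' @param seq DNA string of length `sc_spec$window_size`, pure A/C/G/T.
#' @param sc_spec An [sc_spec()] matching the window size.
#' @return Named numeric vector of length 72 (names from
#'   [feature_names()]).
#' @export
encode_window <- function(seq, sc_spec) {
  if (!inherits(sc_spec, "sc_spec")) abort("`sc_spec` must be an sc_spec.")
  s <- check_dna(seq)
  v <- c(
    trinucleotide_frequency(s),
    GC = gc_content(s),
    sc_features(s, sc_spec)
  )
  stats::setNames(as.numeric(v), feature_names())
}

#' Encode a set of windows as a feature tibble
#'
#' Tidy, many-window version of [encode_window()]: takes a data frame of
#' labelled windows (as produced by [extract_windows()]) or a plain
#' character vector of sequences, and returns one row per window with the
#' 72 feature columns. Non-sequence columns of the input (`chrom`,
#' `center_position`, `label`, ...) are carried through in front of the
#' features.
#'
#' @param windows Data frame with a `sequence` column, or a character
#'   vector of equal-length DNA strings.
#' @param sc_spec An [sc_spec()]; defaults to the fixed-table spec for the
#'   (common) window length.
#' @return A tibble with the input metadata columns followed by the 72
#'   feature columns.
#' @export
encode_windows <- function(windows, sc_spec = NULL) {
  if (is.data.frame(windows)) {
    meta <- dplyr::select(as_tibble(windows), -"sequence")
    seqs <- as.character(windows$sequence)
  } else {
    meta <- NULL
    seqs <- as.character(windows)
  }
  if (length(seqs) == 0L) abort("No windows to encode.")
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) abort("All windows must have the same length.")
  if (is.null(sc_spec)) sc_spec <- sc_spec(lens)
  mat <- t(vapply(seqs, encode_window, numeric(72L),
                  sc_spec = sc_spec, USE.NAMES = FALSE))
  colnames(mat) <- feature_names()
  feats <- as_tibble(mat)
  if (is.null(meta)) feats else dplyr::bind_cols(meta, feats)
}
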