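#' Read a ChromHMM-style region annotation
#'
#' BED with at least 4 columns: chrom, start, end (0-based half-open) and
#' a state label in column 4.
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`, `state_label`.
#' @export
read_regions <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_guess()),
    comment = "#", progress = FALSE
  )
  if (ncol(x) < 4L) abort("Region BED needs >= 4 columns (label in col 4).")
  tibble(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    state_label = as.character(x[[4]])
  )
}

# 0-based positions of CpG cytosines in one chromosome string.
cpg_positions <- function(chr_seq) {
  m <- Biostrings::matchPattern("CG", Biostrings::DNAString(chr_seq))
  Biostrings::start(m) - 1L
}

#' Region-level methylation profiles: assayed vs predicted
#'
#' For each annotated region, enumerates all CpG dinucleotides in the
#' reference. CpGs carrying a methylation call are "assayed" and contribute
#' their mean beta (averaged over stages when a site has several calls);
#' the rest are "unassayed" and contribute the model's binary prediction
#' for their window. Regions with fewer than `min_assayed` assayed or
#' `min_unassayed` unassayed CpGs are dropped, as are regions where no
#' unassayed CpG has a valid window.
#'
#' @param regions Tibble from [read_regions()] (or with the same columns).
#' @param calls Methylation call tibble (any number of stages).
#' @param genome Named character vector / `DNAStringSet` / FASTA path.
#' @param model A trained `meth_model` (its window size, via `sc_spec`,
#'   decides the windows extracted around unassayed CpGs).
#' @param window_size Window length for prediction; defaults to the
#'   model's recorded window size.
#' @param min_assayed,min_unassayed Minimum CpG counts for a region to be
#'   profiled (default 10, applied as >=).
#' @return Tibble: `chrom`, `start`, `end`, `state_label`,
#'   `n_assayed`, `n_unassayed`, `assayed_mean`, `predicted_mean`. The
#'   number of regions dropped by the count filters and for lack of valid
#'   windows is attached as attributes `n_dropped_counts`,
#'   `n_dropped_windows`.
#' @export
profile_regions <- function(regions, calls, genome, model,
                            window_size = NULL,
                            min_assayed = 10L, min_unassayed = 10L) {
  genome <- as_genome(genome)
  if (is.null(window_size)) {
    window_size <- model$window_size
    if (is.null(window_size) || is.na(window_size)) {
      abort("Model has no recorded window size; pass `window_size`.")
    }
  }
  sp <- model$sc_spec
  if (is.null(sp) || sp$window_size != window_size) {
    sp <- sc_spec(window_size)
  }

  call_means <- calls |>
    dplyr::group_by(.data$chrom, .data$position) |>
    dplyr::summarise(beta = mean(.data$beta), .groups = "drop")

  cpg_by_chrom <- lapply(genome, cpg_positions)

  n_drop_counts <- 0L
  n_drop_windows <- 0L
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    pos_all <- cpg_by_chrom[[chrom]]
    if (is.null(pos_all)) next
    pos <- pos_all[pos_all >= regions$start[i] & pos_all < regions$end[i]]
    cm <- call_means[call_means$chrom == chrom &
                       call_means$position %in% pos, ]
    assayed <- cm$position
    unassayed <- setdiff(pos, assayed)
    if (length(assayed) < min_assayed || length(unassayed) < min_unassayed) {
      n_drop_counts <- n_drop_counts + 1L
      next
    }
    wins <- extract_windows(
      tibble(chrom = chrom, position = unassayed, label = NA_integer_),
      genome, window_size
    )
    if (nrow(wins) == 0L) {
      n_drop_windows <- n_drop_windows + 1L
      next
    }
    feats <- encode_windows(wins, sc_spec = sp)
    pred <- predict(model, feats, type = "class")
    rows[[i]] <- tibble(
      chrom = chrom, start = regions$start[i], end = regions$end[i],
      state_label = regions$state_label[i],
      n_assayed = length(assayed), n_unassayed = length(unassayed),
      assayed_mean = mean(cm$beta), predicted_mean = mean(pred)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      chrom = character(), start = integer(), end = integer(),
      state_label = character(), n_assayed = integer(),
      n_unassayed = integer(), assayed_mean = numeric(),
      predicted_mean = numeric()
    )
  }
  attr(out, "n_dropped_counts") <- n_drop_counts
  attr(out, "n_dropped_windows") <- n_drop_windows
  out
}

#' Per-state consistency between assayed and predicted profiles
#'
#' For each state label, runs an unpaired two-sample Wilcoxon rank-sum
#' test between the regions' assayed means and predicted means. A state is
#' "consistent" when the two distributions are not significantly different
#' (`p > alpha`). States with fewer than `flag_below` regions are flagged
#' (`small_n`), mirroring the practice of excluding sparsely populated
#' states from formal testing; states where both distributions are
#' constant and identical are flagged `degenerate` with p = 1.
#'
#' @param profiles Tibble from [profile_regions()].
#' @param alpha Significance level (default 0.01).
#' @param flag_below Region count under which a state is flagged
#'   (default 1000).
#' @return Tibble: `state_label`, `n_regions`, `p_value`, `consistent`,
#'   `small_n`, `degenerate`.
#' @export
consistency_test <- function(profiles, alpha = 0.01, flag_below = 1000L) {
  if (nrow(profiles) == 0L) {
    abort("No region profiles to test.")
  }
  profiles |>
    dplyr::group_by(.data$state_label) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < 2L) {
        return(tibble(
          n_regions = n, p_value = NA_real_, consistent = NA,
          small_n = TRUE, degenerate = TRUE
        ))
      }
      a <- d$assayed_mean
      p <- d$predicted_mean
      if (stats::sd(a) == 0 && stats::sd(p) == 0 && a[1] == p[1]) {
        return(tibble(
          n_regions = n, p_value = 1, consistent = TRUE,
          small_n = n < flag_below, degenerate = TRUE
        ))
      }
      wt <- suppressWarnings(stats::wilcox.test(a, p, exact = FALSE))
      tibble(
        n_regions = n, p_value = wt$p.value,
        consistent = wt$p.value > alpha,
        small_n = n < flag_below, degenerate = FALSE
      )
    }) |>
    dplyr::ungroup()
}
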