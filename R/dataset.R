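#' Read site-level methylation calls
#'
#' Parses tab-separated methylation call files into a validated tibble.
#' Two dialects are supported:
#' \describe{
#'   \item{`bedgraph`}{columns `chrom, start, end, beta[, coverage]`, with
#'     `beta` already in `[0, 1]` and `start` the 0-based coordinate of the
#'     CpG cytosine.}
#'   \item{`encode_rrbs`}{BED9+ with read count in column 10 and percent
#'     methylation in column 11, rescaled to `[0, 1]`.}
#' }
#' Malformed lines (wrong column count, non-numeric coordinates or beta,
#' beta outside range) are skipped and counted; if more than 1\% of data
#' lines are malformed the read fails.
#'
#' @param path File path.
#' @param dialect `"bedgraph"` or `"encode_rrbs"`.
#' @param stage Optional stage label attached to every call (defaults to
#'   the file name without extension).
#' @return A tibble with columns `chrom`, `position` (0-based cytosine
#'   coordinate), `beta`, `coverage`, `stage`. The number of skipped lines
#'   is attached as attribute `n_malformed`.
#' @export
read_methylation <- function(path, dialect = c("bedgraph", "encode_rrbs"),
                             stage = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(stage)) {
    stage <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  min_cols <- if (dialect == "bedgraph") 4L else 11L
  parse_one <- function(f) {
    if (length(f) < min_cols) return(NULL)
    start <- suppressWarnings(as.integer(f[[2]]))
    if (is.na(start) || start < 0L) return(NULL)
    if (dialect == "bedgraph") {
      beta <- suppressWarnings(as.numeric(f[[4]]))
      cov <- if (length(f) >= 5L) suppressWarnings(as.integer(f[[5]])) else 0L
    } else {
      beta <- suppressWarnings(as.numeric(f[[11]])) / 100
      cov <- suppressWarnings(as.integer(f[[10]]))
    }
    if (is.na(beta) || beta < 0 || beta > 1) return(NULL)
    if (is.na(cov) || cov < 0L) cov <- 0L
    list(chrom = f[[1]], position = start, beta = beta, coverage = cov)
  }
  parsed <- lapply(fields, parse_one)
  bad <- vapply(parsed, is.null, logical(1))
  if (length(bad) > 0L && sum(bad) / length(bad) > 0.01) {
    abort(sprintf(
      "%d of %d lines malformed (> 1%%) in %s; first bad line: %d",
      sum(bad), length(bad), path, which(bad)[1]
    ))
  }
  if (any(bad)) {
    warn(sprintf("Skipped %d malformed line(s) in %s (lines %s).",
                 sum(bad), path,
                 paste(utils::head(which(bad), 5L), collapse = ", ")))
  }
  ok <- parsed[!bad]
  out <- tibble(
    chrom = vapply(ok, `[[`, character(1), "chrom"),
    position = vapply(ok, `[[`, integer(1), "position"),
    beta = vapply(ok, `[[`, numeric(1), "beta"),
    coverage = vapply(ok, `[[`, integer(1), "coverage"),
    stage = stage
  )
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Write methylation calls as bedGraph-style TSV
#'
#' @param calls Tibble with `chrom`, `position`, `beta`, `coverage`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(calls, path) {
  readr::write_tsv(
    tibble(
      chrom = calls$chrom, start = calls$position,
      end = calls$position + 1L, beta = calls$beta,
      coverage = calls$coverage
    ),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Label CpG sites by beta thresholds across stages
#'
#' A site is labelled methylated (1) if it is observed in *every* stage
#' with `beta >= pos_threshold` in every stage, and unmethylated (0) if it
#' is observed in every stage with `beta <= neg_threshold` in every stage.
#' Sites missing from any stage, or with any intermediate beta, are dropped
#' (strict intersection semantics).
#'
#' @param stages A list of call tibbles (one per stage, as returned by
#'   [read_methylation()]), or a single long tibble with a `stage` column.
#' @param pos_threshold Minimum beta for the methylated class (default 0.7).
#' @param neg_threshold Maximum beta for the unmethylated class
#'   (default 0.01).
#' @return A tibble `chrom`, `position`, `label` (integer 0/1), sorted by
#'   position within chromosome.
#' @export
label_sites <- function(stages, pos_threshold = 0.7, neg_threshold = 0.01) {
  if (neg_threshold >= pos_threshold) {
    abort("`neg_threshold` must be smaller than `pos_threshold`.")
  }
  calls <- if (is.data.frame(stages)) as_tibble(stages)
           else dplyr::bind_rows(stages)
  if (nrow(calls) == 0L) {
    warn("No calls supplied; returning empty labelling.")
    return(tibble(chrom = character(), position = integer(),
                  label = integer()))
  }
  n_stages <- dplyr::n_distinct(calls$stage)
  out <- calls |>
    dplyr::group_by(.data$chrom, .data$position) |>
    dplyr::summarise(
      n_stage = dplyr::n_distinct(.data$stage),
      all_pos = all(.data$beta >= pos_threshold),
      all_neg = all(.data$beta <= neg_threshold),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_stage == n_stages,
                  .data$all_pos | .data$all_neg) |>
    dplyr::mutate(label = as.integer(.data$all_pos)) |>
    dplyr::select("chrom", "position", "label") |>
    dplyr::arrange(.data$chrom, .data$position)
  if (nrow(out) == 0L) {
    warn("Intersection labelling produced no sites.")
  }
  out
}

#' Extract fixed-size windows centred on labelled CpG sites
#'
#' For each labelled site, extracts a `window_size`-base window from the
#' reference so the CpG dinucleotide straddles the centre: with even `L`
#' the window is the 0-based half-open interval
#' `[c - (L/2 - 1), c + L/2 + 1)` where `c` is the cytosine coordinate
#' (C at offset `L/2 - 1`, G at `L/2`); with odd `L` the cytosine sits at
#' offset `(L - 1) / 2`. Windows running off a chromosome end, containing
#' any `N`, or whose centre is not `CG` in the reference (call/reference
#' mismatch) are skipped; skip counts are attached as attributes.
#'
#' @param sites Tibble with `chrom`, `position`, `label` (from
#'   [label_sites()]).
#' @param genome A named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param window_size Window length in bases (the reference analysis used
#'   100–1000 bp; 600 bp is the recommended default elsewhere in the
#'   package).
#' @return A tibble `chrom`, `center_position`, `label`, `sequence`, with
#'   attributes `n_out_of_bounds`, `n_with_n`, `n_not_cpg`.
#' @export
extract_windows <- function(sites, genome, window_size = 600L) {
  window_size <- check_count(window_size, "window_size", min = 4L)
  genome <- as_genome(genome)
  L <- window_size
  c_off <- if (L %% 2L == 0L) L %/% 2L - 1L else (L - 1L) %/% 2L

  res <- vector("list", nrow(sites))
  n_oob <- 0L; n_withn <- 0L; n_notcpg <- 0L
  chrom_seqs <- lapply(genome, identity)
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    pos <- sites$position[i]
    chr_seq <- chrom_seqs[[chrom]]
    if (is.null(chr_seq)) {
      n_oob <- n_oob + 1L
      next
    }
    start0 <- pos - c_off               # 0-based window start
    end0 <- start0 + L                  # half-open end
    if (start0 < 0L || end0 > nchar(chr_seq)) {
      n_oob <- n_oob + 1L
      next
    }
    s <- substr(chr_seq, start0 + 1L, end0)  # to 1-based inclusive
    if (substr(s, c_off + 1L, c_off + 2L) != "CG") {
      n_notcpg <- n_notcpg + 1L
      next
    }
    if (grepl("N", s, fixed = TRUE)) {
      n_withn <- n_withn + 1L
      next
    }
    res[[i]] <- tibble(
      chrom = chrom, center_position = pos,
      label = sites$label[i], sequence = s
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(chrom = character(), center_position = integer(),
                  label = integer(), sequence = character())
  }
  attr(out, "n_out_of_bounds") <- n_oob
  attr(out, "n_with_n") <- n_withn
  attr(out, "n_not_cpg") <- n_notcpg
  out
}

# Normalize genome input to a named character vector (uppercased).
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(stats::setNames(toupper(as.character(genome)), names(genome)))
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    # FASTA headers may carry descriptions; keep the first token
    nm <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
    return(stats::setNames(toupper(as.character(x)), nm))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  abort("`genome` must be a named character vector, DNAStringSet, or FASTA path.")
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' Greedy incremental clustering in input order, mimicking CD-HIT-EST:
#' each window is compared to the representatives accepted so far and
#' discarded if its ungapped, same-position identity (matching positions /
#' window length) with any representative reaches `identity_threshold`;
#' otherwise it becomes a new representative. A shared-8-mer prescreen
#' limits full comparisons to candidate pairs that share at least one
#' 8-mer. Positive and negative windows should be processed separately
#' (pass each label subset in turn), as redundancy is defined within a
#' subset; when `windows` contains a `label` column this is done
#' automatically.
#'
#' @param windows Tibble with `sequence` (and optionally `label`) columns,
#'   or a character vector of equal-length sequences.
#' @param identity_threshold Identity at or above which a window is folded
#'   into an existing cluster (default 0.8).
#' @param cdhit_path Optional path to an external `cd-hit-est` binary; when
#'   supplied, clustering is delegated to it for full CD-HIT fidelity.
#' @return The retained representative windows, same type as the input.
#' @export
reduce_redundancy <- function(windows, identity_threshold = 0.8,
                              cdhit_path = NULL) {
  is_df <- is.data.frame(windows)
  seqs <- if (is_df) as.character(windows$sequence) else as.character(windows)
  if (length(seqs) == 0L) return(windows)
  if (length(unique(nchar(seqs))) != 1L) {
    abort("All windows must have the same length.")
  }
  if (is_df && "label" %in% names(windows) &&
      dplyr::n_distinct(windows$label) > 1L) {
    parts <- split(seq_len(nrow(windows)), windows$label)
    keep <- sort(unlist(lapply(parts, function(idx) {
      sub <- windows[idx, , drop = FALSE]
      idx[attr(reduce_redundancy(sub, identity_threshold, cdhit_path),
               "kept_index")]
    })))
    out <- windows[keep, , drop = FALSE]
    attr(out, "kept_index") <- keep
    return(out)
  }
  keep <- if (!is.null(cdhit_path)) {
    cdhit_cluster(seqs, identity_threshold, cdhit_path)
  } else {
    greedy_cluster(seqs, identity_threshold)
  }
  out <- if (is_df) windows[keep, , drop = FALSE] else windows[keep]
  attr(out, "kept_index") <- keep
  out
}

# Greedy representative selection with 8-mer prescreen.
# Returns indices (input order) of retained representatives.
greedy_cluster <- function(seqs, threshold) {
  L <- nchar(seqs[1])
  raws <- lapply(seqs, charToRaw)
  kmer_index <- new.env(parent = emptyenv())  # 8-mer -> rep indices
  reps <- integer(0)
  kmers_of <- function(s) {
    if (L < 8L) return(s)
    unique(substring(s, 1:(L - 7L), 8:L))
  }
  for (i in seq_along(seqs)) {
    km <- kmers_of(seqs[i])
    cand <- unique(unlist(lapply(km, function(k) {
      kmer_index[[k]]
    })))
    dup <- FALSE
    for (j in cand) {
      ident <- sum(raws[[i]] == raws[[j]]) / L
      if (ident >= threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      reps <- c(reps, i)
      for (k in km) {
        kmer_index[[k]] <- c(kmer_index[[k]], i)
      }
    }
  }
  reps
}

# Shell out to an external cd-hit-est binary; returns retained indices.
cdhit_cluster <- function(seqs, threshold, cdhit_path) {
  if (!nzchar(Sys.which(cdhit_path)) && !file.exists(cdhit_path)) {
    abort(sprintf("cd-hit-est binary not found: %s", cdhit_path))
  }
  tmp_in <- tempfile(fileext = ".fa")
  tmp_out <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tmp_in, tmp_out, paste0(tmp_out, ".clstr"))))
  writeLines(paste0(">", seq_along(seqs), "\n", seqs), tmp_in)
  status <- system2(cdhit_path,
                    c("-i", tmp_in, "-o", tmp_out, "-c", threshold, "-n", "5"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) abort("cd-hit-est failed.")
  kept <- Biostrings::readDNAStringSet(tmp_out)
  sort(as.integer(names(kept)))
}

#' Write labelled windows as FASTA plus manifest
#'
#' Record ids are `chrom:center_position:label`; the manifest TSV carries
#' the same columns as the window tibble minus the sequence.
#'
#' @param windows Tibble from [extract_windows()].
#' @param fasta_path Output FASTA path.
#' @param manifest_path Optional TSV manifest path.
#' @return `fasta_path`, invisibly.
#' @export
write_windows <- function(windows, fasta_path, manifest_path = NULL) {
  ids <- sprintf("%s:%d:%d", windows$chrom, windows$center_position,
                 windows$label)
  x <- Biostrings::DNAStringSet(windows$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(manifest_path)) {
    readr::write_tsv(dplyr::select(windows, -"sequence"), manifest_path)
  }
  invisible(fasta_path)
}
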