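#' Specification for a synthetic genome and methylome
#'
#' Describes the planted structure the simulator generates: a single
#' synthetic chromosome alternating GC-rich, CpG-dense "island" tracts
#' (stably unmethylated across stages, like CpG islands near promoters)
#' with AT-richer "background" tracts (stably methylated, like bulk
#' genome). Per-stage beta values are clipped-Normal draws around the
#' class mean, so intersection labelling across stages recovers the truth
#' table up to noise. Optionally a fraction of tracts in one class is
#' built as tandem repeats of a short random unit, planting a
#' sequence-complexity contrast between the classes that is independent
#' of average composition.
#'
#' @param genome_length Total chromosome length in bases (default 120000).
#' @param island_fraction Expected fraction of the genome in island tracts
#'   (default 0.25).
#' @param island_gc,background_gc GC fraction of island / background
#'   tracts (defaults 0.65 and 0.40).
#' @param island_cpg_density,background_cpg_density Expected planted CpG
#'   dinucleotides per base (defaults 0.05 and 0.01).
#' @param island_repeat_bias Probability that a tract of `repeat_class`
#'   is built as a tandem repeat of a 20-50 bp unit (default 0.3).
#' @param repeat_class Which class receives repeat tracts, `"background"`
#'   or `"island"` (default background: methylated DNA is the more
#'   repetitive, lower-complexity class).
#' @param n_stages Number of developmental stages assayed (default 8).
#' @param beta_island_mean,beta_background_mean Class means of the
#'   per-stage beta draws (defaults 0 and 0.95).
#' @param beta_noise_sd Standard deviation of the beta noise before
#'   clipping to `[0, 1]` (default 0.01).
#' @param assayed_fraction Fraction of CpG sites that carry calls in all
#'   stages; the rest are unassayed, emulating RRBS coverage
#'   (default 0.6).
#' @param region_flank Bases added to each side of a tract when emitting
#'   the region annotation, emulating imperfect annotation boundaries so
#'   regions contain CpGs of both classes (default 300).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(genome_length = 120000L,
                           island_fraction = 0.25,
                           island_gc = 0.65,
                           background_gc = 0.40,
                           island_cpg_density = 0.05,
                           background_cpg_density = 0.01,
                           island_repeat_bias = 0.3,
                           repeat_class = c("background", "island"),
                           n_stages = 8L,
                           beta_island_mean = 0,
                           beta_background_mean = 0.95,
                           beta_noise_sd = 0.01,
                           assayed_fraction = 0.6,
                           region_flank = 300L,
                           seed = 42L) {
  repeat_class <- match.arg(repeat_class)
  fracs <- c(island_fraction, island_gc, background_gc,
             island_repeat_bias, beta_island_mean, beta_background_mean,
             assayed_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    abort("Invalid spec: all fractions must lie in [0, 1].")
  }
  if (beta_noise_sd < 0) abort("Invalid spec: beta_noise_sd must be >= 0.")
  genome_length <- check_count(genome_length, "genome_length", min = 1000L)
  structure(
    list(
      genome_length = genome_length,
      island_fraction = island_fraction,
      island_gc = island_gc,
      background_gc = background_gc,
      island_cpg_density = island_cpg_density,
      background_cpg_density = background_cpg_density,
      island_repeat_bias = island_repeat_bias,
      repeat_class = repeat_class,
      n_stages = check_count(n_stages, "n_stages"),
      beta_island_mean = beta_island_mean,
      beta_background_mean = beta_background_mean,
      beta_noise_sd = beta_noise_sd,
      assayed_fraction = assayed_fraction,
      region_flank = check_count(region_flank, "region_flank", min = 0L),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# One tract as a character vector of bases.
make_tract <- function(len, gc, repeat_tract) {
  if (repeat_tract) {
    unit_len <- sample(20:50, 1L)
    unit <- random_bases(unit_len, gc)
    rep_len(unit, len)
  } else {
    random_bases(len, gc)
  }
}

#' Simulate a genome with planted methylation classes
#'
#' Generates the synthetic chromosome described by a [synthetic_spec()],
#' per-stage methylation calls for the assayed CpG sites, the truth table
#' of every CpG's class, and a region annotation of the tracts.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_methylome`:
#'   \describe{
#'     \item{genome}{named character vector (one chromosome, `chrS`).}
#'     \item{calls}{tibble `chrom`, `position`, `beta`, `coverage`,
#'       `stage` over all stages (assayed sites only).}
#'     \item{truth}{tibble `chrom`, `position`, `class`
#'       (`"island"`/`"background"`), `methylated` (0/1), `assayed`.}
#'     \item{regions}{tibble `chrom`, `start`, `end`, `state_label`
#'       (tract bodies extended by `region_flank`).}
#'     \item{spec}{the input spec.}
#'   }
#' @export
simulate_methylome <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be a synthetic_spec.")
  }
  with_seed(spec$seed, {
    # --- tract layout -----------------------------------------------------
    f <- spec$island_fraction
    mean_island <- 1200
    tracts <- list()
    total <- 0L
    while (total < spec$genome_length) {
      # background tract
      if (f < 1) {
        mean_bg <- if (f > 0) mean_island * (1 / f - 1) else 4000
        len_bg <- as.integer(stats::runif(1, 0.5 * mean_bg, 1.5 * mean_bg))
        tracts[[length(tracts) + 1L]] <- list(class = "background",
                                              len = len_bg)
        total <- total + len_bg
      }
      if (f > 0 && total < spec$genome_length) {
        len_is <- as.integer(stats::runif(1, 0.5 * mean_island,
                                          1.5 * mean_island))
        tracts[[length(tracts) + 1L]] <- list(class = "island", len = len_is)
        total <- total + len_is
      }
    }
    # trim the final tract to the requested genome length
    excess <- total - spec$genome_length
    if (excess > 0L) {
      last <- tracts[[length(tracts)]]
      if (last$len > excess + 100L) {
        last$len <- last$len - excess
        tracts[[length(tracts)]] <- last
      } else {
        tracts[[length(tracts)]] <- NULL
      }
    }

    # --- sequence + CpG planting -------------------------------------------
    chrom_parts <- vector("list", length(tracts))
    starts <- integer(length(tracts))
    offset <- 0L
    for (i in seq_along(tracts)) {
      tr <- tracts[[i]]
      gc <- if (tr$class == "island") spec$island_gc else spec$background_gc
      dens <- if (tr$class == "island") spec$island_cpg_density
              else spec$background_cpg_density
      rep_tract <- tr$class == spec$repeat_class &&
        stats::runif(1) < spec$island_repeat_bias
      bases <- make_tract(tr$len, gc, rep_tract)
      n_cpg <- stats::rbinom(1L, max(tr$len - 1L, 0L), dens)
      if (n_cpg > 0L) {
        pos <- sort(sample.int(tr$len - 1L, min(n_cpg, tr$len - 1L)))
        pos <- pos[c(TRUE, diff(pos) >= 2L)]
        bases[pos] <- "C"
        bases[pos + 1L] <- "G"
      }
      chrom_parts[[i]] <- bases
      starts[i] <- offset
      offset <- offset + tr$len
    }
    chrom <- paste(unlist(chrom_parts), collapse = "")
    genome <- c(chrS = chrom)

    tract_tbl <- tibble(
      class = vapply(tracts, `[[`, character(1), "class"),
      start = starts,
      end = starts + vapply(tracts, `[[`, integer(1), "len")
    )

    # --- truth table over all realized CpGs --------------------------------
    cpg <- cpg_positions(chrom)
    idx <- findInterval(cpg, tract_tbl$start)
    truth <- tibble(
      chrom = "chrS",
      position = cpg,
      class = tract_tbl$class[idx],
      methylated = as.integer(tract_tbl$class[idx] == "background"),
      assayed = stats::runif(length(cpg)) < spec$assayed_fraction
    )

    # --- per-stage beta draws ----------------------------------------------
    assayed <- truth[truth$assayed, ]
    stage_names <- paste0("stage", seq_len(spec$n_stages))
    mu <- ifelse(assayed$methylated == 1L,
                 spec$beta_background_mean, spec$beta_island_mean)
    calls <- dplyr::bind_rows(lapply(stage_names, function(st) {
      beta <- stats::rnorm(nrow(assayed), mu, spec$beta_noise_sd)
      tibble(
        chrom = assayed$chrom,
        position = assayed$position,
        beta = pmin(pmax(beta, 0), 1),
        coverage = stats::rpois(nrow(assayed), 30L) + 1L,
        stage = st
      )
    }))

    # --- region annotation (tracts + flank) ---------------------------------
    genome_len <- nchar(chrom)
    regions <- tibble(
      chrom = "chrS",
      start = pmax(tract_tbl$start - spec$region_flank, 0L),
      end = pmin(tract_tbl$end + spec$region_flank, genome_len),
      state_label = tract_tbl$class
    )

    structure(
      list(genome = genome, calls = calls, truth = truth,
           regions = regions, spec = spec),
      class = "synthetic_methylome"
    )
  })
}

#' @export
print.synthetic_methylome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_methylome> %d bp, %d CpGs (%d assayed), %d stages, seed %d\n",
    nchar(x$genome[[1]]), nrow(x$truth), sum(x$truth$assayed),
    x$spec$n_stages, x$spec$seed
  ))
  invisible(x)
}

#' Write a synthetic methylome to standard files
#'
#' Emits `genome.fa`, one bedGraph-style `calls_<stage>.tsv` per stage,
#' `truth.tsv`, and `regions.bed` under `dir`, in the same formats the
#' real pipeline consumes.
#'
#' @param sim A `synthetic_methylome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"))
  for (st in unique(sim$calls$stage)) {
    write_methylation(sim$calls[sim$calls$stage == st, ],
                      file.path(dir, paste0("calls_", st, ".tsv")))
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$regions, file.path(dir, "regions.bed"),
                   col_names = FALSE)
  invisible(dir)
}
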