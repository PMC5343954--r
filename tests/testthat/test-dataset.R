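test_that("bedgraph dialect parses, validates and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chr1\t100\t101\t0.95\t30",
    "chr1\t205\t206\t0.02\t12",
    "chr2\t7\t8\t1\t5"
  ), tmp)
  calls <- read_methylation(tmp, "bedgraph", stage = "s1")
  expect_equal(nrow(calls), 3)
  expect_equal(calls$position, c(100L, 205L, 7L))
  expect_equal(calls$beta, c(0.95, 0.02, 1))
  expect_equal(calls$coverage, c(30L, 12L, 5L))
  expect_identical(unique(calls$stage), "s1")
  expect_identical(attr(calls, "n_malformed"), 0L)

  # round trip
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_methylation(calls, tmp2)
  back <- read_methylation(tmp2, "bedgraph", stage = "s1")
  expect_equal(back[c("chrom", "position", "beta", "coverage")],
               calls[c("chrom", "position", "beta", "coverage")])
})

test_that("ENCODE RRBS dialect rescales percent methylation", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    paste(c("chr1", "50", "51", "CpG", "0", "+", "50", "51", "0,0,0",
            "22", "95"), collapse = "\t"),
    paste(c("chr1", "80", "81", "CpG", "0", "+", "80", "81", "0,0,0",
            "10", "0"), collapse = "\t")
  ), tmp)
  calls <- read_methylation(tmp, "encode_rrbs")
  expect_equal(calls$beta, c(0.95, 0))
  expect_equal(calls$coverage, c(22L, 10L))
})

test_that("malformed lines are counted, reported, and capped at 1%", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  good <- sprintf("chr1\t%d\t%d\t0.5\t9", 1:300, 2:301)
  writeLines(c(good[1:150], "chr1\tnope\t3\t0.5\t9", good[151:300]), tmp)
  expect_warning(calls <- read_methylation(tmp, "bedgraph"), "malformed")
  expect_equal(nrow(calls), 300)
  expect_identical(attr(calls, "n_malformed"), 1L)

  writeLines(c(good[1:20], rep("bad line", 5)), tmp)
  expect_error(read_methylation(tmp, "bedgraph"), "malformed")
})

test_that("labelling uses strict intersection semantics", {
  mk <- function(stage, pos, beta) {
    tibble::tibble(chrom = "chr1", position = pos, beta = beta,
                   coverage = 10L, stage = stage)
  }
  stages <- list(
    mk("a", c(1L, 2L, 3L, 4L), c(0.9, 0.9, 0.005, 0.5)),
    mk("b", c(1L, 2L, 3L, 4L), c(0.8, 0.5, 0.001, 0.5)),
    mk("c", c(1L, 2L, 3L),     c(0.75, 0.9, 0.0))
  )
  lab <- label_sites(stages)
  # site 1: all >= 0.7 -> positive; site 2 fails stage b; site 3 negative;
  # site 4 missing from stage c -> dropped
  expect_equal(lab$position, c(1L, 3L))
  expect_equal(lab$label, c(1L, 0L))
})

test_that("labelling matches a brute-force recount on a 1000-site fixture", {
  withr::with_seed(321, {
    n_sites <- 1000
    n_stages <- 4
    betas <- matrix(runif(n_sites * n_stages), n_sites, n_stages)
    # make the decided classes well represented
    betas[1:300, ] <- runif(300 * n_stages, 0.7, 1)
    betas[301:450, ] <- runif(150 * n_stages, 0, 0.01)
    stages <- lapply(seq_len(n_stages), function(s) {
      tibble::tibble(chrom = "chr1", position = seq_len(n_sites),
                     beta = betas[, s], coverage = 1L,
                     stage = paste0("s", s))
    })
    lab <- label_sites(stages)
    truth_pos <- which(apply(betas >= 0.7, 1, all))
    truth_neg <- which(apply(betas <= 0.01, 1, all))
    expect_setequal(lab$position[lab$label == 1], truth_pos)
    expect_setequal(lab$position[lab$label == 0], truth_neg)
    expect_length(intersect(truth_pos, truth_neg), 0)
  })
})

test_that("window extraction centres the CpG and applies all filters", {
  withr::with_seed(432, {
    chr <- strsplit(random_dna(300), "")[[1]]
    chr[50:51] <- c("C", "G")    # 1-based; CpG cytosine at 0-based 49
    chr[3:4] <- c("C", "G")      # near the edge: 0-based 2
    chr[161:162] <- c("T", "T")  # 0-based 160 is definitely not a CpG
    genome <- c(chrT = paste(chr, collapse = ""))
    sites <- tibble::tibble(
      chrom = "chrT",
      position = c(49L, 2L, 160L),  # centred, near-edge, not-a-CpG
      label = c(1L, 1L, 0L)
    )
    wins <- extract_windows(sites, genome, 100)
    expect_equal(nrow(wins), 1)
    expect_equal(wins$center_position, 49L)
    # even window: half-open [c - 49, c + 51) = [0, 100)
    expect_identical(wins$sequence, substr(genome[["chrT"]], 1, 100))
    expect_identical(substr(wins$sequence, 50, 51), "CG")
    expect_identical(attr(wins, "n_out_of_bounds"), 1L)
    expect_identical(attr(wins, "n_not_cpg"), 1L)
  })
})

test_that("windows containing N are skipped", {
  chr <- paste0(strrep("AT", 60), "CG", strrep("TA", 30), "N",
                strrep("AT", 20))
  genome <- c(chrT = chr)  # CpG cytosine at 0-based 120, N at 0-based 182
  sites <- tibble::tibble(chrom = "chrT", position = 120L, label = 1L)
  wins20 <- extract_windows(sites, genome, 20)   # window misses the N
  expect_equal(nrow(wins20), 1)
  wins150 <- extract_windows(sites, genome, 150) # window spans the N
  expect_equal(nrow(wins150), 0)
  expect_identical(attr(wins150, "n_with_n"), 1L)
})

test_that("window extraction retention matches a brute-force bounds check", {
  withr::with_seed(543, {
    L <- 100L
    chr <- strsplit(random_dna(5000), "")[[1]]
    cg_pos <- sort(sample(5:4990, 120))
    cg_pos <- cg_pos[c(TRUE, diff(cg_pos) >= 2)]
    chr[cg_pos + 1L] <- "C"  # 0-based -> 1-based
    chr[cg_pos + 2L] <- "G"
    genome <- c(chrT = paste(chr, collapse = ""))
    real_cg <- methsc:::cpg_positions(genome[["chrT"]])
    sites <- tibble::tibble(chrom = "chrT", position = real_cg,
                            label = rep_len(c(0L, 1L), length(real_cg)))
    wins <- extract_windows(sites, genome, L)
    in_bounds <- real_cg - (L / 2 - 1) >= 0 & real_cg + L / 2 + 1 <= 5000
    expect_equal(nrow(wins), sum(in_bounds))
    expect_true(all(substr(wins$sequence, L / 2, L / 2 + 1) == "CG"))
  })
})

test_that("redundancy reduction keeps exactly the oracle representatives", {
  withr::with_seed(654, {
    # build families of near-duplicates plus unrelated windows
    base <- replicate(20, random_dna(60))
    mutate_seq <- function(s, k) {
      x <- strsplit(s, "")[[1]]
      idx <- sample(length(x), k)
      x[idx] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste(x, collapse = "")
    }
    fam <- unlist(lapply(base, function(s) {
      c(s, mutate_seq(s, 3), mutate_seq(s, 40))
    }))
    seqs <- sample(fam)  # shuffle input order
    kept <- reduce_redundancy(seqs, 0.8)
    expect_identical(attr(kept, "kept_index"),
                     oracle_greedy_cluster(seqs, 0.8))
  })
})

test_that("redundancy reduction trivial cases and error handling", {
  s <- strrep("ACGT", 10)
  expect_length(reduce_redundancy(c(s, s)), 1)
  a <- strrep("A", 10)
  b <- paste0(strrep("A", 7), "CGT")  # identity 0.7 < 0.8
  expect_length(reduce_redundancy(c(a, b)), 2)
  expect_error(reduce_redundancy(c("ACGT", "ACGTA")), "same length")
})

test_that("per-label subsets are deduplicated independently", {
  s <- strrep("ACGT", 25)
  wins <- tibble::tibble(
    label = c(1L, 0L, 1L, 0L),
    sequence = c(s, s, s, s)
  )
  kept <- reduce_redundancy(wins)
  # one representative per label, not one overall
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$label, c(0L, 1L))
})

test_that("no retained window is redundant against an earlier one", {
  withr::with_seed(765, {
    seqs <- c(replicate(30, random_dna(50)),
              replicate(10, strrep(random_dna(5), 10)))
    kept <- reduce_redundancy(sample(seqs), 0.8)
    n <- length(kept)
    if (n > 1) {
      for (i in 2:n) {
        for (j in 1:(i - 1)) {
          a <- strsplit(kept[i], "")[[1]]
          b <- strsplit(kept[j], "")[[1]]
          expect_lt(sum(a == b) / 50, 0.8)
        }
      }
    }
  })
})
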