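# The default-condition synthetic pipeline is used by several tests;
# run it once per test session and cache the pieces.
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (!exists("out", envir = .pipeline_cache)) {
    sim <- simulate_methylome(synthetic_spec())
    sites <- label_sites(split(sim$calls, sim$calls$stage))
    windows <- reduce_redundancy(
      extract_windows(sites, sim$genome, 600)
    )
    features <- encode_windows(windows)
    assign("out", list(sim = sim, sites = sites, windows = windows,
                       features = features),
           envir = .pipeline_cache)
  }
  get("out", envir = .pipeline_cache)
}

# A small fast labelled feature set for model-level tests: two Gaussian
# clouds in 6 features, 3 informative.
toy_features <- function(n_per_class = 60, delta = 2, seed = 11,
                         informative = 3, total = 6) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    m <- matrix(rnorm(n * total), n, total)
    m[seq_len(n_per_class), seq_len(informative)] <-
      m[seq_len(n_per_class), seq_len(informative)] + delta
    colnames(m) <- paste0("f", seq_len(total))
    list(
      features = m,
      labels = rep(c(1L, 0L), each = n_per_class)
    )
  })
}
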