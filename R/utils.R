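#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Validate a DNA string: non-empty, pure ACGT after uppercasing.
# Returns the uppercased string.
check_dna <- function(seq, arg = "seq", allow_n = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single DNA string.", arg))
  }
  s <- toupper(seq)
  if (nchar(s) == 0L) {
    abort(sprintf("`%s` is empty.", arg))
  }
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", s)
  if (nchar(bad) > 0L) {
    abort(sprintf(
      "`%s` contains characters outside {%s}: '%s' ...",
      arg, paste(strsplit(alphabet, "")[[1]], collapse = ","),
      substr(bad, 1L, 10L)
    ))
  }
  s
}

check_count <- function(x, arg, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  as.integer(x)
}

# set.seed() scoped to the call, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
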