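#' Derive a reproducible sub-seed for a named random stream
#'
#' All stochastic functions in the package draw their randomness from a single
#' user-supplied seed via named streams, so that e.g. the genotype draw of a
#' scenario can be reproduced without re-running the phenotype draw. The
#' derived seed is a deterministic 31-bit hash of `(seed, stream)`.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name, e.g. `"genotypes"`, `"effects"`.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' stream_seed(1, "genotypes")
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(stream)) {
    # 31-bit multiplicative string hash; all arithmetic exact in doubles
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(stream_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Bonferroni significance threshold for a family of set tests
#'
#' @param n_sets Number of sets tested (>= 1).
#' @param alpha Family-wise error rate, default 0.05.
#' @return `alpha / n_sets`.
#' @export
#' @examples
#' significance_threshold(25000)  # 2e-06, the usual gene-based threshold
significance_threshold <- function(n_sets, alpha = 0.05) {
  stopifnot(n_sets >= 1, alpha > 0, alpha <= 1)
  alpha / n_sets
}
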