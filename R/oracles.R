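#' Empirical p-value container
#'
#' Resampling p-values use the `(r + 1) / (s + 1)` convention (r
#' exceedances in s draws), so they are never zero but are floored at
#' `1 / (s + 1)` — the resolution limit that motivates the analytic test.
#'
#' @param exceedances Number of resampled statistics >= the observed one.
#' @param draws Number of resampling draws.
#' @return A list of class `empirical_pvalue` with fields `exceedances`,
#'   `draws`, `p`.
#' @export
empirical_pvalue <- function(exceedances, draws) {
  stopifnot(draws >= 1, exceedances >= 0, exceedances <= draws)
  structure(
    list(exceedances = exceedances, draws = draws,
         p = (exceedances + 1) / (draws + 1)),
    class = "empirical_pvalue"
  )
}

#' @export
print.empirical_pvalue <- function(x, ...) {
  cat(sprintf("<empirical_pvalue> p = %.4g (%d/%d draws)\n",
              x$p, x$exceedances, x$draws))
  invisible(x)
}

set_t_statistic <- function(gs, y) {
  # gs: standardised genotype columns; returns T = sum of squared t-stats
  n <- nrow(gs)
  ys <- (y - mean(y)) / sd(y)
  r <- as.vector(crossprod(gs, ys)) / (n - 1)
  sum((n - 2) * r^2 / (1 - r^2))
}

#' Phenotype-permutation set test
#'
#' The individual-level-data reference test: the observed statistic is the
#' sum of squared single-SNP t-statistics of the set, and its null
#' distribution is generated by recomputing the statistic under random
#' permutations of the phenotype vector (which breaks genotype-phenotype
#' association while preserving LD among the SNPs).
#'
#' @param cohort A `synthetic_cohort`.
#' @param snp_ids SNPs of the set (must be in the cohort's panel).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Master seed (stream `"permutation"`).
#' @return An [empirical_pvalue()].
#' @export
permutation_set_test <- function(cohort, snp_ids, n_perm = 1000, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"), n_perm >= 1)
  g <- cohort$panel$genotypes[, match(snp_ids, cohort$panel$map$snp),
                              drop = FALSE]
  if (anyNA(g)) abort("permutation test expects complete genotypes")
  storage.mode(g) <- "double"
  gs <- scale(g)
  if (anyNA(gs)) abort("monomorphic SNP in set")
  y <- cohort$phenotype
  n <- length(y)
  t_obs <- set_t_statistic(gs, y)
  ys <- (y - mean(y)) / sd(y)
  exceed <- with_stream_seed(seed, "permutation", {
    total <- 0L
    chunk <- max(1L, min(n_perm, floor(2e7 / n)))
    done <- 0L
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      # one column per shuffled phenotype
      perm <- vapply(seq_len(k), function(i) ys[sample.int(n)],
                     numeric(n))
      r <- crossprod(gs, perm) / (n - 1)
      t2 <- (n - 2) * r^2 / (1 - r^2)
      total <- total + sum(colSums(t2) >= t_obs)
      done <- done + k
    }
    total
  })
  empirical_pvalue(exceed, n_perm)
}

#' VEGAS-style multivariate-normal simulation set test
#'
#' The summary-data resampling reference: draws z ~ MVN(0, R) through a
#' symmetric eigen square root of R (tolerant of rank deficiency, e.g.
#' duplicated SNPs, where a Cholesky factor does not exist), computes
#' T = sum(z^2) per draw, and returns the empirical tail probability of the
#' observed statistic. In `staged` mode 1,000 draws are run first and the
#' full `n_sims` are only run when the interim corrected p-value is below
#' 0.001 — the classic two-stage design that keeps genome scans cheap.
#'
#' @param ld LD correlation matrix.
#' @param t_obs Observed set statistic (>= 0).
#' @param n_sims Number of MVN draws (final stage when `staged`).
#' @param seed Master seed (stream `"mvn"`).
#' @param staged Use the two-stage 1000 -> `n_sims` design.
#' @return An [empirical_pvalue()]; its `draws` field records the draws
#'   actually used.
#' @export
mvn_simulation_set_test <- function(ld, t_obs, n_sims = 1000, seed = 1,
                                    staged = FALSE) {
  stopifnot(t_obs >= 0, n_sims >= 1)
  ev <- eigen(ld, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  a <- ev$vectors %*% (t(ev$vectors) * sqrt(lam))
  m <- nrow(ld)
  run <- function(s, stream) {
    with_stream_seed(seed, stream, {
      total <- 0L
      chunk <- max(1L, min(s, floor(2e7 / m)))
      done <- 0L
      while (done < s) {
        k <- min(chunk, s - done)
        z <- matrix(rnorm(k * m), nrow = k) %*% a
        total <- total + sum(rowSums(z^2) >= t_obs)
        done <- done + k
      }
      total
    })
  }
  if (staged) {
    interim <- empirical_pvalue(run(1000L, "mvn_stage1"), 1000L)
    if (interim$p >= 0.001) return(interim)
  }
  empirical_pvalue(run(n_sims, "mvn"), n_sims)
}
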