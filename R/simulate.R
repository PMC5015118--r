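#' Simulate a panel of unlinked SNPs
#'
#' Allele frequencies are drawn from U(0.01, 0.99) and genotypes
#' independently from Binomial(2, p) — mutually independent SNPs with no
#' missingness, the standard null genotype model for set-test calibration
#' and power studies. Positions are laid on a 1-bp-spaced grid unless
#' `spacing_bp` says otherwise.
#'
#' @param n Number of samples.
#' @param m Number of SNPs.
#' @param seed Master seed; genotypes draw from the `"genotypes"` stream.
#' @param freq_range Range of the uniform allele-frequency draw.
#' @param spacing_bp Base pairs between adjacent SNP positions.
#' @param chr Chromosome label for the synthetic map.
#' @return A [genotype_panel()].
#' @export
simulate_unlinked_genotypes <- function(n, m, seed = 1,
                                        freq_range = c(0.01, 0.99),
                                        spacing_bp = 1, chr = "1") {
  stopifnot(n >= 1, m >= 1)
  with_stream_seed(seed, "genotypes", {
    p <- runif(m, freq_range[1], freq_range[2])
    g <- matrix(rbinom(n * m, size = 2L, prob = rep(p, each = n)),
                nrow = n, ncol = m)
    map <- tibble::tibble(
      chr = chr, snp = sprintf("snp%05d", seq_len(m)),
      pos = as.integer(seq_len(m) * spacing_bp),
      a1 = "A", a2 = "G"
    )
    genotype_panel(g, map)
  })
}

#' Simulate a panel of SNPs with block-wise LD
#'
#' A latent Gaussian (copula) generator: within each block of `block_size`
#' consecutive SNPs the latent variables follow an AR(1) process with
#' coefficient `within_block_rho`; blocks are independent. Each individual
#' receives two latent vectors (one per haplotype); each latent value is
#' thresholded at the normal quantile of the SNP's allele frequency, and the
#' genotype is the sum of the two resulting Bernoulli alleles. Realised LD
#' between nearby SNPs increases monotonically with `within_block_rho`, and
#' `within_block_rho = 0` reduces exactly to the unlinked generator in
#' distribution.
#'
#' @inheritParams simulate_unlinked_genotypes
#' @param block_size SNPs per LD block.
#' @param within_block_rho AR(1) latent correlation in `[0, 1)`.
#' @return A [genotype_panel()].
#' @export
simulate_block_genotypes <- function(n, m, block_size = 10,
                                     within_block_rho = 0.9, seed = 1,
                                     freq_range = c(0.01, 0.99),
                                     spacing_bp = 1000, chr = "1") {
  stopifnot(n >= 1, m >= 1, within_block_rho >= 0, within_block_rho < 1)
  with_stream_seed(seed, "genotypes", {
    p <- runif(m, freq_range[1], freq_range[2])
    thr <- qnorm(p)
    rho <- within_block_rho
    new_block <- (seq_len(m) - 1L) %% block_size == 0L
    hap <- function() {
      e <- matrix(rnorm(n * m), nrow = n, ncol = m)
      z <- e
      for (j in seq_len(m)[-1]) {
        if (!new_block[j]) {
          z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * e[, j]
        }
      }
      # threshold at the frequency quantile: P(z < thr_j) = p_j
      sweep(z, 2L, thr, `<`)
    }
    g <- hap() + hap()
    storage.mode(g) <- "integer"
    map <- tibble::tibble(
      chr = chr, snp = sprintf("snp%05d", seq_len(m)),
      pos = as.integer(seq_len(m) * spacing_bp),
      a1 = "A", a2 = "G"
    )
    genotype_panel(g, map)
  })
}

#' Simulate a quantitative phenotype with known causal variants
#'
#' `y = sum_j w_j b_j + e`, where `w_j` is the causal genotype standardised
#' to mean 0 and variance 1, effects are drawn `b_j ~ N(0, per_variant_h2)`
#' so each causal variant explains `per_variant_h2` of the phenotypic
#' variance in expectation, and the residual variance is fixed analytically
#' at `1 - k * per_variant_h2` (k causal variants) so that `var(y) = 1` in
#' expectation — no post-hoc rescaling.
#'
#' @param panel A [genotype_panel()].
#' @param causal_snp_ids SNP ids of the causal variants (may be empty for a
#'   null cohort).
#' @param per_variant_h2 Variance fraction explained per causal variant;
#'   `k * per_variant_h2` must be < 1.
#' @param seed Master seed; effects and residuals draw from the
#'   `"effects"` and `"residuals"` streams.
#' @return A `synthetic_cohort`: list with `panel`, `phenotype`,
#'   `causal_snp_ids`, `effects` (the drawn per-causal effect sizes, on the
#'   standardised-genotype scale — the simulation truth, kept for
#'   validation studies), `per_variant_h2`, `seed`.
#' @export
simulate_phenotype <- function(panel, causal_snp_ids = character(),
                               per_variant_h2 = 0.004, seed = 1) {
  k <- length(causal_snp_ids)
  h2_tot <- k * per_variant_h2
  if (h2_tot >= 1) abort("total heritability k * per_variant_h2 must be < 1")
  n <- nrow(panel$genotypes)
  gvalue <- 0
  b <- numeric(0)
  if (k > 0) {
    idx <- match(causal_snp_ids, panel$map$snp)
    if (anyNA(idx)) abort("causal SNP id(s) not in panel")
    w <- scale(panel$genotypes[, idx, drop = FALSE])
    if (anyNA(w)) abort("monomorphic causal SNP")
    b <- with_stream_seed(seed, "effects",
                          rnorm(k, mean = 0, sd = sqrt(per_variant_h2)))
    names(b) <- causal_snp_ids
    gvalue <- as.vector(w %*% b)
  }
  e <- with_stream_seed(seed, "residuals",
                        rnorm(n, mean = 0, sd = sqrt(1 - h2_tot)))
  structure(
    list(panel = panel, phenotype = gvalue + e,
         causal_snp_ids = causal_snp_ids, effects = b,
         per_variant_h2 = per_variant_h2, seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d samples, %d SNPs, %d causal (h2 = %.4g each)\n",
    nrow(x$panel$genotypes), ncol(x$panel$genotypes),
    length(x$causal_snp_ids), x$per_variant_h2
  ))
  invisible(x)
}

#' Place causal variants in random clusters
#'
#' Emulates a clustered genetic architecture: repeatedly pick a uniform
#' random `region_bp` window along the chromosome, draw the cluster size
#' from Binomial(`cluster_size_n`, `cluster_size_p`), and sample that many
#' common SNPs (MAF >= `maf_min`) from the window, until `n_causal_total`
#' causal variants are placed.
#'
#' @param panel A [genotype_panel()].
#' @param n_causal_total Total causal variants to place (default 50).
#' @param region_bp Cluster window width in bp (default 200 Kb).
#' @param cluster_size_n,cluster_size_p Binomial size and frequency
#'   parameters of the per-cluster count (defaults 50 and 0.1, mean 5).
#' @param maf_min Minimum MAF for a SNP to be eligible.
#' @param seed Master seed (stream `"placement"`).
#' @param max_tries Draw attempts before declaring the panel too sparse.
#' @return Character vector of causal SNP ids.
#' @export
place_clustered_causals <- function(panel, n_causal_total = 50,
                                    region_bp = 200000,
                                    cluster_size_n = 50,
                                    cluster_size_p = 0.1,
                                    maf_min = 0.01, seed = 1,
                                    max_tries = 10000) {
  pos <- panel$map$pos
  eligible <- panel$map$snp[panel_maf(panel) >= maf_min]
  if (length(eligible) < n_causal_total) {
    abort("panel has fewer eligible common SNPs than causal variants requested")
  }
  with_stream_seed(seed, "placement", {
    chosen <- character(0)
    tries <- 0
    while (length(chosen) < n_causal_total) {
      tries <- tries + 1
      if (tries > max_tries) {
        abort("panel too sparse to place all clustered causal variants")
      }
      start <- runif(1, min(pos), max(pos))
      cand <- setdiff(
        panel$map$snp[pos >= start & pos < start + region_bp], chosen
      )
      cand <- intersect(cand, eligible)
      k <- rbinom(1, size = cluster_size_n, prob = cluster_size_p)
      k <- min(k, n_causal_total - length(chosen), length(cand))
      if (k > 0) chosen <- c(chosen, sample(cand, k))
    }
    chosen
  })
}

#' Append a SNP in perfect LD with an existing SNP
#'
#' The new SNP's genotype column is an exact copy of the target's, so their
#' correlation is exactly 1. Its map position equals the target's, keeping
#' it inside the same gene windows.
#'
#' @param panel A [genotype_panel()].
#' @param target_snp_id Existing SNP to duplicate.
#' @param new_snp_id Identifier for the copy.
#' @return A new [genotype_panel()] with `m + 1` SNPs.
#' @export
add_perfect_ld_snp <- function(panel, target_snp_id,
                               new_snp_id = paste0(target_snp_id, "_dup")) {
  j <- match(target_snp_id, panel$map$snp)
  if (is.na(j)) abort(sprintf("SNP %s not in panel", target_snp_id))
  g <- cbind(panel$genotypes, panel$genotypes[, j])
  map <- dplyr::bind_rows(
    panel$map,
    dplyr::mutate(panel$map[j, ], snp = new_snp_id)
  )
  genotype_panel(g, map, panel$fam)
}

#' Single-SNP association scan of a synthetic cohort
#'
#' Simple linear regression of the phenotype on each SNP's allele count
#' (with intercept): effect size, standard error, and two-sided p-value from
#' the t statistic on `n - 2` df. Monomorphic SNPs are dropped with a
#' message. Output is in summary-statistics layout, directly usable by
#' [fastbat()] or writable with [write_ma_summary()].
#'
#' @param cohort A `synthetic_cohort` from [simulate_phenotype()], or a
#'   [genotype_panel()] if `phenotype` is given separately.
#' @param phenotype Optional numeric vector overriding `cohort$phenotype`.
#' @return Summary tibble: `snp`, `a1`, `a2`, `freq`, `beta`, `se`, `p`,
#'   `n`.
#' @export
marginal_scan <- function(cohort, phenotype = NULL) {
  if (inherits(cohort, "synthetic_cohort")) {
    panel <- cohort$panel
    y <- phenotype %||% cohort$phenotype
  } else {
    panel <- cohort
    y <- phenotype
    if (is.null(y)) abort("phenotype required when passing a bare panel")
  }
  if (var(y) == 0) abort("phenotype has zero variance")
  g <- panel$genotypes
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    nas <- which(is.na(g), arr.ind = TRUE)
    g[nas] <- mu[nas[, 2L]]
  }
  n <- nrow(g)
  freq <- colMeans(g) / 2
  mono <- apply(g, 2L, var) == 0
  if (any(mono)) {
    inform(sprintf("dropped %d monomorphic SNP(s) from scan", sum(mono)))
    g <- g[, !mono, drop = FALSE]
  }
  xc <- scale(g, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, yc))
  beta <- sxy / sxx
  sse <- sum(yc^2) - beta * sxy
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble::tibble(
    snp = panel$map$snp[!mono],
    a1 = panel$map$a1[!mono], a2 = panel$map$a2[!mono],
    freq = unname(freq[!mono]), beta = unname(beta), se = unname(se),
    p = unname(pmax(p, .Machine$double.xmin)), n = n
  )
}

#' Mean 1-df chi-squared power metric
#'
#' Transforms each set p-value into the 1-df chi-squared value with that
#' tail probability and averages: an expectation-1-under-the-null power
#' measure that remains informative when individual sets rarely cross a
#' significance threshold.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Mean of the transformed chi-squared values.
#' @export
#' @examples
#' power_metric(c(0.5, 0.0455))  # mean of ~0.455 and ~4.0
power_metric <- function(pvalues) {
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  mean(qchisq(pvalues, df = 1, lower.tail = FALSE))
}

#' Synthesise a gene list tiling a panel's positions
#'
#' Convenience for simulation studies: contiguous, non-overlapping genes of
#' `span_bp` base pairs covering the panel's position range, so gene-based
#' sets can be formed on purely synthetic data.
#'
#' @param panel A [genotype_panel()].
#' @param span_bp Gene span in bp.
#' @param gap_bp Gap between consecutive genes (default 0).
#' @return Gene tibble as from [read_gene_list()].
#' @export
tile_gene_list <- function(panel, span_bp, gap_bp = 0) {
  lo <- min(panel$map$pos)
  hi <- max(panel$map$pos)
  starts <- seq(lo, hi, by = span_bp + gap_bp)
  tibble::tibble(
    gene = sprintf("GENE%04d", seq_along(starts)),
    chr = panel$map$chr[1],
    start = as.integer(starts),
    end = as.integer(pmin(starts + span_bp - 1, hi))
  )
}
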