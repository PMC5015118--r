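test_that("unlinked genotypes are reproducible and near-independent", {
  a <- simulate_unlinked_genotypes(200, 15, seed = 10)
  b <- simulate_unlinked_genotypes(200, 15, seed = 10)
  expect_identical(a$genotypes, b$genotypes)
  expect_false(identical(
    a$genotypes, simulate_unlinked_genotypes(200, 15, seed = 11)$genotypes
  ))

  # mean |r| across unlinked pairs tracks the null E|r| ~ sqrt(2 / (pi n))
  panel <- simulate_unlinked_genotypes(3000, 60, seed = 12)
  ld <- compute_ld(panel)
  obs <- mean(abs(ld[upper.tri(ld)]))
  expect_equal(obs, sqrt(2 / (pi * 3000)), tolerance = 0.1)
})

test_that("block generator produces tunable LD matching its latent oracle", {
  # monotonicity in rho
  r2_at <- function(rho) {
    panel <- simulate_block_genotypes(3000, 20, block_size = 5,
                                      within_block_rho = rho, seed = 20)
    ld <- compute_ld(panel)
    adj <- ld[cbind(1:19, 2:20)]
    same_block <- (1:19) %% 5 != 0
    mean(adj[same_block]^2)
  }
  expect_gt(r2_at(0.95), r2_at(0.5))
  expect_lt(r2_at(0), 0.01)

  # adjacent-pair r vs direct Monte Carlo of the thresholded-Gaussian pair
  rho <- 0.9
  panel <- simulate_block_genotypes(20000, 5, block_size = 5,
                                    within_block_rho = rho, seed = 21)
  ld <- compute_ld(panel)
  p <- colMeans(panel$genotypes) / 2  # realised frequencies
  set.seed(22)
  nmc <- 5e5
  mc_pair <- function(p1, p2) {
    z1 <- rnorm(nmc); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nmc)
    w1 <- rnorm(nmc); w2 <- rho * w1 + sqrt(1 - rho^2) * rnorm(nmc)
    g1 <- (z1 < qnorm(p1)) + (w1 < qnorm(p1))
    g2 <- (z2 < qnorm(p2)) + (w2 < qnorm(p2))
    cor(g1, g2)
  }
  for (j in 1:4) {
    expect_lt(abs(ld[j, j + 1] - mc_pair(p[j], p[j + 1])), 0.05)
  }
})

test_that("phenotype generator hits its variance targets", {
  panel <- simulate_unlinked_genotypes(4000, 50, seed = 30)
  # null cohort: variance 1, no genetic signal
  null_c <- simulate_phenotype(panel, character(), seed = 30)
  expect_equal(var(null_c$phenotype), 1, tolerance = 0.1)

  # per-causal realised variance is per_variant_h2 in expectation:
  # regression of realised on target across replicates has slope ~ 1
  # per-causal realised fraction = b_j^2 / var(y) (standardised genotypes
  # have unit variance); averaged over enough effect draws its regression
  # on the target per-variant h2 has slope 1
  small <- simulate_unlinked_genotypes(1000, 10, seed = 31)
  targets <- c(0.002, 0.004, 0.008)
  # common seeds across targets so effect-draw noise cancels in the slope
  realised <- sapply(targets, function(h2) {
    mean(sapply(1:800, function(r) {
      ch <- simulate_phenotype(small, panel_snps(small),
                               per_variant_h2 = h2, seed = 10000 + r)
      mean(ch$effects^2) / var(ch$phenotype)
    }))
  })
  slope <- coef(lm(realised ~ targets))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)

  expect_error(
    simulate_phenotype(panel, panel_snps(panel)[1:2], per_variant_h2 = 0.6),
    "must be < 1"
  )
})

test_that("clustered causal placement follows the binomial cluster law", {
  panel <- simulate_unlinked_genotypes(300, 3000, seed = 40,
                                       spacing_bp = 1000)
  ids <- place_clustered_causals(panel, n_causal_total = 50, seed = 41)
  expect_length(ids, 50)
  expect_length(unique(ids), 50)
  expect_true(all(ids %in% panel_snps(panel)))

  # degenerate binomial: all 50 land in the first window
  ids_all <- place_clustered_causals(panel, n_causal_total = 50,
                                     cluster_size_p = 1, seed = 42)
  pos <- sort(panel$map$pos[match(ids_all, panel$map$snp)])
  expect_lte(max(pos) - min(pos), 200000)

  # cluster sizes follow Binomial(50, 0.1), i.e. mean 5 causals per
  # cluster and so ~10 clusters. Use a sparse 30 Mb panel so windows
  # rarely overlap, and count gaps > 200 Kb as separators.
  wide <- simulate_unlinked_genotypes(300, 3000, seed = 44,
                                      spacing_bp = 10000)
  n_clusters <- vapply(1:150, function(s) {
    idsx <- place_clustered_causals(wide, n_causal_total = 50,
                                    seed = 5000 + s)
    p <- sort(wide$map$pos[match(idsx, wide$map$snp)])
    sum(diff(p) > 200000) + 1
  }, numeric(1))
  expect_equal(mean(n_clusters), 10, tolerance = 0.25)

  tiny <- simulate_unlinked_genotypes(50, 10, seed = 43)
  expect_error(place_clustered_causals(tiny, n_causal_total = 50),
               "fewer eligible")
})

test_that("perfect-LD duplication is exact and prunable", {
  panel <- simulate_unlinked_genotypes(500, 5, seed = 50)
  dup <- add_perfect_ld_snp(panel, "snp00002", "snp00002_dup")
  ld <- compute_ld(dup, c("snp00002", "snp00002_dup"))
  expect_equal(ld[1, 2], 1)
  pr <- prune_by_ld(ld, 0.99)
  expect_length(pr$removed, 1)
  expect_error(add_perfect_ld_snp(panel, "nope"), "not in panel")
})

test_that("marginal scan equals lm() and calibrates under the null", {
  # textbook least squares on a 5-point dataset
  g <- matrix(c(0, 1, 2, 1, 0), ncol = 1)
  map <- tibble::tibble(chr = "1", snp = "s", pos = 1L, a1 = "A", a2 = "G")
  panel <- genotype_panel(g, map)
  y <- c(0.3, 1.1, 2.2, 0.9, -0.1)
  s <- marginal_scan(panel, phenotype = y)
  fit <- summary(lm(y ~ g[, 1]))$coefficients
  expect_equal(s$beta, fit[2, "Estimate"])
  expect_equal(s$se, fit[2, "Std. Error"])
  expect_equal(s$p, fit[2, "Pr(>|t|)"])
  expect_equal(s$freq, mean(g) / 2)

  # null cohort: uniform p-values
  panel2 <- simulate_unlinked_genotypes(1000, 1000, seed = 60)
  nullc <- simulate_phenotype(panel2, character(), seed = 60)
  s2 <- marginal_scan(nullc)
  expect_gt(ks.test(s2$p, "punif")$p.value, 0.01)

  # single causal explaining exactly 0.4% at n = 10000: the scan's
  # chi-square has non-centrality ~ n h2, so a mean of ~41 over replicates
  chis <- vapply(1:50, function(r) {
    p3 <- simulate_unlinked_genotypes(10000, 1, seed = 600 + r)
    w <- scale(p3$genotypes[, 1])[, 1]
    set.seed(700 + r)
    y <- sqrt(0.004) * w + rnorm(10000, sd = sqrt(0.996))
    s3 <- marginal_scan(p3, phenotype = y)
    (s3$beta / s3$se)^2
  }, numeric(1))
  expect_equal(mean(chis), 41, tolerance = 0.15)
})

test_that("power metric transforms p-values through the 1-df quantile", {
  expect_equal(power_metric(c(0.5, 0.5)), 0.4549364, tolerance = 1e-4)
  expect_equal(power_metric(c(0.5, 0.04550026)),
               mean(c(0.4549364, 3.999997)), tolerance = 1e-4)
  set.seed(70)
  expect_equal(power_metric(runif(20000)), 1, tolerance = 0.05)
  expect_error(power_metric(c(0.5, 0)), "pvalues > 0")
})
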