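# Shared fixtures and independent oracles used across the suite.

# Minimal valid summary tibble.
make_summary <- function(snp, beta = NA_real_, se = NA_real_, p = NA_real_,
                         a1 = "A", a2 = "G", freq = 0.3, n = 10000) {
  tibble::tibble(snp = snp, a1 = a1, a2 = a2, freq = freq,
                 beta = beta, se = se, p = p, n = n)
}

# Exact tail of lambda1*X + lambda2*Y (X, Y iid 1-df chi-square) by 1-D
# quadrature -- independent of the package's mixture-series/saddlepoint code.
exact_tail_2 <- function(q, lam) {
  stopifnot(length(lam) == 2)
  f <- function(x) {
    dchisq(x, 1) * pchisq((q - lam[1] * x) / lam[2], 1, lower.tail = FALSE)
  }
  integrate(f, 0, q / lam[1], rel.tol = 1e-12, subdivisions = 2000L)$value +
    pchisq(q / lam[1], 1, lower.tail = FALSE)
}

# Brute-force minimum vertex cover size of the above-threshold r^2 graph.
min_vertex_cover_size <- function(adj) {
  m <- nrow(adj)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(edges) == 0) return(0L)
  for (k in 0:m) {
    for (sel in utils::combn(m, k, simplify = FALSE)) {
      covered <- all(edges[, 1] %in% sel | edges[, 2] %in% sel)
      if (covered) return(k)
    }
  }
  m
}

# Random LD matrix estimated from a simulated panel (mixed structures).
random_ld_matrix <- function(m, rho, seed, n = 2000) {
  panel <- if (rho == 0) {
    simulate_unlinked_genotypes(n, m, seed = seed)
  } else {
    simulate_block_genotypes(n, m, block_size = 5,
                             within_block_rho = rho, seed = seed)
  }
  compute_ld(panel)
}

# Panel whose genes mix a high-LD block of null SNPs with unlinked SNPs,
# used for the pruning-benefit experiments: each gene has `block_m` SNPs in
# one tight LD block plus `free_m` unlinked SNPs, and the causal variant (in
# half the genes) is one of the unlinked SNPs.
make_pruning_panel <- function(n, n_genes, block_m = 8, free_m = 2,
                               rho = 0.999, seed = 1) {
  # moderate frequencies keep realised r^2 above the pruning cutoff
  blocks <- simulate_block_genotypes(n, n_genes * block_m,
                                     block_size = block_m,
                                     within_block_rho = rho, seed = seed,
                                     freq_range = c(0.2, 0.8))
  free <- simulate_unlinked_genotypes(n, n_genes * free_m,
                                      seed = seed + 1)
  geno <- cbind(blocks$genotypes, free$genotypes)
  blk_map <- blocks$map
  blk_map$snp <- paste0("blk_", blk_map$snp)
  free_map <- free$map
  free_map$snp <- paste0("free_", free_map$snp)
  free_map$pos <- free_map$pos + max(blk_map$pos)
  map <- dplyr::bind_rows(blk_map, free_map)
  panel <- genotype_panel(geno, map)
  sets <- lapply(seq_len(n_genes), function(g) {
    c(paste0("blk_", blocks$map$snp[(g - 1) * block_m + seq_len(block_m)]),
      paste0("free_", free$map$snp[(g - 1) * free_m + seq_len(free_m)]))
  })
  names(sets) <- sprintf("GENE%03d", seq_len(n_genes))
  causal <- vapply(seq(1, n_genes, by = 2), function(g) {
    paste0("free_", free$map$snp[(g - 1) * free_m + 1L])
  }, character(1))
  list(panel = panel, sets = sets, causal = causal)
}
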