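#' Default LD-cutoff grid for pruning sweeps
#'
#' Coarse steps of 0.1 between 0.1 and 0.9 and fine steps of 0.01 between
#' 0.9 and 1, where pruning gains concentrate.
#'
#' @return Sorted numeric vector of r^2 cutoffs.
#' @export
default_r2_grid <- function() {
  sort(unique(c(seq(0.1, 0.9, by = 0.1), seq(0.9, 1, by = 0.01))))
}

#' Power sweep of LD-pruned set tests over a grid of r^2 cutoffs
#'
#' Simulates replicate cohorts with block-wise LD, places causal variants
#' (at random or clustered in 200 Kb regions), produces summary statistics
#' by marginal scan, and runs the gene-based test at each LD-pruning cutoff.
#' Power is the mean 1-df chi-squared transform of the gene p-values
#' ([power_metric()]), reported over all genes and over the genes harbouring
#' at least one causal variant. A cutoff of 1 removes nothing (no pair
#' exceeds r^2 = 1), so the grid's right end point is the unpruned test.
#'
#' @param n_samples,m_snps Cohort dimensions per replicate.
#' @param block_size,within_block_rho LD-block structure
#'   ([simulate_block_genotypes()]).
#' @param n_causal Causal variants per replicate.
#' @param per_variant_h2 Variance explained per causal variant (default
#'   0.002, the convention for dense-panel pruning studies).
#' @param placement `"random"` or `"clustered"` causal placement.
#' @param r2_grid Cutoff grid, default [default_r2_grid()].
#' @param replicates Number of simulation replicates averaged.
#' @param gene_span_bp Synthetic gene span for [tile_gene_list()].
#' @param window_kb Gene window for set assembly.
#' @param region_bp,cluster_size_n,cluster_size_p Clustering parameters
#'   ([place_clustered_causals()]).
#' @param seed Master seed.
#' @return Tibble of class `power_sweep`: `r2_cutoff`, `power_all`,
#'   `power_causal`, with the configuration in attributes.
#' @export
power_sweep <- function(n_samples = 2000, m_snps = 400, block_size = 10,
                        within_block_rho = 0.9, n_causal = 10,
                        per_variant_h2 = 0.002,
                        placement = c("random", "clustered"),
                        r2_grid = default_r2_grid(), replicates = 50,
                        gene_span_bp = 20000, window_kb = 0,
                        region_bp = 200000, cluster_size_n = 50,
                        cluster_size_p = 0.1, seed = 1) {
  placement <- match.arg(placement)
  stopifnot(all(r2_grid > 0), all(r2_grid <= 1), replicates >= 1)
  acc_all <- matrix(0, nrow = replicates, ncol = length(r2_grid))
  acc_causal <- matrix(0, nrow = replicates, ncol = length(r2_grid))
  for (rep_i in seq_len(replicates)) {
    rep_seed <- stream_seed(seed, paste0("sweep", rep_i))
    panel <- simulate_block_genotypes(
      n_samples, m_snps, block_size = block_size,
      within_block_rho = within_block_rho, seed = rep_seed
    )
    causal <- if (placement == "clustered") {
      place_clustered_causals(
        panel, n_causal_total = n_causal, region_bp = region_bp,
        cluster_size_n = cluster_size_n, cluster_size_p = cluster_size_p,
        seed = rep_seed
      )
    } else {
      with_stream_seed(rep_seed, "placement",
                       sample(panel_snps(panel), n_causal))
    }
    cohort <- simulate_phenotype(panel, causal,
                                 per_variant_h2 = per_variant_h2,
                                 seed = rep_seed)
    summ <- marginal_scan(cohort)
    genes <- tile_gene_list(panel, gene_span_bp)
    sets <- assemble_gene_sets(panel$map, genes, window_kb = window_kb)
    w <- window_kb * 1000
    causal_pos <- panel$map$pos[match(causal, panel$map$snp)]
    has_causal <- vapply(seq_len(nrow(sets)), function(i) {
      any(causal_pos >= sets$start[i] - w & causal_pos <= sets$end[i] + w)
    }, logical(1))
    for (ti in seq_along(r2_grid)) {
      res <- fastbat(summ, panel, sets = sets, r2_prune = r2_grid[ti])
      ord <- match(sets$set_id, res$set_id)
      p <- res$p_fastbat[ord]
      acc_all[rep_i, ti] <- power_metric(p[!is.na(ord)])
      acc_causal[rep_i, ti] <-
        power_metric(p[which(has_causal & !is.na(ord))])
    }
  }
  out <- tibble::tibble(
    r2_cutoff = r2_grid,
    power_all = colMeans(acc_all),
    power_causal = colMeans(acc_causal)
  )
  structure(out, class = c("power_sweep", class(out)),
            config = list(
              n_samples = n_samples, m_snps = m_snps,
              block_size = block_size,
              within_block_rho = within_block_rho, n_causal = n_causal,
              per_variant_h2 = per_variant_h2, placement = placement,
              replicates = replicates, gene_span_bp = gene_span_bp,
              window_kb = window_kb, seed = seed
            ))
}
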