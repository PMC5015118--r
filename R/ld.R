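#' Estimate the LD correlation matrix for a set of SNPs
#'
#' Pearson correlations of allele counts across the samples of a reference
#' panel (genotypic r; reference panels are unphased). Missing genotypes are
#' mean-imputed per SNP before correlation. The returned matrix is
#' symmetrised as `(r + t(r)) / 2`, clipped to `[-1, 1]`, and its diagonal is
#' forced to exactly 1.
#'
#' Allele orientation is irrelevant downstream: flipping a SNP's coded allele
#' only changes the sign of r, and the set test uses r^2 (through the
#' eigenvalues of R) alone.
#'
#' @param panel A [genotype_panel()].
#' @param snp_ids SNP ids to include, in order; all must be in the panel and
#'   polymorphic (an error names any monomorphic SNP).
#' @return An m x m correlation matrix with `snp_ids` as dimnames.
#' @export
compute_ld <- function(panel, snp_ids = panel_snps(panel)) {
  idx <- match(snp_ids, panel$map$snp)
  if (anyNA(idx)) {
    abort(sprintf("SNPs not in panel: %s",
                  paste(snp_ids[is.na(idx)], collapse = ", ")))
  }
  g <- panel$genotypes[, idx, drop = FALSE]
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    nas <- which(is.na(g), arr.ind = TRUE)
    g[nas] <- mu[nas[, 2L]]
  }
  v <- apply(g, 2L, var)
  if (any(v == 0 | is.na(v))) {
    abort(sprintf("monomorphic SNP(s) with zero variance: %s",
                  paste(snp_ids[v == 0 | is.na(v)], collapse = ", ")))
  }
  r <- cor(g)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

#' Greedy LD pruning of a SNP set
#'
#' Records all SNP pairs whose squared correlation exceeds `r2_threshold`,
#' then repeatedly removes the SNP involved in the largest number of
#' remaining above-threshold pairs (recomputing the counts after each
#' removal) until no such pair is left. Ties on the count are broken by
#' removing the SNP that occurs latest in the set's positional order, making
#' the procedure deterministic and independent of the association
#' statistics. This is a greedy vertex-cover heuristic: it keeps the removal
#' count small but is not guaranteed minimal.
#'
#' @param ld LD correlation matrix as from [compute_ld()].
#' @param r2_threshold Squared-correlation threshold in `(0, 1]`; every pair
#'   kept satisfies `r^2 <= r2_threshold`. The recommended default in the
#'   set test is 0.9.
#' @return A list with character vectors `kept` and `removed` (both in
#'   original positional order).
#' @export
prune_by_ld <- function(ld, r2_threshold = 0.9) {
  stopifnot(is.matrix(ld), nrow(ld) == ncol(ld),
            r2_threshold > 0, r2_threshold <= 1)
  m <- nrow(ld)
  ids <- rownames(ld) %||% as.character(seq_len(m))
  adj <- ld^2 > r2_threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, m)
  removed <- integer(0)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    # ties: drop the latest SNP in positional order
    worst <- max(which(deg == max(deg)))
    alive[worst] <- FALSE
    removed <- c(removed, worst)
  }
  list(kept = ids[alive], removed = ids[sort(removed)])
}
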