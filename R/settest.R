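#' Per-SNP chi-squared statistic from a summary record
#'
#' `z^2 = (beta / se)^2` when both are present (preferred: more precision in
#' deep tails than a rounded p-value), otherwise the 1-df chi-squared
#' quantile at survival probability `p`. Only squares enter the set
#' statistic, so the sign of z is never needed.
#'
#' @param beta,se Effect size and standard error (may be `NA`).
#' @param p Two-sided p-value in `(0, 1]` (may be `NA` if `beta`/`se` given).
#' @param prefer `"beta"` (default) or `"p"`: which source to use when both
#'   are available.
#' @return Non-negative chi-squared value(s); vectorised over records.
#' @export
#' @examples
#' snp_chisq(beta = 0.1, se = 0.05)   # 4
#' snp_chisq(p = 0.0455003)           # ~4
snp_chisq <- function(beta = NA_real_, se = NA_real_, p = NA_real_,
                      prefer = c("beta", "p")) {
  prefer <- match.arg(prefer)
  n <- max(length(beta), length(se), length(p))
  beta <- rep_len(beta, n); se <- rep_len(se, n); p <- rep_len(p, n)
  have_bse <- !is.na(beta) & !is.na(se)
  have_p <- !is.na(p)
  if (any(!have_bse & !have_p)) {
    abort("each record needs (beta, se) or a p-value")
  }
  if (any(have_p & p <= 0)) {
    abort("p-value of 0 cannot be inverted; supply beta and se instead")
  }
  use_bse <- if (prefer == "beta") have_bse else have_bse & !have_p
  out <- numeric(n)
  out[use_bse] <- (beta[use_bse] / se[use_bse])^2
  out[!use_bse] <- qchisq(p[!use_bse], df = 1, lower.tail = FALSE)
  out
}

#' Assemble gene-based SNP sets from positions and annotations
#'
#' A SNP belongs to a gene's set iff it lies on the same chromosome within
#' `[start - W, end + W]` inclusive, `W = window_kb * 1000` (default 50 Kb,
#' the usual gene-based window). SNPs may belong to several overlapping
#' sets. Genes overlapping no SNPs are dropped (with a message giving the
#' count).
#'
#' @param snp_positions Data frame with columns `snp`, `chr`, `pos` —
#'   typically the `map` of a [genotype_panel()].
#' @param genes Tibble from [read_gene_list()].
#' @param window_kb Flanking window in kilobases (>= 0), default 50.
#' @return Tibble with columns `set_id`, `chr`, `start`, `end`, and a
#'   list-column `snps` of member SNP ids (positional order).
#' @export
assemble_gene_sets <- function(snp_positions, genes, window_kb = 50) {
  stopifnot(window_kb >= 0)
  w <- window_kb * 1000
  snp_positions <- tibble::as_tibble(snp_positions)
  genes <- tibble::as_tibble(genes)
  sets <- purrr::pmap(
    list(genes$gene, genes$chr, genes$start, genes$end),
    function(gene, chr, start, end) {
      hit <- snp_positions$chr == chr &
        snp_positions$pos >= start - w &
        snp_positions$pos <= end + w
      snp_positions$snp[hit]
    }
  )
  out <- tibble::tibble(
    set_id = genes$gene, chr = genes$chr,
    start = genes$start, end = genes$end, snps = sets
  )
  empty <- lengths(out$snps) == 0L
  if (any(empty)) {
    inform(sprintf("dropped %d gene(s) with no overlapping SNPs", sum(empty)))
  }
  out[!empty, ]
}

#' Run the set-based association test for one SNP set
#'
#' Pipeline: intersect the set with the summary statistics and the reference
#' panel (matching by SNP id, and by unordered allele pair when alleles are
#' present on both sides); optionally LD-prune the intersection at
#' `r2_prune`; sum the per-SNP chi-squared statistics of the kept SNPs; and
#' evaluate the analytic tail probability with weights from the kept SNPs'
#' LD matrix. The top SNP (smallest single-SNP p) is recorded before
#' pruning, so pruning can never hide the strongest signal from the report.
#'
#' @param snp_ids Character vector: the set's SNP ids.
#' @param summary Validated summary tibble ([read_ma_summary()] /
#'   [marginal_scan()]).
#' @param panel Reference [genotype_panel()] for LD.
#' @param r2_prune LD-pruning r^2 threshold in `(0, 1]`, or `NULL` to
#'   disable. Default 0.9.
#' @param method Tail method passed to [quadform_pvalue()].
#' @param prefer Passed to [snp_chisq()].
#' @param set_id Label for the output row.
#' @return One-row tibble: `set_id`, `n_snps_raw`, `n_snps_pruned`,
#'   `chisq_obs`, `p_fastbat`, `top_snp_id`, `top_snp_p`.
#' @export
run_fastbat <- function(snp_ids, summary, panel, r2_prune = 0.9,
                        method = "auto", prefer = "beta",
                        set_id = "set") {
  summary <- tibble::as_tibble(summary)
  in_sum <- summary[summary$snp %in% snp_ids, , drop = FALSE]
  shared <- intersect(snp_ids, intersect(in_sum$snp, panel_snps(panel)))
  # allele harmonisation: require {A1,A2} to agree as an unordered pair
  if (length(shared)) {
    si <- match(shared, summary$snp)
    pi <- match(shared, panel$map$snp)
    s1 <- toupper(summary$a1[si]); s2 <- toupper(summary$a2[si])
    p1 <- toupper(panel$map$a1[pi]); p2 <- toupper(panel$map$a2[pi])
    checkable <- !is.na(s1) & !is.na(s2)
    ok <- !checkable | (s1 == p1 & s2 == p2) | (s1 == p2 & s2 == p1)
    if (any(!ok)) {
      inform(sprintf("set %s: dropped %d SNP(s) with mismatched alleles",
                     set_id, sum(!ok)))
      shared <- shared[ok]
    }
  }
  if (!length(shared)) {
    abort(sprintf("set %s: no SNPs shared by summary and panel", set_id),
          class = "fastbat_empty_set")
  }
  # top SNP from all set SNPs present in the summary, pre-pruning
  p_single <- single_snp_p(in_sum)
  top <- which.min(p_single)
  ld <- compute_ld(panel, shared)
  kept <- shared
  if (!is.null(r2_prune)) {
    kept <- prune_by_ld(ld, r2_prune)$kept
    ld <- ld[kept, kept, drop = FALSE]
  }
  ks <- match(kept, summary$snp)
  chisq <- snp_chisq(summary$beta[ks], summary$se[ks], summary$p[ks],
                     prefer = prefer)
  q <- sum(chisq)
  pval <- quadform_pvalue(q, spectral_weights(ld), method = method)
  tibble::tibble(
    set_id = set_id,
    n_snps_raw = length(shared),
    n_snps_pruned = length(kept),
    chisq_obs = q,
    p_fastbat = pval,
    top_snp_id = in_sum$snp[top],
    top_snp_p = unname(p_single[top])
  )
}

single_snp_p <- function(records) {
  p <- records$p
  miss <- is.na(p)
  if (any(miss)) {
    p[miss] <- pchisq((records$beta[miss] / records$se[miss])^2,
                      df = 1, lower.tail = FALSE)
  }
  p
}

#' Genome-wide set-based association scan
#'
#' The main driver: assembles gene-based sets (or takes custom sets), runs
#' [run_fastbat()] per set, and returns a results table sorted by p-value
#' (ties broken by set id). Sets that cannot be analysed (no SNP shared by
#' summary and panel, or a monomorphic SNP in the panel) are skipped and
#' listed in the `skipped` attribute rather than failing the scan.
#'
#' @param summary Summary-statistics tibble (first argument, pipe-friendly).
#' @param panel Reference [genotype_panel()].
#' @param genes Gene annotation tibble ([read_gene_list()]); alternatively
#'   supply `sets`.
#' @param sets Named list of SNP-id vectors (custom sets), or a tibble as
#'   from [assemble_gene_sets()].
#' @param window_kb Gene window in Kb (default 50); ignored for custom sets.
#' @param r2_prune LD-pruning threshold, `NULL` to disable (default 0.9).
#' @param method,prefer Passed to [run_fastbat()].
#' @param alpha Family-wise error rate for the reported Bonferroni
#'   threshold (default 0.05).
#' @return A tibble of class `fastbat_result`, one row per analysed set,
#'   with attributes `threshold` (alpha / number of sets tested) and
#'   `skipped` (tibble of set ids and reasons).
#' @export
fastbat <- function(summary, panel, genes = NULL, sets = NULL,
                    window_kb = 50, r2_prune = 0.9, method = "auto",
                    prefer = "beta", alpha = 0.05) {
  summary <- validate_summary(summary)
  if (is.null(genes) == is.null(sets)) {
    abort("supply exactly one of `genes` or `sets`")
  }
  if (!is.null(genes)) {
    set_tb <- assemble_gene_sets(panel$map, genes, window_kb = window_kb)
  } else if (is.data.frame(sets)) {
    set_tb <- tibble::as_tibble(sets)
  } else {
    set_tb <- tibble::tibble(
      set_id = names(sets), chr = NA_character_,
      start = NA_integer_, end = NA_integer_, snps = unname(sets)
    )
  }
  if (!"chr" %in% names(set_tb)) set_tb$chr <- NA_character_
  if (!"start" %in% names(set_tb)) set_tb$start <- NA_integer_
  if (!"end" %in% names(set_tb)) set_tb$end <- NA_integer_
  skipped <- list()
  rows <- purrr::map(seq_len(nrow(set_tb)), function(i) {
    tryCatch(
      run_fastbat(set_tb$snps[[i]], summary, panel, r2_prune = r2_prune,
                  method = method, prefer = prefer,
                  set_id = set_tb$set_id[i]),
      error = function(e) {
        skipped[[length(skipped) + 1L]] <<- tibble::tibble(
          set_id = set_tb$set_id[i], reason = conditionMessage(e)
        )
        NULL
      }
    )
  })
  res <- dplyr::bind_rows(rows)
  if (!nrow(res)) abort("no set could be analysed")
  meta <- set_tb[match(res$set_id, set_tb$set_id),
                 c("chr", "start", "end")]
  res <- dplyr::bind_cols(res[1], meta, res[-1])
  res <- dplyr::arrange(res, .data$p_fastbat, .data$set_id)
  structure(
    res,
    class = c("fastbat_result", class(res)),
    threshold = significance_threshold(nrow(res), alpha),
    alpha = alpha,
    skipped = dplyr::bind_rows(skipped)
  )
}
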