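#' Read GWAS summary statistics in GCTA .ma layout
#'
#' Parses a whitespace-delimited summary file with header
#' `SNP A1 A2 freq b se p N` (the GCTA "ma" convention), or the minimal
#' two-column `SNP p` layout. Column matching is case-insensitive. Every
#' record must carry enough information for a per-SNP chi-squared statistic:
#' either the `(b, se)` pair or a p-value in `(0, 1]`.
#'
#' @param path Path to the summary text file.
#' @return A tibble with columns `snp`, `a1`, `a2`, `freq`, `beta`, `se`,
#'   `p`, `n` (allele/frequency/size columns are `NA` when absent from the
#'   file).
#' @export
read_ma_summary <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.table(path, header = TRUE, colClasses = "character",
                   check.names = FALSE)
  nm <- tolower(names(df))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- match(cand, nm)
      if (!is.na(i)) return(df[[i]])
    }
    NULL
  }
  snp <- pick("snp")
  if (is.null(snp)) abort("summary file must have a SNP column")
  num <- function(x) {
    if (is.null(x)) return(rep(NA_real_, length(snp)))
    out <- suppressWarnings(as.numeric(x))
    out[x %in% c("NA", ".", "-", "")] <- NA_real_
    out
  }
  out <- tibble::tibble(
    snp = snp,
    a1 = pick("a1", "allele1") %||% rep(NA_character_, length(snp)),
    a2 = pick("a2", "allele2") %||% rep(NA_character_, length(snp)),
    freq = num(pick("freq", "frq", "maf")),
    beta = num(pick("b", "beta")),
    se = num(pick("se")),
    p = num(pick("p", "pval", "pvalue")),
    n = num(pick("n"))
  )
  validate_summary(out)
}

#' Validate a summary-statistics tibble
#'
#' Checks the invariants every downstream step relies on: unique SNP ids,
#' p-values in `(0, 1]`, positive standard errors, frequencies in `(0, 1)`,
#' and per-record availability of either `(beta, se)` or `p`.
#'
#' @param summary A data frame with columns as in [read_ma_summary()].
#' @return The input as a tibble, invisibly checked.
#' @export
validate_summary <- function(summary) {
  out <- tibble::as_tibble(summary)
  req <- c("snp", "p")
  if (!all(req %in% names(out))) {
    abort("summary must have at least columns 'snp' and 'p'")
  }
  for (col in c("a1", "a2", "freq", "beta", "se", "n")) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  dup <- out$snp[duplicated(out$snp)]
  if (length(dup)) {
    abort(sprintf("duplicate SNP id(s) in summary: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad_p <- !is.na(out$p) & (out$p <= 0 | out$p > 1)
  if (any(bad_p)) {
    abort(sprintf(
      "p-values must lie in (0, 1]; offending SNP(s): %s (supply b/se for p-values that underflow to 0)",
      paste(head(out$snp[bad_p], 5), collapse = ", ")
    ))
  }
  if (any(!is.na(out$se) & out$se <= 0)) abort("standard errors must be > 0")
  bad_f <- !is.na(out$freq) & (out$freq <= 0 | out$freq >= 1)
  if (any(bad_f)) abort("allele frequencies must lie in (0, 1)")
  no_stat <- (is.na(out$beta) | is.na(out$se)) & is.na(out$p)
  if (any(no_stat)) {
    abort(sprintf(
      "record(s) with neither (b, se) nor p: %s",
      paste(head(out$snp[no_stat], 5), collapse = ", ")
    ))
  }
  out[c("snp", "a1", "a2", "freq", "beta", "se", "p", "n")]
}

#' Write summary statistics in GCTA .ma layout
#'
#' @param summary Tibble as returned by [read_ma_summary()] or
#'   [marginal_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ma_summary <- function(summary, path) {
  num <- function(x) sprintf("%.17g", x)  # lossless double round trip
  df <- data.frame(
    SNP = summary$snp, A1 = summary$a1, A2 = summary$a2,
    freq = num(summary$freq), b = num(summary$beta), se = num(summary$se),
    p = num(summary$p), N = summary$n
  )
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a gene annotation list
#'
#' One gene per line, four whitespace-delimited columns:
#' chromosome, start, end, gene id. Coordinates are 1-based inclusive
#' (PLINK/.bim convention).
#'
#' @param path Path to the gene list file.
#' @return Tibble with columns `gene`, `chr`, `start`, `end`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.table(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 4) abort("gene list must have 4 columns: chr start end gene")
  out <- tibble::tibble(
    gene = df[[4]], chr = df[[1]],
    start = as.integer(df[[2]]), end = as.integer(df[[3]])
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    abort("non-integer coordinates in gene list")
  }
  if (any(out$end < out$start)) {
    abort(sprintf("end < start for gene(s): %s",
                  paste(out$gene[out$end < out$start], collapse = ", ")))
  }
  if (anyDuplicated(out$gene)) {
    abort("duplicate gene id(s) in gene list")
  }
  out
}

#' Write a gene annotation list
#'
#' @param genes Tibble as from [read_gene_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  write.table(
    data.frame(genes$chr, genes$start, genes$end, genes$gene),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(path)
}

#' Read a custom SNP-set list
#'
#' One set per line: the set name followed by its SNP ids, whitespace
#' delimited. A set with a name but no SNPs is an error.
#'
#' @param path Path to the set list file.
#' @return A named list of character vectors of SNP ids.
#' @export
read_set_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty set list")
  toks <- strsplit(trimws(lines), "\\s+")
  names_ <- vapply(toks, `[[`, character(1), 1L)
  sets <- lapply(toks, function(x) x[-1L])
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    abort(sprintf("set(s) with no SNPs: %s",
                  paste(names_[empty], collapse = ", ")))
  }
  if (anyDuplicated(names_)) abort("duplicate set name(s) in set list")
  setNames(sets, names_)
}

#' Write set-test results as TSV
#'
#' Columns: `Gene Chr Start End nSNPs_raw nSNPs_pruned Chisq_obs P_fastBAT
#' TopSNP TopSNP_P`. Optional `header` lines (e.g. the run configuration)
#' are written first as `#`-prefixed comments; [read_results()] skips them,
#' so a write/read round trip is stable.
#'
#' @param results Tibble as returned by [fastbat()].
#' @param path Output path.
#' @param header Optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, header = NULL) {
  df <- data.frame(
    Gene = results$set_id,
    Chr = results$chr %||% NA_character_,
    Start = results$start %||% NA_integer_,
    End = results$end %||% NA_integer_,
    nSNPs_raw = results$n_snps_raw,
    nSNPs_pruned = results$n_snps_pruned,
    Chisq_obs = results$chisq_obs,
    P_fastBAT = results$p_fastbat,
    TopSNP = results$top_snp_id,
    TopSNP_P = results$top_snp_p
  )
  fmt <- function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  }
  cols <- lapply(df, fmt)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path Path to the results file.
#' @return Tibble with the same columns as [fastbat()] output.
#' @export
read_results <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  tibble::tibble(
    set_id = df$Gene,
    chr = df$Chr,
    start = as.integer(df$Start),
    end = as.integer(df$End),
    n_snps_raw = as.integer(df$nSNPs_raw),
    n_snps_pruned = as.integer(df$nSNPs_pruned),
    chisq_obs = as.numeric(df$Chisq_obs),
    p_fastbat = as.numeric(df$P_fastBAT),
    top_snp_id = df$TopSNP,
    top_snp_p = as.numeric(df$TopSNP_P)
  )
}
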