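#' In-memory reference genotype panel
#'
#' A light container for a genotype matrix plus its SNP map and sample list,
#' as read from a PLINK-1 fileset or produced by the simulators. Genotypes are
#' stored as counts of the A1 allele in `{0, 1, 2, NA}`; missing calls are
#' retained and handled downstream (mean imputation in LD estimation).
#'
#' @param genotypes Integer matrix, samples x SNPs, entries 0/1/2/NA.
#' @param map Data frame with columns `chr` (character), `snp`, `pos`
#'   (1-based bp), `a1`, `a2`; one row per SNP, in column order of
#'   `genotypes`.
#' @param fam Data frame with columns `fid`, `iid`; one row per sample.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, map, fam = NULL) {
  map <- tibble::as_tibble(map)
  stopifnot(
    is.matrix(genotypes),
    all(c("chr", "snp", "pos", "a1", "a2") %in% names(map)),
    nrow(map) == ncol(genotypes)
  )
  if (anyDuplicated(map$snp)) {
    abort("duplicate SNP identifiers in genotype panel map")
  }
  if (is.null(fam)) {
    ids <- rownames(genotypes) %||% sprintf("id%04d", seq_len(nrow(genotypes)))
    fam <- tibble::tibble(fid = ids, iid = ids)
  }
  fam <- tibble::as_tibble(fam)
  stopifnot(nrow(fam) == nrow(genotypes))
  map$chr <- as.character(map$chr)
  map$pos <- as.integer(map$pos)
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- list(fam$iid, map$snp)
  structure(list(genotypes = genotypes, map = map, fam = fam),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' SNP identifiers of a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @return Character vector of SNP ids, in column order.
#' @export
panel_snps <- function(panel) panel$map$snp

#' Per-SNP summaries of a genotype panel
#'
#' `panel_maf()` returns minor allele frequencies (in `[0, 0.5]`),
#' `panel_missing_rate()` the fraction of missing calls, and `panel_hwe_p()`
#' a 1-df chi-squared goodness-of-fit p-value for Hardy-Weinberg equilibrium
#' computed from observed vs expected genotype counts (monomorphic SNPs
#' return 1).
#'
#' @param panel A [genotype_panel()].
#' @return Named numeric vector, one entry per SNP.
#' @export
panel_maf <- function(panel) {
  f <- colMeans(panel$genotypes, na.rm = TRUE) / 2
  setNames(pmin(f, 1 - f), panel$map$snp)
}

#' @rdname panel_maf
#' @export
panel_missing_rate <- function(panel) {
  setNames(colMeans(is.na(panel$genotypes)), panel$map$snp)
}

#' @rdname panel_maf
#' @export
panel_hwe_p <- function(panel) {
  g <- panel$genotypes
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2
  e1 <- 2 * n * p * q
  e2 <- n * p^2
  stat <- rep(0, length(n))
  ok <- p > 0 & p < 1 & n > 0
  stat[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  out <- ifelse(ok, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  setNames(out, panel$map$snp)
}

#' Subset a genotype panel by SNP id
#'
#' @param panel A [genotype_panel()].
#' @param snp_ids Character vector of SNP ids to keep (order preserved).
#' @return A new `genotype_panel`.
#' @export
panel_subset <- function(panel, snp_ids) {
  idx <- match(snp_ids, panel$map$snp)
  if (anyNA(idx)) {
    abort(sprintf("SNPs not in panel: %s",
                  paste(snp_ids[is.na(idx)], collapse = ", ")))
  }
  genotype_panel(panel$genotypes[, idx, drop = FALSE],
                 panel$map[idx, ], panel$fam)
}

# ---- PLINK 1 binary codec --------------------------------------------------
# .bed layout: 0x6c 0x1b magic, 0x01 = SNP-major mode, then ceiling(n/4)
# bytes per SNP; each byte packs 4 samples, 2 bits each, lowest-order pair
# first. Codes: 00 = hom A1 (2 copies of A1), 01 = missing, 10 = het,
# 11 = hom A2 (0 copies of A1).

plink_decode_table <- function() {
  code_to_count <- c(2L, NA_integer_, 1L, 0L)  # indices for codes 0..3
  tab <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      tab[b + 1L, k + 1L] <- code_to_count[code + 1L]
    }
  }
  tab
}

.plink_tab <- NULL

plink_tab <- function() {
  if (is.null(.plink_tab)) {
    # memoise in the package namespace; table is 1 KB
    assignInMyNamespace(".plink_tab", plink_decode_table())
  }
  .plink_tab
}

#' Read a PLINK-1 bed/bim/fam fileset into a genotype panel
#'
#' Decodes the SNP-major PLINK 1 binary genotype format and applies the usual
#' reference-panel QC filters: SNPs with minor allele frequency below
#' `maf_min`, Hardy-Weinberg goodness-of-fit p-value below `hwe_p_min`, or
#' missing-call rate above `missing_max` are dropped. Missing genotypes of
#' retained SNPs are kept as `NA`.
#'
#' @param prefix Path stem; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param hwe_p_min Minimum HWE test p-value (default 1e-6).
#' @param missing_max Maximum per-SNP missing rate (default 0.02).
#' @return A [genotype_panel()], genotypes coded as A1-allele counts.
#' @export
read_plink_panel <- function(prefix, maf_min = 0.01, hwe_p_min = 1e-6,
                             missing_max = 0.02) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  bim_df <- read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bim_df) < 6) abort(".bim must have 6 columns")
  map <- tibble::tibble(
    chr = bim_df[[1]], snp = bim_df[[2]],
    pos = as.integer(bim_df[[4]]), a1 = bim_df[[5]], a2 = bim_df[[6]]
  )
  fam_df <- read.table(fam, header = FALSE, colClasses = "character")
  fam_tb <- tibble::tibble(fid = fam_df[[1]], iid = fam_df[[2]])
  n <- nrow(fam_tb)
  m <- nrow(map)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK 1 .bed file (bad magic bytes)")
  }
  if (raw[3] == as.raw(0x00)) {
    abort("individual-major .bed files are not supported (mode byte 0x00)")
  }
  if (raw[3] != as.raw(0x01)) abort("unrecognised .bed mode byte")
  bytes_per_snp <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * m) {
    abort(sprintf(
      ".bed payload is %d bytes; expected %d for %d samples x %d SNPs",
      length(payload), bytes_per_snp * m, n, m
    ))
  }
  tab <- plink_tab()
  idx <- as.integer(payload) + 1L
  # decode all SNPs at once: (bytes_per_snp x m) bytes -> (4*bytes_per_snp x m)
  decoded <- matrix(t(tab[idx, , drop = FALSE]), nrow = 4L * bytes_per_snp,
                    ncol = m)
  geno <- decoded[seq_len(n), , drop = FALSE]
  panel <- genotype_panel(geno, map, fam_tb)
  apply_panel_qc(panel, maf_min = maf_min, hwe_p_min = hwe_p_min,
                 missing_max = missing_max)
}

#' Apply MAF / HWE / missingness filters to a panel
#'
#' The three filters are computed on the input panel and applied jointly, so
#' the result does not depend on the order in which they are listed.
#'
#' @inheritParams read_plink_panel
#' @param panel A [genotype_panel()].
#' @return The filtered `genotype_panel`.
#' @export
apply_panel_qc <- function(panel, maf_min = 0.01, hwe_p_min = 1e-6,
                           missing_max = 0.02) {
  keep <- panel_maf(panel) >= maf_min &
    panel_hwe_p(panel) >= hwe_p_min &
    panel_missing_rate(panel) <= missing_max
  keep[is.na(keep)] <- FALSE
  if (!all(keep)) {
    inform(sprintf("QC removed %d of %d SNPs", sum(!keep), length(keep)))
  }
  if (!any(keep)) abort("all SNPs removed by QC filters")
  panel_subset(panel, panel$map$snp[keep])
}

#' Write a genotype panel as a PLINK-1 bed/bim/fam fileset
#'
#' Inverse of [read_plink_panel()] (without QC): genotypes are encoded in the
#' SNP-major two-bit format, so a write/read round trip reproduces the
#' genotype matrix exactly.
#'
#' @param panel A [genotype_panel()].
#' @param prefix Output path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink_panel <- function(panel, prefix) {
  n <- nrow(panel$genotypes)
  m <- ncol(panel$genotypes)
  count_to_code <- function(g) {
    # A1 count -> 2-bit code
    code <- integer(length(g))
    code[is.na(g)] <- 1L
    code[!is.na(g) & g == 2L] <- 0L
    code[!is.na(g) & g == 1L] <- 2L
    code[!is.na(g) & g == 0L] <- 3L
    code
  }
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4L * bytes_per_snp - n
  codes <- count_to_code(panel$genotypes)  # column-major, length n*m
  codes <- matrix(codes, nrow = n, ncol = m)
  if (pad > 0) codes <- rbind(codes, matrix(0L, nrow = pad, ncol = m))
  k <- matrix(bitwShiftL(1L, 2L * ((seq_len(4L * bytes_per_snp) - 1L) %% 4L)),
              nrow = 4L * bytes_per_snp, ncol = m)
  shifted <- codes * k
  grp <- rep(seq_len(bytes_per_snp), each = 4L)
  bytes <- rowsum(shifted, group = grp)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  write.table(
    data.frame(panel$map$chr, panel$map$snp, 0L, panel$map$pos,
               panel$map$a1, panel$map$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  write.table(
    data.frame(panel$fam$fid, panel$fam$iid, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(prefix)
}
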