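#' Allele count matrix for an F2 cross
#'
#' Container for per-(F2, SNP) marine/freshwater read counts plus per-F2
#' total mapped-read counts. SNPs are rows, F2 individuals are columns.
#'
#' @param snps data.frame with columns `scaffold`, `pos` (1-based bp) and
#'   optionally `chromosome`, `chrom_pos` describing each SNP site.
#' @param m,f integer matrices (SNPs x F2s) of reads supporting the marine
#'   and freshwater allele respectively.
#' @param totals numeric vector of total mapped reads per F2 (normalisation
#'   denominator for reads-per-million-mapped).
#' @param f2 character vector of F2 identifiers (column names).
#'
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(snps, m, f, totals, f2 = colnames(m)) {
  stopifnot(is.data.frame(snps), all(c("scaffold", "pos") %in% names(snps)))
  m <- as.matrix(m); f <- as.matrix(f)
  if (!identical(dim(m), dim(f)))
    stop("marine and freshwater count matrices must have identical dimensions")
  if (nrow(m) != nrow(snps))
    stop("count matrices must have one row per SNP")
  if (is.null(f2)) f2 <- paste0("F2_", seq_len(ncol(m)))
  if (length(totals) != ncol(m))
    stop("need one total mapped-read count per F2")
  if (any(m < 0) || any(f < 0)) stop("negative read counts")
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1 (1-based)")
  dimnames(m) <- dimnames(f) <- list(NULL, f2)
  names(totals) <- f2
  structure(list(snps = snps, m = m, f = f, totals = as.numeric(totals),
                 f2 = f2),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d SNPs x %d F2s on %d scaffolds\n",
              nrow(x$snps), length(x$f2), length(unique(x$snps$scaffold))))
  tot <- sum(x$m) + sum(x$f)
  cat(sprintf("  total allele reads: %.0f (mean %.2fx per SNP per F2)\n",
              tot, tot / (nrow(x$snps) * length(x$f2))))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) c(nrow(x$snps), length(x$f2))

# subset an allele_counts by SNP row index (internal)
subset_snps <- function(counts, idx) {
  allele_counts(counts$snps[idx, , drop = FALSE],
                counts$m[idx, , drop = FALSE],
                counts$f[idx, , drop = FALSE],
                counts$totals, counts$f2)
}
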