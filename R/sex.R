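#' Call F2 sex from relative sex-chromosome sequencing depth
#'
#' XY fish carry a single X, so their sex-chromosome read depth is about
#' half their autosomal depth, while XX fish show equal depth. The depth
#' statistic is reads per SNP site on the sex chromosome divided by reads
#' per SNP site on the autosomes (equivalent to reads per Mb over the
#' SNP territory at uniform SNP density), which cancels per-fish
#' sequencing effort: the call is invariant to global coverage rescaling,
#' so even low-coverage samples separate cleanly.
#'
#' @param counts an [allele_counts()] object whose `snps` table carries a
#'   `chromosome` column (as produced by [simulate_cross()], or add one
#'   from a placement table).
#' @param sex_chromosome chromosome id of the sex chromosome.
#' @param thresholds `(xy_max, xx_min)`: ratio below the first is XY,
#'   above the second XX, in between "unknown" (dead zone guarding
#'   low-coverage edge cases).
#' @param min_reads minimum total sex-chromosome reads for any call;
#'   below it the call is "unknown".
#' @return data.frame of class `sex_calls`: `f2`, `depth_ratio`, `call`
#'   in {"XX", "XY", "unknown"}.
#' @export
call_sex <- function(counts, sex_chromosome, thresholds = c(0.65, 0.85),
                     min_reads = 200) {
  stopifnot(inherits(counts, "allele_counts"))
  if (!"chromosome" %in% names(counts$snps))
    stop("counts$snps needs a 'chromosome' column to locate the sex chromosome")
  on_sex <- counts$snps$chromosome == sex_chromosome
  if (!any(on_sex)) stop("no SNPs on sex chromosome ", sex_chromosome)
  if (all(on_sex)) stop("no autosomal SNPs to normalise against")
  tot <- counts$m + counts$f
  sex_reads <- colSums(tot[on_sex, , drop = FALSE])
  auto_reads <- colSums(tot[!on_sex, , drop = FALSE])
  ratio <- (sex_reads / sum(on_sex)) / (auto_reads / sum(!on_sex))
  call <- ifelse(ratio < thresholds[1], "XY",
                 ifelse(ratio > thresholds[2], "XX", "unknown"))
  call[sex_reads < min_reads] <- "unknown"
  out <- data.frame(f2 = counts$f2, depth_ratio = as.numeric(ratio),
                    call = call, stringsAsFactors = FALSE)
  class(out) <- c("sex_calls", "data.frame")
  out
}

#' Sex-aware genotype calls on the sex chromosome
#'
#' Re-calls sex-chromosome bins for XY fish under a haploid two-state
#' model (hemizygous M or F; the heterozygous state does not exist), with
#' freshwater-read probability `epsilon` (M) or `1 - epsilon` (F) and a
#' uniform prior. Calls requiring less than `call_posterior` posterior
#' mass, or counts inconsistent with haploidy (e.g. balanced reads), come
#' out missing. XX fish pass through unchanged; fish of unknown sex get
#' missing sex-chromosome genotypes.
#'
#' @param geno a `bin_geno` object.
#' @param sex_calls output of [call_sex()].
#' @param sex_scaffolds character vector of scaffold ids on the sex
#'   chromosome.
#' @param config a [geno_config()].
#' @return the `bin_geno` object with sex-chromosome calls for XY fish
#'   replaced by "M"/"F"/`NA`.
#' @export
sex_aware_genotypes <- function(geno, sex_calls, sex_scaffolds,
                                config = geno_config()) {
  stopifnot(inherits(geno, "bin_geno"))
  rows <- which(geno$markers$scaffold %in% sex_scaffolds)
  if (length(rows) == 0) return(geno)
  call <- sex_calls$call[match(colnames(geno$calls), sex_calls$f2)]
  xy <- which(call == "XY")
  unk <- which(call == "unknown" | is.na(call))
  e <- config$epsilon
  for (j in xy) {
    m <- geno$m[rows, j]; f <- geno$f[rows, j]
    n <- m + f
    llM <- stats::dbinom(f, n, e, log = TRUE)
    llF <- stats::dbinom(f, n, 1 - e, log = TRUE)
    pF <- 1 / (1 + exp(llM - llF))
    g <- ifelse(pF >= config$call_posterior, "F",
                ifelse(1 - pF >= config$call_posterior, "M", NA))
    g[n < config$min_reads] <- NA
    geno$calls[rows, j] <- g
  }
  if (length(unk) > 0) geno$calls[rows, unk] <- NA
  geno
}
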