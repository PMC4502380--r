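#' Binning configuration
#'
#' @param max_bin_bp largest allowed bin for large scaffolds (default
#'   500 kb).
#' @param small_scaffold_bp scaffolds below this get a single bin
#'   (default 100 kb).
#' @param two_bin_upper_bp scaffolds between `small_scaffold_bp` and this
#'   get two equal bins (default 1 Mb).
#' @return list of class `binning_config`.
#' @export
binning_config <- function(max_bin_bp = 5e5, small_scaffold_bp = 1e5,
                           two_bin_upper_bp = 1e6) {
  if (!(small_scaffold_bp > 0 && small_scaffold_bp < two_bin_upper_bp &&
          max_bin_bp > 0))
    stop("binning thresholds must be positive and ordered")
  structure(list(max_bin_bp = max_bin_bp, small_scaffold_bp = small_scaffold_bp,
                 two_bin_upper_bp = two_bin_upper_bp),
            class = "binning_config")
}

#' Number of equal-size bins for a scaffold
#'
#' Scaffolds under 100 kb form one bin; 100 kb -- 1 Mb, two equal bins;
#' at or above 1 Mb, `floor(length / 500 kb) + 1` bins (three bins for
#' 1--1.5 Mb, four for 1.5--2 Mb, and so on), which keeps every bin at or
#' under 500 kb.
#'
#' @param length_bp scaffold length(s) in bp (vectorised).
#' @param config a [binning_config()].
#' @return integer vector of bin counts.
#' @export
n_bins_for_scaffold <- function(length_bp, config = binning_config()) {
  if (any(length_bp <= 0)) stop("scaffold length must be positive")
  ifelse(length_bp < config$small_scaffold_bp, 1L,
         ifelse(length_bp < config$two_bin_upper_bp, 2L,
                as.integer(length_bp %/% config$max_bin_bp) + 1L))
}

#' Assign sieve-passing SNPs to scaffold bins
#'
#' Splits every scaffold into its [n_bins_for_scaffold()] equal spans
#' (lengths equal to within 1 bp, covering the scaffold) and assigns each
#' SNP to the span containing its position. Bins with no SNPs are
#' retained with `n_snps = 0`.
#'
#' @param snps data.frame with `scaffold`, `pos` of kept SNPs.
#' @param scaffold_lengths named vector of scaffold lengths (bp).
#' @param config a [binning_config()].
#' @return list with `bins` (data.frame `marker`, `scaffold`,
#'   `bin_index` 0-based, `start`, `end`, `n_snps`) and `snp_bin`
#'   (integer index into `bins` for each SNP row). Marker names follow
#'   the `scaffold_bin` convention (e.g. `"17_8"` is bin 8 of scaffold
#'   17, 0-based).
#' @export
assign_bins <- function(snps, scaffold_lengths, config = binning_config()) {
  if (is.null(names(scaffold_lengths))) stop("scaffold_lengths must be named")
  bad <- !(snps$scaffold %in% names(scaffold_lengths))
  if (any(bad))
    stop("SNP scaffold(s) missing from scaffold_lengths: ",
         paste(unique(snps$scaffold[bad]), collapse = ", "))
  over <- snps$pos > scaffold_lengths[snps$scaffold]
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("SNP at %s:%d lies beyond scaffold end (%d bp)",
                 snps$scaffold[i], snps$pos[i],
                 as.integer(scaffold_lengths[[snps$scaffold[i]]])))
  }
  bins <- do.call(rbind, lapply(names(scaffold_lengths), function(s) {
    L <- scaffold_lengths[[s]]
    nb <- n_bins_for_scaffold(L, config)
    brk <- floor(seq_len(nb) * L / nb)        # inclusive ends
    start <- c(1, brk[-nb] + 1)
    data.frame(marker = paste(sub("^S", "", s), seq_len(nb) - 1L, sep = "_"),
               scaffold = s, bin_index = seq_len(nb) - 1L,
               start = start, end = brk, stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  # SNP -> bin: index within scaffold via span arithmetic
  key <- paste(bins$scaffold, bins$bin_index)
  nb_of <- n_bins_for_scaffold(scaffold_lengths, config)
  L_of <- scaffold_lengths[snps$scaffold]
  nb_s <- nb_of[snps$scaffold]
  bidx <- pmin(nb_s - 1L, floor((snps$pos - 1) * nb_s / L_of))
  # guard against edge effects of the floor-based span ends
  snp_bin <- match(paste(snps$scaffold, bidx), key)
  wrong <- snps$pos > bins$end[snp_bin]
  snp_bin[wrong] <- snp_bin[wrong] + 1L
  wrong <- snps$pos < bins$start[snp_bin]
  snp_bin[wrong] <- snp_bin[wrong] - 1L
  bins$n_snps <- tabulate(snp_bin, nbins = nrow(bins))
  list(bins = bins, snp_bin = snp_bin)
}

#' Genotype-calling configuration
#'
#' @param epsilon per-read mis-allele probability.
#' @param prior genotype prior over (MM, MF, FF); 1:2:1 for an F2.
#' @param call_posterior posterior mass required for a call.
#' @param min_reads minimum pooled reads for a non-missing call.
#' @return list of class `geno_config`.
#' @export
geno_config <- function(epsilon = 0.02, prior = c(0.25, 0.5, 0.25),
                        call_posterior = 0.95, min_reads = 3) {
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  if (abs(sum(prior) - 1) > 1e-8) stop("prior must sum to 1")
  structure(list(epsilon = epsilon, prior = prior,
                 call_posterior = call_posterior, min_reads = min_reads),
            class = "geno_config")
}

GENO_STATES <- c("MM", "MF", "FF")

# posterior over (MM, MF, FF) for pooled counts; vectorised over m, f
bin_posterior <- function(m, f, config = geno_config()) {
  e <- config$epsilon
  n <- m + f
  ll <- cbind(stats::dbinom(f, n, e, log = TRUE),
              stats::dbinom(f, n, 0.5, log = TRUE),
              stats::dbinom(f, n, 1 - e, log = TRUE))
  ll <- sweep(ll, 2, log(config$prior), "+")
  mx <- apply(ll, 1, max)
  w <- exp(ll - mx)
  w / rowSums(w)
}

#' Call a binned genotype from pooled allele counts
#'
#' Binomial likelihoods with freshwater-read probability `epsilon` (MM),
#' 0.5 (MF) and `1 - epsilon` (FF) are combined with a 1:2:1 prior. The
#' top state is called when its posterior reaches `call_posterior`;
#' otherwise an adjacent pair (MM,MF) or (MF,FF) jointly reaching it
#' yields the composite calls `"MM/MF"` / `"MF/FF"` seen in bins spanning
#' a recombination breakpoint; anything else, or fewer than `min_reads`
#' pooled reads, is missing (`NA`).
#'
#' @param m,f pooled marine / freshwater read counts (vectorised).
#' @param config a [geno_config()].
#' @return list with `call` (character vector) and `posterior` (matrix
#'   with columns MM, MF, FF).
#' @export
call_bin_genotype <- function(m, f, config = geno_config()) {
  post <- bin_posterior(m, f, config)
  colnames(post) <- GENO_STATES
  top <- max.col(post, ties.method = "first")
  call <- GENO_STATES[top]
  pmax_ <- post[cbind(seq_along(m), top)]
  tau <- config$call_posterior
  amb <- pmax_ < tau
  mmmf <- amb & (post[, 1] + post[, 2] >= tau)
  mfff <- amb & !mmmf & (post[, 2] + post[, 3] >= tau)
  call[mmmf] <- "MM/MF"
  call[mfff] <- "MF/FF"
  call[amb & !mmmf & !mfff] <- NA
  call[(m + f) < config$min_reads] <- NA
  list(call = call, posterior = post)
}

#' Pool SNP counts into bin markers and call genotypes
#'
#' @param counts an [allele_counts()] object restricted to kept SNPs.
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param bin_config a [binning_config()].
#' @param gconfig a [geno_config()].
#' @return object of class `bin_geno`: `markers` (bin table from
#'   [assign_bins()]), `m`, `f` (pooled count matrices, markers x F2s),
#'   `calls` (character matrix), `posterior` (markers x F2s x 3 array),
#'   `f2`.
#' @export
bin_genotypes <- function(counts, scaffold_lengths,
                          bin_config = binning_config(),
                          gconfig = geno_config()) {
  ab <- assign_bins(counts$snps, scaffold_lengths, bin_config)
  nb <- nrow(ab$bins); nf <- length(counts$f2)
  grp <- factor(ab$snp_bin, levels = seq_len(nb))
  pool <- function(x) {
    out <- rowsum(x, grp, reorder = TRUE)
    idx <- as.integer(rownames(out))
    full <- matrix(0, nb, nf, dimnames = list(ab$bins$marker, counts$f2))
    full[idx, ] <- out
    full
  }
  m <- pool(counts$m); f <- pool(counts$f)
  cb <- call_bin_genotype(as.vector(m), as.vector(f), gconfig)
  calls <- matrix(cb$call, nb, nf, dimnames = list(ab$bins$marker, counts$f2))
  post <- array(cb$posterior, dim = c(nb, nf, 3),
                dimnames = list(ab$bins$marker, counts$f2, GENO_STATES))
  structure(list(markers = ab$bins, m = m, f = f, calls = calls,
                 posterior = post, f2 = counts$f2,
                 geno_config = gconfig),
            class = "bin_geno")
}

#' @export
print.bin_geno <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  comp <- mean(x$calls %in% c("MM/MF", "MF/FF"))
  cat(sprintf("bin_geno: %d markers x %d F2s (%.1f%% missing, %.1f%% composite)\n",
              nrow(x$markers), length(x$f2), 100 * miss, 100 * comp))
  cat(sprintf("  mean pooled coverage: %.0fx per marker per F2\n",
              mean(x$m + x$f)))
  invisible(x)
}

# chi-square statistic vs 1:2:1 on hard-call counts (internal)
seg_chisq_p <- function(n_mm, n_mf, n_ff) {
  n <- n_mm + n_mf + n_ff
  exp_ <- cbind(n / 4, n / 2, n / 4)
  obs <- cbind(n_mm, n_mf, n_ff)
  stat <- rowSums((obs - exp_)^2 / exp_)
  ifelse(n > 0, stats::pchisq(stat, df = 2, lower.tail = FALSE), NA_real_)
}

#' Marker / fish quality control
#'
#' Applied in a fixed order: (1) fish with more than `max_fish_missing`
#' missing genotypes are dropped (fish-level missingness would otherwise
#' inflate marker missingness); (2) markers missing in at least
#' `max_marker_missing` of the remaining fish are dropped; (3) markers
#' whose hard-call MM:MF:FF counts fail a chi-square test against 1:2:1
#' at `ratio_alpha` are dropped unless an adjacent marker on the same
#' scaffold is skewed in the same direction (the marker-level analogue of
#' the SNP skew rescue, protecting genuinely distorted regions).
#'
#' @param geno a `bin_geno` object.
#' @param max_fish_missing fish dropped when missing fraction exceeds
#'   this (default 0.5, strict inequality: "more than 50%").
#' @param max_marker_missing markers dropped when missing fraction is at
#'   least this (default 0.2, inclusive: "at least 20%").
#' @param ratio_alpha chi-square level for the aberrant-ratio drop.
#' @return list with `geno` (filtered `bin_geno`) and `drop_log`
#'   (data.frame `id`, `type`, `reason`).
#' @export
apply_qc <- function(geno, max_fish_missing = 0.5, max_marker_missing = 0.2,
                     ratio_alpha = 0.001) {
  stopifnot(inherits(geno, "bin_geno"))
  calls <- geno$calls
  log <- data.frame(id = character(0), type = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  # 1. fish
  fish_miss <- colMeans(is.na(calls))
  drop_f <- fish_miss > max_fish_missing
  if (any(drop_f))
    log <- rbind(log, data.frame(id = geno$f2[drop_f], type = "fish",
                                 reason = sprintf("missing %.0f%% of markers",
                                                  100 * fish_miss[drop_f]),
                                 stringsAsFactors = FALSE))
  keep_f <- !drop_f
  calls <- calls[, keep_f, drop = FALSE]
  # 2. marker missingness
  mk_miss <- rowMeans(is.na(calls))
  drop_m <- mk_miss >= max_marker_missing
  # 3. aberrant allelic ratio with adjacency rescue
  n_mm <- rowSums(calls == "MM", na.rm = TRUE)
  n_mf <- rowSums(calls == "MF", na.rm = TRUE)
  n_ff <- rowSums(calls == "FF", na.rm = TRUE)
  pval <- seg_chisq_p(n_mm, n_mf, n_ff)
  frac_f <- (n_mf + 2 * n_ff) / (2 * (n_mm + n_mf + n_ff))
  aberrant <- !drop_m & !is.na(pval) & pval <= ratio_alpha
  dirn <- sign(frac_f - 0.5)
  drop_r <- rep(FALSE, nrow(calls))
  for (i in which(aberrant)) {
    s <- geno$markers$scaffold[i]
    nb <- which(geno$markers$scaffold == s & !drop_m &
                  abs(geno$markers$bin_index - geno$markers$bin_index[i]) == 1)
    rescued <- any(aberrant[nb] & dirn[nb] == dirn[i])
    if (!rescued) drop_r[i] <- TRUE
  }
  if (any(drop_m))
    log <- rbind(log, data.frame(id = geno$markers$marker[drop_m],
                                 type = "marker",
                                 reason = sprintf("missing in %.0f%% of fish",
                                                  100 * mk_miss[drop_m]),
                                 stringsAsFactors = FALSE))
  if (any(drop_r))
    log <- rbind(log, data.frame(id = geno$markers$marker[drop_r],
                                 type = "marker",
                                 reason = "aberrant allelic ratio (1:2:1 chi-square)",
                                 stringsAsFactors = FALSE))
  keep_m <- !drop_m & !drop_r
  out <- geno
  out$markers <- geno$markers[keep_m, , drop = FALSE]
  out$m <- geno$m[keep_m, keep_f, drop = FALSE]
  out$f <- geno$f[keep_m, keep_f, drop = FALSE]
  out$calls <- geno$calls[keep_m, keep_f, drop = FALSE]
  out$posterior <- geno$posterior[keep_m, keep_f, , drop = FALSE]
  out$f2 <- geno$f2[keep_f]
  message(sprintf("qc: dropped %d fish, %d markers (%d missingness, %d ratio)",
                  sum(drop_f), sum(drop_m) + sum(drop_r), sum(drop_m), sum(drop_r)))
  list(geno = out, drop_log = log)
}

#' Expected freshwater dosage per call (0, 0.5, 1 scale)
#'
#' Posterior-mean freshwater allele dosage of each genotype entry, used
#' for read-correlation placement and Haley-Knott regression.
#'
#' @param geno a `bin_geno` object.
#' @param use_posterior if `TRUE` use the stored posteriors; otherwise map
#'   hard calls MM, MF, FF, MM/MF, MF/FF to 0, 0.5, 1, 0.25, 0.75.
#' @return numeric matrix (markers x F2s) with `NA` at missing calls.
#' @export
genotype_dosage <- function(geno, use_posterior = TRUE) {
  if (use_posterior && !is.null(geno$posterior)) {
    d <- (geno$posterior[, , "MF"] * 0.5 + geno$posterior[, , "FF"])
    d <- matrix(d, nrow(geno$calls), ncol(geno$calls),
                dimnames = dimnames(geno$calls))
    d[is.na(geno$calls)] <- NA
    return(d)
  }
  map <- c(MM = 0, MF = 0.5, FF = 1, `MM/MF` = 0.25, `MF/FF` = 0.75,
           M = 0, F = 1)
  d <- matrix(map[geno$calls], nrow(geno$calls), ncol(geno$calls),
              dimnames = dimnames(geno$calls))
  d
}
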