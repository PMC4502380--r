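#' Sieve configuration
#'
#' Bounds for the allele-ratio / coverage sieve applied to candidate SNPs.
#' A SNP passes when its pooled freshwater allele fraction lies in
#' `[min_fraction, max_fraction]` (the 4:1 -- 1:4 marine/freshwater RPMM
#' ratio rule expressed on the fraction scale) and its total RPMM lies in
#' `[min_total_rpmm, max_total_rpmm]`. Bounds are inclusive.
#'
#' @param min_fraction,max_fraction freshwater allele-fraction bounds.
#' @param min_total_rpmm,max_total_rpmm total (marine + freshwater) RPMM
#'   bounds; the upper bound drops over-covered, likely repetitive sites.
#' @param skew_window bp window within which a skewed SNP may be rescued
#'   by a similarly skewed neighbour.
#' @param skew_test_alpha two-sided binomial-test level declaring a SNP's
#'   pooled fraction significantly different from 0.5 ("skewed").
#' @param weighted if `TRUE` (default) RPMM is the pooled ratio (per-F2
#'   totals as weights); if `FALSE`, the unweighted mean of per-F2
#'   normalised counts.
#' @return list of class `sieve_config`.
#' @export
sieve_config <- function(min_fraction = 0.2, max_fraction = 0.8,
                         min_total_rpmm = 0.2, max_total_rpmm = 3.0,
                         skew_window = 1e6, skew_test_alpha = 0.001,
                         weighted = TRUE) {
  if (!(min_fraction >= 0 && min_fraction < max_fraction && max_fraction <= 1))
    stop("need 0 <= min_fraction < max_fraction <= 1")
  if (!(min_total_rpmm >= 0 && min_total_rpmm < max_total_rpmm))
    stop("need 0 <= min_total_rpmm < max_total_rpmm")
  structure(list(min_fraction = min_fraction, max_fraction = max_fraction,
                 min_total_rpmm = min_total_rpmm, max_total_rpmm = max_total_rpmm,
                 skew_window = skew_window, skew_test_alpha = skew_test_alpha,
                 weighted = weighted),
            class = "sieve_config")
}

#' Identify phased homozygous-difference SNPs from grandparent genotypes
#'
#' Retains exactly the sites where one grandparent is homozygous for one
#' allele and the other grandparent is homozygous for a different allele,
#' phasing alleles marine/freshwater by the grandparent population labels.
#' Sites with a missing grandparent call are skipped, not errors.
#'
#' @param grandparents data.frame with columns `scaffold`, `pos`,
#'   `marine_gt`, `freshwater_gt`; genotypes as "A/A"-style strings
#'   (missing: `NA`, "" or "./.").
#' @return data.frame of retained sites: `scaffold`, `pos`,
#'   `marine_allele`, `freshwater_allele`.
#' @export
identify_homozygous_snps <- function(grandparents) {
  stopifnot(all(c("scaffold", "pos", "marine_gt", "freshwater_gt") %in%
                  names(grandparents)))
  split_gt <- function(gt) {
    gt[is.na(gt) | gt == "" | gt == "./."] <- NA
    parts <- strsplit(gt, "/", fixed = TRUE)
    a1 <- vapply(parts, function(p) if (length(p) == 2) p[1] else NA_character_,
                 character(1))
    a2 <- vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_,
                 character(1))
    list(a1 = a1, a2 = a2)
  }
  m <- split_gt(grandparents$marine_gt)
  f <- split_gt(grandparents$freshwater_gt)
  keep <- !is.na(m$a1) & !is.na(f$a1) &
    m$a1 == m$a2 & f$a1 == f$a2 & m$a1 != f$a1
  data.frame(scaffold = grandparents$scaffold[keep],
             pos = grandparents$pos[keep],
             marine_allele = m$a1[keep], freshwater_allele = f$a1[keep],
             stringsAsFactors = FALSE)
}

#' Reads per million mapped (RPMM) per SNP
#'
#' For each SNP, pools allele read counts across F2s normalised by total
#' mapped reads and scales by 1e6: the default weighted form is
#' `RPMM_a = 1e6 * sum_i(c_ai) / sum_i(T_i)`, i.e. the T-weighted mean of
#' per-F2 normalised counts. F2s with zero total mapped reads are excluded
#' from the sums with a warning.
#'
#' @param counts an [allele_counts()] object.
#' @param config a [sieve_config()]; `config$weighted = FALSE` selects the
#'   unweighted mean of per-F2 `1e6 * c_ai / T_i`.
#' @return data.frame with one row per SNP: `scaffold`, `pos`,
#'   `rpmm_marine`, `rpmm_freshwater`, `fraction` (freshwater /(total);
#'   `NA` when total RPMM is zero), plus pooled raw counts `m_total`,
#'   `f_total` (used by the skew test).
#' @export
compute_rpmm <- function(counts, config = sieve_config()) {
  stopifnot(inherits(counts, "allele_counts"))
  ok <- counts$totals > 0
  if (!all(ok)) {
    warning(sprintf("%d F2(s) with zero total mapped reads excluded: %s",
                    sum(!ok), paste(counts$f2[!ok], collapse = ", ")))
  }
  m <- counts$m[, ok, drop = FALSE]
  f <- counts$f[, ok, drop = FALSE]
  Tt <- counts$totals[ok]
  if (config$weighted) {
    rm_ <- 1e6 * rowSums(m) / sum(Tt)
    rf_ <- 1e6 * rowSums(f) / sum(Tt)
  } else {
    rm_ <- 1e6 * rowMeans(sweep(m, 2, Tt, "/"))
    rf_ <- 1e6 * rowMeans(sweep(f, 2, Tt, "/"))
  }
  tot <- rm_ + rf_
  frac <- ifelse(tot > 0, rf_ / tot, NA_real_)
  data.frame(scaffold = counts$snps$scaffold, pos = counts$snps$pos,
             rpmm_marine = rm_, rpmm_freshwater = rf_, fraction = frac,
             m_total = rowSums(counts$m[, ok, drop = FALSE]),
             f_total = rowSums(counts$f[, ok, drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Apply the allele-ratio / coverage sieve
#'
#' @param records data.frame from [compute_rpmm()].
#' @param config a [sieve_config()].
#' @return logical vector: `TRUE` where the SNP passes both the fraction
#'   and the total-RPMM criterion (inclusive bounds); SNPs with undefined
#'   fraction fail.
#' @export
apply_sieve <- function(records, config = sieve_config()) {
  tot <- records$rpmm_marine + records$rpmm_freshwater
  pass <- !is.na(records$fraction) &
    records$fraction >= config$min_fraction &
    records$fraction <= config$max_fraction &
    tot >= config$min_total_rpmm & tot <= config$max_total_rpmm
  pass
}

# vectorised two-sided exact binomial p-value for f successes of n at p=0.5
binom_p2 <- function(f, n) {
  p <- 2 * pmin(stats::pbinom(f, n, 0.5),
                stats::pbinom(n - f, n, 0.5))
  pmin(p, 1)
}

#' Remove isolated skewed SNPs, keeping genuinely distorted regions
#'
#' A sieve-passing SNP whose pooled freshwater fraction differs
#' significantly from 0.5 (two-sided binomial test at
#' `config$skew_test_alpha`) is kept only if at least one of its nearest
#' flanking SNPs on the same scaffold, within `config$skew_window` bp, is
#' skewed in the same direction. Regions of true segregation distortion
#' (runs of similarly skewed SNPs) therefore survive, while isolated
#' skewed SNPs -- likely mapping or genotyping artefacts -- are removed.
#' Non-skewed SNPs are unaffected.
#'
#' @param records data.frame from [compute_rpmm()], ordered by scaffold
#'   and position.
#' @param pass logical vector from [apply_sieve()].
#' @param config a [sieve_config()].
#' @return logical keep vector (same length as `pass`); `FALSE` wherever
#'   `pass` was `FALSE`.
#' @export
rescue_skewed_snps <- function(records, pass, config = sieve_config()) {
  keep <- pass
  n <- records$m_total + records$f_total
  pval <- binom_p2(records$f_total, n)
  skewed <- pass & !is.na(records$fraction) & n > 0 &
    pval <= config$skew_test_alpha
  dir <- sign(records$fraction - 0.5)
  for (s in unique(records$scaffold[skewed])) {
    idx <- which(records$scaffold == s & pass)  # candidates in positional order
    if (length(idx) < 2) {
      keep[idx[skewed[idx]]] <- FALSE
      next
    }
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (!skewed[i]) next
      ok <- FALSE
      if (j > 1) {
        l <- idx[j - 1]
        ok <- skewed[l] && dir[l] == dir[i] &&
          (records$pos[i] - records$pos[l]) <= config$skew_window
      }
      if (!ok && j < length(idx)) {
        r <- idx[j + 1]
        ok <- skewed[r] && dir[r] == dir[i] &&
          (records$pos[r] - records$pos[i]) <= config$skew_window
      }
      if (!ok) keep[i] <- FALSE
    }
  }
  keep
}

#' Run the full SNP sieve
#'
#' Convenience wrapper: RPMM computation, quadrilateral sieve, and skew
#' rescue in one call, with per-stage counts reported via `message()`.
#'
#' @inheritParams compute_rpmm
#' @return list with `records` (RPMM table), `pass` (sieve flags) and
#'   `keep` (final keep flags after skew rescue).
#' @export
sieve_snps <- function(counts, config = sieve_config()) {
  records <- compute_rpmm(counts, config)
  pass <- apply_sieve(records, config)
  keep <- rescue_skewed_snps(records, pass, config)
  message(sprintf("sieve: %d SNPs in, %d pass ratio/coverage, %d kept after skew rescue",
                  nrow(records), sum(pass), sum(keep)))
  list(records = records, pass = pass, keep = keep)
}
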