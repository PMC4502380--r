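#' Percent variance explained from a LOD score
#'
#' `PVE = 100 * (1 - 10^(-2 * LOD / n))`, the coefficient of
#' determination implied by a likelihood-ratio LOD from an n-individual
#' regression scan.
#'
#' @param lod LOD score(s).
#' @param n number of individuals in the fit.
#' @return PVE in percent (vectorised).
#' @export
pve_from_lod <- function(lod, n) 100 * (1 - 10^(-2 * lod / n))

#' Adjust a phenotype for size and sex
#'
#' Optionally log-transforms, then removes standard length and/or sex by
#' ordinary least squares, re-centring residuals at the grand mean so the
#' adjusted trait keeps its original scale.
#'
#' @param values raw phenotype values.
#' @param covariates data.frame with any of `standard_length`, `sex`
#'   (rows matching `values`); `NULL` to only log/centre.
#' @param log_transform log-transform first (values must be positive).
#' @return numeric vector of adjusted values (`NA` where inputs are
#'   missing).
#' @export
adjust_phenotype <- function(values, covariates = NULL, log_transform = FALSE) {
  y <- values
  if (log_transform) {
    bad <- !is.na(y) & y <= 0
    if (any(bad))
      stop("log transform impossible for non-positive values at rows: ",
           paste(which(bad), collapse = ", "))
    y <- log(y)
  }
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(y - mean(y, na.rm = TRUE) + mean(y, na.rm = TRUE))
  cv <- as.data.frame(covariates)
  use <- intersect(c("standard_length", "sex"), names(cv))
  # constant covariates (e.g. a single-sex cross) carry no information
  use <- use[vapply(cv[use], function(x) length(unique(x[!is.na(x)])) > 1,
                    logical(1))]
  if (length(use) == 0) return(y)
  dat <- cbind(data.frame(.y = y), cv[use])
  fit <- stats::lm(.y ~ ., data = dat, na.action = stats::na.exclude)
  as.numeric(stats::residuals(fit)) + mean(y, na.rm = TRUE)
}

#' Genotype probabilities at markers for Haley-Knott regression
#'
#' Hard calls contribute their (near-degenerate) calling posteriors;
#' missing and composite calls are replaced by smoothed posteriors from
#' the three-state recombination HMM run across each linkage group at
#' marker resolution (genetic distances drive the transitions), or by
#' the 1:2:1 prior when no map is supplied.
#'
#' @param geno a `bin_geno` object.
#' @param map optional `linkage_map` for HMM smoothing; markers are
#'   returned in map order when given.
#' @return list with `probs` (markers x F2s x 3 array) and `markers`
#'   (data.frame `marker`, `group`, `cM`).
#' @export
hk_probs <- function(geno, map = NULL) {
  if (is.null(map)) {
    probs <- geno$posterior
    miss <- is.na(geno$calls)
    for (s in 1:3) {
      pl <- probs[, , s]; pl[miss] <- c(0.25, 0.5, 0.25)[s]; probs[, , s] <- pl
    }
    mk <- data.frame(marker = rownames(geno$calls), group = NA_character_,
                     cM = NA_real_, stringsAsFactors = FALSE)
    return(list(probs = probs, markers = mk))
  }
  idx <- match(map$marker, rownames(geno$calls))
  probs <- geno$posterior[idx, , , drop = FALSE]
  need <- is.na(geno$calls[idx, , drop = FALSE]) |
    geno$calls[idx, , drop = FALSE] %in% c("MM/MF", "MF/FF")
  for (g in unique(map$group)) {
    rows <- which(map$group == g)
    if (length(rows) < 2) next
    pos <- map$cM[rows] * 1e6          # cM expressed as "bp" with rho = 1
    ord <- order(pos)
    spec <- hmm_spec(rho = 1, epsilon = geno$geno_config$epsilon)
    for (j in seq_len(dim(probs)[2])) {
      if (!any(need[rows, j])) next
      dec <- decode_chromosome(geno$m[idx[rows][ord], j],
                               geno$f[idx[rows][ord], j], pos[ord], spec)
      repl <- which(need[rows, j])
      for (s in 1:3)
        probs[rows[repl], j, s] <- dec$posterior[match(repl, ord), s]
    }
  }
  list(probs = probs,
       markers = data.frame(marker = map$marker, group = map$group,
                            cM = map$cM, stringsAsFactors = FALSE))
}

# centred additive/dominance dosage matrices (n_fish x K) from a prob
# array; returns the sufficient statistics for the projection identity
hk_design <- function(probs) {
  A <- t(probs[, , 2] * 1 + probs[, , 3] * 2)  # expected freshwater dosage
  D <- t(probs[, , 2])                         # heterozygosity probability
  list(A = A, D = D)
}

# vectorised Haley-Knott LOD for one or more phenotype columns
# probs: K x n x 3; Y: n x P matrix (no NAs)
hk_lod_matrix <- function(probs, Y) {
  ds <- hk_design(probs)
  n <- nrow(ds$A)
  Ac <- scale(ds$A, scale = FALSE)
  Dc <- scale(ds$D, scale = FALSE)
  Saa <- colSums(Ac^2); Sdd <- colSums(Dc^2); Sad <- colSums(Ac * Dc)
  det <- Saa * Sdd - Sad^2
  Yc <- scale(Y, scale = FALSE)
  Syy <- colSums(Yc^2)
  Say <- crossprod(Ac, Yc)             # K x P
  Sdy <- crossprod(Dc, Yc)
  K <- ncol(Ac); P <- ncol(Yc)
  expl <- matrix(0, K, P)
  full <- det > 1e-10 * pmax(Saa, 1) * pmax(Sdd, 1)
  if (any(full))
    expl[full, ] <- (Sdd[full] * Say[full, , drop = FALSE]^2 -
                       2 * Sad[full] * Say[full, , drop = FALSE] *
                       Sdy[full, , drop = FALSE] +
                       Saa[full] * Sdy[full, , drop = FALSE]^2) / det[full]
  single <- !full & Saa > 1e-10
  if (any(single))
    expl[single, ] <- Say[single, , drop = FALSE]^2 / Saa[single]
  rss0 <- matrix(Syy, K, P, byrow = TRUE)
  rss1 <- pmax(rss0 - expl, 1e-300)
  lod <- (n / 2) * log10(rss0 / rss1)
  lod[rss0 == 0] <- 0                  # constant phenotype
  lod
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' At every marker the (adjusted) phenotype is regressed on the expected
#' additive and dominance dosages derived from genotype probabilities;
#' `LOD = (n/2) log10(RSS0 / RSS1)`.
#'
#' @param hk output of [hk_probs()] (or a list with `probs`, `markers`).
#' @param phenotype numeric phenotype vector (one per F2; fish with `NA`
#'   are dropped from the whole scan).
#' @return data.frame of class `scan_result`: `marker`, `group`, `cM`,
#'   `lod`, with attribute `n` (fish used).
#' @export
scanone_hk <- function(hk, phenotype) {
  ok <- !is.na(phenotype)
  probs <- hk$probs[, ok, , drop = FALSE]
  lod <- hk_lod_matrix(probs, matrix(phenotype[ok], ncol = 1))[, 1]
  out <- data.frame(marker = hk$markers$marker, group = hk$markers$group,
                    cM = hk$markers$cM, lod = lod, stringsAsFactors = FALSE)
  structure(out, class = c("scan_result", "data.frame"), n = sum(ok))
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d markers, n = %d; max LOD %.2f at %s\n",
              nrow(x), attr(x, "n"), max(x$lod), x$marker[which.max(x$lod)]))
  if (!is.null(attr(x, "threshold")))
    cat(sprintf("  genome-wide threshold (alpha = %.2f): %.2f\n",
                attr(x, "alpha"), attr(x, "threshold")))
  invisible(x)
}

#' Genome-wide permutation significance threshold
#'
#' The `1 - alpha` quantile of the genome-wide maximum LOD over
#' phenotype permutations, seeded and reproducible.
#'
#' @inheritParams scanone_hk
#' @param n_perm number of permutations (at least 20; the default 1000
#'   matches standard practice).
#' @param alpha genome-wide significance level.
#' @param seed integer seed.
#' @return the threshold (numeric), with the permutation maxima as
#'   attribute `max_lods`.
#' @export
permutation_threshold <- function(hk, phenotype, n_perm = 1000, alpha = 0.05,
                                  seed = 1L) {
  if (n_perm < 20) stop("n_perm < 20 gives an unstable quantile; refuse")
  ok <- !is.na(phenotype)
  y <- phenotype[ok]
  probs <- hk$probs[, ok, , drop = FALSE]
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  lod <- hk_lod_matrix(probs, Y)
  mx <- apply(lod, 2, max)
  structure(as.numeric(stats::quantile(mx, 1 - alpha)), max_lods = mx)
}

#' Summarise significant QTL from a scan
#'
#' For every linkage group whose maximum LOD reaches the threshold:
#' peak marker, 1.5-LOD support interval (outermost markers on the group
#' within 1.5 LOD of the peak), percent variance explained, and
#' genotype-class phenotype means +/- SE from hard calls at the peak
#' marker (composite calls excluded from the means).
#'
#' @param scan a `scan_result`.
#' @param geno the `bin_geno` the scan used.
#' @param phenotype the scanned phenotype vector.
#' @param threshold genome-wide LOD threshold.
#' @return data.frame, one row per significant QTL (zero rows when
#'   nothing reaches the threshold): group, peak/left/right markers and
#'   cM, `lod`, `n`, `pve`, class means and SEs.
#' @export
summarize_qtl <- function(scan, geno, phenotype, threshold) {
  n <- attr(scan, "n")
  rows <- list()
  for (g in unique(scan$group)) {
    sc <- scan[scan$group == g, ]
    if (max(sc$lod) < threshold) next
    pk <- which.max(sc$lod)
    supp <- which(sc$lod >= sc$lod[pk] - 1.5)
    li <- min(supp); ri <- max(supp)
    calls <- geno$calls[match(sc$marker[pk], rownames(geno$calls)), ]
    stats_by <- lapply(GENO_STATES, function(s) {
      v <- phenotype[!is.na(calls) & calls == s & !is.na(phenotype)]
      c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
    })
    names(stats_by) <- GENO_STATES
    rows[[length(rows) + 1]] <- data.frame(
      group = g, peak = sc$marker[pk], peak_cM = sc$cM[pk],
      left = sc$marker[li], right = sc$marker[ri],
      left_cM = sc$cM[li], right_cM = sc$cM[ri],
      lod = sc$lod[pk], n = n, pve = pve_from_lod(sc$lod[pk], n),
      mean_MM = stats_by$MM["mean"], se_MM = stats_by$MM["se"],
      mean_MF = stats_by$MF["mean"], se_MF = stats_by$MF["se"],
      mean_FF = stats_by$FF["mean"], se_FF = stats_by$FF["se"],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(group = character(0), peak = character(0), lod = numeric(0),
               n = integer(0), pve = numeric(0))
  rownames(out) <- NULL
  out
}

#' Conditioned scan within one genotype class at a marker
#'
#' Subsets the cross to fish with a given hard call at a conditioning
#' marker (e.g. heterozygotes at a known major locus, to expose modifier
#' QTL), then runs [scanone_hk()] and [permutation_threshold()] on the
#' subset.
#'
#' @param hk output of [hk_probs()].
#' @param geno the `bin_geno` behind it.
#' @param phenotype phenotype vector.
#' @param marker conditioning marker name.
#' @param class required genotype class (`"MM"`, `"MF"` or `"FF"`).
#' @param n_perm,alpha,seed see [permutation_threshold()].
#' @return list with `scan` (a `scan_result` carrying `threshold`,
#'   `alpha` attributes), `threshold`, `n` (subset size).
#' @export
conditioned_scan <- function(hk, geno, phenotype, marker, class,
                             n_perm = 1000, alpha = 0.05, seed = 1L) {
  i <- match(marker, rownames(geno$calls))
  if (is.na(i)) stop("conditioning marker not genotyped: ", marker)
  sel <- !is.na(geno$calls[i, ]) & geno$calls[i, ] == class
  if (sum(sel) == 0) stop("conditioning class ", class, " absent at ", marker)
  if (sum(sel) < 10) stop("fewer than 10 fish in conditioning class; refuse")
  if (sum(sel) < 30)
    warning("only ", sum(sel), " fish in conditioning class; scan under-powered")
  sub_hk <- list(probs = hk$probs[, sel, , drop = FALSE], markers = hk$markers)
  y <- phenotype[sel]
  scan <- scanone_hk(sub_hk, y)
  thr <- permutation_threshold(sub_hk, y, n_perm, alpha, seed)
  attr(scan, "threshold") <- as.numeric(thr)
  attr(scan, "alpha") <- alpha
  list(scan = scan, threshold = as.numeric(thr), n = sum(sel))
}
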