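# Two-point recombination fractions for an F2 intercross.
#
# Observations per marker fall in 5 categories: the hard calls MM, MF, FF
# and the composite calls MM/MF, MF/FF (partial observations, likelihood
# summed over compatible states). An F2 carries two independent gametes;
# for a marker pair each gamete is parental (prob (1-r)/2 per type) or
# recombinant (r/2 per type). Everything needed by the EM reduces, per
# joint observation class, to three integers (a, b, c): the number of
# compatible ordered gamete-pair configurations with 0, 1, 2 recombinant
# gametes. Class probability is (a*u^2 + b*u*r + c*r^2)/4 with u = 1-r,
# and the conditional expected recombinant-gamete count is
# (b*u*r + 2*c*r^2) / (a*u^2 + b*u*r + c*r^2).

RF_CATS <- c("MM", "MF", "FF", "MM/MF", "MF/FF")

# compatible dosage sets per observation category
rf_cat_sets <- list(0L, 1L, 2L, c(0L, 1L), c(1L, 2L))

# 25 x 3 coefficient table (a, b, c) over joint classes, built once
rf_coef_table <- local({
  gam <- expand.grid(aA = 0:1, aB = 0:1)          # gamete allele at A, B
  rec <- as.integer(gam$aA != gam$aB)
  combos <- expand.grid(g1 = 1:4, g2 = 1:4)
  gA <- gam$aA[combos$g1] + gam$aA[combos$g2]
  gB <- gam$aB[combos$g1] + gam$aB[combos$g2]
  nrec <- rec[combos$g1] + rec[combos$g2]
  tab <- array(0L, dim = c(5, 5, 3))
  for (ca in 1:5) for (cb in 1:5) {
    ok <- gA %in% rf_cat_sets[[ca]] & gB %in% rf_cat_sets[[cb]]
    for (k in 0:2) tab[ca, cb, k + 1] <- sum(ok & nrec == k)
  }
  tab
})

# encode genotype calls to categories 1..5 (NA preserved)
rf_encode <- function(g) {
  if (is.numeric(g)) g <- GENO_STATES[g + 1]
  match(g, RF_CATS)
}

#' Two-point recombination fraction between two markers
#'
#' Maximum-likelihood estimate of the recombination fraction r for an F2
#' intercross by EM over the joint genotype classes, with composite calls
#' (MM/MF, MF/FF) treated as partial observations and missing genotypes
#' excluded pairwise. LOD is the log10 likelihood ratio against r = 0.5.
#'
#' @param gA,gB genotype vectors (values among `"MM"`, `"MF"`, `"FF"`,
#'   `"MM/MF"`, `"MF/FF"`, `NA`), or freshwater dosages 0/1/2.
#' @param max_iter,tol EM iteration control.
#' @return list `r` (estimate in [0, 0.5]), `lod`, `n_informative`.
#' @export
estimate_rf <- function(gA, gB, max_iter = 200, tol = 1e-10) {
  stopifnot(length(gA) == length(gB))
  ca <- rf_encode(gA); cb <- rf_encode(gB)
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  if (n < 2)
    return(list(r = NA_real_, lod = NA_real_, n_informative = n))
  N <- matrix(0, 5, 5)
  tt <- table(factor(ca[ok], levels = 1:5), factor(cb[ok], levels = 1:5))
  N[] <- tt
  a <- rf_coef_table[, , 1]; b <- rf_coef_table[, , 2]; cc <- rf_coef_table[, , 3]
  loglik <- function(r) {
    u <- 1 - r
    p <- (a * u^2 + b * u * r + cc * r^2) / 4
    sum(N[N > 0] * log(p[N > 0]))
  }
  r <- 0.25
  for (it in seq_len(max_iter)) {
    u <- 1 - r
    den <- a * u^2 + b * u * r + cc * r^2
    e <- (b * u * r + 2 * cc * r^2) / pmax(den, 1e-300)
    r_new <- sum(N * e) / (2 * n)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  r <- min(max(r, 0), 0.5)
  lod <- (loglik(r) - loglik(0.5)) / log(10)
  list(r = r, lod = max(lod, 0), n_informative = n)
}

#' All-pairs recombination fractions and LODs
#'
#' Vectorised version of [estimate_rf()] for a full genotype matrix: the
#' EM update is applied simultaneously to every marker pair via the
#' 25-class sufficient-statistic decomposition, so composite calls enter
#' as partial observations throughout.
#'
#' @param calls character genotype matrix (markers x F2s).
#' @param max_iter EM iterations.
#' @return list of K x K matrices `r`, `lod`, `n` (jointly informative
#'   F2 counts). Diagonals are `r = 0`, `lod = NA`.
#' @export
rf_matrix <- function(calls, max_iter = 60) {
  K <- nrow(calls)
  cat_m <- matrix(rf_encode(calls), K, ncol(calls))
  ind <- lapply(1:5, function(k) {
    x <- matrix(0, K, ncol(calls)); x[which(cat_m == k)] <- 1; x
  })
  N <- vector("list", 25)
  for (ca in 1:5) for (cb in 1:5)
    N[[(ca - 1) * 5 + cb]] <- tcrossprod(ind[[ca]], ind[[cb]])
  a <- rf_coef_table[, , 1]; b <- rf_coef_table[, , 2]; cc <- rf_coef_table[, , 3]
  n_pair <- Reduce(`+`, N)
  r <- matrix(0.25, K, K)
  nz <- which(vapply(N, function(x) any(x > 0), logical(1)))
  for (it in seq_len(max_iter)) {
    u <- 1 - r
    num <- matrix(0, K, K);
    for (idx in nz) {
      ca <- (idx - 1) %/% 5 + 1; cb <- (idx - 1) %% 5 + 1
      A <- a[ca, cb]; B <- b[ca, cb]; C <- cc[ca, cb]
      if (B == 0 && C == 0) next
      den <- A * u^2 + B * u * r + C * r^2
      num <- num + N[[idx]] * ((B * u * r + 2 * C * r^2) / pmax(den, 1e-300))
    }
    r <- num / pmax(2 * n_pair, 1)
  }
  r <- pmin(pmax(r, 0), 0.5)
  ll <- function(rm) {
    u <- 1 - rm
    out <- matrix(0, K, K)
    for (idx in nz) {
      ca <- (idx - 1) %/% 5 + 1; cb <- (idx - 1) %% 5 + 1
      A <- a[ca, cb]; B <- b[ca, cb]; C <- cc[ca, cb]
      p <- (A * u^2 + B * u * rm + C * rm^2) / 4
      out <- out + N[[idx]] * log(pmax(p, 1e-300))
    }
    out
  }
  lod <- (ll(r) - ll(matrix(0.5, K, K))) / log(10)
  lod <- pmax(lod, 0)
  diag(r) <- 0; diag(lod) <- NA
  dimnames(r) <- dimnames(lod) <- dimnames(n_pair) <-
    list(rownames(calls), rownames(calls))
  list(r = r, lod = lod, n = n_pair)
}

#' Group markers into linkage groups
#'
#' Single-linkage clustering: markers are joined when their two-point
#' LOD is at least `lod_min` and the recombination fraction at most
#' `rf_max`; linkage groups are the connected components.
#'
#' @param est output of [rf_matrix()].
#' @param lod_min,rf_max edge thresholds.
#' @return integer vector of group ids (1-based, largest group first),
#'   named by marker.
#' @export
group_markers <- function(est, lod_min = 6, rf_max = 0.35) {
  K <- nrow(est$r)
  adj <- !is.na(est$lod) & est$lod >= lod_min & est$r <= rf_max
  comp <- integer(K); cur <- 0L
  for (i in seq_len(K)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0)
      queue <- c(queue, nb)
    }
  }
  sizes <- table(comp)
  relab <- match(comp, as.integer(names(sort(sizes, decreasing = TRUE))))
  stats::setNames(relab, rownames(est$r))
}

#' Order markers within a linkage group
#'
#' Seriation minimising the sum of adjacent recombination fractions:
#' deterministic greedy nearest-neighbour chains (best over all start
#' markers for small groups) polished by 2-opt segment reversals. The
#' overall orientation is arbitrary; when physical coordinates are given
#' the order is normalised so the first marker has the smaller one.
#'
#' @param est output of [rf_matrix()] (or a list with an `r` matrix).
#' @param group integer/logical index of the markers to order.
#' @param phys optional numeric physical coordinate per group marker used
#'   only to normalise the orientation.
#' @return integer permutation of `group` (indices into the full marker
#'   set) in map order.
#' @export
order_markers <- function(est, group, phys = NULL) {
  idx <- if (is.logical(group)) which(group) else group
  K <- length(idx)
  if (K <= 2) {
    ord <- idx
  } else {
    D <- est$r[idx, idx, drop = FALSE]
    diag(D) <- Inf
    chain_from <- function(s) {
      path <- integer(K); used <- rep(FALSE, K)
      path[1] <- s; used[s] <- TRUE
      for (p in 2:K) {
        d <- D[path[p - 1], ]; d[used] <- Inf
        nxt <- which.min(d)
        path[p] <- nxt; used[nxt] <- TRUE
      }
      path
    }
    starts <- if (K <= 80) seq_len(K) else
      order(apply(D, 1, function(x) mean(x[is.finite(x)])), decreasing = TRUE)[1:10]
    best <- NULL; best_cost <- Inf
    cost <- function(p) sum(D[cbind(p[-K], p[-1])])
    for (s in starts) {
      p <- chain_from(s); cst <- cost(p)
      if (cst < best_cost) { best <- p; best_cost <- cst }
    }
    # 2-opt polish on the open path
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in 1:(K - 1)) for (j in (i + 1):K) {
        old <- (if (i > 1) D[best[i - 1], best[i]] else 0) +
          (if (j < K) D[best[j], best[j + 1]] else 0)
        new <- (if (i > 1) D[best[i - 1], best[j]] else 0) +
          (if (j < K) D[best[i], best[j + 1]] else 0)
        if (new < old - 1e-12) {
          best[i:j] <- best[j:i]
          improved <- TRUE
        }
      }
    }
    ord <- idx[best]
  }
  if (!is.null(phys)) {
    p <- phys[match(ord, idx)]
    ok <- !is.na(p)
    if (sum(ok) >= 2 && p[ok][1] > p[ok][sum(ok)]) ord <- rev(ord)
  }
  ord
}

#' Genetic distances from adjacent recombination fractions
#'
#' Haldane `d = -50 ln(1 - 2r)` or Kosambi
#' `d = 25 ln((1+2r)/(1-2r))`, in cM, accumulated from 0.
#'
#' @param r vector of adjacent recombination fractions.
#' @param fun `"haldane"` or `"kosambi"`.
#' @return list `d` (per-interval cM) and `cM` (cumulative positions,
#'   length `length(r) + 1`).
#' @export
map_distances <- function(r, fun = c("haldane", "kosambi")) {
  fun <- match.arg(fun)
  if (any(r >= 0.5))
    stop("recombination fraction >= 0.5: markers are unlinked, group first")
  if (any(r < 0)) stop("negative recombination fraction")
  d <- switch(fun,
              haldane = -50 * log(1 - 2 * r),
              kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
  list(d = d, cM = c(0, cumsum(d)))
}

#' Build a linkage map from binned genotypes
#'
#' Two-point estimation, LOD grouping, seriation ordering and genetic
#' distances in one pass.
#'
#' @param geno a `bin_geno` object (after QC).
#' @param lod_min,rf_max grouping thresholds (see [group_markers()]).
#' @param fun mapping function, `"haldane"` (default, matching the
#'   no-interference meiosis model) or `"kosambi"`.
#' @param min_group_size groups with fewer markers are left out of the
#'   map (reported in the `dropped` attribute).
#' @return object of class `linkage_map`: data.frame `marker`, `group`,
#'   `scaffold`, `bin_index`, `cM`, plus attributes `mapping_function`,
#'   `total_cM`, `est` (the [rf_matrix()] result) and `geno`.
#' @export
build_linkage_map <- function(geno, lod_min = 6, rf_max = 0.35,
                              fun = c("haldane", "kosambi"),
                              min_group_size = 2) {
  fun <- match.arg(fun)
  est <- rf_matrix(geno$calls)
  grp <- group_markers(est, lod_min, rf_max)
  maps <- list()
  gi <- 0
  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    if (length(idx) < min_group_size) next
    gi <- gi + 1
    phys <- geno$markers$bin_index[idx] +
      1000 * as.integer(factor(geno$markers$scaffold[idx]))
    ord <- order_markers(est, idx, phys = phys)
    r_adj <- pmin(est$r[cbind(ord[-length(ord)], ord[-1])], 0.499)
    cM <- map_distances(r_adj, fun)$cM
    maps[[gi]] <- data.frame(marker = rownames(geno$calls)[ord],
                             group = paste0("LG", gi),
                             scaffold = geno$markers$scaffold[ord],
                             bin_index = geno$markers$bin_index[ord],
                             cM = cM, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  structure(map, class = c("linkage_map", "data.frame"),
            mapping_function = fun,
            total_cM = sum(tapply(map$cM, map$group, max)),
            est = est, geno = geno)
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("linkage_map: %d markers in %d groups, total %.1f cM (%s)\n",
              nrow(x), length(unique(x$group)), attr(x, "total_cM"),
              attr(x, "mapping_function")))
  spans <- tapply(x$cM, x$group, max)
  cnts <- table(x$group)
  for (g in names(sort(spans, decreasing = TRUE)))
    cat(sprintf("  %s: %d markers, %.1f cM\n", g, cnts[[g]], spans[[g]]))
  invisible(x)
}

#' Marey profile: genetic vs physical position
#'
#' Places every mapped marker at its physical midpoint on the revised
#' assembly (strand-aware, using the placement table's order and
#' orientation with fixed inter-scaffold gaps) and reports the local
#' recombination rate (cM/Mb) per inter-marker interval. Maximal runs of
#' at least `min_run` consecutive zero-cM intervals are flagged as
#' recombination-suppression candidates (e.g. inversions heterozygous in
#' the cross).
#'
#' @param map a `linkage_map`.
#' @param placements placement data.frame (`scaffold`, `chromosome`,
#'   `rank`, `orientation`).
#' @param scaffold_lengths named vector of scaffold lengths (bp).
#' @param gap_bp inter-scaffold gap size used for physical coordinates.
#' @param min_run minimum run length of zero-cM intervals to flag.
#' @param zero_cM intervals with at most this much cM count as zero.
#' @return list with `markers` (chromosome, physical bp, cM), `intervals`
#'   (per-interval cM/Mb) and `suppression` (flagged runs). Markers on
#'   unplaced scaffolds are excluded with a warning.
#' @export
marey_profile <- function(map, placements, scaffold_lengths, gap_bp = 1000,
                          min_run = 3, zero_cM = 1e-9) {
  stopifnot(inherits(map, "linkage_map"))
  geno <- attr(map, "geno")
  mk <- geno$markers[match(map$marker, geno$markers$marker), ]
  pl <- placements[match(mk$scaffold, placements$scaffold), ]
  unplaced <- is.na(pl$chromosome)
  if (any(unplaced)) {
    warning(sum(unplaced), " marker(s) on unplaced scaffolds excluded")
  }
  # chromosome offsets per scaffold
  off <- placement_offsets(placements, scaffold_lengths, gap_bp)
  mid <- (mk$start + mk$end) / 2
  L <- scaffold_lengths[mk$scaffold]
  within <- ifelse(pl$orientation == "-", L - mid + 1, mid)
  phys <- off[mk$scaffold] + within
  df <- data.frame(marker = map$marker, group = map$group,
                   chromosome = pl$chromosome, phys = phys, cM = map$cM,
                   stringsAsFactors = FALSE)[!unplaced, ]
  df <- df[order(df$chromosome, df$phys), ]
  ints <- do.call(rbind, lapply(split(df, df$chromosome), function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(chromosome = d$chromosome[-1],
               start = d$phys[-nrow(d)], end = d$phys[-1],
               dcM = abs(diff(d$cM)),
               rate = abs(diff(d$cM)) / (diff(d$phys) / 1e6),
               stringsAsFactors = FALSE)
  }))
  rownames(ints) <- NULL
  runs <- NULL
  if (!is.null(ints)) {
    z <- ints$dcM <= zero_cM
    r <- rle(paste(ints$chromosome, z))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    flag <- grepl("TRUE$", r$values) & r$lengths >= min_run
    if (any(flag))
      runs <- data.frame(chromosome = ints$chromosome[starts[flag]],
                         start = ints$start[starts[flag]],
                         end = ints$end[ends[flag]],
                         n_intervals = r$lengths[flag],
                         stringsAsFactors = FALSE)
  }
  list(markers = df, intervals = ints, suppression = runs)
}

# physical start offset (0-based) of each placed scaffold on its
# chromosome, using placement order and fixed gaps (internal)
placement_offsets <- function(placements, scaffold_lengths, gap_bp = 1000) {
  off <- stats::setNames(rep(NA_real_, nrow(placements)), placements$scaffold)
  for (cn in unique(placements$chromosome[!is.na(placements$chromosome)])) {
    p <- placements[!is.na(placements$chromosome) & placements$chromosome == cn, ]
    p <- p[order(p$rank), ]
    lens <- scaffold_lengths[p$scaffold]
    starts <- cumsum(c(0, (lens + gap_bp)[-length(lens)]))
    off[p$scaffold] <- starts
  }
  off
}
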