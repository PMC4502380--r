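#' Three-state recombination HMM specification
#'
#' Hidden states are the F2 genotypes (MM, MF, FF). Between SNPs
#' separated by d bp, with per-meiosis recombination probability
#' `r = (1 - exp(-2 rho d)) / 2` (Haldane), the two-gamete transition
#' matrix is
#' \preformatted{
#'   [ (1-r)^2      2r(1-r)        r^2    ]
#'   [ r(1-r)   (1-r)^2 + r^2    r(1-r)   ]
#'   [ r^2         2r(1-r)      (1-r)^2   ]
#' }
#' Emissions are freshwater read counts f ~ Binomial(m + f, p) with
#' p in {epsilon, 1/2, 1 - epsilon}; SNPs with zero reads contribute flat
#' emissions. The initial distribution is (1/4, 1/2, 1/4).
#'
#' @param rho recombination rate in cM per Mb (typically estimated from
#'   the linkage map as total cM / total Mb, which stabilises decoding at
#'   ~1.5x coverage).
#' @param epsilon per-read mis-allele probability (shared with
#'   [geno_config()]).
#' @param init initial state distribution.
#' @return list of class `hmm_spec`.
#' @export
hmm_spec <- function(rho = 3.5, epsilon = 0.02, init = c(0.25, 0.5, 0.25)) {
  if (rho < 0) stop("rho must be >= 0")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon in [0, 0.5)")
  structure(list(rho = rho, epsilon = epsilon, init = init),
            class = "hmm_spec")
}

# per-interval transition matrix from distance d (bp) and rho (cM/Mb)
hmm_transition <- function(d, rho) {
  r <- (1 - exp(-2 * rho * d / 1e8)) / 2   # rho d in Morgans
  u <- 1 - r
  matrix(c(u^2, 2 * r * u, r^2,
           r * u, u^2 + r^2, r * u,
           r^2, 2 * r * u, u^2),
         3, 3, byrow = TRUE)
}

# log emission matrix (n_snp x 3) for marine/freshwater counts
hmm_emissions <- function(m, f, epsilon) {
  n <- m + f
  cbind(stats::dbinom(f, n, epsilon, log = TRUE),
        stats::dbinom(f, n, 0.5, log = TRUE),
        stats::dbinom(f, n, 1 - epsilon, log = TRUE))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Decode one F2's chromosome with the recombination HMM
#'
#' Log-space forward-backward posteriors and the Viterbi path over the
#' three genotype states, from raw per-SNP allele counts.
#'
#' @param m,f per-SNP marine / freshwater read counts for one F2, in
#'   position order.
#' @param pos SNP positions (bp, sorted increasing).
#' @param spec an [hmm_spec()].
#' @return list with `posterior` (n_snp x 3 matrix, columns MM, MF, FF;
#'   rows sum to 1), `viterbi` (state strings), `loglik`.
#' @export
decode_chromosome <- function(m, f, pos, spec = hmm_spec()) {
  n <- length(pos)
  if (n == 0) stop("empty chromosome: no SNPs to decode")
  stopifnot(length(m) == n, length(f) == n, !is.unsorted(pos))
  if (any(m < 0 | f < 0)) stop("negative read counts")
  le <- hmm_emissions(m, f, spec$epsilon)
  lp <- log(spec$init)
  trs <- if (n > 1) lapply(diff(pos), hmm_transition, rho = spec$rho)
  else list()

  # forward-backward in log space, propagated via linear-space matrix
  # products with per-step rescaling
  fa <- matrix(-Inf, n, 3)
  fa[1, ] <- lp + le[1, ]
  if (n > 1) for (t in 2:n) {
    v <- fa[t - 1, ]; mx <- max(v)
    fa[t, ] <- mx + log(as.vector(exp(v - mx) %*% trs[[t - 1]])) + le[t, ]
  }
  loglik <- logsumexp(fa[n, ])
  bw <- matrix(0, n, 3)
  if (n > 1) for (t in (n - 1):1) {
    v <- le[t + 1, ] + bw[t + 1, ]; mx <- max(v)
    bw[t, ] <- mx + log(as.vector(trs[[t]] %*% exp(v - mx)))
  }
  post <- exp(fa + bw - loglik)
  post <- post / rowSums(post)
  colnames(post) <- GENO_STATES

  # Viterbi
  vt <- matrix(-Inf, n, 3); ptr <- matrix(0L, n, 3)
  vt[1, ] <- lp + le[1, ]
  if (n > 1) for (t in 2:n) {
    ltr <- log(trs[[t - 1]])
    cand <- vt[t - 1, ] + ltr          # 3x3: rows = previous state
    ptr[t, ] <- max.col(t(cand), ties.method = "first")
    vt[t, ] <- cand[cbind(ptr[t, ], 1:3)] + le[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(vt[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  list(posterior = post, viterbi = GENO_STATES[path], loglik = loglik)
}

#' Extract breakpoint intervals from a decoded chromosome
#'
#' One interval per state change in the Viterbi path. The left bound is
#' the position of the last SNP (at or before the change) whose posterior
#' for the departing state reaches `tau`; the right bound is the first
#' SNP after the change whose posterior for the arriving state reaches
#' `tau` (falling back to the SNPs flanking the transition when no SNP
#' reaches `tau`). Transitions jumping two allele copies (MM<->FF), and
#' pairs of breakpoints closer than `min_separation` (unreliable close
#' double crossovers at low coverage), are flagged for review.
#'
#' @param decoded output of [decode_chromosome()].
#' @param pos SNP positions used for decoding.
#' @param tau posterior mass defining confident flanks.
#' @param min_separation bp; closer consecutive breakpoints are flagged.
#' @return data.frame: `left_bp`, `right_bp`, `from_state`, `to_state`,
#'   `flagged`.
#' @export
extract_breakpoints <- function(decoded, pos, tau = 0.95,
                                min_separation = 1e6) {
  path <- match(decoded$viterbi, GENO_STATES)
  post <- decoded$posterior
  ch <- which(diff(path) != 0)
  if (length(ch) == 0)
    return(data.frame(left_bp = numeric(0), right_bp = numeric(0),
                      from_state = character(0), to_state = character(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  out <- lapply(ch, function(t) {
    from <- path[t]; to <- path[t + 1]
    lcand <- which(post[seq_len(t), from] >= tau)
    left <- if (length(lcand) > 0) pos[max(lcand)] else pos[t]
    rcand <- t + which(post[(t + 1):nrow(post), to] >= tau)
    right <- if (length(rcand) > 0) pos[min(rcand)] else pos[t + 1]
    data.frame(left_bp = left, right_bp = right,
               from_state = GENO_STATES[from], to_state = GENO_STATES[to],
               flagged = abs(from - to) == 2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (nrow(out) > 1) {
    mids <- (out$left_bp + out$right_bp) / 2
    close <- c(FALSE, diff(mids) < min_separation)
    out$flagged <- out$flagged | close | c(close[-1], FALSE)
  }
  out
}

#' Fine-map breakpoints for every F2 on every chromosome
#'
#' Runs [decode_chromosome()] + [extract_breakpoints()] over an
#' [allele_counts()] object (its `snps` table must carry `chromosome`
#' and `chrom_pos` columns).
#'
#' @param counts an [allele_counts()] object.
#' @param spec an [hmm_spec()].
#' @param tau,min_separation see [extract_breakpoints()].
#' @return data.frame `f2`, `chromosome`, `left_bp`, `right_bp`,
#'   `from_state`, `to_state`, `flagged`.
#' @export
finemap_breakpoints <- function(counts, spec = hmm_spec(), tau = 0.95,
                                min_separation = 1e6) {
  stopifnot(inherits(counts, "allele_counts"),
            all(c("chromosome", "chrom_pos") %in% names(counts$snps)))
  out <- list()
  for (cn in unique(counts$snps$chromosome)) {
    rows <- which(counts$snps$chromosome == cn)
    rows <- rows[order(counts$snps$chrom_pos[rows])]
    pos <- counts$snps$chrom_pos[rows]
    for (j in seq_along(counts$f2)) {
      dec <- decode_chromosome(counts$m[rows, j], counts$f[rows, j], pos, spec)
      bp <- extract_breakpoints(dec, pos, tau, min_separation)
      if (nrow(bp) > 0) {
        bp$f2 <- counts$f2[j]; bp$chromosome <- cn
        out[[length(out) + 1]] <- bp
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(f2 = character(0), chromosome = character(0),
                      left_bp = numeric(0), right_bp = numeric(0),
                      from_state = character(0), to_state = character(0),
                      flagged = logical(0)))
  out <- do.call(rbind, out)
  out[, c("f2", "chromosome", "left_bp", "right_bp", "from_state",
          "to_state", "flagged")]
}

#' Minimal QTL interval from recombinant individuals
#'
#' Each recombinant F2 carries a breakpoint interval (left, right) inside
#' the candidate region and a binary phenotype class; `class_of` maps a
#' genotype state to the phenotype class it predicts. A recombinant whose
#' phenotype matches its left-side genotype class (but not the right)
#' forces the causal locus to lie at or left of its interval's right
#' bound, and symmetrically. Intersecting all constraints yields the
#' maximal interval on which genotype perfectly correlates with
#' phenotype; contradictory constraints yield an explicit
#' "no consistent interval" result listing the offending fish.
#'
#' @param recombinants data.frame with `f2`, `left_bp`, `right_bp`,
#'   `from_state`, `to_state`, `phenotype` columns.
#' @param class_of named vector mapping states (e.g. `"MF"`, `"FF"`) to
#'   phenotype classes.
#' @param region optional numeric `(start, end)` bounds of the candidate
#'   region.
#' @return list with `consistent` (logical), `interval` (`c(start, end)`
#'   or `NULL`) and `offending` (character vector of fish ids).
#' @export
minimal_qtl_interval <- function(recombinants, class_of, region = NULL) {
  lo <- if (is.null(region)) -Inf else region[1]
  hi <- if (is.null(region)) Inf else region[2]
  offending <- character(0)
  for (i in seq_len(nrow(recombinants))) {
    rc <- recombinants[i, ]
    left_class <- class_of[[rc$from_state]]
    right_class <- class_of[[rc$to_state]]
    matches_left <- identical(rc$phenotype, left_class)
    matches_right <- identical(rc$phenotype, right_class)
    if (matches_left && !matches_right) {
      hi <- min(hi, rc$right_bp)       # locus cannot lie right of the change
    } else if (matches_right && !matches_left) {
      lo <- max(lo, rc$left_bp)
    } else if (!matches_left && !matches_right) {
      offending <- c(offending, rc$f2) # phenotype fits neither side
    }                                  # matches both: uninformative
  }
  if (lo > hi) {
    # find fish whose constraints cross: any right-bound below lo or
    # left-bound above hi
    for (i in seq_len(nrow(recombinants))) {
      rc <- recombinants[i, ]
      lc <- class_of[[rc$from_state]]; rcl <- class_of[[rc$to_state]]
      if (identical(rc$phenotype, lc) && !identical(rc$phenotype, rcl) &&
          rc$right_bp < lo) offending <- c(offending, rc$f2)
      if (identical(rc$phenotype, rcl) && !identical(rc$phenotype, lc) &&
          rc$left_bp > hi) offending <- c(offending, rc$f2)
    }
    return(list(consistent = FALSE, interval = NULL,
                offending = unique(offending)))
  }
  if (length(offending) > 0)
    return(list(consistent = FALSE, interval = NULL,
                offending = unique(offending)))
  list(consistent = TRUE, interval = c(lo, hi), offending = character(0))
}
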