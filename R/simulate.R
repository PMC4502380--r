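#' Configuration for a synthetic F2 intercross
#'
#' Defines the genome, cross size, sequencing depth and genetic model used
#' by [simulate_cross()]. Defaults emulate a large marine x freshwater
#' stickleback-style intercross genotyped by low-coverage GBS: ~1.5x reads
#' per SNP per fish over a dense SNP set, later pooled into high-coverage
#' binned markers.
#'
#' @param n_f2 number of F2 individuals (>= 1).
#' @param n_chromosomes number of chromosomes; scaffolds are assigned to
#'   chromosomes in contiguous blocks of roughly equal total length.
#' @param scaffold_lengths named numeric vector of scaffold lengths in bp.
#'   Unnamed vectors are named `S1`, `S2`, ...
#' @param snp_density expected phased SNPs per Mb (Poisson-placed).
#' @param mean_coverage expected reads per SNP per F2 for an average
#'   sequencing effort (x).
#' @param error_rate probability that a read reports the wrong parental
#'   allele (0 <= e < 0.5).
#' @param recomb_rate recombination rate in cM per Mb. Crossovers follow a
#'   Haldane (no-interference) Poisson process, matching the Haldane map
#'   function used downstream. Default 3.5 cM/Mb, a realistic genome-wide
#'   average for a ~460 Mb fish genome with a ~1600 cM map.
#' @param distorted_regions optional data.frame (`scaffold`, `start`,
#'   `end`, `freq`) of segregation-distorted spans: gametes carry the
#'   freshwater allele across the span with probability `freq` in (0, 1).
#' @param male_fraction proportion of XY F2s.
#' @param sex_chromosome chromosome id (integer index) carrying the sex
#'   locus, or `NA` for none. XY fish are simulated X-hemizygous there:
#'   one informative haplotype and halved read depth; Y reads not modelled.
#' @param qtl_spec optional data.frame (`scaffold`, `pos`, `additive`,
#'   `dominance`, `residual_sd`) describing quantitative trait loci for the
#'   simulated trait. With freshwater dosage x in {0,1,2} the genetic value
#'   of a QTL is `additive*(x-1) + dominance*(x==1)`; residual noise uses
#'   the first row's `residual_sd`.
#' @param length_effect,sex_effect optional covariate effects on the trait
#'   (per mm of standard length; additive shift for XY fish).
#' @param mean_total_reads expected total mapped reads per F2; per-F2
#'   sequencing effort varies as Gamma(10, 10) around it and scales SNP
#'   coverage, so total RPMM per SNP centres on `mean_coverage`.
#' @param seed integer seed; a fixed seed makes [simulate_cross()] output
#'   byte-identical across runs.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_f2,
                       n_chromosomes = 1,
                       scaffold_lengths = c(S1 = 1e7),
                       snp_density = 100,
                       mean_coverage = 1.5,
                       error_rate = 0.01,
                       recomb_rate = 3.5,
                       distorted_regions = NULL,
                       male_fraction = 0,
                       sex_chromosome = NA,
                       qtl_spec = NULL,
                       length_effect = 0,
                       sex_effect = 0,
                       mean_total_reads = 1e6,
                       seed = 1L) {
  if (n_f2 < 1) stop("n_f2 must be >= 1")
  if (any(scaffold_lengths <= 0)) stop("scaffold lengths must be positive")
  if (snp_density <= 0) stop("snp_density must be positive")
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (recomb_rate < 0) stop("recomb_rate must be >= 0")
  if (n_chromosomes < 1 || n_chromosomes > length(scaffold_lengths))
    stop("n_chromosomes must be between 1 and the number of scaffolds")
  if (male_fraction < 0 || male_fraction > 1) stop("male_fraction in [0,1]")
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- paste0("S", seq_along(scaffold_lengths))
  if (!is.null(distorted_regions)) {
    stopifnot(all(c("scaffold", "start", "end", "freq") %in% names(distorted_regions)))
    if (any(distorted_regions$freq <= 0 | distorted_regions$freq >= 1))
      stop("distorted frequencies must be in (0, 1)")
  }
  structure(list(n_f2 = as.integer(n_f2), n_chromosomes = as.integer(n_chromosomes),
                 scaffold_lengths = scaffold_lengths, snp_density = snp_density,
                 mean_coverage = mean_coverage, error_rate = error_rate,
                 recomb_rate = recomb_rate, distorted_regions = distorted_regions,
                 male_fraction = male_fraction, sex_chromosome = sex_chromosome,
                 qtl_spec = qtl_spec, length_effect = length_effect,
                 sex_effect = sex_effect, mean_total_reads = mean_total_reads,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# split scaffolds into n contiguous chromosome blocks of ~equal total bp
assign_chromosomes <- function(lengths, n_chrom) {
  k <- length(lengths)
  if (n_chrom == k) return(seq_len(k))
  target <- cumsum(rep(sum(lengths) / n_chrom, n_chrom))
  chrom <- integer(k); cum <- 0; ci <- 1L
  for (i in seq_len(k)) {
    chrom[i] <- ci
    cum <- cum + lengths[i]
    # advance when past the running target, keeping enough scaffolds for
    # the remaining chromosomes
    while (ci < n_chrom && cum >= target[ci] && (k - i) >= (n_chrom - ci)) {
      ci <- ci + 1L
      break
    }
  }
  chrom
}

#' Simulate a phased low-coverage GBS dataset for an F2 intercross
#'
#' Draws two independent meioses per F2 per chromosome under a Haldane
#' (no-interference) crossover model, places phased homozygous-difference
#' SNPs along each scaffold, and generates marine/freshwater allele read
#' counts with Poisson depth and per-read allele error. XY individuals are
#' X-hemizygous on the sex chromosome (single haplotype, halved depth).
#' Segregation-distorted regions transmit the freshwater allele at the
#' configured gamete frequency. Everything needed to score downstream
#' stages (genotypes, crossover positions, sex, true scaffold placement,
#' phenotypes) is returned as a truth set.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `counts` (an [allele_counts()] object) and
#'   `truth` (class `sim_truth`): `genotypes` (SNP x F2 freshwater-dosage
#'   matrix, hemizygous sites coded 0/2), `breakpoints` (data.frame `f2`,
#'   `chromosome`, `pos` of genotype transitions in chromosome bp),
#'   `sex`, `placement` (true scaffold placement table), `phenotypes`,
#'   and the `config`.
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- config$scaffold_lengths
  scafs <- names(lens)
  chrom_of <- assign_chromosomes(lens, config$n_chromosomes)
  names(chrom_of) <- scafs

  # true placement: scaffolds in listed order, all forward strand
  placement <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ci) {
    s <- scafs[chrom_of == ci]
    data.frame(scaffold = s, chromosome = paste0("chr", ci),
               rank = seq_along(s), orientation = "+",
               length = unname(lens[s]), stringsAsFactors = FALSE)
  }))
  rownames(placement) <- NULL

  # SNP placement: Poisson count per scaffold, uniform positions
  snps <- do.call(rbind, lapply(scafs, function(s) {
    n <- stats::rpois(1, config$snp_density * lens[[s]] / 1e6)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(lens[[s]], n, replace = FALSE))
    data.frame(scaffold = s, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(snps) || nrow(snps) == 0) stop("no SNPs simulated; raise snp_density")
  # chromosome coordinates: offset of scaffold within chromosome (gapless)
  offset <- numeric(length(scafs)); names(offset) <- scafs
  for (ci in seq_len(config$n_chromosomes)) {
    s <- scafs[chrom_of == ci]
    offset[s] <- cumsum(c(0, unname(lens[s])))[seq_along(s)]
  }
  snps$chromosome <- paste0("chr", chrom_of[snps$scaffold])
  snps$chrom_pos <- offset[snps$scaffold] + snps$pos
  snps <- snps[order(match(snps$chromosome, paste0("chr", seq_len(config$n_chromosomes))),
                     snps$chrom_pos), ]
  rownames(snps) <- NULL

  n_f2 <- config$n_f2
  f2_ids <- sprintf("F2_%03d", seq_len(n_f2))
  sex <- ifelse(stats::runif(n_f2) < config$male_fraction, "XY", "XX")
  sex_chr <- if (is.na(config$sex_chromosome)) NA_character_ else
    paste0("chr", config$sex_chromosome)

  chrom_len <- tapply(lens, chrom_of, sum)
  n_snp <- nrow(snps)
  dosage <- matrix(0L, n_snp, n_f2)
  bp_list <- vector("list", n_f2 * config$n_chromosomes)
  bi <- 0L

  # distorted regions in chromosome coordinates
  dist_chr <- NULL
  if (!is.null(config$distorted_regions)) {
    dr <- config$distorted_regions
    dist_chr <- data.frame(chromosome = paste0("chr", chrom_of[dr$scaffold]),
                           start = offset[dr$scaffold] + dr$start,
                           end = offset[dr$scaffold] + dr$end,
                           freq = dr$freq, stringsAsFactors = FALSE)
  }

  for (ci in seq_len(config$n_chromosomes)) {
    cn <- paste0("chr", ci)
    rows <- which(snps$chromosome == cn)
    if (length(rows) == 0) next
    cpos <- snps$chrom_pos[rows]
    L <- chrom_len[[as.character(ci)]]
    morgans <- config$recomb_rate * L / 1e8  # cM/Mb * bp -> Morgans
    hemi <- identical(cn, sex_chr)
    dreg <- if (!is.null(dist_chr)) dist_chr[dist_chr$chromosome == cn, , drop = FALSE] else NULL

    for (i in seq_len(n_f2)) {
      n_gam <- if (hemi && sex[i] == "XY") 1L else 2L
      g <- matrix(0L, length(rows), n_gam)
      xos <- numeric(0)
      for (k in seq_len(n_gam)) {
        nxo <- stats::rpois(1, morgans)
        xo <- sort(stats::runif(nxo, 0, L))
        start <- stats::rbinom(1, 1, 0.5)
        al <- (start + findInterval(cpos, xo)) %% 2L  # 1 = freshwater
        if (!is.null(dreg) && nrow(dreg) > 0) {
          for (r in seq_len(nrow(dreg))) {
            inr <- cpos >= dreg$start[r] & cpos <= dreg$end[r]
            if (any(inr)) al[inr] <- stats::rbinom(1, 1, dreg$freq[r])
          }
        }
        g[, k] <- al
        xos <- c(xos, xo)
      }
      d <- rowSums(g)
      if (n_gam == 1L) d <- 2L * d  # hemizygous coded 0/2
      dosage[rows, i] <- as.integer(d)
      # truth breakpoints = genotype transitions visible along the SNP
      # track; where a transition interval contains recorded crossovers
      # the exact crossover positions are kept, otherwise (distortion
      # boundaries) the interval midpoint stands in
      if (length(rows) > 1) {
        ch <- which(diff(d) != 0)
        if (length(ch) > 0) {
          keep <- unlist(lapply(ch, function(j) {
            inside <- xos[xos > cpos[j] & xos < cpos[j + 1]]
            if (length(inside) > 0) inside else (cpos[j] + cpos[j + 1]) / 2
          }))
          bi <- bi + 1L
          bp_list[[bi]] <- data.frame(f2 = f2_ids[i], chromosome = cn,
                                      pos = keep, stringsAsFactors = FALSE)
        }
      }
    }
  }
  breakpoints <- if (bi > 0) do.call(rbind, bp_list[seq_len(bi)]) else
    data.frame(f2 = character(0), chromosome = character(0), pos = numeric(0))

  # sequencing: per-F2 effort scales both SNP coverage and mapped totals
  effort <- stats::rgamma(n_f2, shape = 10, rate = 10)
  totals <- round(config$mean_total_reads * effort)
  lam <- outer(rep(config$mean_coverage, n_snp), effort)
  if (!is.na(sex_chr)) {
    on_sex <- snps$chromosome == sex_chr
    lam[on_sex, sex == "XY"] <- lam[on_sex, sex == "XY"] / 2
  }
  nread <- matrix(stats::rpois(n_snp * n_f2, lam), n_snp, n_f2)
  e <- config$error_rate
  pf <- (dosage / 2) * (1 - e) + (1 - dosage / 2) * e
  fr <- matrix(stats::rbinom(n_snp * n_f2, nread, pf), n_snp, n_f2)
  mr <- nread - fr

  counts <- allele_counts(snps, mr, fr, totals, f2_ids)

  # phenotype: optional QTL effects + covariates + residual noise
  standard_length <- stats::rnorm(n_f2, 45, 4)
  trait <- rep(0, n_f2); res_sd <- 1
  if (!is.null(config$qtl_spec)) {
    qs <- config$qtl_spec
    res_sd <- qs$residual_sd[1]
    for (r in seq_len(nrow(qs))) {
      on_s <- which(snps$scaffold == qs$scaffold[r])
      if (length(on_s) == 0) stop("QTL scaffold has no SNPs: ", qs$scaffold[r])
      near <- on_s[which.min(abs(snps$pos[on_s] - qs$pos[r]))]
      x <- dosage[near, ]
      trait <- trait + qs$additive[r] * (x - 1) + qs$dominance[r] * (x == 1)
    }
  }
  trait <- trait + config$length_effect * (standard_length - mean(standard_length)) +
    config$sex_effect * (sex == "XY") + stats::rnorm(n_f2, 0, res_sd)
  phenotypes <- data.frame(f2 = f2_ids, sex = sex,
                           standard_length = standard_length, trait = trait,
                           stringsAsFactors = FALSE)

  truth <- structure(list(genotypes = dosage, breakpoints = breakpoints,
                          sex = stats::setNames(sex, f2_ids),
                          placement = placement, phenotypes = phenotypes,
                          snps = snps, config = config),
                     class = "sim_truth")
  list(counts = counts, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d F2s, %d SNPs, %d scaffolds on %d chromosomes\n",
              x$config$n_f2, nrow(x$snps), nrow(x$placement),
              length(unique(x$placement$chromosome))))
  cat(sprintf("  %d recorded breakpoints; %d XY fish\n",
              nrow(x$breakpoints), sum(x$sex == "XY")))
  invisible(x)
}

#' Scramble a true scaffold placement into a degraded "prior" assembly
#'
#' Produces the situation an assembly-revision step must repair: some
#' scaffolds unplaced, some orientation-flipped, some moved to a wrong
#' location. Edit sets are disjoint; a log of the edits is returned so
#' recovery can be scored against truth.
#'
#' @param truth a `sim_truth` object or a placement data.frame with
#'   columns `scaffold`, `chromosome`, `rank`, `orientation`.
#' @param n_unanchor,n_flip,n_move number of scaffolds to unplace, flip,
#'   and relocate.
#' @param seed integer seed (fixed seed gives an identical log on rerun).
#' @return list with `placement` (the scrambled prior table, ranks
#'   re-densified per chromosome) and `log` (data.frame `scaffold`,
#'   `edit`, `from_chromosome`, `from_rank`, `to_chromosome`, `to_rank`).
#' @export
scramble_assembly <- function(truth, n_unanchor = 0, n_flip = 0, n_move = 0,
                              seed = 1L) {
  pl <- if (inherits(truth, "sim_truth")) truth$placement else truth
  stopifnot(all(c("scaffold", "chromosome", "rank", "orientation") %in% names(pl)))
  k <- nrow(pl)
  if (n_unanchor + n_flip + n_move > k)
    stop("edit counts exceed available scaffolds (edit sets must be disjoint)")
  set.seed(seed)
  pool <- sample(pl$scaffold)
  un <- pool[seq_len(n_unanchor)]
  fl <- pool[n_unanchor + seq_len(n_flip)]
  mv <- pool[n_unanchor + n_flip + seq_len(n_move)]
  out <- pl
  log <- data.frame(scaffold = character(0), edit = character(0),
                    from_chromosome = character(0), from_rank = integer(0),
                    to_chromosome = character(0), to_rank = integer(0),
                    stringsAsFactors = FALSE)
  rec <- function(s, edit, to_chr, to_rank) {
    i <- match(s, pl$scaffold)
    rbind(log, data.frame(scaffold = s, edit = edit,
                          from_chromosome = pl$chromosome[i],
                          from_rank = pl$rank[i],
                          to_chromosome = to_chr, to_rank = to_rank,
                          stringsAsFactors = FALSE))
  }
  for (s in un) {
    i <- match(s, out$scaffold)
    out$chromosome[i] <- NA_character_
    out$rank[i] <- NA_integer_
    out$orientation[i] <- "unknown"
    log <- rec(s, "unanchored", NA_character_, NA_integer_)
  }
  for (s in fl) {
    i <- match(s, out$scaffold)
    out$orientation[i] <- if (out$orientation[i] == "+") "-" else "+"
    log <- rec(s, "flipped", out$chromosome[i], out$rank[i])
  }
  chroms <- unique(pl$chromosome)
  for (s in mv) {
    i <- match(s, out$scaffold)
    new_chr <- if (length(chroms) > 1)
      sample(setdiff(chroms, out$chromosome[i]), 1) else chroms
    # insert at a random rank position on the target chromosome
    occ <- out$rank[!is.na(out$chromosome) & out$chromosome == new_chr &
                      out$scaffold != s]
    new_rank <- if (length(occ) == 0) 1L else sample(max(occ) + 1L, 1)
    out$chromosome[i] <- new_chr
    out$rank[i] <- new_rank - 0.5  # placed between existing ranks
    log <- rec(s, "moved", new_chr, as.integer(new_rank))
  }
  # re-densify ranks within each chromosome (ties broken by scaffold id)
  for (cn in unique(out$chromosome[!is.na(out$chromosome)])) {
    i <- which(!is.na(out$chromosome) & out$chromosome == cn)
    out$rank[i] <- rank(out$rank[i], ties.method = "first")
  }
  out$rank <- as.integer(out$rank)
  out$evidence <- "prior"
  list(placement = out, log = log)
}
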