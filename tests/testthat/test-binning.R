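test_that("bin counts reproduce the published size series", {
  expect_equal(n_bins_for_scaffold(5e4), 1L)     # < 100 kb: one bin
  expect_equal(n_bins_for_scaffold(6e5), 2L)     # 100 kb - 1 Mb: two bins
  expect_equal(n_bins_for_scaffold(1.2e6), 3L)   # 1 - 1.5 Mb: three
  expect_equal(n_bins_for_scaffold(1.7e6), 4L)   # 1.5 - 2 Mb: four
  expect_equal(n_bins_for_scaffold(2.6e6), 6L)
  expect_error(n_bins_for_scaffold(0), "positive")
  # every scaffold >= 1 Mb ends with bins of at most 500 kb
  lens <- seq(1e6, 3e7, by = 250000)
  expect_true(all(lens / n_bins_for_scaffold(lens) <= 5e5))
})

test_that("SNPs land in the span containing their position and bins partition the scaffold", {
  lens <- c(S1 = 1e6)
  snps <- data.frame(scaffold = "S1", pos = c(1, 400001, 999999))
  ab <- assign_bins(snps, lens)
  expect_equal(nrow(ab$bins), 3)                      # 1 Mb -> 3 bins
  expect_equal(ab$bins$end - ab$bins$start + 1, c(333333, 333334, 333333),
               tolerance = 1.1)
  expect_equal(ab$snp_bin, c(1, 2, 3))                # 400001 in bin index 1
  # partition: contiguous, covering, non-overlapping
  expect_equal(ab$bins$start, c(1, ab$bins$end[-3] + 1))
  expect_equal(ab$bins$end[3], 1e6)
  # random positions: each lands in exactly one bin whose span contains it
  set.seed(41)
  pos <- sample.int(1e6, 200)
  ab2 <- assign_bins(data.frame(scaffold = "S1", pos = pos), lens)
  expect_true(all(pos >= ab2$bins$start[ab2$snp_bin] &
                    pos <= ab2$bins$end[ab2$snp_bin]))
  expect_error(assign_bins(data.frame(scaffold = "S1", pos = 2e6), lens),
               "beyond scaffold end")
})

test_that("genotype calls match a brute-force Bayes oracle", {
  cfgs <- list(geno_config(), geno_config(epsilon = 0.05, call_posterior = 0.9))
  set.seed(42)
  for (cfg in cfgs) {
    m <- rpois(50, 40); f <- rpois(50, 40)
    got <- call_bin_genotype(m, f, cfg)
    for (i in seq_along(m)) {
      # oracle: enumerate the three states directly
      lik <- c(dbinom(f[i], m[i] + f[i], cfg$epsilon),
               dbinom(f[i], m[i] + f[i], 0.5),
               dbinom(f[i], m[i] + f[i], 1 - cfg$epsilon))
      post <- lik * cfg$prior / sum(lik * cfg$prior)
      expect_equal(unname(got$posterior[i, ]), post, tolerance = 1e-12)
    }
  }
})

test_that("calling behaviour at the boundaries: missing, confident, composite", {
  expect_true(is.na(call_bin_genotype(0, 0)$call))
  expect_true(is.na(call_bin_genotype(1, 1)$call))      # below min_reads
  r <- call_bin_genotype(80, 75)
  expect_equal(r$call, "MF")
  expect_gt(r$posterior[, "MF"], 0.999)
  expect_equal(call_bin_genotype(0, 150)$call, "FF")    # ~150x binned marker
  expect_equal(call_bin_genotype(150, 0)$call, "MM")
  # a bin straddling a breakpoint: counts between MF and FF
  r2 <- call_bin_genotype(20, 96)
  expect_equal(r2$call, "MF/FF")
  r3 <- call_bin_genotype(96, 20)
  expect_equal(r3$call, "MM/MF")
})

test_that("pooled bin counts conserve member SNP counts per F2", {
  sim <- sim_small()
  geno <- bin_genotypes(sim$counts, sim$truth$config$scaffold_lengths)
  expect_equal(unname(colSums(geno$m)), unname(colSums(sim$counts$m)))
  expect_equal(unname(colSums(geno$f)), unname(colSums(sim$counts$f)))
  # and per scaffold
  for (s in unique(geno$markers$scaffold)) {
    expect_equal(colSums(geno$m[geno$markers$scaffold == s, , drop = FALSE]),
                 colSums(sim$counts$m[sim$counts$snps$scaffold == s, , drop = FALSE]))
  }
})

test_that("fish-then-marker QC drops by the stated thresholds", {
  # synthetic bin_geno: 10 markers x 10 fish
  set.seed(43)
  calls <- matrix(sample(c("MM", "MF", "FF"), 100, replace = TRUE,
                         prob = c(0.25, 0.5, 0.25)), 10, 10,
                  dimnames = list(paste0("1_", 0:9), paste0("F", 1:10)))
  calls[1:6, 1] <- NA           # fish 1: 60% missing -> dropped
  calls[2, 2:3] <- NA           # marker 2: 2/9 = 22% missing after fish drop
  geno <- structure(list(
    markers = data.frame(marker = rownames(calls), scaffold = "S1",
                         bin_index = 0:9, start = 1, end = 1000, n_snps = 5),
    m = matrix(50, 10, 10, dimnames = dimnames(calls)),
    f = matrix(50, 10, 10, dimnames = dimnames(calls)),
    calls = calls,
    posterior = array(1 / 3, c(10, 10, 3)),
    f2 = colnames(calls), geno_config = geno_config()), class = "bin_geno")
  qc <- apply_qc(geno)
  expect_false("F1" %in% qc$geno$f2)
  expect_false("1_1" %in% qc$geno$markers$marker)
  expect_true(all(c("fish", "marker") %in% qc$drop_log$type))
  # a marker missing in exactly 20% of fish is dropped ("at least")
  calls2 <- calls[, -1]
  calls2[] <- "MF"
  calls2[5, 1:2] <- NA          # 2/9... construct exact 20%: use 10 fish
  calls3 <- matrix("MF", 10, 10, dimnames = dimnames(calls))
  calls3[1, ] <- rep(c("MM", "MF", "FF", "MF"), length.out = 10)
  calls3[4, 1:2] <- NA          # exactly 20% missing
  geno3 <- geno; geno3$calls <- calls3
  qc3 <- apply_qc(geno3, ratio_alpha = 1e-12)
  expect_false("1_3" %in% qc3$geno$markers$marker)
})

test_that("aberrant-ratio markers are dropped unless rescued by a skewed neighbour", {
  set.seed(44)
  n <- 200
  mk_calls <- function(p) sample(c("MM", "MF", "FF"), n, TRUE, prob = p)
  calls <- rbind(mk_calls(c(.25, .5, .25)),
                 mk_calls(c(.70, .25, .05)),   # isolated aberrant -> drop
                 mk_calls(c(.25, .5, .25)),
                 mk_calls(c(.05, .25, .70)),   # adjacent same-direction pair
                 mk_calls(c(.05, .25, .70)),   # -> both rescued
                 mk_calls(c(.25, .5, .25)))
  dimnames(calls) <- list(paste0("1_", 0:5), paste0("F", 1:n))
  geno <- structure(list(
    markers = data.frame(marker = rownames(calls), scaffold = "S1",
                         bin_index = 0:5, start = 1, end = 1000, n_snps = 5),
    m = matrix(50, 6, n, dimnames = dimnames(calls)),
    f = matrix(50, 6, n, dimnames = dimnames(calls)),
    calls = calls, posterior = array(1 / 3, c(6, n, 3)),
    f2 = colnames(calls), geno_config = geno_config()), class = "bin_geno")
  qc <- apply_qc(geno)
  kept <- qc$geno$markers$marker
  expect_false("1_1" %in% kept)
  expect_true(all(c("1_3", "1_4") %in% kept))
  # a clean 1:2:1 matrix loses nothing
  geno2 <- geno
  geno2$calls <- rbind(calls[c(1, 3, 6), ], calls[c(1, 3, 6), ])
  dimnames(geno2$calls) <- dimnames(calls)
  qc2 <- apply_qc(geno2)
  expect_equal(nrow(qc2$geno$markers), 6)
  expect_equal(nrow(qc2$drop_log), 0)
})

test_that("binned calls recover simulated truth at high accuracy", {
  # 350 F2s, ~100 SNPs per bin at 1.5x, epsilon = 0.01
  cfg <- sim_config(n_f2 = 350, n_chromosomes = 2,
                    scaffold_lengths = stats::setNames(rep(1.2e6, 4), paste0("S", 1:4)),
                    snp_density = 260, mean_coverage = 1.5, error_rate = 0.01,
                    seed = 45)
  sim <- simulate_cross(cfg)
  sv <- sieve_snps(sim$counts)
  counts <- binGBS:::subset_snps(sim$counts, which(sv$keep))
  geno <- bin_genotypes(counts, cfg$scaffold_lengths)
  expect_true(all(geno$markers$n_snps[geno$markers$n_snps > 0] >= 50))
  # truth at bin = truth genotype at the bin midpoint SNP
  truth_at <- function(marker_row, f2col) {
    mk <- geno$markers[marker_row, ]
    on <- which(sim$truth$snps$scaffold == mk$scaffold &
                  sim$truth$snps$pos >= mk$start & sim$truth$snps$pos <= mk$end)
    mid <- on[ceiling(length(on) / 2)]
    c("MM", "MF", "FF")[sim$truth$genotypes[mid, f2col] + 1]
  }
  tm <- vapply(seq_len(nrow(geno$markers)), function(i)
    vapply(seq_along(geno$f2), function(j) truth_at(i, j), character(1)),
    character(length(geno$f2)))
  tm <- t(tm)
  hard <- !is.na(geno$calls) & geno$calls %in% c("MM", "MF", "FF")
  concord <- mean(geno$calls[hard] == tm[hard])
  composite_ok <- mean(vapply(which(geno$calls %in% c("MM/MF", "MF/FF")),
                              function(k) grepl(tm[k], geno$calls[k], fixed = TRUE),
                              logical(1)))
  expect_gte(concord, 0.99)
  expect_lt(mean(is.na(geno$calls)), 0.05)
  expect_gt(composite_ok, 0.9)
  # undistorted markers segregate 1:2:1
  cnt <- c(sum(geno$calls == "MM", na.rm = TRUE),
           sum(geno$calls == "MF", na.rm = TRUE),
           sum(geno$calls == "FF", na.rm = TRUE))
  expect_gt(chisq.test(cnt, p = c(.25, .5, .25))$p.value, 1e-4)
})
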