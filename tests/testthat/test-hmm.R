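# exhaustive-enumeration oracle over all 3^n state paths
enum_oracle <- function(m, f, pos, spec) {
  n <- length(pos)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  le <- cbind(dbinom(f, m + f, spec$epsilon, log = TRUE),
              dbinom(f, m + f, 0.5, log = TRUE),
              dbinom(f, m + f, 1 - spec$epsilon, log = TRUE))
  trs <- lapply(diff(pos), function(d) {
    r <- (1 - exp(-2 * spec$rho * d / 1e8)) / 2; u <- 1 - r
    log(matrix(c(u^2, 2*r*u, r^2, r*u, u^2 + r^2, r*u, r^2, 2*r*u, u^2),
               3, 3, byrow = TRUE))
  })
  lp <- log(spec$init)[paths[, 1]] + le[cbind(rep(1, nrow(paths)), paths[, 1])]
  if (n > 1) for (t in 2:n)
    lp <- lp + vapply(seq_len(nrow(paths)), function(i)
      trs[[t - 1]][paths[i, t - 1], paths[i, t]], numeric(1)) +
      le[cbind(rep(t, nrow(paths)), paths[, t])]
  tot <- max(lp) + log(sum(exp(lp - max(lp))))
  post <- matrix(0, n, 3)
  for (t in 1:n) for (s in 1:3)
    post[t, s] <- sum(exp(lp[paths[, t] == s] - tot))
  list(posterior = post, loglik = tot, best = paths[which.max(lp), ],
       best_lp = max(lp))
}

test_that("transition matrices are stochastic and M/F-symmetric", {
  for (d in c(1e3, 1e5, 5e6)) {
    P <- binGBS:::hmm_transition(d, 3.5)
    expect_equal(rowSums(P), rep(1, 3))
    expect_equal(P, P[3:1, 3:1])        # relabeling M<->F mirrors the matrix
    expect_true(all(P >= 0))
  }
  expect_equal(binGBS:::hmm_transition(1e6, 0), diag(3))  # rho = 0: no moves
})

test_that("decoding matches exhaustive path enumeration on short chromosomes", {
  spec <- hmm_spec(rho = 5, epsilon = 0.02)
  set.seed(81)
  for (rep in 1:3) {
    n <- 8
    pos <- sort(sample.int(3e6, n))
    m <- rpois(n, 1.2); f <- rpois(n, 1.2)
    dec <- decode_chromosome(m, f, pos, spec)
    ora <- enum_oracle(m, f, pos, spec)
    expect_equal(unname(dec$posterior), ora$posterior, tolerance = 1e-9)
    expect_equal(dec$loglik, ora$loglik, tolerance = 1e-9)
    # Viterbi path attains the maximal path probability
    vit <- match(dec$viterbi, c("MM", "MF", "FF"))
    lp_vit <- log(spec$init[vit[1]]) +
      sum(dbinom(f, m + f, c(spec$epsilon, 0.5, 1 - spec$epsilon)[vit], log = TRUE))
    for (t in 2:n)
      lp_vit <- lp_vit + log(binGBS:::hmm_transition(pos[t] - pos[t - 1],
                                                     spec$rho)[vit[t - 1], vit[t]])
    expect_equal(lp_vit, ora$best_lp, tolerance = 1e-9)
  }
})

test_that("degenerate decodes behave as limits demand", {
  spec <- hmm_spec(rho = 3.5, epsilon = 0.02)
  # all-freshwater reads: FF throughout
  dec <- decode_chromosome(rep(0, 6), rep(5, 6), seq(1e5, 6e5, 1e5), spec)
  expect_true(all(dec$viterbi == "FF"))
  expect_true(all(dec$posterior[, "FF"] > 0.99))
  # rho = 0: posterior constant, equal to the pooled single-state posterior
  spec0 <- hmm_spec(rho = 0, epsilon = 0.02)
  m <- c(2, 1, 0, 3); f <- c(1, 2, 1, 1)
  dec0 <- decode_chromosome(m, f, c(1, 2, 3, 4) * 1e5, spec0)
  pooled <- binGBS:::bin_posterior(sum(m), sum(f), geno_config(epsilon = 0.02))
  for (t in 1:4) expect_equal(unname(dec0$posterior[t, ]), as.vector(pooled),
                              tolerance = 1e-12)
  # zero-read SNPs contribute flat emissions
  decz <- decode_chromosome(c(5, 0, 5), c(0, 0, 0), c(1e5, 2e5, 3e5), spec)
  expect_true(all(decz$viterbi == "MM"))
  expect_error(decode_chromosome(numeric(0), numeric(0), numeric(0), spec),
               "empty chromosome")
})

test_that("posteriors are normalised and label-symmetric", {
  spec <- hmm_spec(rho = 3.5, epsilon = 0.02)
  set.seed(82)
  n <- 60
  pos <- sort(sample.int(5e6, n))
  m <- rpois(n, 1.5); f <- rpois(n, 1.5)
  dec <- decode_chromosome(m, f, pos, spec)
  expect_equal(rowSums(dec$posterior), rep(1, n), tolerance = 1e-12)
  swapped <- decode_chromosome(f, m, pos, spec)
  expect_equal(unname(swapped$posterior), unname(dec$posterior[, 3:1]),
               tolerance = 1e-12)
})

test_that("breakpoint extraction brackets state changes and flags close doubles", {
  spec <- hmm_spec(rho = 3.5, epsilon = 0.01)
  pos <- seq(5e4, 3e6, by = 5e4)
  n <- length(pos)
  m <- c(rep(6, 25), rep(3, 5), rep(0, n - 30))
  f <- c(rep(0, 25), rep(3, 5), rep(6, n - 30))
  dec <- decode_chromosome(m, f, pos, spec)
  bp <- extract_breakpoints(dec, pos)
  expect_gte(nrow(bp), 1)
  expect_true(all(bp$left_bp < bp$right_bp))
  expect_equal(bp$from_state[1], "MM")
  expect_equal(bp$to_state[nrow(bp)], "FF")
  # no state change: empty result
  dec2 <- decode_chromosome(rep(3, 10), rep(0, 10), pos[1:10], spec)
  expect_equal(nrow(extract_breakpoints(dec2, pos[1:10])), 0)
  # two breakpoints within min_separation get flagged
  m3 <- c(rep(6, 20), rep(0, 4), rep(6, n - 24))
  f3 <- c(rep(0, 20), rep(6, 4), rep(0, n - 24))
  dec3 <- decode_chromosome(m3, f3, pos, spec)
  bp3 <- extract_breakpoints(dec3, pos, min_separation = 1e6)
  if (nrow(bp3) >= 2) expect_true(all(bp3$flagged))
})

test_that("breakpoint intervals are calibrated to the flank confidence", {
  cfg <- sim_config(n_f2 = 120, scaffold_lengths = c(S1 = 2e7), snp_density = 200,
                    mean_coverage = 1.5, error_rate = 0.02, seed = 83)
  sim <- simulate_cross(cfg)
  tr <- sim$truth$breakpoints
  containment <- function(tau) {
    bp <- finemap_breakpoints(sim$counts, hmm_spec(rho = 3.5, epsilon = 0.02),
                              tau = tau)
    hit <- mapply(function(f2, p)
      any(bp$f2 == f2 & bp$left_bp <= p & bp$right_bp >= p), tr$f2, tr$pos)
    c(rate = mean(hit), width = stats::median(bp$right_bp - bp$left_bp))
  }
  c95 <- containment(0.95)
  c975 <- containment(0.975)
  # joint containment ~ 1 - 2(1 - tau), allowing Monte-Carlo slack
  expect_gte(c95["rate"], 2 * 0.95 - 1 - 0.04)
  expect_gte(c975["rate"], 2 * 0.975 - 1 - 0.04)
  expect_gte(c975["width"], c95["width"])   # wider flanks, higher coverage
  # intervals are far smaller than the 500-kb bin scale
  expect_lt(c95["width"], 1e5)
})

test_that("minimal QTL intervals intersect recombinant constraints", {
  class_of <- c(MF = "high", FF = "low", MM = "high")
  # one recombinant matching its left side: right-bounded at b
  one <- data.frame(f2 = "x", left_bp = 100, right_bp = 200,
                    from_state = "MF", to_state = "FF", phenotype = "high",
                    stringsAsFactors = FALSE)
  res <- minimal_qtl_interval(one, class_of, region = c(0, 1000))
  expect_true(res$consistent)
  expect_equal(res$interval, c(0, 200))
  # opposite side
  two <- one; two$phenotype <- "low"
  res2 <- minimal_qtl_interval(two, class_of, region = c(0, 1000))
  expect_equal(res2$interval, c(100, 1000))
  # contradictory recombinants: no consistent interval
  both <- rbind(one, data.frame(f2 = "y", left_bp = 300, right_bp = 400,
                                from_state = "MF", to_state = "FF",
                                phenotype = "low", stringsAsFactors = FALSE))
  res3 <- minimal_qtl_interval(both, class_of, region = c(0, 1000))
  expect_false(res3$consistent)
  expect_true("y" %in% res3$offending)
})

test_that("simulated recombinants pin down a causal locus", {
  # causal recessive locus; recombinants bracket it from both sides
  set.seed(84)
  causal <- 5e5
  n_rec <- 10
  left <- runif(n_rec, 0, 1e6)
  width <- runif(n_rec, 2e4, 8e4)
  rec <- data.frame(f2 = paste0("r", 1:n_rec),
                    left_bp = left, right_bp = left + width,
                    from_state = "MF", to_state = "FF",
                    stringsAsFactors = FALSE)
  # true crossover inside each interval; genotype at the causal position
  # is the from-state left of the crossover, the to-state right of it
  x <- rec$left_bp + runif(n_rec) * width
  geno_at <- ifelse(causal < x, "MF", "FF")
  class_of <- c(MF = "high", FF = "low")
  rec$phenotype <- unname(class_of[geno_at])
  res <- minimal_qtl_interval(rec, class_of, region = c(0, 1e6))
  expect_true(res$consistent)
  expect_true(res$interval[1] <= causal && res$interval[2] >= causal)
})
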