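# Shared fixtures, built in code. Seeds are fixed per fixture so tests are
# deterministic; sims are cached per session to keep the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small two-chromosome cross used by several modules
sim_small <- function() cached("small", {
  cfg <- sim_config(n_f2 = 150, n_chromosomes = 2,
                    scaffold_lengths = stats::setNames(rep(2e6, 4), paste0("S", 1:4)),
                    snp_density = 150, mean_coverage = 1.5, error_rate = 0.01,
                    seed = 101)
  simulate_cross(cfg)
})

# simulate genotype calls for markers along one chromosome directly from
# the gamete Markov chain (independent oracle-style generator: no reads,
# no binning -- used by linkage tests)
sim_marker_calls <- function(n_f2, r_adj, seed) {
  set.seed(seed)
  K <- length(r_adj) + 1
  dos <- matrix(0L, K, n_f2)
  for (i in seq_len(n_f2)) {
    g <- matrix(0L, K, 2)
    for (k in 1:2) {
      a <- integer(K)
      a[1] <- stats::rbinom(1, 1, 0.5)
      for (t in 2:K)
        a[t] <- if (stats::runif(1) < r_adj[t - 1]) 1L - a[t - 1] else a[t - 1]
      g[, k] <- a
    }
    dos[, i] <- rowSums(g)
  }
  matrix(c("MM", "MF", "FF")[dos + 1], K, n_f2,
         dimnames = list(paste0("M", seq_len(K)), NULL))
}
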