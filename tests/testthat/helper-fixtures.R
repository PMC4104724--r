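# Shared fixtures: small cohorts and hand-built matrices.

small_cohort <- function(n_probes = 60, n_cases = 10, n_controls = 8,
                         n_de = 6, effect_size = 2, noise_sd = 1, seed = 42) {
  generate_expression(n_probes, n_cases, n_controls, n_de,
                      effect_size, noise_sd, seed = seed)
}

# random centered/scaled design + centered 0/1 response, wrapped as the
# standardized container the NIPALS fitter consumes
random_standardized <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X)
  attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  y <- rep(c(0, 1), length.out = n)[sample(n)]
  structure(list(X = `dimnames<-`(unclass(X), list(sprintf("s%02d", 1:n),
                                                   sprintf("p%03d", 1:p))),
                 y = y - mean(y), center = setNames(rep(0, p), sprintf("p%03d", 1:p)),
                 scale = setNames(rep(1, p), sprintf("p%03d", 1:p)),
                 y_mean = mean(y), probe_ids = sprintf("p%03d", 1:p),
                 sample_ids = sprintf("s%02d", 1:n),
                 dropped = character(), scale_columns = TRUE),
            class = "pls_standardized")
}

# per-stage seeds, mirroring the pipeline's own derivation convention
derive_seed_for_test <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}

# independent brute-force evaluation of the upper-tail hypergeometric sum
brute_hyper_upper <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# brute-force Benjamini-Hochberg step-up
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}
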