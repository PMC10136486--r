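# Brute-force multivariate-normal log-density, written independently of the
# engine (determinant + solve, per case) to serve as the FIML oracle.
mvn_logdens <- function(x, mu, sigma) {
  p <- length(x)
  d <- x - mu
  as.numeric(-0.5 * (p * log(2 * pi) +
                       determinant(sigma, logarithm = TRUE)$modulus +
                       drop(d %*% solve(sigma, d))))
}

# Per-case FIML log-likelihood computed the slow way from a raw score matrix.
bruteforce_fiml <- function(theta, X) {
  mom <- implied_moments(theta)
  sum(vapply(seq_len(nrow(X)), function(i) {
    v <- which(!is.na(X[i, ]))
    mvn_logdens(X[i, v], mom$mu[v], mom$sigma[v, v, drop = FALSE])
  }, numeric(1)))
}

# Default illustrative truth used across engine tests.
default_truth <- function() synthetic_config()$true_paths

# A cohort matrix with a controllable share of baseline-only cases.
make_panel <- function(n, seed = 1, dropout_rate = 0.229, theta = default_truth()) {
  cfg <- synthetic_config(n_participants = n, seed = seed,
                          dropout = dropout_spec(target_rate = dropout_rate))
  cfg$true_paths <- theta
  generate_cohort(cfg)
}
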