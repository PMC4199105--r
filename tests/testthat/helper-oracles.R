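# Dense, brute-force oracles kept deliberately independent of the package's
# rotated/Woodbury code paths: everything here goes through solve() and
# determinant() on the full covariance.

dense_mvn_nll <- function(z, mean, Sigma) {
  n <- length(z)
  r <- z - mean
  0.5 * (n * log(2 * pi) +
           as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
           drop(crossprod(r, solve(Sigma, r))))
}

# Profiled Gaussian NLL at a fixed covariance V (unit residual scale
# profiled out), used as the GLS oracle for association statistics.
dense_gls_nll <- function(z, X, V) {
  n <- length(z)
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% z))
  r <- z - X %*% beta
  q <- drop(crossprod(r, Vi %*% r))
  0.5 * (n * log(2 * pi) +
           as.numeric(determinant(V, logarithm = TRUE)$modulus) +
           n * log(q / n) + n)
}

# quick standardized genotype matrix for small fixtures
small_std_geno <- function(n, s, seed) {
  cfg <- sim_config(n = n, s = s, n_causal = 1, h2 = 0.5, seed = seed)
  suppressMessages(standardize_genotypes(simulate_genotypes(cfg)))
}
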