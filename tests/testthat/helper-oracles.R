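# Independent maximizer of the penalized glasso objective on p = 3 problems:
# Nelder-Mead over the 6 free entries of symmetric K (log-parameterized
# diagonal), restarted from its own optimum until it stops improving.
nm_glasso_objective <- function(K, S, lam)
  as.numeric(determinant(K)$modulus) - sum(S * K) -
    lam * 2 * sum(abs(K[upper.tri(K)]))

nm_glasso_oracle <- function(S, lam, restarts = 8) {
  to_K <- function(th) {
    K <- diag(exp(th[1:3]))
    K[1, 2] <- K[2, 1] <- th[4]; K[1, 3] <- K[3, 1] <- th[5]
    K[2, 3] <- K[3, 2] <- th[6]
    K
  }
  f <- function(th) {
    K <- to_K(th)
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
      return(1e10)
    -nm_glasso_objective(K, S, lam)
  }
  th <- rep(0, 6)
  best <- f(th)
  for (r in seq_len(restarts)) {
    opt <- optim(th, f, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-15))
    if (best - opt$value < 1e-12) { best <- opt$value; th <- opt$par; break }
    best <- opt$value
    th <- opt$par
  }
  list(objective = -best, K = to_K(th))
}
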