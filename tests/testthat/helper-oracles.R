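# Independent oracles used to cross-check the package's estimators.
# These deliberately avoid the code paths they verify.

# Brute-force maximum-likelihood logistic regression via general-purpose
# optimisation of the Bernoulli log-likelihood (no IRLS).
oracle_logistic <- function(y, X) {
  X1 <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  k <- ncol(X1)
  o <- stats::optim(rep(0, k), nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o <- stats::optim(o$par, nll, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  o$par
}

# Gaussian Bayes factor by numeric integration of the N(0, W) effect prior
# against the N(beta, se^2) likelihood of the estimate.
oracle_log_abf <- function(beta, se, w) {
  num <- stats::integrate(
    function(b) stats::dnorm(beta, b, se) * stats::dnorm(b, 0, sqrt(w)),
    -Inf, Inf, rel.tol = 1e-12
  )$value
  log(num) - stats::dnorm(beta, 0, se, log = TRUE)
}

# Maximum-likelihood IBD estimation over the (k0, k1, k2) simplex by a
# coarse-then-refined grid search on the per-site IBS-class likelihood.
oracle_pihat <- function(g1, g2, freqs) {
  ok <- !is.na(g1) & !is.na(g2) & freqs > 0 & freqs < 1
  g1 <- g1[ok]; g2 <- g2[ok]; p <- freqs[ok]
  d <- abs(g1 - g2)
  q <- 1 - p
  p0_0 <- 2 * p^2 * q^2
  p1_0 <- 4 * p^3 * q + 4 * p * q^3
  p2_0 <- 1 - p0_0 - p1_0
  p1_1 <- 2 * p * q
  p2_1 <- p^2 + q^2
  l0 <- ifelse(d == 2, p0_0, ifelse(d == 1, p1_0, p2_0))
  l1 <- ifelse(d == 2, 0, ifelse(d == 1, p1_1, p2_1))
  l2 <- ifelse(d == 0, 1, 0)
  eval_grid <- function(k0s, k1s) {
    grid <- expand.grid(k0 = k0s, k1 = k1s)
    grid <- grid[grid$k0 + grid$k1 <= 1 + 1e-12, ]
    K <- rbind(grid$k0, grid$k1, pmax(1 - grid$k0 - grid$k1, 0))
    mix <- cbind(l0, l1, l2) %*% K
    ll <- colSums(log(pmax(mix, 1e-300)))
    ll[apply(mix <= 0, 2, any)] <- -Inf
    grid[which.max(ll), ]
  }
  best <- eval_grid(seq(0, 1, 0.05), seq(0, 1, 0.05))
  for (step in c(0.01, 0.002)) {
    win <- 5 * step
    best <- eval_grid(
      seq(max(best$k0 - win, 0), min(best$k0 + win, 1), step),
      seq(max(best$k1 - win, 0), min(best$k1 + win, 1), step)
    )
  }
  unname(best$k1 / 2 + max(1 - best$k0 - best$k1, 0))
}

# HWE genotypes for independent individuals at given alt freqs.
sim_hwe_geno <- function(n, freqs) {
  sapply(freqs, function(p) stats::rbinom(n, 2, p))
}

# Study alternate-allele frequency from a genotype matrix.
est_freq <- function(geno) colMeans(geno, na.rm = TRUE) / 2
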