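# Independent oracles used across the suite. These never call the package's
# own likelihood code.

# Closed-form REML estimators for a balanced one-way layout:
# sigma2_between = (MSB - MSW) / n_per_group, sigma2_within = MSW.
oracle_oneway <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  m <- length(y) / k
  gm <- tapply(y, g, mean)
  msb <- m * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[g])^2) / (length(y) - k)
  c(between = (msb - msw) / m, within = msw)
}

# Brute-force restricted log-likelihood from its definition, dense algebra.
bruteforce_reml_loglik <- function(y, X, Zlist, sigma2, s2e) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(s2e, n)
  for (k in seq_along(Zlist)) {
    V <- V + sigma2[k] * tcrossprod(as.matrix(Zlist[[k]]))
  }
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XVX)$modulus +
                       t(y) %*% P %*% y))
}

# Brute-force REML log-likelihood for the explicitly *correlated bivariate*
# focal/competitor strain parameterisation on both orientations of each
# pot: strain s has a focal effect f_s and competitor effect c_s with
# var(f) = var(c) = s2g and cor(f, c) = rho (+1 or -1). Equivalent to the
# signed single-vector incidence the package uses.
bruteforce_bivariate_loglik <- function(y, X, focal, comp, rho, s2g,
                                        Zother = list(), s2other = numeric(0),
                                        s2e) {
  strains <- sort(unique(c(focal, comp)))
  Zf <- outer(focal, strains, "==") * 1
  Zc <- outer(comp, strains, "==") * 1
  # cov contribution: s2g (Zf Zf' + Zc Zc') + rho s2g (Zf Zc' + Zc Zf')
  V <- s2g * (tcrossprod(Zf) + tcrossprod(Zc)) +
    rho * s2g * (Zf %*% t(Zc) + Zc %*% t(Zf)) + diag(s2e, length(y))
  for (k in seq_along(Zother)) {
    V <- V + s2other[k] * tcrossprod(as.matrix(Zother[[k]]))
  }
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
                       determinant(XVX)$modulus + t(y) %*% P %*% y))
}

# Straight normal-equations OLS with the F test computed from sums of
# squares and pf(), independent of lm().
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  e <- y - X %*% beta
  n <- length(y)
  sse <- sum(e^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  f <- (ssr / 1) / (sse / (n - 2))
  list(intercept = beta[1], slope = beta[2], f = f,
       p = stats::pf(f, 1, n - 2, lower.tail = FALSE),
       r2 = ssr / sst)
}

# Small ready-made simulated dataset shared by several tests.
small_sim <- function(seed = 11, ...) {
  simulate_experiment(sim_config(n_strains = 4, n_blocks = 3, seed = seed,
                                 ...))
}
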