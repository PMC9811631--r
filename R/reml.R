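#' Restricted maximum likelihood fit of a variance-component model
#'
#' Fits `y = X beta + sum_k Z_k u_k + e` with `u_k ~ N(0, sigma2_k I)` and
#' `e ~ N(0, sigma2_e I)` by maximising the restricted log-likelihood
#' `-1/2 [ (n-p) log 2pi + log|V| + log|X' V^-1 X| + y' P y ]` over
#' non-negative variances, where `V = sum_k sigma2_k Z_k Z_k' + sigma2_e I`.
#' Incidence matrices may carry signed entries, which is how the
#' equal-variance, correlation +1 / -1 constraints between focal and
#' competitor strain effects are imposed: a single strain-effect vector
#' with +1/+1 (shoot mass) or +1/-1 (nodule proportion) incidence is
#' exactly equivalent to a correlated bivariate effect.
#'
#' Internally the residual variance is profiled out and the likelihood is
#' evaluated through the q x q matrix `I + D Z'Z D` (`D` diagonal in the
#' square-root variance ratios), so the cost per evaluation scales with
#' the number of random-effect levels, not with the number of
#' observations. One disjoint 0/1 grouping term (typically the pot term,
#' whose levels outnumber everything else) can be absorbed analytically
#' through its block-diagonal contribution, which keeps the inner solve
#' small. Variance ratios are optimised on the log scale (Nelder-Mead from
#' several starts, then a bounded quasi-Newton polish); a floor on the
#' log-ratio keeps estimates non-negative while allowing components to
#' collapse to the boundary.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effects design matrix (full column rank).
#' @param random Named list of incidence matrices `Z_k` (same row count as
#'   `y`); may be empty.
#' @param absorb Optional name of one element of `random` whose incidence
#'   is a disjoint 0/1 indicator (each row has a single 1); it is handled
#'   in closed form. `NULL` picks the indicator term with the most levels
#'   automatically when that term has more than 32 levels.
#' @param lower_log_gamma Floor for log(sigma2_k / sigma2_e).
#' @param n_starts Number of Nelder-Mead starting points (1-3).
#' @param start Optional named vector of starting log variance ratios,
#'   tried in addition to the fixed starting points.
#' @param control List; `maxit` caps Nelder-Mead iterations.
#' @return An object of class `"reml_fit"`: `sigma2` (named vector of
#'   variance components, residual last), `loglik`, `beta`, `blup` (named
#'   list of predicted random effects), `converged`, `iterations`, `n`,
#'   `p`.
#' @export
reml_fit <- function(y, X, random, absorb = NULL, lower_log_gamma = -18,
                     n_starts = 3, start = NULL,
                     control = list(maxit = 400)) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) abort("More fixed-effect columns than observations.")
  if (qr(X)$rank < p) abort("Fixed-effects design is rank deficient.")
  K <- length(random)
  if (K > 0 && (is.null(names(random)) || any(names(random) == ""))) {
    abort("`random` must be a named list of incidence matrices.")
  }

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  if (K == 0L) {
    cX <- chol(XtX)
    beta <- backsolve(cX, forwardsolve(t(cX), Xty))
    r <- yty - sum(Xty * beta)
    s2e <- r / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * (1 + log(s2e)) +
                    determinant(XtX / s2e)$modulus[1])
    return(structure(list(sigma2 = c(residual = s2e), gamma = numeric(0),
                          loglik = as.numeric(ll),
                          beta = setNames(as.numeric(beta), colnames(X)),
                          blup = list(), converged = TRUE, iterations = 0L,
                          n = n, p = p),
                     class = "reml_fit"))
  }

  Zs <- lapply(random, as.matrix)
  is_ind <- vapply(Zs, function(Z) {
    all(Z %in% c(0, 1)) && all(rowSums(Z) == 1)
  }, logical(1))
  if (is.null(absorb)) {
    cand <- which(is_ind & vapply(Zs, ncol, integer(1)) > 32L)
    if (length(cand)) absorb <- names(Zs)[cand[which.max(
      vapply(Zs[cand], ncol, integer(1)))]]
  } else if (is.na(absorb) || !nzchar(absorb)) {
    absorb <- NULL
  }
  if (!is.null(absorb)) {
    if (!absorb %in% names(Zs) || !is_ind[[absorb]]) {
      abort("`absorb` must name a disjoint 0/1 indicator term.")
    }
  }

  a_idx <- if (is.null(absorb)) 0L else match(absorb, names(Zs))
  other <- setdiff(seq_len(K), a_idx)
  Ko <- length(other)
  Z <- if (Ko) do.call(cbind, Zs[other]) else matrix(0, n, 0)
  sizes <- if (Ko) vapply(Zs[other], ncol, integer(1)) else integer(0)
  grp <- rep(seq_len(Ko), sizes)
  q <- ncol(Z)

  A <- crossprod(Z)
  ZtX <- crossprod(Z, X)
  Zty <- crossprod(Z, y)
  if (a_idx > 0L) {
    gidx <- max.col(Zs[[a_idx]], ties.method = "first")
    G <- ncol(Zs[[a_idx]])
    m_g <- as.numeric(tabulate(gidx, nbins = G))
    if (any(m_g == 0)) {
      abort("Absorbed grouping term has empty levels; drop them first.")
    }
    Zg <- rowsum(Z, gidx, reorder = TRUE)
    Xg <- rowsum(X, gidx, reorder = TRUE)
    yg <- as.numeric(rowsum(y, gidx, reorder = TRUE))
  }

  # evaluate -logL (profiled over residual variance) at log-ratios theta
  crit <- function(theta) {
    fail <- list(value = 1e10)
    ga <- if (a_idx > 0L) exp(theta[a_idx]) else 0
    if (a_idx > 0L) {
      w <- ga / (1 + ga * m_g)
      A_R <- A - crossprod(sqrt(w) * Zg)
      ZtX_R <- ZtX - crossprod(Zg, w * Xg)
      Zty_R <- Zty - crossprod(Zg, w * yg)
      XtX_R <- XtX - crossprod(Xg, w * Xg)
      Xty_R <- Xty - crossprod(Xg, w * yg)
      yty_R <- yty - sum(w * yg^2)
      logdetR <- sum(log1p(ga * m_g))
    } else {
      A_R <- A; ZtX_R <- ZtX; Zty_R <- Zty
      XtX_R <- XtX; Xty_R <- Xty; yty_R <- yty
      logdetR <- 0
    }
    if (q > 0L) {
      dvec <- sqrt(exp(theta[other]))[grp]
      M <- A_R * tcrossprod(dvec)
      diag(M) <- diag(M) + 1
      L <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(L)) return(fail)
      logdetH <- logdetR + 2 * sum(log(diag(L)))
      B <- cbind(dvec * ZtX_R, dvec * Zty_R)
      U <- backsolve(L, forwardsolve(t(L), B))
      XtHiX <- XtX_R - crossprod(B[, seq_len(p), drop = FALSE],
                                 U[, seq_len(p), drop = FALSE])
      XtHiy <- Xty_R - crossprod(B[, seq_len(p), drop = FALSE],
                                 U[, p + 1L, drop = FALSE])
      ytHiy <- yty_R - sum(B[, p + 1L] * U[, p + 1L])
    } else {
      dvec <- numeric(0); L <- NULL
      logdetH <- logdetR
      XtHiX <- XtX_R; XtHiy <- Xty_R; ytHiy <- yty_R
    }
    cF <- tryCatch(chol(XtHiX), error = function(e) NULL)
    if (is.null(cF)) return(fail)
    beta <- backsolve(cF, forwardsolve(t(cF), XtHiy))
    r <- ytHiy - sum(XtHiy * beta)
    if (!is.finite(r) || r <= 1e-12 * yty) return(fail)
    s2e <- r / (n - p)
    nll <- 0.5 * ((n - p) * log(2 * pi) + (n - p) * (1 + log(s2e)) +
                    logdetH + 2 * sum(log(diag(cF))))
    list(value = nll, beta = beta, s2e = s2e, L = L, dvec = dvec,
         gamma = exp(theta))
  }
  obj <- function(theta) crit(theta)$value

  starts <- list(rep(log(0.5 / K), K), rep(log(0.1), K), rep(log(1), K))
  starts <- starts[seq_len(min(max(1L, n_starts), 3L))]
  if (!is.null(start)) {
    th <- rep(log(0.1), K)
    names(th) <- names(random)
    th[intersect(names(start), names(th))] <-
      start[intersect(names(start), names(th))]
    starts <- c(list(pmin(pmax(unname(th), lower_log_gamma), 15)), starts)
  }

  best <- NULL
  iters <- 0L
  conv <- FALSE
  maxit_nm <- control$maxit %||% 400
  for (th0 in starts) {
    op <- tryCatch(
      if (K == 1L) {
        optim(th0, obj, method = "Brent", lower = lower_log_gamma,
              upper = 15)
      } else {
        optim(th0, obj, method = "Nelder-Mead",
              control = list(maxit = maxit_nm, reltol = 1e-12))
      },
      error = function(e) NULL)
    if (is.null(op)) next
    iters <- iters + op$counts[[1]]
    if (is.null(best) || op$value < best$value - 1e-9) {
      best <- op
      conv <- op$convergence == 0
    }
  }
  if (!is.null(best) && best$value < 1e9 && K > 1L) {
    pol <- tryCatch(
      optim(pmin(pmax(best$par, lower_log_gamma), 15), obj,
            method = "L-BFGS-B", lower = lower_log_gamma, upper = 15,
            control = list(maxit = 30)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) {
      iters <- iters + pol$counts[[1]]
      conv <- conv || pol$convergence == 0
      best <- pol
    }
  }
  if (is.null(best) || best$value >= 1e9) {
    abort("REML optimisation failed for every starting point.")
  }

  fin <- crit(best$par)
  gamma <- setNames(fin$gamma, names(random))
  s2e <- fin$s2e
  sigma2 <- setNames(c(gamma * s2e, s2e), c(names(random), "residual"))
  at_floor <- gamma <= exp(lower_log_gamma) * (1 + 1e-6)
  sigma2[seq_len(K)][at_floor] <- 0

  # BLUPs: u_k = gamma_k Z_k' H^-1 (y - X beta), computed at row level
  resid_v <- as.numeric(y - X %*% fin$beta)
  Rinv <- function(v) {
    if (a_idx == 0L) return(v)
    ga <- gamma[[a_idx]]
    w <- ga / (1 + ga * m_g)
    v - (w * as.numeric(rowsum(v, gidx, reorder = TRUE)))[gidx]
  }
  Hr <- Rinv(resid_v)
  if (q > 0L) {
    t1 <- fin$dvec * crossprod(Z, Hr)
    s <- backsolve(fin$L, forwardsolve(t(fin$L), t1))
    Hr <- Hr - Rinv(as.numeric(Z %*% (fin$dvec * s)))
  }
  blup <- lapply(seq_len(K), function(k) {
    u <- gamma[[k]] * as.numeric(crossprod(Zs[[k]], Hr))
    setNames(u, colnames(Zs[[k]]))
  })
  names(blup) <- names(random)

  structure(list(sigma2 = sigma2, gamma = gamma,
                 loglik = -best$value,
                 beta = setNames(as.numeric(fin$beta), colnames(X)),
                 blup = blup, converged = conv, iterations = iters,
                 n = n, p = p),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML variance-component fit\n")
  cat(sprintf("  n = %d, fixed effects = %d, REML logLik = %.4f%s\n",
              x$n, x$p, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$sigma2, 6))
  invisible(x)
}
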