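# Restricted maximum likelihood for the one-kernel mixed model
#   y = 1 mu + g + e,  g ~ N(0, varU * K),  e ~ N(0, varE * I)
# profiled over lambda = varE / varU via the spectral decomposition of the
# kernel restricted to the complement of the intercept.

.REML_LAMBDA_RANGE <- c(1e-5, 1e5)

# Returns mu, alpha = (K + lambda I)^{-1} (y - mu), lambda, varU, varE, logLik.
remlKernel <- function(K, y, lambda = NULL, tol = 1e-8) {
  n <- length(y)
  if (nrow(K) != n) stop("kernel and phenotype dimensions disagree")
  X <- matrix(1, n, 1)
  # orthonormal complement of the intercept
  Q <- qr.Q(qr(X), complete = TRUE)[, -1L, drop = FALSE]
  K2 <- crossprod(Q, K %*% Q)
  K2 <- (K2 + t(K2)) / 2
  eg <- eigen(K2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  y2 <- drop(crossprod(eg$vectors, crossprod(Q, y)))
  ss <- sum(y2^2)
  if (ss < 1e-24) {
    # constant phenotype: no genetic signal, predictions collapse to the mean
    lambda <- .REML_LAMBDA_RANGE[2L]
    mu <- mean(y)
    return(list(mu = mu, alpha = rep(0, n), lambda = lambda,
                varU = 0, varE = 0, logLik = NA_real_, converged = TRUE))
  }
  negll <- function(loglam) {
    lam <- exp(loglam)
    dl <- d + lam
    vu <- sum(y2^2 / dl) / (n - 1)
    0.5 * ((n - 1) * log(vu) + sum(log(dl)))
  }
  converged <- TRUE
  if (is.null(lambda)) {
    opt <- stats::optimize(negll, log(.REML_LAMBDA_RANGE), tol = tol)
    lambda <- exp(opt$minimum)
    if (!is.finite(opt$objective)) {
      # flat likelihood: fall back to a coarse grid optimum
      grid <- exp(seq(log(.REML_LAMBDA_RANGE[1L]), log(.REML_LAMBDA_RANGE[2L]),
                      length.out = 41L))
      vals <- vapply(log(grid), negll, numeric(1))
      lambda <- grid[which.min(vals)]
      converged <- FALSE
      warning("REML optimization did not converge; using grid optimum")
    }
  }
  dl <- d + lambda
  varU <- sum(y2^2 / dl) / (n - 1)
  varE <- lambda * varU
  # GLS intercept and coefficients on the original scale
  Vinv <- function(b) {
    # (K + lambda I)^{-1} b via full eigen of K (computed lazily once)
    drop(egK$vectors %*% ((crossprod(egK$vectors, b)) / (egK$values + lambda)))
  }
  Ks <- (K + t(K)) / 2
  egK <- eigen(Ks, symmetric = TRUE)
  # floor tiny negative eigenvalues; lambda > 0 keeps the inversion stable
  egK$values <- pmax(egK$values, 0)
  viy <- Vinv(y)
  vi1 <- Vinv(rep(1, n))
  mu <- sum(viy) / sum(vi1)
  alpha <- Vinv(y - mu)
  list(mu = mu, alpha = alpha, lambda = lambda, varU = varU, varE = varE,
       logLik = -negll(log(lambda)), converged = converged)
}
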