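# shared fixture builders (everything generated in code)

tinyHistory <- function() {
  detectionHistory(rbind(a = c(0L, 1L, 0L, NA, 0L),
                         b = c(0L, 0L, 0L, 0L, 0L),
                         c = c(1L, 1L, NA, NA, 1L)))
}

# random parameter draw for the correlated kernel, away from the boundary
randomChainParams <- function() {
  list(psi = runif(1, 0.05, 0.95),
       theta0 = runif(1, 0.05, 0.95),
       theta1 = runif(1, 0.05, 0.95),
       pi = runif(1, 0.05, 0.95),
       p = runif(1, 0.05, 0.95))
}

randomHistory <- function(K, missProb = 0.15) {
  h <- sample(0:1, K, replace = TRUE)
  h[runif(K) < missProb] <- NA
  h
}

# all 2^K binary histories as rows
allHistories <- function(K) {
  as.matrix(expand.grid(rep(list(0:1), K)))
}

# a fitted standard intercept-only model wrapped by hand, for tests that
# need exact parameter values rather than an optimiser output
handmadeFit <- function(psi, p, y, covs = NULL) {
  if (is.null(covs)) {
    d <- data.frame(row.names = siteIDs(y))
    covs <- new("SiteCovariates", data = d, scaled = FALSE,
                scaleParams = list())
  }
  spec <- occuSpec(correlated = FALSE)
  coefs <- c(qlogis(psi), qlogis(p))
  names(coefs) <- c("psi_(Intercept)", "p_(Intercept)")
  ll <- -negLogLikelihood(coefs, y, covs, spec)
  new("OccuFit", spec = spec, coefficients = coefs, loglik = ll,
      K = 2L, aic = -2 * ll + 4, vcov = matrix(NA_real_, 2, 2),
      converged = TRUE, gradNorm = 0, nStartsUsed = 1L,
      boundaryFlags = character(0), y = y, covs = covs)
}
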