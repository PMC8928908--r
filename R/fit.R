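## local RNG scope: seed without disturbing the caller's stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## central-difference gradient and Hessian of a scalar function
.numGradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

.numHessian <- function(f, x, h = 1e-5) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- numeric(k); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Fit an occupancy model by maximum likelihood
#'
#' Minimises the negative log-likelihood with quasi-Newton (BFGS) runs from
#' multiple jittered starting points (the likelihood surface of the
#' correlated model can be multimodal), keeping the best local optimum.
#' Starts are drawn N(0, 1) around zero on the link scale from the given
#' seed, with the first start always exactly zero. The variance-covariance
#' matrix is the inverse of the central-difference Hessian of the NLL at the
#' optimum; a non-positive-definite Hessian marks the fit as not converged
#' rather than silently pseudo-inverting.
#'
#' @param y a \linkS4class{DetectionHistory}.
#' @param covs scaled \linkS4class{SiteCovariates} with matching sites.
#' @param spec an \linkS4class{OccuModelSpec}.
#' @param nStarts number of optimisation starts (default 10).
#' @param seed integer seed for the start jitter.
#' @param start optional explicit starting vector used for the first start
#'   (remaining starts jitter around it).
#' @param segCovs optional segment-level covariates.
#' @return an \linkS4class{OccuFit}.
#' @examples
#' sim <- simulateDataset(simConfig(nSites = 60, seed = 7))
#' fitOccu(sim$y, sim$covs, occuSpec(), nStarts = 2, seed = 1)
#' @export
fitOccu <- function(y, covs, spec, nStarts = 10L, seed = 1L, start = NULL,
                    segCovs = NULL) {
  stopifnot(is(y, "DetectionHistory"), is(covs, "SiteCovariates"),
            is(spec, "OccuModelSpec"), nStarts >= 1L)
  if (!isScaled(covs) &&
      (length(spec@psiCovariates) || length(spec@pCovariates)))
    stop("covariates must be scaled before fitting (scaleCovariates)")
  K <- countParameters(spec)
  obj <- function(par) negLogLikelihood(par, y, covs, spec, segCovs)
  base_start <- if (is.null(start)) numeric(K) else {
    stopifnot(length(start) == K); as.numeric(start)
  }
  starts <- .withSeed(seed, {
    s <- replicate(nStarts, base_start + stats::rnorm(K), simplify = FALSE)
    s[[1L]] <- base_start
    s
  })
  best <- NULL
  diagnostics <- character(0)
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(res))
      next
    }
    if (!is.finite(res$value)) {
      diagnostics <- c(diagnostics, "non-finite objective at optimum")
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all starts failed:\n", paste(diagnostics, collapse = "\n"))

  mle <- best$par
  names(mle) <- .paramNames(spec)
  nll <- best$value
  grad <- .numGradient(obj, mle)
  gradNorm <- sqrt(sum(grad^2))
  H <- .numHessian(obj, mle)
  ev <- eigen(0.5 * (H + t(H)), symmetric = TRUE, only.values = TRUE)$values
  pd <- all(ev > 0)
  V <- if (pd) {
    Vm <- solve(0.5 * (H + t(H)))
    0.5 * (Vm + t(Vm))
  } else matrix(NA_real_, K, K)
  dimnames(V) <- list(names(mle), names(mle))
  converged <- best$convergence == 0 && pd &&
    gradNorm < 1e-4 * (1 + abs(nll))

  lp <- linearPredictors(spec, mle, covs, nSeg = nSegments(y), segCovs)
  boundary <- character(0)
  if (any(lp$psi < 1e-4) || any(lp$psi > 1 - 1e-4))
    boundary <- c(boundary, "psi")
  pv <- if (is.matrix(lp$p)) as.vector(lp$p) else lp$p
  if (any(pv < 1e-4) || any(pv > 1 - 1e-4)) boundary <- c(boundary, "p")
  if (spec@correlated) {
    for (nm in c("theta0", "theta1", "pi")) {
      v <- lp[[nm]]
      if (v < 1e-4 || v > 1 - 1e-4) boundary <- c(boundary, nm)
    }
  }

  new("OccuFit", spec = spec, coefficients = mle, loglik = -nll,
      K = as.integer(K), aic = 2 * nll + 2 * K, vcov = V,
      converged = converged, gradNorm = gradNorm,
      nStartsUsed = as.integer(nStarts), boundaryFlags = boundary,
      y = y, covs = covs)
}

## real-scale parameter vector as a function of the packed parameters,
## evaluated at covariate profile `at` (named list/vector on the scaled
## covariate scale; missing names default to 0 = training mean)
.realFun <- function(spec, covNamesPsi, covNamesP) {
  function(params, at) {
    sp <- .splitParams(params, spec)
    xpsi <- c(1, vapply(covNamesPsi, function(nm)
      if (nm %in% names(at)) at[[nm]] else 0, numeric(1)))
    xp <- c(1, vapply(covNamesP, function(nm)
      if (nm %in% names(at)) at[[nm]] else 0, numeric(1)))
    out <- c(psi = stats::plogis(sum(xpsi * sp$betaPsi)),
             p = stats::plogis(sum(xp * sp$alphaP)))
    if (spec@correlated)
      out <- c(out, theta0 = sp$theta0, theta1 = sp$theta1, pi = sp$pi)
    out
  }
}

#' Real-scale parameter estimates with delta-method SEs
#'
#' Back-transforms the fitted logit-scale parameters to probabilities
#' (occupancy, detection, and for correlated fits theta0, theta1, pi),
#' evaluated at a covariate profile (default: all covariates at their
#' training mean, i.e. zero on the z-scale). Standard errors come from the
#' delta method, J V J' with J the Jacobian of the back-transformation. The
#' 95% confidence limits are computed as a Wald interval on the logit scale
#' and back-transformed, so they respect (0, 1) and are asymmetric; this
#' construction has markedly better coverage than a symmetric real-scale
#' interval when a parameter sits near a likelihood ridge or boundary.
#'
#' @param fit a converged \linkS4class{OccuFit}.
#' @param at named numeric vector/list of scaled covariate values; omitted
#'   covariates sit at 0 (the sample mean).
#' @param force evaluate even when the fit did not converge.
#' @return data.frame with columns parameter, estimate, se, lci, uci.
#' @export
realParameters <- function(fit, at = list(), force = FALSE) {
  stopifnot(is(fit, "OccuFit"))
  if (!fit@converged && !force)
    stop("fit did not converge; use force = TRUE to evaluate anyway")
  spec <- fit@spec
  f <- .realFun(spec, spec@psiCovariates, spec@pCovariates)
  vals <- f(fit@coefficients, at)
  J <- t(vapply(seq_along(fit@coefficients), function(i) {
    e <- numeric(length(fit@coefficients)); e[i] <- 1e-6
    (f(fit@coefficients + e, at) - f(fit@coefficients - e, at)) / 2e-6
  }, numeric(length(vals))))
  V <- fit@vcov
  se <- if (anyNA(V)) rep(NA_real_, length(vals)) else
    sqrt(pmax(0, diag(t(J) %*% V %*% J)))
  ci <- .logitScaleCI(unname(vals), unname(se))
  data.frame(parameter = names(vals), estimate = unname(vals),
             se = unname(se), lci = ci$lci, uci = ci$uci,
             stringsAsFactors = FALSE)
}

## Wald CI on the logit scale, back-transformed; falls back to a truncated
## symmetric interval at the boundary where the logit transform degenerates
.logitScaleCI <- function(value, se, level = 1.96) {
  denom <- value * (1 - value)
  seEta <- ifelse(denom > 0, se / denom, NA_real_)
  eta <- stats::qlogis(value)
  usable <- is.finite(eta) & is.finite(seEta)
  lci <- ifelse(usable, stats::plogis(eta - level * seEta),
                pmax(0, value - level * se))
  uci <- ifelse(usable, stats::plogis(eta + level * seEta),
                pmin(1, value + level * se))
  list(lci = lci, uci = uci)
}

#' Coefficient table on the link scale
#'
#' Estimates, standard errors and Wald 95% limits (estimate +/- 1.96 SE) for
#' every fitted logit-scale parameter.
#'
#' @param fit an \linkS4class{OccuFit}.
#' @return data.frame with columns term, beta, se, lci, uci.
#' @export
coefTable <- function(fit) {
  stopifnot(is(fit, "OccuFit"))
  b <- fit@coefficients
  se <- if (anyNA(fit@vcov)) rep(NA_real_, length(b)) else
    sqrt(pmax(0, diag(fit@vcov)))
  data.frame(term = names(b), beta = unname(b), se = unname(se),
             lci = unname(b - 1.96 * se), uci = unname(b + 1.96 * se),
             stringsAsFactors = FALSE)
}

#' Per-site occupancy predictions
#'
#' Site-specific occupancy probabilities with delta-method SEs, for mapping
#' or averaging. Covariates must be on the training scale (either the
#' training table itself or new sites passed through \code{applyScale}).
#'
#' @param fit an \linkS4class{OccuFit}.
#' @param covs scaled \linkS4class{SiteCovariates}; defaults to the
#'   training covariates stored in the fit.
#' @param force evaluate even when the fit did not converge.
#' @return data.frame with columns site, psi, se, lci, uci.
#' @export
predictPsi <- function(fit, covs = NULL, force = FALSE) {
  stopifnot(is(fit, "OccuFit"))
  if (!fit@converged && !force)
    stop("fit did not converge; use force = TRUE to evaluate anyway")
  if (is.null(covs)) covs <- fit@covs
  stopifnot(is(covs, "SiteCovariates"))
  if (!isScaled(covs) && length(fit@spec@psiCovariates))
    stop("covariates must be on the training (scaled) scale")
  spec <- fit@spec
  X <- .designMatrix(spec@psiCovariates, covs, nSites(covs))
  npsi <- 1L + length(spec@psiCovariates)
  beta <- fit@coefficients[seq_len(npsi)]
  eta <- drop(X %*% beta)
  psi <- stats::plogis(eta)
  if (anyNA(fit@vcov)) {
    se <- rep(NA_real_, length(psi))
  } else {
    Vb <- fit@vcov[seq_len(npsi), seq_len(npsi), drop = FALSE]
    g <- X * (psi * (1 - psi))  # d psi / d beta, row-wise
    se <- sqrt(pmax(0, rowSums((g %*% Vb) * g)))
  }
  ci <- .logitScaleCI(psi, se)
  data.frame(site = siteIDs(covs), psi = psi, se = se,
             lci = ci$lci, uci = ci$uci, stringsAsFactors = FALSE)
}
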