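#' Build an occupancy model specification
#'
#' @param psi character vector of covariate names on logit occupancy
#'   (empty = intercept only).
#' @param p character vector of covariate names on logit detection.
#' @param correlated logical; TRUE (default) for the Markov
#'   correlated-detection model, FALSE for the standard independent-replicate
#'   model.
#' @param piMode "estimated" (default), "stationary" or "fixed" — how the
#'   first-segment local-presence probability pi is handled.
#' @param piValue value of pi when \code{piMode = "fixed"}.
#' @param pLevel "site" (default) or "segment".
#' @return an \linkS4class{OccuModelSpec}.
#' @examples
#' occuSpec(psi = "Term", p = c("Term", "EVI", "TRI"))
#' @export
occuSpec <- function(psi = character(), p = character(), correlated = TRUE,
                     piMode = "estimated", piValue = NA_real_,
                     pLevel = "site") {
  new("OccuModelSpec", psiCovariates = as.character(psi),
      pCovariates = as.character(p), correlated = correlated,
      piMode = piMode, piValue = as.numeric(piValue), pLevel = pLevel)
}

#' @rdname occuCorr-accessors
setMethod("modelNotation", "OccuModelSpec", function(x) {
  term <- function(v) if (length(v)) paste(v, collapse = "+") else "."
  if (x@correlated) {
    pi_lab <- switch(x@piMode, estimated = "th0pi()",
                     stationary = "th0pi(eq)",
                     fixed = sprintf("th0pi(=%g)", x@piValue))
    sprintf("psi(%s),th0(),th1(),p(%s),%s",
            term(x@psiCovariates), term(x@pCovariates), pi_lab)
  } else {
    sprintf("psi(%s),p(%s)", term(x@psiCovariates), term(x@pCovariates))
  }
})

#' Number of free parameters of a model specification
#'
#' Intercept plus one slope per covariate for each of psi and p; the
#' correlated model adds the chain parameters theta0 and theta1, and one
#' more when the first-segment probability pi is itself estimated.
#'
#' @param spec an \linkS4class{OccuModelSpec}.
#' @return integer parameter count K.
#' @examples
#' # global psi (6 covariates) + p(3 covariates), correlated, pi estimated:
#' countParameters(occuSpec(psi = paste0("x", 1:6), p = paste0("x", 1:3)))
#' @export
countParameters <- function(spec) {
  stopifnot(is(spec, "OccuModelSpec"))
  k <- (1L + length(spec@psiCovariates)) + (1L + length(spec@pCovariates))
  if (spec@correlated)
    k <- k + 2L + as.integer(spec@piMode == "estimated")
  k
}

## parameter packing ----------------------------------------------------
## order: beta_psi (intercept, slopes), alpha_p (intercept, slopes),
##        logit(theta0), logit(theta1), logit(pi) [if estimated]

.paramNames <- function(spec) {
  nm <- c("psi_(Intercept)",
          if (length(spec@psiCovariates)) paste0("psi_", spec@psiCovariates),
          "p_(Intercept)",
          if (length(spec@pCovariates)) paste0("p_", spec@pCovariates))
  if (spec@correlated) {
    nm <- c(nm, "logit_theta0", "logit_theta1")
    if (spec@piMode == "estimated") nm <- c(nm, "logit_pi")
  }
  nm
}

.splitParams <- function(params, spec) {
  npsi <- 1L + length(spec@psiCovariates)
  np <- 1L + length(spec@pCovariates)
  stopifnot(length(params) == countParameters(spec))
  out <- list(betaPsi = params[seq_len(npsi)],
              alphaP = params[npsi + seq_len(np)])
  if (spec@correlated) {
    extra <- unname(params[(npsi + np + 1L):length(params)])
    out$theta0 <- stats::plogis(extra[1L])
    out$theta1 <- stats::plogis(extra[2L])
    out$pi <- switch(spec@piMode,
      estimated = stats::plogis(extra[3L]),
      stationary = {
        t0 <- stats::plogis(extra[1L]); t1 <- stats::plogis(extra[2L])
        t0 / (1 + t0 - t1)
      },
      fixed = spec@piValue)
  }
  out
}

.designMatrix <- function(covNames, covs, n) {
  if (!length(covNames)) return(matrix(1, n, 1L))
  d <- covValues(covs)
  miss <- setdiff(covNames, names(d))
  if (length(miss))
    stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  cbind(1, as.matrix(d[, covNames, drop = FALSE]))
}

#' Linear predictors on the probability scale
#'
#' Expands a packed parameter vector into per-site occupancy probabilities,
#' detection probabilities (per site, or per site x segment when
#' \code{pLevel = "segment"}) and the chain parameters, through logit links.
#'
#' @param spec an \linkS4class{OccuModelSpec}.
#' @param params packed parameter vector (see \code{countParameters} for the
#'   length; ordering is beta_psi, alpha_p, logit theta0, logit theta1,
#'   logit pi).
#' @param covs scaled \linkS4class{SiteCovariates}.
#' @param nSeg number of segments (used to shape segment-level p).
#' @param segCovs optional named list of site x segment matrices holding
#'   segment-level detection covariates (\code{pLevel = "segment"} only).
#' @return list with \code{psi} (n), \code{p} (n or n x K matrix),
#'   and for correlated specs \code{theta0}, \code{theta1}, \code{pi}.
#' @export
linearPredictors <- function(spec, params, covs, nSeg = NULL,
                             segCovs = NULL) {
  stopifnot(is(spec, "OccuModelSpec"), is(covs, "SiteCovariates"))
  n <- nSites(covs)
  sp <- .splitParams(params, spec)
  psi <- unname(stats::plogis(drop(.designMatrix(spec@psiCovariates, covs, n)
                                   %*% sp$betaPsi)))
  if (spec@pLevel == "segment") {
    if (is.null(nSeg)) stop("nSeg required for segment-level p")
    eta <- matrix(sp$alphaP[1L], n, nSeg)
    if (length(spec@pCovariates)) {
      if (is.null(segCovs))
        stop("segCovs required for segment-level p with covariates")
      miss <- setdiff(spec@pCovariates, names(segCovs))
      if (length(miss))
        stop("unknown segment covariate(s): ", paste(miss, collapse = ", "))
      for (j in seq_along(spec@pCovariates))
        eta <- eta + sp$alphaP[1L + j] * segCovs[[spec@pCovariates[j]]]
    }
    p <- stats::plogis(eta)
  } else {
    p <- unname(stats::plogis(drop(.designMatrix(spec@pCovariates, covs, n)
                                   %*% sp$alphaP)))
  }
  out <- list(psi = psi, p = p)
  if (spec@correlated)
    out <- c(out, sp[c("theta0", "theta1", "pi")])
  out
}

.checkProbs <- function(...) {
  v <- unlist(list(...))
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("probabilities must lie in [0, 1]")
}

#' Site likelihood, standard model
#'
#' Probability of one detection history under the standard single-season
#' model: psi * prod over surveyed segments of Bernoulli(p_k) terms, plus
#' (1 - psi) when no detection was made. Missing segments contribute
#' factor 1.
#'
#' @param history vector of 0/1/NA.
#' @param psi occupancy probability.
#' @param p detection probability, scalar or per-segment vector.
#' @return the history probability.
#' @examples
#' siteLikelihoodStandard(c(0, 1, 0), 0.7, 0.3)  # 0.7 * 0.7*0.3*0.7
#' @export
siteLikelihoodStandard <- function(history, psi, p) {
  K <- length(history)
  p <- rep_len(p, K)
  .checkProbs(psi, p)
  obs <- !is.na(history)
  h <- history[obs]; pk <- p[obs]
  cond <- prod(ifelse(h == 1, pk, 1 - pk))
  psi * cond + (1 - psi) * as.numeric(sum(h) == 0)
}

#' Site likelihood, correlated-detection model
#'
#' Probability of one detection history when local presence of sign along
#' the transect follows a two-state first-order Markov chain: Pr(z1 = 1) =
#' pi, Pr(z_k = 1 | z_{k-1} = 0) = theta0, Pr(z_k = 1 | z_{k-1} = 1) =
#' theta1, with detection only possible where z_k = 1 (emission p_k).
#' Computed by the forward algorithm; missing segments emit factor 1 while
#' the chain still transitions.
#'
#' @inheritParams siteLikelihoodStandard
#' @param theta0,theta1,pi chain parameters.
#' @return the history probability.
#' @seealso \code{\link{siteLikelihoodBruteforce}} for the enumeration
#'   oracle used in tests.
#' @export
siteLikelihoodCorrelated <- function(history, psi, theta0, theta1, pi, p) {
  K <- length(history)
  p <- rep_len(p, K)
  .checkProbs(psi, theta0, theta1, pi, p)
  e <- .emissions(history, p)
  a0 <- (1 - pi) * e$e0[1L]
  a1 <- pi * e$e1[1L]
  if (K > 1L) for (k in 2:K) {
    na0 <- (a0 * (1 - theta0) + a1 * (1 - theta1)) * e$e0[k]
    na1 <- (a0 * theta0 + a1 * theta1) * e$e1[k]
    a0 <- na0; a1 <- na1
  }
  noDet <- as.numeric(sum(history == 1, na.rm = TRUE) == 0)
  psi * (a0 + a1) + (1 - psi) * noDet
}

## emission factors given local presence (e1) / absence (e0); NA -> 1
.emissions <- function(history, p) {
  e1 <- ifelse(is.na(history), 1, ifelse(history == 1, p, 1 - p))
  e0 <- ifelse(is.na(history), 1, ifelse(history == 1, 0, 1))
  list(e0 = e0, e1 = e1)
}

#' Brute-force site likelihood (enumeration oracle)
#'
#' Explicit sum over all 2^K latent local-presence sequences. Exponential in
#' K; intended as an independent check of the forward recursion on short
#' histories.
#'
#' @inheritParams siteLikelihoodCorrelated
#' @return the history probability.
#' @export
siteLikelihoodBruteforce <- function(history, psi, theta0, theta1, pi, p) {
  K <- length(history)
  if (K > 16L) stop("brute force limited to 16 segments")
  p <- rep_len(p, K)
  .checkProbs(psi, theta0, theta1, pi, p)
  e <- .emissions(history, p)
  total <- 0
  for (code in 0:(2^K - 1)) {
    z <- as.integer(intToBits(code))[seq_len(K)]
    pz <- if (z[1L] == 1) pi else 1 - pi
    if (K > 1L) for (k in 2:K) {
      pz <- pz * if (z[k - 1L] == 1) {
        if (z[k] == 1) theta1 else 1 - theta1
      } else {
        if (z[k] == 1) theta0 else 1 - theta0
      }
    }
    py <- prod(ifelse(z == 1, e$e1, e$e0))
    total <- total + pz * py
  }
  noDet <- as.numeric(sum(history == 1, na.rm = TRUE) == 0)
  psi * total + (1 - psi) * noDet
}

#' Negative log-likelihood of a model on a dataset
#'
#' Sum of minus log site likelihoods, vectorised over sites (the forward
#' recursion runs on all sites simultaneously, with per-segment rescaling
#' against underflow on long transects).
#'
#' @param params packed parameter vector on the link scale.
#' @param y a \linkS4class{DetectionHistory}.
#' @param covs scaled \linkS4class{SiteCovariates} with matching sites.
#' @param spec an \linkS4class{OccuModelSpec}.
#' @param segCovs optional segment-level covariates (see
#'   \code{\link{linearPredictors}}).
#' @return scalar NLL; +Inf when some site has probability 0.
#' @export
negLogLikelihood <- function(params, y, covs, spec, segCovs = NULL) {
  stopifnot(is(y, "DetectionHistory"), is(covs, "SiteCovariates"))
  ym <- detections(y)
  if (nSites(covs) != nrow(ym)) stop("site count mismatch")
  lp <- linearPredictors(spec, params, covs, nSeg = ncol(ym),
                         segCovs = segCovs)
  lik <- .siteLikVector(ym, lp, spec)
  if (any(lik <= 0)) return(Inf)
  -sum(log(lik))
}

## vectorised site likelihoods for all sites at once
.siteLikVector <- function(ym, lp, spec) {
  n <- nrow(ym); K <- ncol(ym)
  pmat <- if (is.matrix(lp$p)) lp$p else matrix(lp$p, n, K)
  noDet <- rowSums(ym == 1, na.rm = TRUE) == 0
  if (!spec@correlated) {
    contrib <- ifelse(is.na(ym), 0, ifelse(ym == 1, log(pmat), log1p(-pmat)))
    cond <- exp(rowSums(contrib))
    return(lp$psi * cond + (1 - lp$psi) * noDet)
  }
  t0 <- lp$theta0; t1 <- lp$theta1; pi1 <- lp$pi
  e1 <- ifelse(is.na(ym), 1, ifelse(ym == 1, pmat, 1 - pmat))
  e0 <- ifelse(is.na(ym), 1, ifelse(ym == 1, 0, 1))
  a0 <- (1 - pi1) * e0[, 1L]
  a1 <- pi1 * e1[, 1L]
  logScale <- numeric(n)
  if (K > 1L) for (k in 2:K) {
    na0 <- (a0 * (1 - t0) + a1 * (1 - t1)) * e0[, k]
    na1 <- (a0 * t0 + a1 * t1) * e1[, k]
    s <- na0 + na1
    dead <- s <= 0
    s[dead] <- 1  # forward mass extinct; keep 0 through the recursion
    a0 <- na0 / s; a1 <- na1 / s
    logScale <- logScale + log(s)
  }
  Fwd <- (a0 + a1) * exp(logScale)
  lp$psi * Fwd + (1 - lp$psi) * noDet
}

#' Serialize / deserialize a model specification
#'
#' Writes an \linkS4class{OccuModelSpec} as a small YAML document
#' (\code{psi:}, \code{p:}, \code{correlated:}, \code{pi:}, \code{pLevel:})
#' and reads it back. \code{pi} is either \code{estimated},
#' \code{stationary}, or a number in (0,1) meaning a fixed value.
#'
#' @param spec an \linkS4class{OccuModelSpec}.
#' @param path file path.
#' @return \code{readOccuSpec}: an \linkS4class{OccuModelSpec};
#'   \code{writeOccuSpec}: \code{path}, invisibly.
#' @export
writeOccuSpec <- function(spec, path) {
  stopifnot(is(spec, "OccuModelSpec"))
  obj <- list(psi = as.list(spec@psiCovariates),
              p = as.list(spec@pCovariates),
              correlated = spec@correlated,
              pi = if (spec@piMode == "fixed") spec@piValue else spec@piMode,
              pLevel = spec@pLevel)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeOccuSpec
#' @export
readOccuSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  pi_field <- if (is.null(obj$pi)) "estimated" else obj$pi
  if (is.numeric(pi_field)) {
    piMode <- "fixed"; piValue <- pi_field
  } else {
    piMode <- pi_field; piValue <- NA_real_
  }
  occuSpec(psi = unlist(obj$psi) %||% character(),
           p = unlist(obj$p) %||% character(),
           correlated = isTRUE(obj$correlated),
           piMode = piMode, piValue = piValue,
           pLevel = obj$pLevel %||% "site")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
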