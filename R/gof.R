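## probability of each site's own observed history under the fitted model
.siteHistoryProbs <- function(fit, y = NULL) {
  if (is.null(y)) y <- fit@y
  lp <- linearPredictors(fit@spec, fit@coefficients, fit@covs,
                         nSeg = nSegments(y))
  .siteLikVector(detections(y), lp, fit@spec)
}

#' Pearson chi-square on detection histories
#'
#' MacKenzie-Bailey-style fit statistic. Sites are grouped into cohorts
#' sharing a missingness pattern and covariate profile (with site-level
#' covariates each site is typically its own cohort). Within a cohort, every
#' distinct observed history h contributes (O_h - E_h)^2 / E_h with E_h the
#' cohort size times the model probability of h, and one pooled complement
#' category absorbs the remaining probability mass (O = 0 there unless a
#' history repeats).
#'
#' @param fit an \linkS4class{OccuFit}.
#' @param y optional \linkS4class{DetectionHistory} to evaluate (default:
#'   the training data; must share the fit's covariates and shape).
#' @return the chi-square statistic (+Inf, with a warning, if some observed
#'   history has model probability 0).
#' @export
pearsonChisq <- function(fit, y = NULL) {
  stopifnot(is(fit, "OccuFit"))
  if (is.null(y)) y <- fit@y
  ym <- detections(y)
  cv <- covValues(fit@covs)
  covkey <- if (ncol(cv)) apply(cv, 1L, paste, collapse = "\r") else
    character(nrow(cv))
  misskey <- apply(is.na(ym), 1L, paste, collapse = "")
  cohort <- paste(misskey, covkey, sep = "|")
  histkey <- apply(ym, 1L, paste, collapse = ",")
  prob <- unname(.siteHistoryProbs(fit, y))
  x2 <- 0
  for (co in unique(cohort)) {
    idx <- which(cohort == co)
    n_c <- length(idx)
    hk <- histkey[idx]
    firsts <- idx[!duplicated(hk)]
    massed <- 0
    for (i in firsts) {
      O <- sum(hk == histkey[i])
      E <- n_c * prob[i]
      if (E == 0) {
        warning("observed history with expected probability 0")
        return(Inf)
      }
      x2 <- x2 + (O - E)^2 / E
      massed <- massed + E
    }
    rem <- n_c - massed
    if (rem > 1e-12) x2 <- x2 + rem  # (0 - rem)^2 / rem
  }
  x2
}

## simulate a detection history from fitted parameters, keeping the
## missingness pattern of `template`
.simulateFromFit <- function(fit, template) {
  spec <- fit@spec
  ym <- detections(template)
  n <- nrow(ym); K <- ncol(ym)
  lp <- linearPredictors(spec, fit@coefficients, fit@covs, nSeg = K)
  occ <- stats::rbinom(n, 1L, lp$psi)
  pmat <- if (is.matrix(lp$p)) lp$p else matrix(lp$p, n, K)
  if (spec@correlated) {
    z <- matrix(0L, n, K)
    z[, 1L] <- stats::rbinom(n, 1L, lp$pi)
    if (K > 1L) for (k in 2:K) {
      pk <- ifelse(z[, k - 1L] == 1L, lp$theta1, lp$theta0)
      z[, k] <- stats::rbinom(n, 1L, pk)
    }
  } else {
    z <- matrix(1L, n, K)
  }
  ynew <- matrix(stats::rbinom(n * K, 1L, as.vector(pmat)), n, K)
  ynew <- ynew * z * occ
  ynew[is.na(ym)] <- NA_integer_
  detectionHistory(ynew, siteIDs = siteIDs(template),
                   segmentLength = template@segmentLength)
}

#' Parametric-bootstrap goodness-of-fit
#'
#' Simulates B datasets from the fitted model (same covariates, missingness
#' patterns held fixed), refits each under the same specification, and
#' compares the observed \code{\link{pearsonChisq}} against the bootstrap
#' distribution. The p-value uses the add-one estimator
#' (1 + #\{boot >= observed\}) / (B + 1); the overdispersion factor is
#' c-hat = observed / mean(bootstrap).
#'
#' @param fit a converged \linkS4class{OccuFit}.
#' @param B number of bootstrap datasets (default 1000).
#' @param seed integer seed; the bootstrap stream is fully reproducible.
#' @param nStarts starts per refit (refits start from the observed MLE, so
#'   1 is usually enough).
#' @return an \linkS4class{OccuGof}.
#' @export
gofBootstrap <- function(fit, B = 1000L, seed = 1L, nStarts = 1L) {
  stopifnot(is(fit, "OccuFit"))
  if (B < 1L) stop("B must be >= 1")
  if (!fit@converged) stop("fit did not converge")
  observed <- pearsonChisq(fit)
  boot <- rep(NA_real_, B)
  failed <- 0L
  for (b in seq_len(B)) {
    yb <- .withSeed(seed + b, .simulateFromFit(fit, fit@y))
    fb <- tryCatch(
      fitOccu(yb, fit@covs, fit@spec, nStarts = nStarts, seed = seed + b,
              start = fit@coefficients),
      error = function(e) NULL)
    ## a refit pushed to the boundary still yields a usable statistic;
    ## only optimisation failure discards the replicate
    if (is.null(fb)) { failed <- failed + 1L; next }
    boot[b] <- pearsonChisq(fb, yb)
  }
  if (failed > 0.2 * B)
    stop(failed, "/", B,
         " bootstrap refits failed; increase nStarts or simplify the model")
  ok <- !is.na(boot) & is.finite(boot)
  pValue <- (1 + sum(boot[ok] >= observed)) / (sum(ok) + 1)
  cHat <- observed / mean(boot[ok])
  new("OccuGof", observed = observed, boot = boot, pValue = pValue,
      cHat = cHat, B = as.integer(B))
}
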