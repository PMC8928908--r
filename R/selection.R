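#' AIC from a log-likelihood
#'
#' @param loglik maximised log-likelihood.
#' @param K number of estimated parameters.
#' @return -2 loglik + 2 K.
#' @export
aicScore <- function(loglik, K) {
  stopifnot(K >= 0)
  -2 * loglik + 2 * K
}

#' Akaike weights from AIC (or delta-AIC) values
#'
#' w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2), with delta_i the
#' difference to the smallest value supplied. Invariant to adding a
#' constant, so raw AICs and delta-AICs give identical weights.
#'
#' @param aic numeric vector of AIC (or delta-AIC) values.
#' @return numeric weights summing to 1, in input order.
#' @examples
#' akaikeWeights(c(0, 0.13, 2.25, 4.37, 4.53, 5.47, 5.89, 5.93, 6.48))
#' @export
akaikeWeights <- function(aic) {
  rel <- exp(-(aic - min(aic)) / 2)
  rel / sum(rel)
}

#' Rank a set of fitted models by AIC
#'
#' Builds the standard model-comparison table: AIC, delta-AIC, Akaike
#' weight, model likelihood exp(-delta/2) and K, sorted ascending by AIC.
#' AIC ties break towards the smaller K, then input order. All fits must be
#' on the same data.
#'
#' @param fits list of \linkS4class{OccuFit} objects.
#' @return an \linkS4class{OccuAICTable} carrying the fits in table order.
#' @export
rankModels <- function(fits) {
  if (is(fits, "OccuFit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, is, logical(1), "OccuFit")))
  dims <- vapply(fits, function(f) dim(detections(f@y)), integer(2))
  if (length(unique(split(dims, col(dims)))) != 1L)
    stop("fits are not on identically shaped data")
  aic <- vapply(fits, function(f) f@aic, numeric(1))
  K <- vapply(fits, function(f) f@K, integer(1))
  ord <- order(aic, K, seq_along(fits))
  aic <- aic[ord]; K <- K[ord]
  delta <- aic - aic[1L]
  tb <- data.frame(
    model = vapply(fits[ord], function(f) modelNotation(f@spec), character(1)),
    AIC = aic, deltaAIC = delta, w = akaikeWeights(aic),
    ML = exp(-delta / 2), K = K, stringsAsFactors = FALSE)
  new("OccuAICTable", table = tb, fits = fits[ord])
}

#' AIC table from bare AIC values
#'
#' Same arithmetic as \code{\link{rankModels}} when only AIC (or delta-AIC)
#' values and labels are at hand, e.g. when re-deriving weights from a
#' published table.
#'
#' @param aic numeric AIC or delta-AIC values.
#' @param model optional model labels.
#' @param K optional parameter counts.
#' @return an \linkS4class{OccuAICTable} without fits.
#' @export
aicTableFromValues <- function(aic, model = NULL,
                               K = rep(NA_integer_, length(aic))) {
  if (is.null(model)) model <- sprintf("model%02d", seq_along(aic))
  ord <- order(aic, K, seq_along(aic))
  aic <- aic[ord]
  delta <- aic - aic[1L]
  tb <- data.frame(model = model[ord], AIC = aic, deltaAIC = delta,
                   w = akaikeWeights(aic), ML = exp(-delta / 2),
                   K = K[ord], stringsAsFactors = FALSE)
  new("OccuAICTable", table = tb)
}

.fitQuietly <- function(y, covs, spec, nStarts, seed) {
  tryCatch(fitOccu(y, covs, spec, nStarts = nStarts, seed = seed),
           error = function(e) {
             warning("fit of ", modelNotation(spec), " failed: ",
                     conditionMessage(e), call. = FALSE)
             NULL
           })
}

#' Two-step detection-then-occupancy model selection
#'
#' Step 1 holds occupancy at the global structure (all covariates in
#' \code{psiPool}) and ranks candidate detection structures by AIC. Step 2
#' fixes the best detection structure and searches occupancy structures:
#' the null model, every univariate model, and stepwise-additive expansions
#' of the best univariate (see \code{\link{stepwiseAdditive}}); the null
#' model under the second-best detection structure is included as well when
#' step 1 fitted more than one structure.
#'
#' @param y a \linkS4class{DetectionHistory}.
#' @param covs scaled \linkS4class{SiteCovariates}.
#' @param psiPool character; covariates eligible for occupancy (the global
#'   model uses all of them).
#' @param pCandidates list of character vectors, the detection structures to
#'   try in step 1 (default: null plus each univariate from
#'   \code{psiPool}).
#' @param correlated,piMode passed to every \code{\link{occuSpec}}.
#' @param nStarts,seed optimisation controls (each fit gets a distinct
#'   deterministic sub-seed).
#' @param secondBestP also run occupancy structures under the second-best
#'   detection model (default TRUE).
#' @return list with elements \code{detectionTable},
#'   \code{occupancyTable} (both \linkS4class{OccuAICTable}) and
#'   \code{fits} (all step-2 fits, for model averaging).
#' @export
twoStepSelection <- function(y, covs, psiPool,
                             pCandidates = NULL, correlated = TRUE,
                             piMode = "estimated", nStarts = 5L, seed = 1L,
                             secondBestP = TRUE) {
  stopifnot(length(psiPool) >= 1L)
  if (is.null(pCandidates))
    pCandidates <- c(list(character(0)), as.list(psiPool))
  stopifnot(length(pCandidates) >= 1L)

  ## step 1: psi(Global), vary p
  step1 <- list()
  for (i in seq_along(pCandidates)) {
    spec <- occuSpec(psi = psiPool, p = pCandidates[[i]],
                     correlated = correlated, piMode = piMode)
    f <- .fitQuietly(y, covs, spec, nStarts, seed + i)
    if (!is.null(f) && f@converged) step1[[length(step1) + 1L]] <- f
  }
  if (!length(step1)) stop("no detection-step model converged")
  detTable <- rankModels(step1)

  bestP <- detTable@fits[[1L]]@spec@pCovariates
  ## step 2: fix p, search psi
  step2 <- list()
  add <- function(f) if (!is.null(f) && f@converged)
    step2[[length(step2) + 1L]] <<- f
  seed2 <- seed + 1000L
  sw <- stepwiseAdditive(y, covs, bestP, psiPool, correlated = correlated,
                         piMode = piMode, nStarts = nStarts, seed = seed2)
  for (f in sw) add(f)
  if (secondBestP && nrow(detTable@table) > 1L) {
    p2 <- detTable@fits[[2L]]@spec@pCovariates
    spec <- occuSpec(psi = character(0), p = p2, correlated = correlated,
                     piMode = piMode)
    add(.fitQuietly(y, covs, spec, nStarts, seed2 + 500L))
  }
  if (!length(step2)) stop("no occupancy-step model converged")
  occTable <- rankModels(step2)
  list(detectionTable = detTable, occupancyTable = occTable, fits = step2)
}

#' Stepwise-additive occupancy covariate search
#'
#' Fits the null model and every univariate occupancy model under a fixed
#' detection structure; starting from the best univariate, repeatedly adds
#' the remaining covariate that most decreases AIC, stopping when no
#' addition strictly decreases it. Every model fitted along the path is
#' returned (the search is a heuristic over the additive-model lattice, not
#' an exhaustive enumeration).
#'
#' @inheritParams twoStepSelection
#' @param pStructure character; the fixed detection covariates.
#' @param psiPool character; candidate occupancy covariates.
#' @return list of \linkS4class{OccuFit}, in the order fitted.
#' @export
stepwiseAdditive <- function(y, covs, pStructure, psiPool,
                             correlated = TRUE, piMode = "estimated",
                             nStarts = 5L, seed = 1L) {
  stopifnot(length(psiPool) >= 1L)
  fits <- list()
  keyOf <- function(v) paste(sort(v), collapse = "+")
  seen <- character(0)
  tryFit <- function(psiVars, s) {
    key <- keyOf(psiVars)
    if (key %in% seen) return(NULL)
    seen <<- c(seen, key)
    spec <- occuSpec(psi = psiVars, p = pStructure,
                     correlated = correlated, piMode = piMode)
    f <- .fitQuietly(y, covs, spec, nStarts, s)
    if (!is.null(f) && f@converged) {
      fits[[length(fits) + 1L]] <<- f
      f
    } else NULL
  }
  null_fit <- tryFit(character(0), seed)
  uni <- list()
  for (i in seq_along(psiPool))
    uni[[psiPool[i]]] <- tryFit(psiPool[i], seed + i)
  uni <- Filter(Negate(is.null), uni)
  if (!length(uni)) return(fits)
  uniAIC <- vapply(uni, function(f) f@aic, numeric(1))
  current <- uni[[which.min(uniAIC)]]
  bench <- if (!is.null(null_fit)) min(null_fit@aic, current@aic) else
    current@aic
  if (current@aic > bench) return(fits)  # null beats every univariate
  repeat {
    remaining <- setdiff(psiPool, current@spec@psiCovariates)
    if (!length(remaining)) break
    cand <- list()
    for (i in seq_along(remaining)) {
      f <- tryFit(c(current@spec@psiCovariates, remaining[i]),
                  seed + 100L + length(seen) + i)
      if (!is.null(f)) cand[[length(cand) + 1L]] <- f
    }
    if (!length(cand)) break
    candAIC <- vapply(cand, function(f) f@aic, numeric(1))
    if (min(candAIC) < current@aic) {
      current <- cand[[which.min(candAIC)]]
    } else break
  }
  fits
}

#' AIC-weighted model averaging
#'
#' Averages a real-scale quantity over a fitted model set with Akaike
#' weights. For \code{quantity = "psi"} each model contributes the
#' unweighted mean of its site-specific occupancy estimates (with the
#' delta-method SE of that mean); for \code{"p"} each model contributes
#' detection probability at the covariate means. The unconditional standard
#' error combines within-model and between-model variance:
#' sum_i w_i sqrt(se_i^2 + (est_i - avg)^2).
#'
#' @param fits list of converged \linkS4class{OccuFit} on common data, or an
#'   \linkS4class{OccuAICTable} carrying fits.
#' @param quantity "psi" or "p".
#' @return list with \code{estimate}, \code{se} (unconditional) and
#'   \code{components} (data.frame: model, w, estimate, se).
#' @export
modelAverage <- function(fits, quantity = c("psi", "p")) {
  quantity <- match.arg(quantity)
  tab <- if (is(fits, "OccuAICTable")) fits else rankModels(fits)
  if (!length(tab@fits)) stop("table carries no fits to average")
  w <- tab@table$w
  comp <- lapply(tab@fits, function(f) {
    if (quantity == "psi") {
      pr <- predictPsi(f)
      est <- mean(pr$psi)
      ## delta-method se of the mean of site-level psi
      spec <- f@spec
      X <- .designMatrix(spec@psiCovariates, f@covs, nSites(f@covs))
      npsi <- 1L + length(spec@psiCovariates)
      psi <- pr$psi
      gbar <- colMeans(X * (psi * (1 - psi)))
      Vb <- f@vcov[seq_len(npsi), seq_len(npsi), drop = FALSE]
      se <- if (anyNA(Vb)) NA_real_ else
        sqrt(max(0, drop(gbar %*% Vb %*% gbar)))
    } else {
      rp <- realParameters(f)
      est <- rp$estimate[rp$parameter == "p"]
      se <- rp$se[rp$parameter == "p"]
    }
    c(est = est, se = se)
  })
  est <- vapply(comp, `[[`, numeric(1), "est")
  se <- vapply(comp, `[[`, numeric(1), "se")
  if (abs(sum(w) - 1) > 1e-9) stop("weights do not sum to 1")
  avg <- sum(w * est)
  use <- sum(w * sqrt(se^2 + (est - avg)^2))
  list(estimate = avg, se = use,
       components = data.frame(model = tab@table$model, w = w,
                               estimate = est, se = se,
                               stringsAsFactors = FALSE))
}
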