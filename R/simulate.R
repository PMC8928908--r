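#' Simulation configuration
#'
#' Describes a synthetic sign survey with the same statistical structure
#' the models assume: site occupancy is Bernoulli with a logit-linear
#' covariate model, local presence of sign along the transect follows a
#' two-state Markov chain within occupied sites, and detection on a segment
#' is Bernoulli given local presence. Segment-indicator covariates (termite
#' mounds, fruit plants, the three disturbance components) are generated
#' per segment and aggregated to site-level proportions exactly as a field
#' survey would record them; remote-sensing covariates are standard normal
#' across sites. Defaults mirror the study design this package grew out of:
#' 45 grid cells, 20 segments of 200 m, occupancy near 0.7, detection near
#' 0.25, a moderately sticky chain (theta0 = 0.3, theta1 = 0.7, pi = 0.45)
#' and no missing segments.
#'
#' @param nSites number of sites (default 45).
#' @param nSegments segments per site (default 20).
#' @param betaPsi named coefficients on logit occupancy; first element is
#'   the intercept (unnamed or named "(Intercept)"); further elements are
#'   named after covariates.
#' @param alphaP named coefficients on logit detection, same convention.
#' @param theta0,theta1,piFirst Markov chain parameters in [0, 1] (the
#'   closed ends give degenerate chains, useful for checks).
#' @param correlated FALSE collapses the chain (local presence everywhere).
#' @param segmentProbs named per-segment presence probabilities for the
#'   indicator covariates (names among termite, fruit, human, livestock,
#'   fire).
#' @param continuousCovs names of standard-normal site covariates.
#' @param missingRate fraction of segments set missing, uniformly at random
#'   (default 0); \code{missingMode = "block"} instead removes a contiguous
#'   tail block of the expected length from randomly chosen sites,
#'   mimicking whole areas that could not be surveyed.
#' @param missingMode "uniform" or "block".
#' @param seed integer seed.
#' @return a list of class-free configuration values, validated.
#' @export
simConfig <- function(nSites = 45L, nSegments = 20L,
                      betaPsi = c(`(Intercept)` = stats::qlogis(0.7)),
                      alphaP = c(`(Intercept)` = stats::qlogis(0.25)),
                      theta0 = 0.3, theta1 = 0.7, piFirst = 0.45,
                      correlated = TRUE,
                      segmentProbs = c(termite = 0.30, fruit = 0.25,
                                       human = 0.10, livestock = 0.08,
                                       fire = 0.05),
                      continuousCovs = c("EVI", "TRI", "Tcov"),
                      missingRate = 0, missingMode = c("uniform", "block"),
                      seed = 1L) {
  missingMode <- match.arg(missingMode)
  stopifnot(nSites >= 1L, nSegments >= 1L,
            theta0 >= 0, theta0 <= 1, theta1 >= 0, theta1 <= 1,
            piFirst >= 0, piFirst <= 1,
            missingRate >= 0, missingRate < 1,
            all(segmentProbs > 0 & segmentProbs < 1))
  if (is.null(names(betaPsi))) names(betaPsi) <- "(Intercept)"
  if (is.null(names(alphaP))) names(alphaP) <- "(Intercept)"
  list(nSites = as.integer(nSites), nSegments = as.integer(nSegments),
       betaPsi = betaPsi, alphaP = alphaP, theta0 = theta0, theta1 = theta1,
       piFirst = piFirst, correlated = correlated,
       segmentProbs = segmentProbs, continuousCovs = continuousCovs,
       missingRate = missingRate, missingMode = missingMode,
       seed = as.integer(seed))
}

#' Simulate a sign survey
#'
#' Draws covariates, latent occupancy and local presence, and detection
#' histories from a \code{\link{simConfig}}, fully seeded. The covariate
#' table is returned z-scaled (as the models consume it) and the raw
#' segment records, latent occupancy and chain states are kept as truth for
#' recovery studies.
#'
#' @param config output of \code{\link{simConfig}}.
#' @return a \linkS4class{SimulatedOccuData}.
#' @examples
#' sim <- simulateDataset(simConfig(nSites = 50, seed = 3))
#' naiveOccupancy(sim$y)
#' @export
simulateDataset <- function(config) {
  .withSeed(config$seed, .simulateDatasetImpl(config))
}

.simulateDatasetImpl <- function(config) {
  n <- config$nSites; K <- config$nSegments
  ids <- sprintf("site%03d", seq_len(n))

  ## segment-indicator covariates
  recs <- lapply(config$segmentProbs, function(pr) {
    m <- matrix(stats::rbinom(n * K, 1L, pr), n, K,
                dimnames = list(ids, sprintf("seg%02d", seq_len(K))))
    m
  })
  records <- segmentRecords(recs)
  covs_prop <- covValues(aggregateSegmentPresence(records, siteIDs = ids))

  ## continuous covariates
  covs_cont <- as.data.frame(lapply(
    stats::setNames(config$continuousCovs, config$continuousCovs),
    function(nm) stats::rnorm(n)))
  raw <- cbind(covs_prop, covs_cont)
  rownames(raw) <- ids
  rawTab <- siteCovariates(raw, siteIDs = ids)
  sds <- vapply(raw, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("degenerate covariate draw (constant column): ",
         paste(names(sds)[sds == 0], collapse = ", "),
         "; increase nSites or the segment presence probability")
  covs <- scaleCovariates(rawTab)

  ## linear predictors from named true coefficients
  etaOf <- function(coefs) {
    eta <- rep(unname(coefs[1L]), n)
    extra <- coefs[-1L]
    for (nm in names(extra)) {
      if (!nm %in% names(covValues(covs)))
        stop("true coefficient references unknown covariate: ", nm)
      eta <- eta + extra[[nm]] * covValues(covs)[[nm]]
    }
    eta
  }
  psi <- stats::plogis(etaOf(config$betaPsi))
  p <- stats::plogis(etaOf(config$alphaP))

  occupied <- stats::rbinom(n, 1L, psi)
  if (config$correlated) {
    z <- matrix(0L, n, K)
    z[, 1L] <- stats::rbinom(n, 1L, config$piFirst)
    if (K > 1L) for (k in 2:K) {
      pk <- ifelse(z[, k - 1L] == 1L, config$theta1, config$theta0)
      z[, k] <- stats::rbinom(n, 1L, pk)
    }
  } else {
    z <- matrix(1L, n, K)
  }
  y <- matrix(stats::rbinom(n * K, 1L, rep(p, K)), n, K)
  y <- y * z * occupied
  z <- z * occupied  # truth invariant: detections only where z = 1

  if (config$missingRate > 0) {
    if (config$missingMode == "uniform") {
      miss <- matrix(stats::runif(n * K) < config$missingRate, n, K)
    } else {
      nblock <- max(1L, round(config$missingRate * K))
      hit <- stats::runif(n) < 0.5
      miss <- matrix(FALSE, n, K)
      miss[hit, (K - nblock + 1L):K] <- TRUE
    }
    keep <- rowSums(!miss) > 0L
    miss[!keep, 1L] <- FALSE  # never blank out a whole site
    y[miss] <- NA_integer_
  }

  yObj <- detectionHistory(y, siteIDs = ids, segmentLength = 200)
  new("SimulatedOccuData", y = yObj, covs = covs, records = records,
      truth = list(occupied = occupied, z = z, psi = psi, p = p,
                   config = config))
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates from a configuration, fits the matching model, and
#' summarises bias, RMSE and 95% CI coverage for every real-scale parameter
#' (occupancy and detection evaluated at the covariate means). Replicates
#' whose fit fails are recorded and excluded from the summaries.
#'
#' @param config a \code{\link{simConfig}}; replicate r runs with seed
#'   \code{seed + r}.
#' @param nReplicates number of replicates (>= 2).
#' @param seed integer base seed.
#' @param nStarts optimisation starts per fit.
#' @return data.frame with one row per parameter: parameter, true, mean
#'   estimate, bias, RMSE, coverage, nConverged; attribute
#'   \code{"failures"} lists failed replicates.
#' @export
recoveryExperiment <- function(config, nReplicates, seed = 1L,
                               nStarts = 2L) {
  stopifnot(nReplicates >= 2L)
  spec <- occuSpec(psi = names(config$betaPsi)[-1L],
                   p = names(config$alphaP)[-1L],
                   correlated = config$correlated)
  trueReal <- c(psi = stats::plogis(unname(config$betaPsi[1L])),
                p = stats::plogis(unname(config$alphaP[1L])))
  if (config$correlated)
    trueReal <- c(trueReal, theta0 = config$theta0, theta1 = config$theta1,
                  pi = config$piFirst)
  est <- cover <- matrix(NA_real_, nReplicates, length(trueReal),
                         dimnames = list(NULL, names(trueReal)))
  failures <- integer(0)
  for (r in seq_len(nReplicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulateDataset(cfg)
    f <- tryCatch(fitOccu(sim$y, sim$covs, spec, nStarts = nStarts,
                          seed = seed + r),
                  error = function(e) NULL)
    if (is.null(f) || !f@converged) { failures <- c(failures, r); next }
    rp <- realParameters(f)
    rownames(rp) <- rp$parameter
    for (nm in names(trueReal)) {
      est[r, nm] <- rp[nm, "estimate"]
      cover[r, nm] <- as.numeric(rp[nm, "lci"] <= trueReal[[nm]] &&
                                 trueReal[[nm]] <= rp[nm, "uci"])
    }
  }
  ok <- stats::complete.cases(est)
  out <- data.frame(
    parameter = names(trueReal), true = unname(trueReal),
    meanEstimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(trueReal),
    medianBias = apply(est[ok, , drop = FALSE], 2L, stats::median) -
      unname(trueReal),
    rmse = sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2L,
                               unname(trueReal))^2)),
    coverage = colMeans(cover[ok, , drop = FALSE]),
    nConverged = sum(ok), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
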