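#' @import methods
#' @importFrom stats coef vcov AIC logLik
NULL

#' Detection histories on spatial replicates
#'
#' Sites-by-segments matrix of detection (1), non-detection (0) and missing
#' (NA) outcomes from a sign survey in which each site (grid cell) is walked
#' once and the trail is divided into contiguous segments. Rows are sites
#' (rownames are the site identifiers), columns are segments in transect
#' order. Segments that could not be surveyed are NA and are treated as
#' information-less.
#'
#' @slot y integer matrix of 0/1/NA with unique rownames (site ids).
#' @slot segmentLength optional segment length in metres (metadata only;
#'   \code{NA_real_} when unknown).
#' @export
setClass("DetectionHistory",
  representation(y = "matrix", segmentLength = "numeric"),
  prototype(segmentLength = NA_real_)
)

setValidity("DetectionHistory", function(object) {
  y <- object@y
  if (nrow(y) < 1L) return("no sites")
  if (ncol(y) < 1L) return("need at least one segment")
  if (is.null(rownames(y))) return("rownames (site ids) required")
  if (anyDuplicated(rownames(y))) return("duplicate site ids")
  vals <- y[!is.na(y)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    return("entries must be 0, 1 or NA")
  if (length(object@segmentLength) != 1L)
    return("segmentLength must be a single number")
  if (!is.na(object@segmentLength) && object@segmentLength <= 0)
    return("segmentLength must be positive")
  TRUE
})

#' Site covariates, raw or z-scaled
#'
#' Per-site named covariates. Proportion-type covariates (e.g. the fraction
#' of segments with termite mounds) live alongside continuous remote-sensing
#' scores; before modelling all columns are centred and scaled to unit sample
#' standard deviation, and the scaling parameters are retained so that new
#' sites can be placed on the training scale and estimates back-transformed.
#'
#' @slot data data.frame of numeric columns, rownames are site ids.
#' @slot scaled logical; TRUE once \code{\link{scaleCovariates}} has run.
#' @slot scaleParams named list with numeric vectors \code{center} and
#'   \code{scale} (empty until scaled).
#' @export
setClass("SiteCovariates",
  representation(data = "data.frame", scaled = "logical",
                 scaleParams = "list"),
  prototype(scaled = FALSE, scaleParams = list())
)

setValidity("SiteCovariates", function(object) {
  d <- object@data
  if (nrow(d) < 1L) return("no sites")
  if (is.null(rownames(d))) return("rownames (site ids) required")
  if (anyDuplicated(rownames(d))) return("duplicate site ids")
  if (!all(vapply(d, is.numeric, logical(1))))
    return("all covariate columns must be numeric")
  if (anyNA(d)) return("missing covariate values are not allowed")
  if (object@scaled) {
    sp <- object@scaleParams
    if (!all(c("center", "scale") %in% names(sp)))
      return("scaled table must carry scaleParams$center and $scale")
    if (nrow(d) >= 2L && ncol(d) >= 1L) {
      m <- vapply(d, mean, numeric(1))
      s <- vapply(d, stats::sd, numeric(1))
      if (isTRUE(any(abs(m) > 1e-8)) || isTRUE(any(abs(s - 1) > 1e-8)))
        return("scaled columns must have mean 0 and sd 1")
    }
  }
  TRUE
})

#' Per-segment presence/absence records
#'
#' Binary indicators recorded on every transect segment while walking the
#' trail (termite mounds, fruit plants, humans, livestock, fire, ...), one
#' sites-by-segments matrix per indicator. These are aggregated to site-level
#' proportions by \code{\link{aggregateSegmentPresence}}.
#'
#' @slot records named list of 0/1/NA matrices, identical dimnames.
#' @export
setClass("SegmentRecords", representation(records = "list"))

setValidity("SegmentRecords", function(object) {
  r <- object@records
  if (length(r) < 1L) return("no indicator matrices")
  if (is.null(names(r)) || any(!nzchar(names(r))))
    return("indicator matrices must be named")
  dims <- lapply(r, dim)
  if (length(unique(dims)) != 1L) return("indicator matrices differ in shape")
  for (nm in names(r)) {
    m <- r[[nm]]
    if (!is.matrix(m)) return(sprintf("'%s' is not a matrix", nm))
    vals <- m[!is.na(m)]
    if (length(vals) && !all(vals %in% c(0, 1)))
      return(sprintf("'%s' has entries other than 0/1/NA", nm))
  }
  TRUE
})

#' Occupancy model specification
#'
#' Covariate structure for occupancy (psi) and detection (p), plus the
#' correlated-detection switches. Under the correlated model, local presence
#' of sign on segment k follows a two-state Markov chain with colonisation
#' probability theta0 (present given absent on the previous segment),
#' persistence theta1 (present given present) and first-segment probability
#' pi. \code{piMode} controls pi: \code{"estimated"} (a free logit-scale
#' parameter, the default), \code{"stationary"} (the chain equilibrium
#' theta0 / (1 + theta0 - theta1)) or \code{"fixed"} (a supplied constant).
#'
#' @slot psiCovariates character; covariate names on logit psi (empty =
#'   intercept only).
#' @slot pCovariates character; covariate names on logit p.
#' @slot correlated logical; FALSE gives the standard independent-replicate
#'   model.
#' @slot piMode one of "estimated", "stationary", "fixed".
#' @slot piValue numeric in (0,1); used only when piMode = "fixed".
#' @slot pLevel "site" (detection covariates are site-level, p constant over
#'   segments) or "segment" (p varies by segment via per-segment covariates).
#' @export
setClass("OccuModelSpec",
  representation(psiCovariates = "character", pCovariates = "character",
                 correlated = "logical", piMode = "character",
                 piValue = "numeric", pLevel = "character"),
  prototype(psiCovariates = character(), pCovariates = character(),
            correlated = TRUE, piMode = "estimated", piValue = NA_real_,
            pLevel = "site")
)

setValidity("OccuModelSpec", function(object) {
  if (!object@piMode %in% c("estimated", "stationary", "fixed"))
    return("piMode must be 'estimated', 'stationary' or 'fixed'")
  if (!object@pLevel %in% c("site", "segment"))
    return("pLevel must be 'site' or 'segment'")
  if (object@piMode == "fixed" &&
      (is.na(object@piValue) || object@piValue <= 0 || object@piValue >= 1))
    return("piMode 'fixed' requires piValue in (0,1)")
  if (anyDuplicated(object@psiCovariates))
    return("duplicated psi covariate names")
  if (anyDuplicated(object@pCovariates))
    return("duplicated p covariate names")
  TRUE
})

#' A fitted occupancy model
#'
#' Maximum-likelihood fit of an \linkS4class{OccuModelSpec} to a
#' \linkS4class{DetectionHistory} and its \linkS4class{SiteCovariates}.
#' Carries the data so that prediction, model averaging and goodness-of-fit
#' can run from the fit alone.
#'
#' @slot spec the model specification.
#' @slot coefficients named MLE vector on the link (logit) scale.
#' @slot loglik maximised log-likelihood.
#' @slot K number of free parameters.
#' @slot aic -2 loglik + 2 K.
#' @slot vcov variance-covariance matrix on the link scale (inverse observed
#'   information); all-NA when the Hessian was not positive definite.
#' @slot converged logical convergence diagnosis.
#' @slot gradNorm Euclidean norm of the numerical NLL gradient at the MLE.
#' @slot nStartsUsed number of optimisation starts run.
#' @slot boundaryFlags names of real-scale parameters within 1e-4 of 0 or 1.
#' @slot y,covs the training data.
#' @export
setClass("OccuFit",
  representation(spec = "OccuModelSpec", coefficients = "numeric",
                 loglik = "numeric", K = "integer", aic = "numeric",
                 vcov = "matrix", converged = "logical", gradNorm = "numeric",
                 nStartsUsed = "integer", boundaryFlags = "character",
                 y = "DetectionHistory", covs = "SiteCovariates")
)

setValidity("OccuFit", function(object) {
  if (length(object@coefficients) != object@K)
    return("coefficient length must equal K")
  if (abs(object@aic - (-2 * object@loglik + 2 * object@K)) > 1e-9)
    return("aic inconsistent with loglik and K")
  if (!all(dim(object@vcov) == c(object@K, object@K)))
    return("vcov must be K x K")
  if (object@converged && !anyNA(object@vcov)) {
    if (max(abs(object@vcov - t(object@vcov))) > 1e-8)
      return("vcov must be symmetric")
    if (any(diag(object@vcov) < -1e-12))
      return("vcov diagonal must be non-negative")
  }
  TRUE
})

#' AIC model-comparison table
#'
#' Ranked model set: AIC, differences to the best model (deltaAIC), Akaike
#' weights w = exp(-delta/2) / sum exp(-delta/2), model likelihoods
#' ML = exp(-delta/2) and parameter counts, sorted by AIC ascending.
#'
#' @slot table data.frame with columns model, AIC, deltaAIC, w, ML, K.
#' @slot fits list of the \linkS4class{OccuFit} objects in table order (may
#'   be empty when the table was built from AIC values alone).
#' @export
setClass("OccuAICTable",
  representation(table = "data.frame", fits = "list"),
  prototype(fits = list())
)

setValidity("OccuAICTable", function(object) {
  tb <- object@table
  need <- c("model", "AIC", "deltaAIC", "w", "ML", "K")
  if (!all(need %in% names(tb))) return("table missing required columns")
  if (nrow(tb) < 1L) return("empty table")
  if (is.unsorted(tb$AIC)) return("table must be sorted by AIC")
  if (abs(tb$deltaAIC[1L]) > 1e-9) return("first deltaAIC must be 0")
  if (abs(sum(tb$w) - 1) > 1e-9) return("weights must sum to 1")
  if (max(abs(tb$ML - exp(-tb$deltaAIC / 2))) > 1e-9)
    return("ML must equal exp(-deltaAIC/2)")
  if (length(object@fits) && length(object@fits) != nrow(tb))
    return("fits must match table rows")
  TRUE
})

#' Parametric-bootstrap goodness-of-fit result
#'
#' @slot observed observed Pearson chi-square on detection histories.
#' @slot boot bootstrap chi-square values (length B, NA where a refit failed).
#' @slot pValue (1 + #\{boot >= observed\}) / (B + 1).
#' @slot cHat observed / mean(boot), the overdispersion factor.
#' @slot B number of bootstrap datasets.
#' @export
setClass("OccuGof",
  representation(observed = "numeric", boot = "numeric", pValue = "numeric",
                 cHat = "numeric", B = "integer")
)

setValidity("OccuGof", function(object) {
  if (object@observed < 0) return("observed chi-square must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) return("pValue outside [0,1]")
  if (object@B < 1L) return("B must be >= 1")
  TRUE
})

#' Simulated survey with latent truth
#'
#' Output of \code{\link{simulateDataset}}: a detection history and covariate
#' table in exactly the form the fitting functions consume, plus the latent
#' truth (occupancy indicators, local-presence chain, true parameters) needed
#' by recovery and calibration studies.
#'
#' @slot y detection history.
#' @slot covs z-scaled covariates.
#' @slot records the raw segment indicators behind the proportion covariates.
#' @slot truth list: occupied (0/1 per site), z (sites x segments local
#'   presence), psi/p per site, config (the generating configuration).
#' @export
setClass("SimulatedOccuData",
  representation(y = "DetectionHistory", covs = "SiteCovariates",
                 records = "SegmentRecords", truth = "list")
)

setValidity("SimulatedOccuData", function(object) {
  tr <- object@truth
  y <- object@y@y
  if (!all(c("occupied", "z", "config") %in% names(tr)))
    return("truth must carry occupied, z and config")
  if (length(tr$occupied) != nrow(y)) return("truth/occupancy length mismatch")
  if (!all(dim(tr$z) == dim(y))) return("truth z dimension mismatch")
  det <- which(y == 1, arr.ind = TRUE)
  if (nrow(det)) {
    if (any(tr$occupied[det[, 1L]] == 0))
      return("detection at an unoccupied site")
    if (any(tr$z[det] == 0))
      return("detection where local presence is 0")
  }
  TRUE
})
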