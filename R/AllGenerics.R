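#' @name occuCorr-accessors
#' @title Accessors for occuCorr objects
#' @description Small accessor generics: \code{siteIDs}, \code{nSites},
#'   \code{nSegments}, \code{detections} (the 0/1/NA matrix),
#'   \code{covValues} (the covariate data.frame), \code{isScaled},
#'   \code{scaleParams}, \code{modelNotation} (PRESENCE-style model string).
#' @param x,object an occuCorr object.
#' @return See the individual methods.
NULL

#' @rdname occuCorr-accessors
#' @export
setGeneric("siteIDs", function(x) standardGeneric("siteIDs"))

#' @rdname occuCorr-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname occuCorr-accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @rdname occuCorr-accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname occuCorr-accessors
#' @export
setGeneric("covValues", function(x) standardGeneric("covValues"))

#' @rdname occuCorr-accessors
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname occuCorr-accessors
#' @export
setGeneric("scaleParams", function(x) standardGeneric("scaleParams"))

#' @rdname occuCorr-accessors
#' @export
setGeneric("modelNotation", function(x) standardGeneric("modelNotation"))

#' @rdname occuCorr-accessors
setMethod("siteIDs", "DetectionHistory", function(x) rownames(x@y))

#' @rdname occuCorr-accessors
setMethod("siteIDs", "SiteCovariates", function(x) rownames(x@data))

#' @rdname occuCorr-accessors
setMethod("nSites", "DetectionHistory", function(x) nrow(x@y))

#' @rdname occuCorr-accessors
setMethod("nSites", "SiteCovariates", function(x) nrow(x@data))

#' @rdname occuCorr-accessors
setMethod("nSegments", "DetectionHistory", function(x) ncol(x@y))

#' @rdname occuCorr-accessors
setMethod("detections", "DetectionHistory", function(x) x@y)

#' @rdname occuCorr-accessors
setMethod("covValues", "SiteCovariates", function(x) x@data)

#' @rdname occuCorr-accessors
setMethod("isScaled", "SiteCovariates", function(x) x@scaled)

#' @rdname occuCorr-accessors
setMethod("scaleParams", "SiteCovariates", function(x) x@scaleParams)

#' @describeIn occuCorr-accessors coefficient vector (link scale) of a fit.
#' @export
setMethod("coef", "OccuFit", function(object) object@coefficients)

#' @describeIn occuCorr-accessors link-scale variance-covariance of a fit.
#' @export
setMethod("vcov", "OccuFit", function(object) object@vcov)

#' @describeIn occuCorr-accessors maximised log-likelihood.
#' @export
setMethod("logLik", "OccuFit", function(object) {
  structure(object@loglik, df = object@K, class = "logLik")
})

#' @rdname occuCorr-accessors
#' @param ... unused.
#' @param k penalty per parameter (2 for AIC).
#' @export
setMethod("AIC", "OccuFit", function(object, ..., k = 2) {
  -2 * object@loglik + k * object@K
})

setMethod("show", "DetectionHistory", function(object) {
  y <- object@y
  cat(sprintf("DetectionHistory: %d sites x %d segments\n", nrow(y), ncol(y)))
  if (!is.na(object@segmentLength))
    cat(sprintf("  segment length: %g m\n", object@segmentLength))
  cat(sprintf("  detections: %d  missing entries: %d  naive occupancy: %.3f\n",
              sum(y == 1, na.rm = TRUE), sum(is.na(y)), naiveOccupancy(object)))
})

setMethod("show", "SiteCovariates", function(object) {
  cat(sprintf("SiteCovariates: %d sites, %d covariates (%s)\n",
              nrow(object@data), ncol(object@data),
              if (object@scaled) "z-scaled" else "raw"))
  cat(" ", paste(colnames(object@data), collapse = ", "), "\n")
})

setMethod("show", "SegmentRecords", function(object) {
  d <- dim(object@records[[1L]])
  cat(sprintf("SegmentRecords: %d indicators on %d sites x %d segments\n",
              length(object@records), d[1L], d[2L]))
  cat(" ", paste(names(object@records), collapse = ", "), "\n")
})

setMethod("show", "OccuModelSpec", function(object) {
  cat("OccuModelSpec:", modelNotation(object), "\n")
})

setMethod("show", "OccuFit", function(object) {
  cat("OccuFit:", modelNotation(object@spec), "\n")
  cat(sprintf("  logLik %.4f  K %d  AIC %.2f  %s\n", object@loglik, object@K,
              object@aic,
              if (object@converged) "converged" else "NOT converged"))
  print(round(object@coefficients, 4))
  if (length(object@boundaryFlags))
    cat("  boundary:", paste(object@boundaryFlags, collapse = ", "), "\n")
})

setMethod("show", "OccuAICTable", function(object) {
  cat("OccuAICTable (", nrow(object@table), " models)\n", sep = "")
  tb <- object@table
  tb$AIC <- sprintf("%.2f", tb$AIC)
  tb$deltaAIC <- sprintf("%.2f", tb$deltaAIC)
  tb$w <- sprintf("%.2f", tb$w)
  tb$ML <- sprintf("%.2f", tb$ML)
  print(tb, row.names = FALSE)
})

setMethod("show", "OccuGof", function(object) {
  cat(sprintf(
    "Parametric-bootstrap goodness-of-fit\n  X-squared %.4f  B %d  p %.4f  c-hat %.4f\n",
    object@observed, object@B, object@pValue, object@cHat))
})

setMethod("show", "SimulatedOccuData", function(object) {
  cat(sprintf("SimulatedOccuData: %d sites x %d segments (true occupancy %.3f)\n",
              nSites(object@y), nSegments(object@y), mean(object@truth$occupied)))
})

#' Extract parts of a simulated dataset
#'
#' @param x a \linkS4class{SimulatedOccuData}.
#' @param name one of \code{y}, \code{covs}, \code{records}, \code{truth}.
#' @export
setMethod("$", "SimulatedOccuData", function(x, name) slot(x, name))

#' @rdname occuCorr-accessors
#' @export
setMethod("as.data.frame", "OccuAICTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)
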