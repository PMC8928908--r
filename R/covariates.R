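#' Construct a site-covariate table
#'
#' @param data data.frame of numeric covariates, one row per site.
#' @param siteIDs site labels; defaults to existing rownames or
#'   \code{site01, ...}.
#' @return an unscaled \linkS4class{SiteCovariates}.
#' @export
siteCovariates <- function(data, siteIDs = NULL) {
  data <- as.data.frame(data)
  if (is.null(siteIDs))
    siteIDs <- if (.has_real_rownames(data)) rownames(data) else
      sprintf("site%02d", seq_len(nrow(data)))
  rownames(data) <- as.character(siteIDs)
  new("SiteCovariates", data = data, scaled = FALSE, scaleParams = list())
}

.has_real_rownames <- function(d) {
  !is.null(attr(d, "row.names")) && !is.integer(attr(d, "row.names"))
}

#' Read / write site covariates as CSV
#'
#' Header \code{site,<name>,...}; first column is the site id.
#'
#' @param path file path.
#' @return \code{readSiteCovariates}: an unscaled
#'   \linkS4class{SiteCovariates}.
#' @export
readSiteCovariates <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (nrow(raw) == 0L) stop("no sites in '", path, "'")
  ids <- as.character(raw[[1L]])
  d <- raw[, -1L, drop = FALSE]
  if (anyNA(d)) stop("missing covariate values in '", path, "'")
  siteCovariates(d, siteIDs = ids)
}

#' @rdname readSiteCovariates
#' @param x a \linkS4class{SiteCovariates} (raw or scaled; values are
#'   written as stored).
#' @export
writeSiteCovariates <- function(x, path) {
  stopifnot(is(x, "SiteCovariates"))
  df <- data.frame(site = siteIDs(x), covValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment records constructor
#'
#' @param ... named 0/1/NA matrices (sites x segments), or a single named
#'   list of them.
#' @return a \linkS4class{SegmentRecords}.
#' @export
segmentRecords <- function(...) {
  r <- list(...)
  if (length(r) == 1L && is.list(r[[1L]]) && !is.matrix(r[[1L]]))
    r <- r[[1L]]
  r <- lapply(r, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  })
  new("SegmentRecords", records = r)
}

#' Aggregate segment indicators to site-level proportion covariates
#'
#' Food-resource indicators recorded per segment become site covariates as
#' the proportion of surveyed (non-missing) segments in which they were
#' present. The three disturbance indicators (\code{human},
#' \code{livestock}, \code{fire}) are pooled into a single score: a segment
#' counts as disturbed when any of the three is present, and \code{Dist} is
#' the mean of that pooled indicator over surveyed segments — so all three
#' outputs remain proportions in [0, 1].
#'
#' @param records a \linkS4class{SegmentRecords} containing matrices named
#'   \code{termite}, \code{fruit}, \code{human}, \code{livestock},
#'   \code{fire} (any subset; \code{Dist} needs at least one of the three
#'   disturbance indicators).
#' @param siteIDs optional site labels (default: rownames of the first
#'   indicator matrix, else \code{site01, ...}).
#' @return an unscaled \linkS4class{SiteCovariates} with columns among
#'   \code{Term}, \code{Frut}, \code{Dist}.
#' @export
aggregateSegmentPresence <- function(records, siteIDs = NULL) {
  stopifnot(is(records, "SegmentRecords"))
  r <- records@records
  first <- r[[1L]]
  n <- nrow(first)
  nobs <- Reduce(pmin, lapply(r, function(m) rowSums(!is.na(m))))
  if (any(nobs == 0L)) {
    ids <- if (!is.null(rownames(first))) rownames(first) else
      sprintf("site%02d", seq_len(n))
    stop("site(s) with all segments missing: ",
         paste(ids[nobs == 0L], collapse = ", "))
  }
  prop <- function(m) rowSums(m == 1, na.rm = TRUE) / rowSums(!is.na(m))
  out <- list()
  if ("termite" %in% names(r)) out$Term <- prop(r$termite)
  if ("fruit" %in% names(r)) out$Frut <- prop(r$fruit)
  dist_parts <- intersect(c("human", "livestock", "fire"), names(r))
  if (length(dist_parts)) {
    pooled <- Reduce(function(a, b) pmax(a, b, na.rm = FALSE),
                     r[dist_parts])
    out$Dist <- prop(pooled)
  }
  if (!length(out))
    stop("no recognised indicator names (termite, fruit, human, livestock, fire)")
  if (is.null(siteIDs))
    siteIDs <- if (!is.null(rownames(first))) rownames(first) else
      sprintf("site%02d", seq_len(n))
  siteCovariates(as.data.frame(out), siteIDs = siteIDs)
}

#' Z-scale covariates
#'
#' Centres every column and scales to unit sample standard deviation
#' (denominator n - 1), storing the per-column (mean, sd) so that the
#' transformation is invertible and new sites can be projected onto the
#' training scale.
#'
#' @param x an unscaled \linkS4class{SiteCovariates}.
#' @return a scaled \linkS4class{SiteCovariates}.
#' @seealso \code{\link{unscaleCovariates}}, \code{\link{applyScale}}
#' @export
scaleCovariates <- function(x) {
  stopifnot(is(x, "SiteCovariates"))
  if (isScaled(x)) stop("covariates are already scaled")
  d <- covValues(x)
  ctr <- vapply(d, mean, numeric(1))
  scl <- vapply(d, stats::sd, numeric(1))
  if (any(scl == 0))
    stop("constant column(s): ",
         paste(names(scl)[scl == 0], collapse = ", "))
  scaled <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                                 d, ctr, scl, SIMPLIFY = FALSE))
  rownames(scaled) <- rownames(d)
  new("SiteCovariates", data = scaled, scaled = TRUE,
      scaleParams = list(center = ctr, scale = scl))
}

#' Invert the z-scaling
#'
#' @param x a scaled \linkS4class{SiteCovariates}.
#' @return the covariates on their original scale.
#' @export
unscaleCovariates <- function(x) {
  stopifnot(is(x, "SiteCovariates"), isScaled(x))
  sp <- scaleParams(x)
  d <- covValues(x)
  raw <- as.data.frame(mapply(function(col, m, s) col * s + m,
                              d, sp$center[names(d)], sp$scale[names(d)],
                              SIMPLIFY = FALSE))
  rownames(raw) <- rownames(d)
  siteCovariates(raw, siteIDs = rownames(d))
}

#' Project new sites onto a training scale
#'
#' @param x an unscaled \linkS4class{SiteCovariates} for new sites.
#' @param params \code{scaleParams} from a scaled training table.
#' @return a scaled-flagged \linkS4class{SiteCovariates} using the training
#'   centre/scale (columns need not have sample mean 0 on the new sites, so
#'   validity of the scaled invariant is not enforced here).
#' @export
applyScale <- function(x, params) {
  stopifnot(is(x, "SiteCovariates"), !isScaled(x),
            all(c("center", "scale") %in% names(params)))
  d <- covValues(x)
  miss <- setdiff(names(d), names(params$center))
  if (length(miss)) stop("no scale parameters for: ",
                         paste(miss, collapse = ", "))
  scaled <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                                 d, params$center[names(d)],
                                 params$scale[names(d)], SIMPLIFY = FALSE))
  rownames(scaled) <- rownames(d)
  out <- new("SiteCovariates", data = d, scaled = FALSE, scaleParams = params)
  out@data <- scaled
  out@scaled <- TRUE
  validObject(out, test = TRUE)  # may legitimately fail mean-0 check; ignore
  out
}

#' Pairwise collinearity screen
#'
#' Pearson correlation for every unordered covariate pair, flagging
#' |r| >= threshold. Used before modelling to drop redundant covariates.
#'
#' @param x a \linkS4class{SiteCovariates} (raw or scaled; r is
#'   scale-invariant).
#' @param threshold flag cutoff on |r|, default 0.5.
#' @return data.frame with columns var1, var2, r, flagged.
#' @export
screenCollinearity <- function(x, threshold = 0.5) {
  stopifnot(is(x, "SiteCovariates"), threshold > 0, threshold <= 1)
  d <- covValues(x)
  if (nrow(d) < 3L) stop("need at least 3 sites for a correlation screen")
  nm <- names(d)
  if (length(nm) < 2L) stop("need at least 2 covariates")
  pairs <- utils::combn(nm, 2L)
  r <- apply(pairs, 2L, function(p) stats::cor(d[[p[1L]]], d[[p[2L]]]))
  data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ], r = r,
             flagged = abs(r) >= threshold, stringsAsFactors = FALSE)
}
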