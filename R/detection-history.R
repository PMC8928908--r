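#' Construct a detection history
#'
#' @param y matrix (or data.frame) of 0/1/NA, rows = sites, columns =
#'   segments in transect order.
#' @param siteIDs site labels; defaults to existing rownames or
#'   \code{site01, site02, ...}.
#' @param segmentLength optional segment length in metres (metadata).
#' @return a \linkS4class{DetectionHistory}.
#' @examples
#' h <- detectionHistory(rbind(c(0, 1, NA), c(0, 0, 0)))
#' naiveOccupancy(h)
#' @export
detectionHistory <- function(y, siteIDs = NULL, segmentLength = NA_real_) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (is.null(siteIDs))
    siteIDs <- if (!is.null(rownames(y))) rownames(y) else
      sprintf("site%02d", seq_len(nrow(y)))
  rownames(y) <- as.character(siteIDs)
  if (is.null(colnames(y)))
    colnames(y) <- sprintf("seg%02d", seq_len(ncol(y)))
  new("DetectionHistory", y = y, segmentLength = as.numeric(segmentLength))
}

#' Read a detection history from CSV
#'
#' Expects a comma-delimited table whose first column holds the site id and
#' whose remaining columns hold one segment each (header
#' \code{site,seg01,...}). Tokens in \code{missingTokens} become NA
#' (unsurveyed segment); anything else must parse as 0 or 1.
#'
#' @param path file path.
#' @param missingTokens character tokens mapped to missing.
#' @param segmentLength optional metadata, see \code{\link{detectionHistory}}.
#' @return a \linkS4class{DetectionHistory}.
#' @export
readDetectionHistory <- function(path, missingTokens = c("NA", "-", ""),
                                 segmentLength = NA_real_) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE,
                         na.strings = character(0))
  if (nrow(raw) == 0L) stop("no sites in '", path, "'")
  if (ncol(raw) < 2L) stop("no segment columns in '", path, "'")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate site id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seg <- as.matrix(raw[, -1L, drop = FALSE])
  out <- matrix(NA_integer_, nrow(seg), ncol(seg),
                dimnames = list(ids, colnames(seg)))
  is_missing <- matrix(seg %in% missingTokens, nrow(seg), ncol(seg))
  bad <- !is_missing & !(seg %in% c("0", "1"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary value '%s' at site '%s', column '%s'",
                 seg[w[1L], w[2L]], ids[w[1L]], colnames(seg)[w[2L]]))
  }
  out[!is_missing] <- as.integer(seg[!is_missing])
  detectionHistory(out, siteIDs = ids, segmentLength = segmentLength)
}

#' Write a detection history to CSV
#'
#' Inverse of \code{\link{readDetectionHistory}}; missing segments are
#' written as \code{NA}.
#'
#' @param x a \linkS4class{DetectionHistory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDetectionHistory <- function(x, path) {
  stopifnot(is(x, "DetectionHistory"))
  df <- data.frame(site = siteIDs(x), detections(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Naive occupancy
#'
#' Fraction of sites with at least one detection among their surveyed
#' segments — the raw proportion uncorrected for imperfect detection, a
#' lower bound on occupancy.
#'
#' @param y a \linkS4class{DetectionHistory}.
#' @return proportion in [0, 1].
#' @export
naiveOccupancy <- function(y) {
  stopifnot(is(y, "DetectionHistory"))
  mean(rowSums(detections(y) == 1, na.rm = TRUE) > 0)
}
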