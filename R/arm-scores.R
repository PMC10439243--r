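# Orchestrates per-arm segmentation, masking and Z_w scoring of a
# normalized profile.

#' Compute arm-level Z_w scores for a normalized profile
#'
#' For every scored (non-acrocentric) arm of the profile's layout:
#' segments the arm's standardized residuals by CBS, masks germline CNVs
#' and outlier intervals, Stouffer-combines the retained intervals into
#' Z_w and thresholds it into a gain/loss/neutral call. Arms with fewer
#' than `minRetained` retained intervals are flagged and carry `NA` Z_w
#' (they contribute a neutral 0 to classifier features).
#'
#' @param profile a \linkS4class{NormalizedProfile}.
#' @param seed integer seed; each (arm) gets a deterministic sub-seed.
#' @param alpha,minWidth,nPerm segmentation parameters, see
#'   [segmentArm()].
#' @param outlierMadMult,germlineMaxIntervals,germlineZ masking
#'   parameters, see [maskSegments()].
#' @param minRetained minimum retained intervals for a defined Z_w
#'   (default 10).
#' @param gainThreshold,lossThreshold,borderlineThreshold call
#'   thresholds, see [callArm()].
#' @return An \linkS4class{ArmZScores}; the profile's mask reasons are
#'   recorded in the returned object's `scores` attribute `maskReason`.
#' @examples
#' # see the package vignette for an end-to-end example
#' @export
armZScores <- function(profile, seed = 1L, alpha = 0.01, minWidth = 3,
                       nPerm = 1000, outlierMadMult = 4,
                       germlineMaxIntervals = 6, germlineZ = 4,
                       minRetained = 10, gainThreshold = 7.5,
                       lossThreshold = -7.5, borderlineThreshold = 5) {
  stopifnot(is(profile, "NormalizedProfile"))
  grid <- profile@grid
  arms <- gridArmLabels(grid)
  maskReason <- profile@mask
  rows <- vector("list", length(arms))
  for (a in seq_along(arms)) {
    idx <- armBinIndices(grid, arms[a])
    z <- profile@z[idx]
    segs <- segmentArm(z, alpha = alpha, minWidth = minWidth,
                       nPerm = nPerm, seed = .nodeSeed(seed, a, 0L))
    reason <- maskSegments(z, segs, outlierMadMult = outlierMadMult,
                           germlineMaxIntervals = germlineMaxIntervals,
                           germlineZ = germlineZ)
    maskReason[idx] <- reason
    retained <- reason == ""
    m <- sum(retained)
    if (m < minRetained) {
      rows[[a]] <- data.frame(arm = arms[a], zw = NA_real_, m = m,
                              call = "neutral", borderline = FALSE,
                              flagged = TRUE)
      next
    }
    zw <- armZw(z, retained)
    cl <- callArm(zw, gainThreshold, lossThreshold, borderlineThreshold)
    rows[[a]] <- data.frame(arm = arms[a], zw = zw, m = m,
                            call = cl$call, borderline = cl$borderline,
                            flagged = FALSE)
  }
  scores <- do.call(rbind, rows)
  attr(scores, "maskReason") <- maskReason
  new("ArmZScores", sampleId = profile@sampleId, scores = scores)
}

#' Extract the classifier feature vector from arm scores
#'
#' Z_w values in a fixed arm order, with undefined arms imputed to 0
#' (neutral prior) and values clipped to +/- `clip` so extreme aneuploidy
#' saturates rather than destabilizes kernel distances.
#'
#' @param armScores an \linkS4class{ArmZScores}.
#' @param featureOrder character vector of arm labels fixing the order.
#' @param clip clipping bound (default 50).
#' @return Named numeric vector of length `length(featureOrder)`.
#' @export
gasFeatures <- function(armScores, featureOrder = NULL, clip = 50) {
  stopifnot(is(armScores, "ArmZScores"))
  tab <- armScores@scores
  if (is.null(featureOrder)) featureOrder <- tab$arm
  i <- match(featureOrder, tab$arm)
  if (anyNA(i))
    stop("feature-order mismatch: arm(s) ",
         paste(featureOrder[is.na(i)], collapse = ", "),
         " absent from the arm scores")
  x <- tab$zw[i]
  x[!is.finite(x)] <- 0
  x <- pmin(pmax(x, -clip), clip)
  names(x) <- featureOrder
  x
}

#' Write per-arm scores as TSV
#'
#' @param armScores an \linkS4class{ArmZScores}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeArmScores <- function(armScores, path) {
  df <- cbind(sample = armScores@sampleId, armScores@scores)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
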