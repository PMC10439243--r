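# Focal oncogene amplification scoring: Poisson Z of observed window
# depth against the panel expectation.

#' Observed read depth over a focal window
#'
#' Sum of counts over the window's member grid intervals (for binned
#' input) or of amplicon records whose midpoint lies inside the window
#' span (for amplicon-resolution input).
#'
#' @param x an \linkS4class{IntervalVector} or \linkS4class{SampleCounts}.
#' @param window a \linkS4class{FocalWindow}.
#' @return Observed read count (numeric, integer-valued).
#' @export
observedGeneDepth <- function(x, window) {
  stopifnot(is(window, "FocalWindow"))
  if (is(x, "IntervalVector"))
    return(sum(x@counts[window@members]))
  if (is(x, "SampleCounts")) {
    r <- x@records
    mid <- floor((start(r) - 1 + end(r)) / 2)
    inWin <- as.character(seqnames(r)) == window@chrom &
      mid >= window@start & mid < window@end
    return(sum(mcols(r)$count[inWin]))
  }
  stop("x must be an IntervalVector or SampleCounts")
}

#' Poisson Z statistic for a focal window
#'
#' `Z_gene = (Observed_gene - lambda_gene) / sqrt(lambda_gene)`, the
#' standardized excess of observed over expected reads under a Poisson
#' model of the window count.
#'
#' @param observed observed read count over the window.
#' @param lambda expected read count from [expectedGeneDepth()].
#' @return Z (numeric); `NA` with a warning-free not-scorable signal when
#'   `lambda` is not positive.
#' @examples
#' focalZ(484, 400)  # 4.2
#' @export
focalZ <- function(observed, lambda) {
  if (!is.finite(lambda) || lambda <= 0) return(NA_real_)
  (observed - lambda) / sqrt(lambda)
}

#' Call focal amplification positivity
#'
#' One-sided: only amplifications (Z at or above `threshold`) gate
#' positivity; focal deletions are reported as negative Z values but never
#' called by this gate.
#'
#' @param z focal Z value.
#' @param threshold positivity threshold (default 7.5, mirroring the
#'   arm-level convention; configurable).
#' @return Logical; `FALSE` for non-scorable (`NA`) input.
#' @export
callFocal <- function(z, threshold = 7.5) {
  is.finite(z) && z >= threshold
}

#' Score all registered focal windows of a sample
#'
#' @param v an \linkS4class{IntervalVector}.
#' @param panel a \linkS4class{ReferencePanel} with registered windows.
#' @param threshold positivity threshold passed to [callFocal()].
#' @return data.frame with one row per window: gene, observed, lambda, z,
#'   scorable, positive.
#' @export
focalScores <- function(v, panel, threshold = 7.5) {
  stopifnot(is(v, "IntervalVector"), is(panel, "ReferencePanel"))
  if (length(panel@windows) == 0)
    return(data.frame(gene = character(0), observed = numeric(0),
                      lambda = numeric(0), z = numeric(0),
                      scorable = logical(0), positive = logical(0)))
  coverage <- totalAutosomalCoverage(v)
  rows <- lapply(panel@windows, function(w) {
    obs <- observedGeneDepth(v, w)
    lam <- expectedGeneDepth(panel, w, coverage)
    z <- focalZ(obs, lam)
    data.frame(gene = w@gene, observed = obs,
               lambda = if (is.finite(lam)) lam else NA_real_,
               z = z, scorable = is.finite(z),
               positive = callFocal(z, threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
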