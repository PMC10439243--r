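# Circular binary segmentation of per-arm normalized profiles: recursive
# max-|t| binary splitting with permutation p-values. The statistic at a
# candidate split i of a segment x[1..n] is the standardized mean
# difference between the two halves using the segment-wide SD, so a
# permutation of x leaves the denominator invariant and only the cumulative
# sums need recomputing per permutation.

# deterministic per-node seed so early-stopped permutation streams in one
# node never shift the draws of another (also gives the fixed
# seed-per-(sample, arm) reproducibility contract)
.nodeSeed <- function(seed, lo, hi) {
  as.integer((abs(as.numeric(seed)) * 1000003 + lo * 7919 + hi * 104729) %%
             2147483629)
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# best split of x by max |t|; returns list(i = last index of left part, t)
.maxTSplit <- function(x, minWidth) {
  n <- length(x)
  if (n < 2 * minWidth) return(list(i = NA_integer_, t = 0))
  sdx <- sd(x)
  if (!is.finite(sdx) || sdx <= 0) return(list(i = NA_integer_, t = 0))
  s <- sum(x)
  i <- seq.int(minWidth, n - minWidth)
  cs <- cumsum(x)[i]
  tt <- abs(cs / i - (s - cs) / (n - i)) / (sdx * sqrt(1 / i + 1 / (n - i)))
  j <- which.max(tt)
  list(i = i[j], t = tt[j])
}

# permutation test of the observed max |t|; early-stops once the exceedance
# count can no longer reach significance (decision identical to the full
# n_perm run). p = (1 + exceed) / (1 + done).
.permSplitTest <- function(x, tObs, minWidth, nPerm, alpha, seed) {
  n <- length(x)
  i <- seq.int(minWidth, n - minWidth)
  sdx <- sd(x)
  denom <- sdx * sqrt(1 / i + 1 / (n - i))
  s <- sum(x)
  # smallest exceedance count that already makes p >= alpha; reaching it
  # early gives the same accept/reject decision as the full run
  stopAt <- ceiling(alpha * (nPerm + 1)) - 1
  exceed <- 0L; done <- 0L
  block <- 64L
  .withSeed(seed, {
    while (done < nPerm) {
      b <- min(block, nPerm - done)
      P <- matrix(0, n, b)
      for (j in seq_len(b)) P[, j] <- x[sample.int(n)]
      csf <- cumsum(as.vector(P))
      cs <- matrix(csf, n, b)
      if (b > 1) {
        off <- c(0, csf[n * seq_len(b - 1)])
        cs <- sweep(cs, 2, off)
      }
      tm <- abs(cs[i, , drop = FALSE] / i -
                (s - cs[i, , drop = FALSE]) / (n - i)) / denom
      mx <- apply(tm, 2, max)
      # tolerance so permutations tied with the observed grouping (equal
      # left/right multisets) count as exceedances regardless of the
      # floating-point path used to evaluate the statistic
      exceed <- exceed + sum(mx >= tObs - 1e-9)
      done <- done + b
      if (exceed >= stopAt) break
    }
  })
  p <- (1 + exceed) / (1 + done)
  list(p = p, significant = p < alpha)
}

#' Segment one chromosome arm by circular binary segmentation
#'
#' Recursively splits the arm's per-interval values at the position
#' maximizing the standardized mean-difference |t| statistic, accepting a
#' split when its permutation p-value falls below `alpha`; accepted splits
#' recurse into both halves. Each recursion node draws its permutations
#' from a seed derived deterministically from (`seed`, node bounds), so
#' results are exactly reproducible and independent across nodes. Arms
#' shorter than `minWidth` return a single flagged segment.
#'
#' @param z numeric per-interval values for one arm.
#' @param alpha split significance level (default 0.01).
#' @param minWidth minimum segment width in intervals (default 3).
#' @param nPerm permutations per split test (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `start`, `end` (1-based, half-open:
#'   `end` is one past the last interval), `mean`, `n`, `p` (split p-value
#'   of the node that stopped, NA for forced segments) and `flagged`.
#' @examples
#' segmentArm(c(rnorm(25), rnorm(25, 3)), seed = 1)
#' @export
segmentArm <- function(z, alpha = 0.01, minWidth = 3, nPerm = 1000,
                       seed = 1L) {
  n <- length(z)
  if (n < minWidth) {
    return(data.frame(start = 1L, end = n + 1L, mean = mean(z), n = n,
                      p = NA_real_, flagged = TRUE))
  }
  rec <- function(lo, hi) {   # 1-based inclusive bounds
    x <- z[lo:hi]
    sp <- .maxTSplit(x, minWidth)
    leaf <- function(p) data.frame(start = lo, end = hi + 1L,
                                   mean = mean(x), n = hi - lo + 1L,
                                   p = p, flagged = FALSE)
    if (is.na(sp$i)) return(leaf(NA_real_))
    pt <- .permSplitTest(x, sp$t, minWidth, nPerm, alpha,
                         .nodeSeed(seed, lo, hi))
    if (pt$p < alpha)
      rbind(rec(lo, lo + sp$i - 1L), rec(lo + sp$i, hi))
    else leaf(pt$p)
  }
  out <- rec(1L, n)
  rownames(out) <- NULL
  out
}

#' Mask germline CNVs and outlier intervals
#'
#' Applies the two exclusion rules to a segmented arm: (i) segments
#' narrower than `germlineMaxIntervals` whose |mean z| exceeds
#' `germlineZ` are masked entirely as inherited copy-number variants
#' ("germline"); (ii) within every other segment, intervals deviating from
#' the segment mean by more than `outlierMadMult` x MAD are masked as
#' "outlier". Tumor-scale events (whole or near-whole arm shifts) are wider
#' than the germline width cap and are never masked by rule (i).
#'
#' @param z numeric per-interval values for one arm.
#' @param segments segmentation of `z` from [segmentArm()].
#' @param outlierMadMult MAD multiplier for the outlier rule (default 4).
#' @param germlineMaxIntervals maximum width (in intervals, exclusive) of a
#'   germline event (default 6, i.e. < 3 Mb at 500-kb bins).
#' @param germlineZ |mean z| threshold for the germline rule (default 4).
#' @return Character vector of reason codes per interval ("" = retained).
#' @export
maskSegments <- function(z, segments, outlierMadMult = 4,
                         germlineMaxIntervals = 6, germlineZ = 4) {
  reason <- character(length(z))
  for (r in seq_len(nrow(segments))) {
    idx <- segments$start[r]:(segments$end[r] - 1L)
    xs <- z[idx]
    if (length(idx) < germlineMaxIntervals &&
        abs(mean(xs)) > germlineZ) {
      reason[idx] <- "germline"
      next
    }
    md <- mad(xs)
    if (is.finite(md) && md > 0) {
      out <- abs(xs - mean(xs)) > outlierMadMult * md
      reason[idx][out] <- "outlier"
    }
  }
  reason
}

#' Arm-level Z_w statistic
#'
#' Stouffer combination of the retained intervals of one arm:
#' `Z_w = sum(z_i) / sqrt(m)`. Under the euploid null (z_i approximately
#' standard normal) Z_w is itself approximately standard normal, which is
#' the calibration contract checked by the null-simulation tests.
#'
#' @param z numeric per-interval values of the arm.
#' @param retained logical vector; which intervals enter the sum (default
#'   all).
#' @return Z_w (numeric); `NA` when no interval is retained.
#' @export
armZw <- function(z, retained = rep(TRUE, length(z))) {
  m <- sum(retained)
  if (m == 0) return(NA_real_)
  sum(z[retained]) / sqrt(m)
}

#' Threshold an arm Z_w into a gain/loss/neutral call
#'
#' Gains are called at Z_w above `gainThreshold` (default 7.5), losses
#' below `lossThreshold` (default -7.5); otherwise neutral. Arms with
#' `borderlineThreshold < |Z_w| <=` the call threshold are flagged
#' borderline (evidence just below positivity).
#'
#' @param zw arm Z_w value.
#' @param gainThreshold,lossThreshold call thresholds (defaults +/- 7.5).
#' @param borderlineThreshold borderline band lower edge (default 5).
#' @return list(call = "gain"/"loss"/"neutral", borderline = logical).
#' @export
callArm <- function(zw, gainThreshold = 7.5, lossThreshold = -7.5,
                    borderlineThreshold = 5) {
  if (!is.finite(zw))
    return(list(call = "neutral", borderline = FALSE))
  call <- if (zw > gainThreshold) "gain"
          else if (zw < lossThreshold) "loss" else "neutral"
  borderline <- call == "neutral" && abs(zw) > borderlineThreshold
  list(call = call, borderline = borderline)
}
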