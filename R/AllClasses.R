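#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom stats mad median quantile rnorm rpois rnbinom runif sd qnorm
#' @importFrom utils read.table write.table head
NULL

# ---- genome model -----------------------------------------------------------

#' Autosome layout: chromosome lengths and centromere gaps
#'
#' Describes the chromosomes available for copy-number scoring: name, length,
#' the centromere gap, and whether the p arm is acrocentric (satellite-only,
#' excluded from scoring). Coordinates are 0-based half-open.
#'
#' @slot chrom character, unique chromosome names.
#' @slot length numeric, chromosome lengths in bp.
#' @slot cenStart,cenEnd numeric, centromere gap in bp.
#' @slot acrocentric logical, TRUE when the p arm carries no scorable sequence.
#' @seealso [loadGenomeLayout()], [hg19Layout()], [scoredArms()]
#' @export
setClass("GenomeLayout",
  slots = c(chrom = "character", length = "numeric",
            cenStart = "numeric", cenEnd = "numeric",
            acrocentric = "logical"))

setValidity("GenomeLayout", function(object) {
  n <- length(object@chrom)
  if (length(object@length) != n || length(object@cenStart) != n ||
      length(object@cenEnd) != n || length(object@acrocentric) != n)
    return("all layout slots must have one entry per chromosome")
  if (anyDuplicated(object@chrom))
    return("chrom: duplicate chromosome names")
  if (any(!is.finite(object@length)) || any(object@length <= 0))
    return("length: chromosome lengths must be positive")
  if (any(object@cenStart < 0))
    return("cenStart: must be >= 0")
  if (any(object@cenEnd <= object@cenStart))
    return("cenEnd: must exceed cenStart")
  if (any(object@cenEnd > object@length))
    return("cenEnd: centromere outside chromosome")
  TRUE
})

#' Fixed-width autosomal interval grid
#'
#' Non-overlapping, width-uniform tiling of every autosome from position 0;
#' trailing partial bins are dropped. Each bin is assigned to exactly one
#' chromosome arm or flagged excluded (centromeric gap overlap, or acrocentric
#' p arm). The grid owns the coordinate frame every downstream count vector,
#' panel and score refers to.
#'
#' @slot bins a `GRanges` with metadata columns `arm` (e.g. "1p"; `NA` when
#'   excluded), `scored` (logical) and `excludedReason`.
#' @slot width numeric, bin width in bp.
#' @slot layout the \linkS4class{GenomeLayout} the grid was built from.
#' @seealso [buildIntervalGrid()]
#' @export
setClass("IntervalGrid",
  slots = c(bins = "GRanges", width = "numeric", layout = "GenomeLayout"))

#' Focal oncogene window
#'
#' A genomic window around an oncogene (gene span plus flanking sequence)
#' together with the indices of the grid intervals overlapping it.
#'
#' @slot gene gene symbol.
#' @slot chrom,start,end window coordinates (bp, 0-based half-open).
#' @slot members integer indices of overlapping grid intervals.
#' @seealso [makeFocalWindow()], [defaultFocalWindows()]
#' @export
setClass("FocalWindow",
  slots = c(gene = "character", chrom = "character",
            start = "numeric", end = "numeric", members = "integer"))

setValidity("FocalWindow", function(object) {
  if (object@end <= object@start) return("end must exceed start")
  TRUE
})

# ---- counts -----------------------------------------------------------------

#' Per-amplicon (or per-interval) read counts for one sample
#'
#' @slot sampleId sample identifier.
#' @slot records a `GRanges` with a `count` metadata column (non-negative).
#' @seealso [readCountsTable()], [binCounts()]
#' @export
setClass("SampleCounts",
  slots = c(sampleId = "character", records = "GRanges"))

setValidity("SampleCounts", function(object) {
  cnt <- mcols(object@records)$count
  if (is.null(cnt)) return("records must carry a 'count' metadata column")
  if (any(cnt < 0)) return("counts must be non-negative")
  TRUE
})

#' Binned counts on an interval grid
#'
#' One count per grid interval for a single sample, plus the total autosomal
#' coverage and a tally of input records that fell outside every bin.
#'
#' @slot sampleId sample identifier.
#' @slot counts numeric vector, one entry per grid interval.
#' @slot grid the \linkS4class{IntervalGrid}.
#' @slot dropped numeric, count mass dropped during binning.
#' @export
setClass("IntervalVector",
  slots = c(sampleId = "character", counts = "numeric",
            grid = "IntervalGrid", dropped = "numeric"))

setValidity("IntervalVector", function(object) {
  if (length(object@counts) != length(object@grid@bins))
    return("counts length must equal grid size")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

# ---- reference panel --------------------------------------------------------

#' Euploid reference panel
#'
#' Per-interval mean proportions, PCA loadings of correlated technical
#' structure, residual standard deviations (floored), and the expected window
#' fractions for registered focal windows — everything needed to normalize a
#' test sample and score focal amplifications.
#'
#' @slot grid the \linkS4class{IntervalGrid} the panel lives on.
#' @slot nSamples number of euploid samples the panel was built from.
#' @slot mu per-interval mean proportion (sums to 1).
#' @slot sigma per-interval residual SD after removing `k` components.
#' @slot loadings p x k PCA loadings matrix.
#' @slot k number of retained components.
#' @slot kind "csf" or "plasma" (panel provenance; pipeline code identical).
#' @slot geneMu named numeric: expected fraction of reads per focal window.
#' @slot windows list of \linkS4class{FocalWindow}.
#' @slot version schema version string.
#' @seealso [buildReferencePanel()], [pcaNormalize()], [writeReferencePanel()]
#' @export
setClass("ReferencePanel",
  slots = c(grid = "IntervalGrid", nSamples = "integer",
            mu = "numeric", sigma = "numeric", loadings = "matrix",
            k = "integer", kind = "character",
            geneMu = "numeric", windows = "list", version = "character"))

setValidity("ReferencePanel", function(object) {
  p <- length(object@grid@bins)
  if (length(object@mu) != p || length(object@sigma) != p)
    return("mu and sigma must have one entry per grid interval")
  if (any(object@mu < 0)) return("mu must be non-negative")
  if (abs(sum(object@mu) - 1) > 1e-6) return("mu must sum to 1")
  if (any(object@sigma <= 0)) return("sigma must be positive (floored)")
  if (object@k >= object@nSamples)
    return("number of components must be below panel size")
  TRUE
})

#' PCA-normalized per-interval profile
#'
#' Standardized residuals z_i of one sample against a euploid reference
#' panel, plus a mask recording intervals excluded downstream (with reason
#' codes "outlier" or "germline"; empty string = retained).
#'
#' @slot sampleId sample identifier.
#' @slot z numeric standardized residuals, one per grid interval.
#' @slot mask character reason codes, "" when retained.
#' @slot grid the \linkS4class{IntervalGrid}.
#' @seealso [pcaNormalize()], [armZScores()]
#' @export
setClass("NormalizedProfile",
  slots = c(sampleId = "character", z = "numeric",
            mask = "character", grid = "IntervalGrid"))

# ---- scores -----------------------------------------------------------------

#' Arm-level Z_w scores for one sample
#'
#' One row per scored chromosome arm: the Stouffer-combined Z_w statistic,
#' the number of retained intervals m, the gain/loss/neutral call and the
#' borderline flag (5 < |Z_w| <= 7.5).
#'
#' @slot sampleId sample identifier.
#' @slot scores data.frame with columns arm, zw, m, call, borderline, flagged.
#' @seealso [armZScores()], [callArm()]
#' @export
setClass("ArmZScores",
  slots = c(sampleId = "character", scores = "data.frame"))

#' Global Aneuploidy Score classifier
#'
#' A radial-basis-kernel SVM over the arm-level Z_w features, stored as its
#' numeric parts (support vectors, dual coefficients, kernel width, Platt
#' calibration) so that models serialize to portable text and prediction is
#' exactly reproducible.
#'
#' @slot SV support vector matrix (rows = SVs, on the feature scale).
#' @slot coefs dual coefficients (one per SV, label-signed).
#' @slot rho decision-function offset.
#' @slot gamma RBF kernel width.
#' @slot center,scale feature standardization applied before the kernel.
#' @slot probA,probB Platt sigmoid coefficients for probability output.
#' @slot classes character of length 2; `classes[1]` is the class whose
#'   decision values are positive (libsvm first training label).
#' @slot featureOrder arm labels fixing the feature order (immutable).
#' @slot meta training metadata (n per class, seed, curriculum settings).
#' @slot version schema version string.
#' @seealso [trainGAS()], [gasScore()], [defaultGASModel()]
#' @export
setClass("GASModel",
  slots = c(SV = "matrix", coefs = "numeric", rho = "numeric",
            gamma = "numeric", center = "numeric", scale = "numeric",
            probA = "numeric", probB = "numeric", classes = "character",
            featureOrder = "character", meta = "list", version = "character"))

#' Global Aneuploidy Score for one sample
#'
#' @slot sampleId sample identifier.
#' @slot gas calibrated probability in [0, 1] that the sample is aneuploid.
#' @slot positive TRUE iff gas >= threshold.
#' @slot threshold positivity threshold (default 0.25).
#' @export
setClass("GASResult",
  slots = c(sampleId = "character", gas = "numeric",
            positive = "logical", threshold = "numeric"))

setValidity("GASResult", function(object) {
  if (object@gas < 0 || object@gas > 1) return("gas must lie in [0, 1]")
  if (object@positive != (object@gas >= object@threshold))
    return("positive flag inconsistent with threshold")
  TRUE
})

#' Composite Real-CSF call
#'
#' Boolean OR combination of the Global Aneuploidy Score call and the focal
#' amplification calls, with evidence attribution.
#'
#' @slot sampleId sample identifier.
#' @slot gas the \linkS4class{GASResult}.
#' @slot focal data.frame of focal scores (gene, observed, lambda, z,
#'   scorable, positive).
#' @slot arms the \linkS4class{ArmZScores}.
#' @slot positive overall call.
#' @slot evidence one of "gas", "focal", "both", "none".
#' @seealso [compositeCall()], [scoreSample()]
#' @export
setClass("RealCSFCall",
  slots = c(sampleId = "character", gas = "GASResult",
            focal = "data.frame", arms = "ArmZScores",
            positive = "logical", evidence = "character"))

setValidity("RealCSFCall", function(object) {
  anyFocal <- nrow(object@focal) > 0 && any(object@focal$positive)
  if (object@positive != (object@gas@positive || anyFocal))
    return("positive must be the OR of the GAS call and any focal call")
  want <- if (object@gas@positive && anyFocal) "both"
          else if (object@gas@positive) "gas"
          else if (anyFocal) "focal" else "none"
  if (object@evidence != want) return("evidence inconsistent with components")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout with", length(object@chrom), "chromosomes (",
      sum(object@acrocentric), "acrocentric )\n")
  cat("  total length:", format(sum(object@length), big.mark = ","), "bp\n")
})

setMethod("show", "IntervalGrid", function(object) {
  cat("IntervalGrid:", length(object@bins), "intervals of width",
      format(object@width, big.mark = ","), "bp on",
      length(object@layout@chrom), "chromosomes\n")
  cat("  arm-assigned:", sum(mcols(object@bins)$scored),
      "| excluded:", sum(!mcols(object@bins)$scored), "\n")
})

setMethod("show", "FocalWindow", function(object) {
  cat(sprintf("FocalWindow %s %s:%s-%s (%.1f Mb, %d member intervals)\n",
              object@gene, object@chrom,
              format(object@start, big.mark = ","),
              format(object@end, big.mark = ","),
              (object@end - object@start) / 1e6, length(object@members)))
})

setMethod("show", "SampleCounts", function(object) {
  cat("SampleCounts", object@sampleId, "-", length(object@records),
      "records, total", sum(mcols(object@records)$count), "reads\n")
})

setMethod("show", "IntervalVector", function(object) {
  cat("IntervalVector", object@sampleId, "-", length(object@counts),
      "intervals, coverage", sum(object@counts),
      "( dropped:", object@dropped, ")\n")
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel (", object@kind, ") from", object@nSamples,
      "euploid samples;", length(object@mu), "intervals; k =",
      object@k, "components\n")
  if (length(object@geneMu))
    cat("  focal windows:", paste(names(object@geneMu), collapse = ", "), "\n")
})

setMethod("show", "NormalizedProfile", function(object) {
  cat("NormalizedProfile", object@sampleId, "-", length(object@z),
      "intervals,", sum(object@mask != ""), "masked\n")
})

setMethod("show", "ArmZScores", function(object) {
  cat("ArmZScores", object@sampleId, "-", nrow(object@scores), "arms:",
      sum(object@scores$call == "gain"), "gains,",
      sum(object@scores$call == "loss"), "losses\n")
})

setMethod("show", "GASModel", function(object) {
  cat("GASModel (RBF SVM):", nrow(object@SV), "support vectors,",
      length(object@featureOrder), "features, gamma =",
      signif(object@gamma, 4), "\n")
})

setMethod("show", "GASResult", function(object) {
  cat(sprintf("GASResult %s: GAS = %.4f (%s at threshold %.2f)\n",
              object@sampleId, object@gas,
              if (object@positive) "positive" else "negative",
              object@threshold))
})

setMethod("show", "RealCSFCall", function(object) {
  cat(sprintf("RealCSFCall %s: %s (evidence: %s); GAS = %.4f\n",
              object@sampleId,
              if (object@positive) "POSITIVE" else "negative",
              object@evidence, object@gas@gas))
})

# ---- accessors --------------------------------------------------------------

#' @rdname sampleId
#' @export
setMethod("sampleId", "SampleCounts", function(x) x@sampleId)
#' @rdname sampleId
#' @export
setMethod("sampleId", "IntervalVector", function(x) x@sampleId)
#' @rdname sampleId
#' @export
setMethod("sampleId", "NormalizedProfile", function(x) x@sampleId)
#' @rdname sampleId
#' @export
setMethod("sampleId", "ArmZScores", function(x) x@sampleId)
#' @rdname sampleId
#' @export
setMethod("sampleId", "GASResult", function(x) x@sampleId)
#' @rdname sampleId
#' @export
setMethod("sampleId", "RealCSFCall", function(x) x@sampleId)

#' @rdname nBins
#' @export
setMethod("nBins", "IntervalGrid", function(x) length(x@bins))
#' @rdname nBins
#' @export
setMethod("nBins", "IntervalVector", function(x) length(x@counts))
#' @rdname nBins
#' @export
setMethod("nBins", "NormalizedProfile", function(x) length(x@z))
#' @rdname nBins
#' @export
setMethod("nBins", "ReferencePanel", function(x) length(x@mu))

#' @rdname totalAutosomalCoverage
#' @export
setMethod("totalAutosomalCoverage", "IntervalVector",
          function(x) sum(x@counts))

#' Grid bins as a GRanges
#'
#' @param grid an \linkS4class{IntervalGrid}.
#' @return The `GRanges` of grid bins with `arm`, `scored` and
#'   `excludedReason` metadata columns.
#' @export
gridBins <- function(grid) {
  stopifnot(is(grid, "IntervalGrid"))
  grid@bins
}

#' Per-arm score table
#'
#' @param x an \linkS4class{ArmZScores}.
#' @return data.frame with columns arm, zw, m, call, borderline, flagged.
#' @export
armScoreTable <- function(x) {
  stopifnot(is(x, "ArmZScores"))
  x@scores
}

#' Focal score table of a composite call
#'
#' @param x a \linkS4class{RealCSFCall}.
#' @return data.frame with columns gene, observed, lambda, z, scorable,
#'   positive.
#' @export
focalScoreTable <- function(x) {
  stopifnot(is(x, "RealCSFCall"))
  x@focal
}
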