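#' @import methods
NULL

#' Sample identifier of a per-sample object
#'
#' @param x a \linkS4class{SampleCounts}, \linkS4class{IntervalVector},
#'   \linkS4class{NormalizedProfile}, \linkS4class{ArmZScores},
#'   \linkS4class{GASResult} or \linkS4class{RealCSFCall}.
#' @return Character scalar.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' Number of intervals in a grid-shaped object
#'
#' @param x an \linkS4class{IntervalGrid}, \linkS4class{IntervalVector},
#'   \linkS4class{NormalizedProfile} or \linkS4class{ReferencePanel}.
#' @return Integer scalar.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Total autosomal coverage of a binned sample
#'
#' Sum of read counts over all autosomal grid intervals; this is the
#' \emph{Coverage} term that scales the expected focal read depth.
#'
#' @param x an \linkS4class{IntervalVector}.
#' @return Numeric scalar (integer-valued).
#' @export
setGeneric("totalAutosomalCoverage",
           function(x) standardGeneric("totalAutosomalCoverage"))
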