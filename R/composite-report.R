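# Composite Boolean-OR call, end-to-end sample scoring, cohort summaries.

#' Combine GAS and focal calls by a Boolean OR gate
#'
#' A sample is positive when it scores positively either for global
#' aneuploidy or for a focal amplification of any registered gene, with
#' evidence attribution ("gas", "focal", "both", "none").
#'
#' @param gas a \linkS4class{GASResult}.
#' @param focal data.frame of focal scores from [focalScores()].
#' @param arms the sample's \linkS4class{ArmZScores}.
#' @return A \linkS4class{RealCSFCall}.
#' @export
compositeCall <- function(gas, focal, arms) {
  stopifnot(is(gas, "GASResult"), is(arms, "ArmZScores"))
  if (gas@sampleId != arms@sampleId)
    stop("sample id mismatch between GAS result ('", gas@sampleId,
         "') and arm scores ('", arms@sampleId, "')")
  anyFocal <- nrow(focal) > 0 && any(focal$positive)
  positive <- gas@positive || anyFocal
  evidence <- if (gas@positive && anyFocal) "both"
              else if (gas@positive) "gas"
              else if (anyFocal) "focal" else "none"
  new("RealCSFCall", sampleId = gas@sampleId, gas = gas, focal = focal,
      arms = arms, positive = positive, evidence = evidence)
}

#' Score one sample end to end
#'
#' Runs the full pipeline on a binned sample: PCA normalization against
#' the panel, per-arm CBS + masking + Z_w, GAS scoring, focal window
#' scoring, and the composite OR-gate call. Deterministic given `seed`.
#' When `outDir` is given, writes the arm TSV, focal TSV and a versioned
#' JSON call record (all thresholds echoed so a call is self-describing).
#'
#' @param v an \linkS4class{IntervalVector} (or a path to a counts TSV,
#'   which is read and binned first).
#' @param panel a \linkS4class{ReferencePanel}.
#' @param model a \linkS4class{GASModel}.
#' @param gasThreshold GAS positivity threshold (default 0.25).
#' @param focalThreshold focal Z positivity threshold (default 7.5).
#' @param seed integer seed for the segmentation permutations.
#' @param outDir optional output directory for reports.
#' @param ... further arguments passed to [armZScores()].
#' @return A \linkS4class{RealCSFCall}.
#' @export
scoreSample <- function(v, panel, model, gasThreshold = 0.25,
                        focalThreshold = 7.5, seed = 1L, outDir = NULL,
                        ...) {
  if (is.character(v))
    v <- binCounts(readCountsTable(v), panel@grid)
  stopifnot(is(v, "IntervalVector"))
  profile <- pcaNormalize(v, panel)
  arms <- armZScores(profile, seed = seed, ...)
  gas <- gasScore(model, arms, threshold = gasThreshold)
  focal <- focalScores(v, panel, threshold = focalThreshold)
  call <- compositeCall(gas, focal, arms)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    id <- call@sampleId
    writeArmScores(arms, file.path(outDir, paste0(id, ".arms.tsv")))
    write.table(cbind(sample = rep(id, nrow(focal)), focal),
                file.path(outDir, paste0(id, ".focal.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeCallRecord(call, file.path(outDir, paste0(id, ".call.json")),
                    seed = seed)
  }
  call
}

#' Write a self-describing JSON call record
#'
#' @param call a \linkS4class{RealCSFCall}.
#' @param path output path.
#' @param seed the seed used, echoed for traceability.
#' @return Invisibly, the path.
#' @export
writeCallRecord <- function(call, path, seed = NA_integer_) {
  stopifnot(is(call, "RealCSFCall"))
  tab <- call@arms@scores
  obj <- list(
    format = "realcsf-call", version = "1.0",
    sample = call@sampleId,
    positive = call@positive, evidence = call@evidence,
    gas = list(score = call@gas@gas, positive = call@gas@positive,
               threshold = call@gas@threshold),
    focal = call@focal,
    arms = tab[, c("arm", "zw", "m", "call", "borderline")],
    maskedIntervals = sum(attr(tab, "maskReason") != ""),
    seed = seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", na = "null"), path)
  invisible(path)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Numeric vector `c(estimate, lower, upper)`.
#' @examples
#' wilsonInterval(34, 34)  # specificity 100%, lower bound ~ 0.898
#' @export
wilsonInterval <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = centre - half, upper = centre + half)
}

#' Summarize cohort performance with Wilson intervals
#'
#' Overall sensitivity (among truth-positive samples) and specificity
#' (among truth-negatives), each with its Wilson 95% CI; optionally
#' per-class sensitivities when `class` labels are supplied.
#'
#' @param positive logical vector of composite calls (or a list of
#'   \linkS4class{RealCSFCall} objects).
#' @param truth logical vector; TRUE for samples with cancer.
#' @param class optional character vector of cancer-type labels for the
#'   truth-positive samples (NA for controls).
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns metric, class, k, n, estimate, lower,
#'   upper.
#' @export
cohortSummary <- function(positive, truth, class = NULL, conf = 0.95) {
  if (is.list(positive))
    positive <- vapply(positive, function(x) x@positive, logical(1))
  stopifnot(length(positive) == length(truth))
  if (!any(truth) || !any(!truth))
    stop("cohort must contain at least one sample in each truth class")
  row <- function(metric, cls, k, n) {
    ci <- wilsonInterval(k, n, conf)
    data.frame(metric = metric, class = cls, k = k, n = n,
               estimate = ci[["estimate"]], lower = ci[["lower"]],
               upper = ci[["upper"]])
  }
  out <- rbind(
    row("sensitivity", "all", sum(positive & truth), sum(truth)),
    row("specificity", "all", sum(!positive & !truth), sum(!truth)))
  if (!is.null(class)) {
    for (cls in unique(class[truth & !is.na(class)])) {
      sel <- truth & !is.na(class) & class == cls
      out <- rbind(out, row("sensitivity", cls,
                            sum(positive & sel), sum(sel)))
    }
  }
  rownames(out) <- NULL
  out
}
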