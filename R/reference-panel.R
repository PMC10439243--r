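# Euploid reference panel: depth normalization, PCA denoising, expected
# focal-window depth.

#' Depth-normalize a binned sample to proportions
#'
#' Divides each interval count by the total autosomal coverage, removing
#' global depth differences between samples. The result sums to 1.
#'
#' @param v an \linkS4class{IntervalVector} (or a plain numeric vector).
#' @return Numeric proportion vector.
#' @export
depthNormalize <- function(v) {
  counts <- if (is(v, "IntervalVector")) v@counts else as.numeric(v)
  tot <- sum(counts)
  if (tot <= 0) stop("total autosomal coverage is zero; cannot normalize")
  counts / tot
}

#' Build a euploid reference panel
#'
#' Computes per-interval mean proportions over the panel samples, fits a
#' PCA on the centered panel matrix to capture correlated technical
#' structure, and records the per-interval SD of the residuals after
#' removing the top `kComponents` components (with `nSamples - 1 - k`
#' degrees of freedom). SDs are floored at the `sigmaFloorQuantile`
#' quantile so quiet intervals cannot blow up downstream Z scores.
#' Expected read fractions for the registered focal windows are
#' precomputed from the panel mean.
#'
#' @param samples list of \linkS4class{IntervalVector}s on the same grid.
#' @param grid the shared \linkS4class{IntervalGrid}.
#' @param kComponents number of PCA components to remove (default 5).
#' @param minPanelSize minimum panel size (default 10).
#' @param kind "csf" or "plasma". Panels are interchangeable plumbing-wise;
#'   the attribute records provenance.
#' @param windows list of \linkS4class{FocalWindow}s to register; defaults
#'   to [defaultFocalWindows()] on the grid.
#' @param sigmaFloorQuantile quantile used to floor per-interval SDs.
#' @return A \linkS4class{ReferencePanel}.
#' @export
buildReferencePanel <- function(samples, grid, kComponents = 5L,
                                minPanelSize = 10L,
                                kind = c("csf", "plasma"),
                                windows = NULL,
                                sigmaFloorQuantile = 0.05) {
  kind <- match.arg(kind)
  n <- length(samples)
  if (n < minPanelSize)
    stop("reference panel needs >= ", minPanelSize, " samples; got ", n)
  kComponents <- as.integer(kComponents)
  if (kComponents >= n)
    stop("kComponents must be below the panel size")
  p <- nBins(grid)
  P <- t(vapply(samples, depthNormalize, numeric(p)))   # n x p
  mu <- colMeans(P)
  X <- sweep(P, 2, mu)
  V <- if (kComponents > 0) svd(X, nu = 0, nv = kComponents)$v
       else matrix(0, p, 0)
  R <- if (kComponents > 0) X - (X %*% V) %*% t(V) else X
  sigma <- sqrt(colSums(R^2) / max(1, n - 1 - kComponents))
  floorVal <- as.numeric(quantile(sigma, sigmaFloorQuantile))
  if (!is.finite(floorVal) || floorVal <= 0)
    stop("reference panel has (near-)zero residual variance; ",
         "panel samples may be identical")
  sigma <- pmax(sigma, floorVal)
  if (is.null(windows)) windows <- defaultFocalWindows(grid)
  geneMu <- vapply(windows, function(w) sum(mu[w@members]), numeric(1))
  panel <- new("ReferencePanel", grid = grid, nSamples = as.integer(n),
               mu = mu, sigma = sigma, loadings = V, k = kComponents,
               kind = kind, geneMu = geneMu, windows = windows,
               version = "1.0")
  validObject(panel)
  panel
}

#' PCA-normalize a test sample against a reference panel
#'
#' The sample's proportion vector is centered by the panel mean, its
#' projection onto the panel's top-k components is subtracted, and the
#' residual is divided by the panel's per-interval residual SD, giving a
#' standardized residual z_i per interval.
#'
#' @param v an \linkS4class{IntervalVector}.
#' @param panel a \linkS4class{ReferencePanel} on the same grid.
#' @return A \linkS4class{NormalizedProfile}.
#' @export
pcaNormalize <- function(v, panel) {
  stopifnot(is(v, "IntervalVector"), is(panel, "ReferencePanel"))
  if (nBins(v) != nBins(panel))
    stop("grid mismatch between sample (", nBins(v), ") and panel (",
         nBins(panel), ")")
  r <- depthNormalize(v) - panel@mu
  if (panel@k > 0)
    r <- r - as.numeric(panel@loadings %*% crossprod(panel@loadings, r))
  z <- r / panel@sigma
  new("NormalizedProfile", sampleId = v@sampleId, z = z,
      mask = character(length(z)), grid = panel@grid)
}

#' Expected focal-window read depth
#'
#' lambda_gene = mu_gene x Coverage: the panel-mean fraction of reads in
#' the window scaled to the test sample's total autosomal coverage.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param window a \linkS4class{FocalWindow} or a gene name registered on
#'   the panel ("HER2" is accepted as a synonym of "ERBB2").
#' @param coverage total autosomal coverage of the test sample.
#' @return Expected read count lambda (numeric). A window with zero panel
#'   coverage yields `NA` (not scorable).
#' @export
expectedGeneDepth <- function(panel, window, coverage) {
  stopifnot(is(panel, "ReferencePanel"))
  muG <- if (is(window, "FocalWindow")) sum(panel@mu[window@members])
         else panel@geneMu[[resolveGeneName(window, names(panel@geneMu))]]
  if (!is.finite(muG) || muG <= 0) return(NA_real_)
  muG * coverage
}

resolveGeneName <- function(gene, known) {
  if (gene == "HER2" && !"HER2" %in% known && "ERBB2" %in% known)
    return("ERBB2")
  if (!gene %in% known)
    stop("window '", gene, "' not registered on this panel")
  gene
}

# ---- serialization ----------------------------------------------------------

#' Write a reference panel to a portable JSON container
#'
#' The panel is stored as versioned JSON with full-precision numerics
#' (17 significant digits) so panels are diffable, portable and round-trip
#' bit-identically.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeReferencePanel <- function(panel, path) {
  stopifnot(is(panel, "ReferencePanel"))
  b <- panel@grid@bins
  obj <- list(
    format = "realcsf-panel", version = panel@version,
    kind = panel@kind, nSamples = panel@nSamples, k = panel@k,
    layout = list(chrom = panel@grid@layout@chrom,
                  length = .num17(panel@grid@layout@length),
                  cenStart = .num17(panel@grid@layout@cenStart),
                  cenEnd = .num17(panel@grid@layout@cenEnd),
                  acrocentric = panel@grid@layout@acrocentric),
    width = .num17(panel@grid@width),
    mu = .num17(panel@mu), sigma = .num17(panel@sigma),
    loadings = list(values = .num17(as.vector(panel@loadings)),
                    nrow = nrow(panel@loadings),
                    ncol = ncol(panel@loadings)),
    windows = lapply(panel@windows, function(w)
      list(gene = w@gene, chrom = w@chrom,
           start = .num17(w@start), end = .num17(w@end))))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a reference panel written by [writeReferencePanel()]
#'
#' @param path path to the panel JSON.
#' @return A \linkS4class{ReferencePanel}.
#' @export
readReferencePanel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "realcsf-panel"))
    stop("not a realcsf panel file: ", path)
  layout <- new("GenomeLayout",
                chrom = obj$layout$chrom,
                length = .un17(obj$layout$length),
                cenStart = .un17(obj$layout$cenStart),
                cenEnd = .un17(obj$layout$cenEnd),
                acrocentric = obj$layout$acrocentric)
  grid <- buildIntervalGrid(layout, width = .un17(obj$width))
  L <- matrix(.un17(obj$loadings$values),
              nrow = obj$loadings$nrow, ncol = obj$loadings$ncol)
  wdf <- obj$windows
  windows <- list()
  for (g in names(wdf)) {
    w <- wdf[[g]]
    windows[[g]] <- makeFocalWindow(w$gene, w$chrom, .un17(w$start),
                                    .un17(w$end), grid, flank = 0)
  }
  mu <- .un17(obj$mu)
  geneMu <- vapply(windows, function(w) sum(mu[w@members]), numeric(1))
  panel <- new("ReferencePanel", grid = grid,
               nSamples = as.integer(obj$nSamples),
               mu = mu, sigma = .un17(obj$sigma), loadings = L,
               k = as.integer(obj$k), kind = obj$kind,
               geneMu = geneMu, windows = windows,
               version = as.character(obj$version))
  validObject(panel)
  panel
}

# full-precision numeric <-> string helpers (exact double round trip)
.num17 <- function(x) sprintf("%.17g", x)
.un17 <- function(x) as.numeric(x)
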