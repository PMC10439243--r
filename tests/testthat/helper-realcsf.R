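# Shared fixtures, built in code and memoised for the test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

toyGrid <- function() memo("toyGrid", buildIntervalGrid(toyGenomeLayout()))

# a simulated "assay": shared propensities + euploid panel on the toy grid
toyAssay <- function(seed = 42L, depth = 2e5) {
  memo(paste0("assay", seed, "-", depth), {
    grid <- toyGrid()
    prop <- simulatePropensities(grid, efficiencySd = 0.5, seed = seed)
    panel <- simulateReferencePanel(grid, prop, nSamples = 20,
                                    depth = depth, kComponents = 5,
                                    seed = subSeed(seed, 1L),
                                    windows = list())
    list(grid = grid, prop = prop, panel = panel, depth = depth)
  })
}

# hg19-scale assay at study depth, for integration-scale checks
hg19Assay <- function(seed = 11L, depth = 1e6) {
  memo(paste0("hg19assay", seed), {
    grid <- memo("hg19grid", buildIntervalGrid(hg19Layout()))
    prop <- simulatePropensities(grid, efficiencySd = 0.5, seed = seed)
    panel <- simulateReferencePanel(grid, prop, nSamples = 20,
                                    depth = depth, kComponents = 5,
                                    seed = subSeed(seed, 1L))
    list(grid = grid, prop = prop, panel = panel, depth = depth)
  })
}

# small GAS model trained on the toy grid (fast path for unit tests)
toyGASModel <- function(seed = 7L) {
  memo(paste0("toygas", seed), {
    a <- toyAssay()
    cur <- makeGASCurriculum(a$grid, nEuploid = 50, nAneuploid = 50,
                             depth = a$depth, seed = seed,
                             panel = a$panel, propensities = a$prop)
    list(model = trainGAS(cur$features, cur$labels, seed = seed),
         curriculum = cur)
  })
}

# independent exhaustive-search segmentation oracle: naive loops over all
# split points with the same standardized mean-difference statistic and a
# full-length naive permutation test. Seeds per node follow the package's
# published subSeed() convention so decisions are comparable; the search
# and statistic are computed independently.
oracleSegment <- function(z, alpha = 0.01, minWidth = 3, nPerm = 1000,
                          seed = 1L) {
  rec <- function(lo, hi) {
    x <- z[lo:hi]; n <- length(x)
    single <- data.frame(start = lo, end = hi + 1L)
    if (n < 2 * minWidth || sd(x) == 0 || !is.finite(sd(x))) return(single)
    tAt <- function(v, i) {
      abs(mean(v[1:i]) - mean(v[(i + 1):length(v)])) /
        (sd(v) * sqrt(1 / i + 1 / (length(v) - i)))
    }
    ts <- sapply(minWidth:(n - minWidth), function(i) tAt(x, i))
    best <- which.max(ts)
    tObs <- ts[best]
    iBest <- (minWidth:(n - minWidth))[best]
    set.seed(subSeed(seed, lo, hi))
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      xp <- x[sample.int(n)]
      tp <- max(sapply(minWidth:(n - minWidth), function(i) tAt(xp, i)))
      if (tp >= tObs - 1e-9) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + nPerm)
    if (p < alpha)
      rbind(rec(lo, lo + iBest - 1L), rec(lo + iBest, hi))
    else single
  }
  out <- rec(1L, length(z))
  rownames(out) <- NULL
  out
}
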