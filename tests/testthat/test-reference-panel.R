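# Panel construction, PCA normalization, expected focal depth,
# serialization.

test_that("depth normalization yields proportions, scale-invariant", {
  g <- toyGrid()
  v <- intervalVector(rep(2, nBins(g)), g)
  expect_equal(depthNormalize(v), rep(1 / nBins(g), nBins(g)))
  expect_equal(depthNormalize(c(1, 3)), c(0.25, 0.75))
  expect_equal(depthNormalize(c(2, 6)), c(0.25, 0.75))  # doubling invariant
  expect_error(depthNormalize(intervalVector(rep(0, nBins(g)), g)), "zero")
})

test_that("panel building validates size, k and degenerate variance", {
  g <- toyGrid()
  mk <- function(x) intervalVector(x, g)
  same <- lapply(1:12, function(i) mk(rep(5, nBins(g))))
  expect_error(buildReferencePanel(same[1:5], g, windows = list()),
               ">= 10")
  expect_error(buildReferencePanel(same, g, kComponents = 12,
                                   windows = list()), "kComponents")
  # identical samples: zero residual variance everywhere -> rejected
  expect_error(buildReferencePanel(same, g, windows = list()),
               "residual variance")
})

test_that("panel residual SDs recover the injected noise scale", {
  a <- toyAssay()
  g <- a$grid
  samples <- lapply(1:20, function(i)
    simulateSample(g, a$prop, depth = 2e5, seed = subSeed(5000, i))$vector)
  panel <- buildReferencePanel(samples, g, kComponents = 3,
                               windows = list())
  # injected per-interval noise on the proportion scale is Poisson:
  # sd_i = sqrt(depth * w_i) / depth
  inj <- sqrt(2e5 * a$prop) / 2e5
  ratio <- panel@sigma / inj
  expect_lt(abs(mean(ratio) - 1), 0.25)
})

test_that("mu_gene is the panel-mean window fraction", {
  toy <- new("GenomeLayout", chrom = "c1", length = 5e6,
             cenStart = 2.4e6, cenEnd = 2.5e6, acrocentric = FALSE)
  g <- buildIntervalGrid(toy, width = 5e5)  # 10 bins
  w <- makeFocalWindow("G", "c1", 0, 1.5e6, g, flank = 0)  # 3 bins
  set.seed(8)
  samples <- lapply(1:12, function(i)
    intervalVector(rpois(10, 1000), g))
  panel <- buildReferencePanel(samples, g, kComponents = 2,
                               windows = list(G = w))
  expect_equal(panel@geneMu[["G"]], sum(panel@mu[1:3]))
  # uniform expected reads over 10 intervals -> lambda ~= 3/10 x coverage
  expect_equal(expectedGeneDepth(panel, w, 1000), panel@geneMu[["G"]] * 1000)
  expect_lt(abs(expectedGeneDepth(panel, w, 1000) - 300), 15)
  expect_equal(expectedGeneDepth(panel, "G", 1e6),
               panel@geneMu[["G"]] * 1e6)
  # constructed 10%-of-reads window
  prop <- c(0.1, rep(0.9 / 9, 9))
  samples10 <- lapply(1:12, function(i)
    intervalVector(rmultinom(1, 5e4, prop)[, 1], g))
  w1 <- makeFocalWindow("W1", "c1", 0, 5e5, g, flank = 0)
  p10 <- buildReferencePanel(samples10, g, kComponents = 2,
                             windows = list(W1 = w1))
  expect_lt(abs(p10@geneMu[["W1"]] - 0.10), 0.01)
  # zero coverage -> lambda 0, not scorable downstream
  expect_equal(expectedGeneDepth(p10, "W1", 0), 0)
  expect_true(is.na(focalZ(0, expectedGeneDepth(p10, "W1", 0))))
})

test_that("pca normalization standardizes held-out euploid samples", {
  a <- toyAssay()
  # input equal to the panel-mean profile -> z identically 0
  vMean <- intervalVector(a$panel@mu * 1e6, a$grid)
  expect_lt(max(abs(pcaNormalize(vMean, a$panel)@z)), 1e-8)

  # held-out euploid samples: z approximately standard
  zs <- unlist(lapply(1:8, function(i) {
    sim <- simulateSample(a$grid, a$prop, depth = a$depth,
                          seed = subSeed(6000, i))
    pcaNormalize(sim$vector, a$panel)@z
  }))
  expect_lt(abs(mean(zs)), 0.2)
  expect_gt(sd(zs), 0.7)
  expect_lt(sd(zs), 1.3)

  # grid mismatch rejected
  small <- buildIntervalGrid(toyGenomeLayout(), width = 1e6)
  vBad <- intervalVector(rep(1, nBins(small)), small)
  expect_error(pcaNormalize(vBad, a$panel), "mismatch")
})

test_that("an arm at copy ratio 1.5 stands out after normalization", {
  a <- toyAssay()
  sim <- simulateSample(a$grid, a$prop, depth = a$depth,
                        tumorFraction = 1,
                        armEvents = data.frame(arm = "toy2p", cn = 3),
                        seed = 61)
  z <- pcaNormalize(sim$vector, a$panel)@z
  onArm <- armBinIndices(a$grid, "toy2p")
  expect_gt(mean(z[onArm]), mean(z[-onArm]) + 3)
})

test_that("panel residuals are orthogonal to the retained loadings", {
  a <- toyAssay()
  samples <- lapply(1:20, function(i)
    simulateSample(a$grid, a$prop, depth = a$depth,
                   seed = subSeed(a$panel@nSamples + 7000, i))$vector)
  panel <- buildReferencePanel(samples, a$grid, kComponents = 5,
                               windows = list())
  for (i in c(1, 10, 20)) {
    prof <- pcaNormalize(samples[[i]], panel)
    resid <- prof@z * panel@sigma
    expect_lt(max(abs(crossprod(panel@loadings, resid))), 1e-8)
  }
})

test_that("panel serialization round-trips bit-identically", {
  a <- toyAssay()
  tmp <- withr::local_tempfile(fileext = ".json")
  writeReferencePanel(a$panel, tmp)
  back <- readReferencePanel(tmp)
  expect_identical(back@mu, a$panel@mu)
  expect_identical(back@sigma, a$panel@sigma)
  expect_identical(unname(back@loadings), unname(a$panel@loadings))
  expect_identical(back@k, a$panel@k)
  expect_identical(back@kind, a$panel@kind)
  # normalization is bit-identical through the round trip
  sim <- simulateSample(a$grid, a$prop, depth = a$depth, seed = 77)
  expect_identical(pcaNormalize(sim$vector, back)@z,
                   pcaNormalize(sim$vector, a$panel)@z)
})
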