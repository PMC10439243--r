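# CBS splitting, masking rules, arm Z_w and calls.

test_that("a constant arm yields a single segment", {
  segs <- segmentArm(rep(0.3, 50), seed = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start, segs$end), c(1, 51))
  # arm shorter than the minimum width: single flagged segment
  short <- segmentArm(c(0.1, -0.2), minWidth = 3, seed = 1)
  expect_equal(nrow(short), 1)
  expect_true(short$flagged)
})

test_that("a clear step is split near the true breakpoint", {
  set.seed(1234)
  z <- c(rnorm(25, 0, 0.5), rnorm(25, 3, 0.5))
  segs <- segmentArm(z, seed = 5)
  expect_equal(nrow(segs), 2)
  expect_lte(abs(segs$end[1] - 26), 2)   # breakpoint within +/- 2 of 25|26
  # exhaustive single-split max-t oracle on the same data
  n <- 50
  tAt <- function(i) abs(mean(z[1:i]) - mean(z[(i + 1):n])) /
    (sd(z) * sqrt(1 / i + 1 / (n - i)))
  ts <- sapply(3:(n - 3), function(i) tAt(i))
  oracleSplit <- (3:(n - 3))[which.max(ts)]
  expect_equal(segs$end[1] - 1, oracleSplit)
})

test_that("pure noise is rarely split at alpha = 0.01", {
  splits <- vapply(1:200, function(r) {
    z <- local({ set.seed(3000 + r); rnorm(50) })
    nrow(segmentArm(z, seed = r))
  }, numeric(1))
  expect_gte(mean(splits == 1), 0.95)
})

test_that("segmentation matches the exhaustive oracle on short vectors", {
  # all boundary decisions on vectors of length <= 12, with and without
  # embedded steps
  cases <- list()
  set.seed(42)
  for (n in c(6, 8, 10, 12)) {
    for (r in 1:8) {
      cases[[length(cases) + 1]] <- rnorm(n)
      cases[[length(cases) + 1]] <-
        c(rnorm(floor(n / 2)), rnorm(ceiling(n / 2), 5, 0.3))
    }
  }
  for (k in seq_along(cases)) {
    z <- cases[[k]]
    got <- segmentArm(z, minWidth = 3, nPerm = 400, seed = k)
    want <- oracleSegment(z, minWidth = 3, nPerm = 400, seed = k)
    expect_equal(got[, c("start", "end")], want,
                 info = paste("case", k))
  }
})

test_that("masking removes spikes and short germline events, not arm shifts", {
  # single spike in a flat arm -> that interval masked as outlier
  zz <- local({ set.seed(9); rnorm(40, 0, 0.3) })
  zz[17] <- 12
  segs <- segmentArm(zz, seed = 3)
  reason <- maskSegments(zz, segs)
  expect_equal(reason[17], "outlier")
  expect_lte(sum(reason != ""), 2)   # arm otherwise intact

  # 2-interval inherited CNV at z ~ 6 inside an otherwise euploid arm:
  # too narrow to segment out (minWidth 3), caught by the outlier rule,
  # and the arm Z_w returns to the null range
  zg <- local({ set.seed(1); rnorm(24) })
  zg[10:11] <- c(6.2, 5.9)
  segs <- segmentArm(zg, seed = 11)
  reason <- maskSegments(zg, segs)
  expect_true(all(reason[10:11] %in% c("germline", "outlier")))
  expect_lt(abs(armZw(zg, reason == "")), 3)

  # when CBS does isolate a short high segment, within-segment deviations
  # vanish and the germline (short, high |mean|) rule takes over
  zg3 <- local({ set.seed(22); rnorm(40) })
  zg3[12:16] <- 6 + local({ set.seed(23); rnorm(5, 0, 0.3) })
  segs3 <- data.frame(start = c(1L, 12L, 17L), end = c(12L, 17L, 41L),
                      mean = c(mean(zg3[1:11]), mean(zg3[12:16]),
                               mean(zg3[17:40])),
                      n = c(11L, 5L, 24L), p = NA_real_, flagged = FALSE)
  reason3 <- maskSegments(zg3, segs3)
  expect_equal(reason3[12:16], rep("germline", 5))
  expect_false(any(reason3[-(12:16)] == "germline"))
  expect_lt(abs(armZw(zg3, reason3 == "")), 3)

  # whole-arm tumor shift is never germline-masked
  zt <- rep(2.5, 200) + local({ set.seed(10); rnorm(200, 0, 1) })
  segsT <- segmentArm(zt, seed = 12)
  reasonT <- maskSegments(zt, segsT)
  expect_false(any(reasonT == "germline"))
})

test_that("Z_w is the Stouffer sum and antisymmetric", {
  expect_equal(armZw(rep(0, 20)), 0)
  expect_equal(armZw(rep(2, 4)), 4)          # 8 / sqrt(4)
  z <- rnorm(30)
  expect_equal(armZw(-z), -armZw(z))
  ret <- rep(c(TRUE, FALSE), 15)
  expect_equal(armZw(-z, ret), -armZw(z, ret))
  expect_true(is.na(armZw(z, rep(FALSE, 30))))
})

test_that("arm calls follow the gain/loss thresholds and borderline band", {
  expect_equal(callArm(8.0)$call, "gain")
  expect_equal(callArm(-8.0)$call, "loss")
  six <- callArm(6.0)
  expect_equal(six$call, "neutral")
  expect_true(six$borderline)
  expect_false(callArm(7.5)$call == "gain")   # strict inequality
  expect_false(callArm(4.9)$borderline)
  expect_equal(callArm(NA_real_)$call, "neutral")
})

test_that("masking does not inflate |Z_w| of euploid arms on average", {
  a <- toyAssay()
  deltas <- c()
  for (i in 1:25) {  # 25 samples x 8 arms = 200 euploid arms
    sim <- simulateSample(a$grid, a$prop, depth = a$depth,
                          seed = subSeed(8000, i))
    prof <- pcaNormalize(sim$vector, a$panel)
    for (arm in gridArmLabels(a$grid)) {
      z <- prof@z[armBinIndices(a$grid, arm)]
      segs <- segmentArm(z, seed = subSeed(8100, i))
      reason <- maskSegments(z, segs)
      deltas <- c(deltas, abs(armZw(z, reason == "")) - abs(armZw(z)))
    }
  }
  expect_lte(mean(deltas), 0.05)
})
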