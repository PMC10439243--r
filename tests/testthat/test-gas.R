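# GAS classifier: training, scoring, serialization, invariances.

test_that("training validates inputs", {
  set.seed(2)
  x <- matrix(rnorm(200 * 8), 200, 8)
  lb <- rep(c("euploid", "aneuploid"), each = 100)
  expect_error(trainGAS(x, rep("euploid", 200)), "per class")
  xb <- x; xb[1, 1] <- NA
  expect_error(trainGAS(xb, lb), "finite")
  expect_error(trainGAS(x, sub("euploid", "diploid", lb)), "labels")
})

test_that("extracted predictor agrees with the fitting engine", {
  tg <- toyGASModel()
  cur <- tg$curriculum
  fit <- realcsf:::.withSeed(7L, e1071::svm(
    x = pmin(pmax(cur$features, -50), 50),
    y = factor(cur$labels, levels = c("euploid", "aneuploid")),
    kernel = "radial", probability = TRUE, scale = FALSE))
  pr <- predict(fit, cur$features, probability = TRUE)
  pEngine <- attr(pr, "probabilities")[, "aneuploid"]
  pOurs <- apply(cur$features, 1, function(r)
    gasScore(tg$model, structure(r, names = colnames(cur$features)))@gas)
  expect_lt(max(abs(pOurs - pEngine)), 1e-8)
})

test_that("GAS separates held-out euploid from aneuploid toy samples", {
  tg <- toyGASModel()
  a <- toyAssay()
  arms <- gridArmLabels(a$grid)
  gasOf <- function(sim, i) {
    az <- armZScores(pcaNormalize(sim$vector, a$panel),
                     seed = subSeed(9100, i))
    gasScore(tg$model, az)@gas
  }
  ge <- vapply(1:20, function(i)
    gasOf(simulateSample(a$grid, a$prop, depth = a$depth,
                         seed = subSeed(9000, i)), i), numeric(1))
  ga <- vapply(1:20, function(i)
    gasOf(simulateSample(a$grid, a$prop, depth = a$depth,
                         tumorFraction = 0.3,
                         armEvents = data.frame(arm = c("toy1p", "toy3q"),
                                                cn = c(3, 1)),
                         seed = subSeed(9200, i)), 100 + i), numeric(1))
  expect_gte(mean(ge < 0.25), 0.95)
  expect_gte(mean(ga >= 0.25), 0.95)
})

test_that("flipping training labels inverts the score ordering", {
  tg <- toyGASModel()
  cur <- tg$curriculum
  flipped <- ifelse(cur$labels == "euploid", "aneuploid", "euploid")
  mFlip <- trainGAS(cur$features, flipped, seed = 7L)
  sOrig <- apply(cur$features, 1, function(r)
    gasScore(tg$model, structure(r, names = colnames(cur$features)))@gas)
  sFlip <- apply(cur$features, 1, function(r)
    gasScore(mFlip, structure(r, names = colnames(cur$features)))@gas)
  expect_lt(cor(sOrig, sFlip, method = "spearman"), -0.95)
  expect_lt(mean(abs(sFlip - (1 - sOrig))), 0.1)
})

test_that("scores are probabilities and respect the feature contract", {
  tg <- toyGASModel()
  p <- ncol(tg$model@SV)
  set.seed(31)
  for (i in 1:200) {
    x <- rnorm(p, 0, 10)
    g <- gasScore(tg$model, x)@gas
    expect_gte(g, 0); expect_lte(g, 1)
  }
  # all-zero features score negative at the default threshold
  res0 <- gasScore(tg$model, rep(0, p))
  expect_false(res0@positive)
  # strong multi-arm aneuploidy scores positive
  xHot <- rep(0, p); xHot[1:4] <- 15
  expect_true(gasScore(tg$model, xHot)@positive)
  # feature-order mismatch is an error
  az <- structure(rnorm(3), names = c("bad1", "bad2", "bad3"))
  expect_error(gasScore(tg$model, az), "mismatch")
})

test_that("model serialization round-trips scores exactly", {
  tg <- toyGASModel()
  tmp <- withr::local_tempfile(fileext = ".json")
  writeGASModel(tg$model, tmp)
  back <- readGASModel(tmp)
  set.seed(5)
  xs <- matrix(rnorm(50 * ncol(tg$model@SV), 0, 8), 50)
  s1 <- apply(xs, 1, function(r) gasScore(tg$model, r)@gas)
  s2 <- apply(xs, 1, function(r) gasScore(back, r)@gas)
  expect_identical(s1, s2)
  expect_lt(max(abs(s1 - s2)), 1e-9)
})

test_that("duplicating every training row leaves the classifier stable", {
  # soft-margin SVMs are not exactly invariant to duplicating the training
  # set (duplication doubles the effective cost, and the calibration folds
  # repartition), but the fitted score surface must stay essentially
  # unchanged: same calls everywhere, score drift well below the decision
  # scale.
  tg <- toyGASModel()
  cur <- tg$curriculum
  mDup <- trainGAS(rbind(cur$features, cur$features),
                   c(cur$labels, cur$labels), seed = 7L)
  s1 <- apply(cur$features, 1, function(r)
    gasScore(tg$model, structure(r, names = colnames(cur$features)))@gas)
  s2 <- apply(cur$features, 1, function(r)
    gasScore(mDup, structure(r, names = colnames(cur$features)))@gas)
  expect_identical(s1 >= 0.25, s2 >= 0.25)
  expect_lt(max(abs(s1 - s2)), 0.05)
  set.seed(6)
  xs <- matrix(rnorm(30 * ncol(cur$features), 0, 6), 30)
  p1 <- apply(xs, 1, function(r) gasScore(tg$model, r)@gas)
  p2 <- apply(xs, 1, function(r) gasScore(mDup, r)@gas)
  expect_lt(max(abs(p1 - p2)), 0.05)
})
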