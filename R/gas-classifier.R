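# Global Aneuploidy Score: an RBF-kernel SVM over the arm-level Z_w
# features. e1071 (libsvm) is the fitting engine; the fitted model is
# extracted into plain numeric parts so prediction is a pure function of
# the serialized model and round-trips exactly.

#' Train the Global Aneuploidy Score classifier
#'
#' Fits a radial-basis-kernel SVM with default hyperparameters
#' (cost = 1, gamma = 1/n_features) and internal cross-validated Platt
#' probability calibration on a matrix of arm Z_w feature rows. Feature
#' values are clipped to +/- `clip` before fitting. The features are kept
#' on their native Z scale (no per-column rescaling): Z_w is already
#' standardized — unit variance under the euploid null — and rescaling by
#' the class-mixture SD would shrink the euploid cluster far below the
#' kernel length scale, degrading the low-dose behavior of the score.
#' Deterministic given `seed`.
#'
#' @param features numeric matrix, rows = samples, columns = arms (column
#'   names fix the immutable feature order).
#' @param labels factor/character with levels "euploid" and "aneuploid".
#' @param seed integer seed (controls the calibration folds).
#' @param clip feature clipping bound (default 50).
#' @param minPerClass minimum training examples per class (default 50).
#' @return A \linkS4class{GASModel}.
#' @seealso [gasScore()], [defaultGASModel()], [makeGASCurriculum()]
#' @export
trainGAS <- function(features, labels, seed = 17L, clip = 50,
                     minPerClass = 50L) {
  features <- as.matrix(features)
  if (any(!is.finite(features)))
    stop("features must be finite")
  labels <- factor(as.character(labels), levels = c("euploid", "aneuploid"))
  if (anyNA(labels)) stop("labels must be 'euploid' or 'aneuploid'")
  tab <- table(labels)
  if (any(tab < minPerClass))
    stop("need >= ", minPerClass, " training examples per class; got ",
         paste(tab, collapse = "/"))
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  features <- pmin(pmax(features, -clip), clip)
  fit <- .withSeed(seed, e1071::svm(x = features, y = labels,
                                    kernel = "radial", probability = TRUE,
                                    scale = FALSE))
  # libsvm decision values are positive for the first training label
  firstClass <- fit$levels[fit$labels[1]]
  otherClass <- setdiff(fit$levels, firstClass)
  new("GASModel",
      SV = unname(as.matrix(fit$SV)),
      coefs = as.numeric(fit$coefs),
      rho = as.numeric(fit$rho),
      gamma = as.numeric(fit$gamma),
      center = numeric(ncol(features)),
      scale = rep(1, ncol(features)),
      probA = as.numeric(fit$probA),
      probB = as.numeric(fit$probB),
      classes = c(firstClass, otherClass),
      featureOrder = colnames(features),
      meta = list(nEuploid = as.integer(tab[["euploid"]]),
                  nAneuploid = as.integer(tab[["aneuploid"]]),
                  seed = as.integer(seed), clip = clip,
                  engine = "e1071::svm radial, default cost/gamma"),
      version = "1.0")
}

# calibrated P(aneuploid) for feature rows (matrix or vector)
.gasProbability <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model@featureOrder))
    stop("feature-order mismatch: expected ",
         length(model@featureOrder), " features")
  xs <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  # RBF kernel against support vectors
  d2 <- outer(rowSums(xs^2), rowSums(model@SV^2), "+") -
    2 * xs %*% t(model@SV)
  K <- exp(-model@gamma * pmax(d2, 0))
  f <- drop(K %*% model@coefs) - model@rho
  pFirst <- 1 / (1 + exp(model@probA * f + model@probB))
  if (model@classes[1] == "aneuploid") pFirst else 1 - pFirst
}

#' Score a sample's aneuploidy with a GAS model
#'
#' Maps the 39 arm Z_w features (in the model's immutable feature order,
#' undefined arms imputed to 0, clipped) through the calibrated RBF-SVM to
#' a Global Aneuploidy Score in [0, 1]; positive at `threshold` (default
#' 0.25).
#'
#' @param model a \linkS4class{GASModel}.
#' @param armScores an \linkS4class{ArmZScores}, or a named numeric
#'   feature vector.
#' @param threshold positivity threshold (default 0.25).
#' @return A \linkS4class{GASResult}.
#' @export
gasScore <- function(model, armScores, threshold = 0.25) {
  stopifnot(is(model, "GASModel"))
  if (is(armScores, "ArmZScores")) {
    x <- gasFeatures(armScores, model@featureOrder,
                     clip = model@meta$clip %||% 50)
    id <- armScores@sampleId
  } else {
    x <- armScores
    if (!is.null(names(x))) {
      i <- match(model@featureOrder, names(x))
      if (anyNA(i)) stop("feature-order mismatch")
      x <- x[i]
    }
    id <- "sample"
  }
  gas <- unname(.gasProbability(model, x))
  gas <- min(max(gas, 0), 1)
  new("GASResult", sampleId = id, gas = gas,
      positive = gas >= threshold, threshold = threshold)
}

#' Write a GAS model as portable JSON
#'
#' Full-precision (17 significant digit) serialization; scores round-trip
#' exactly.
#'
#' @param model a \linkS4class{GASModel}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeGASModel <- function(model, path) {
  stopifnot(is(model, "GASModel"))
  obj <- list(format = "realcsf-gas", version = model@version,
              classes = model@classes, featureOrder = model@featureOrder,
              SV = list(values = .num17(as.vector(model@SV)),
                        nrow = nrow(model@SV), ncol = ncol(model@SV)),
              coefs = .num17(model@coefs), rho = .num17(model@rho),
              gamma = .num17(model@gamma), center = .num17(model@center),
              scale = .num17(model@scale), probA = .num17(model@probA),
              probB = .num17(model@probB),
              meta = model@meta)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a GAS model written by [writeGASModel()]
#'
#' @param path path to the model JSON.
#' @return A \linkS4class{GASModel}.
#' @export
readGASModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "realcsf-gas"))
    stop("not a realcsf GAS model file: ", path)
  SV <- matrix(.un17(obj$SV$values), nrow = obj$SV$nrow,
               ncol = obj$SV$ncol)
  meta <- obj$meta
  meta$seed <- as.integer(meta$seed)
  new("GASModel", SV = unname(SV), coefs = .un17(obj$coefs),
      rho = .un17(obj$rho), gamma = .un17(obj$gamma),
      center = .un17(obj$center), scale = .un17(obj$scale),
      probA = .un17(obj$probA), probB = .un17(obj$probB),
      classes = obj$classes, featureOrder = obj$featureOrder,
      meta = meta, version = as.character(obj$version))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
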