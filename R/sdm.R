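#' The five suitability algorithms
#'
#' @return character vector of valid algorithm ids: binomial GLM with
#'   linear + quadratic terms (`"glm"`), a penalized-logistic
#'   presence/background analogue of maximum entropy (`"maxent_like"`),
#'   random forest (`"rf"`), a probability-calibrated support vector
#'   machine (`"svm"`), and a Gaussian-process classifier (`"gau"`).
#' @export
sdmAlgorithms <- function() c("glm", "maxent_like", "rf", "svm", "gau")

# Linear + quadratic design matrix shared by glm and maxent_like.
quadFeatures <- function(X) {
  X <- as.matrix(X)
  Q <- X^2
  colnames(Q) <- paste0(colnames(X), "_sq")
  cbind(X, Q)
}

#' Fit one suitability algorithm
#'
#' Trains a single algorithm on presence/pseudo-absence records. All
#' stochastic learners are seeded, so a fit is reproducible from its
#' inputs. Hyperparameters are fixed package defaults (no tuning):
#' `rf` uses 500 trees; `svm` a radial kernel with Platt-scaled
#' probabilities; `maxent_like` ridge-penalized logistic regression
#' (lambda = 0.01) on linear + quadratic features of presences versus
#' background; `gau` a Gaussian-process classifier with an RBF kernel whose
#' width is the median heuristic.
#'
#' @param algorithm one of [sdmAlgorithms()].
#' @param train a [LabeledPoints-class] with env values and both classes.
#' @param seed integer seed.
#' @param background optional background env matrix for `maxent_like`
#'   (e.g. uniform cells from the study mask); defaults to the
#'   pseudo-absence rows of `train`.
#' @return An [SDMFit-class].
#' @export
fitSDM <- function(algorithm, train, seed = 1, background = NULL) {
  if (!algorithm %in% sdmAlgorithms())
    stop("unknown algorithm '", algorithm, "'; valid: ",
         paste(sdmAlgorithms(), collapse = ", "), call. = FALSE)
  X <- pointEnv(train)
  if (ncol(X) == 0) stop("training points carry no env values", call. = FALSE)
  lab <- pointLabels(train)
  if (length(unique(lab)) < 2L && algorithm != "maxent_like")
    stop("training set has a single class", call. = FALSE)
  if (!any(lab == "presence"))
    stop("training set has no presences", call. = FALSE)
  y <- factor(lab, levels = c("pseudo_absence", "presence"))
  model <- withSeed(seed, switch(algorithm,
    glm = {
      df <- as.data.frame(quadFeatures(X))
      df$.y <- as.integer(y == "presence")
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
    },
    maxent_like = {
      bg <- if (is.null(background)) X[lab == "pseudo_absence", , drop = FALSE]
            else as.matrix(background)
      if (nrow(bg) == 0) stop("maxent_like needs background points", call. = FALSE)
      Xf <- quadFeatures(rbind(X[lab == "presence", , drop = FALSE], bg))
      yy <- c(rep(1L, sum(lab == "presence")), rep(0L, nrow(bg)))
      glmnet::glmnet(Xf, yy, family = "binomial", alpha = 0, lambda = 0.01)
    },
    rf = randomForest::randomForest(X, y, ntree = 500),
    svm = e1071::svm(X, y, kernel = "radial", probability = TRUE),
    gau = {
      sig <- kernlab::sigest(X, scaled = FALSE)[2]
      if (!is.finite(sig) || sig <= 0) sig <- 1
      kernlab::gausspr(X, y, type = "classification",
                       kernel = "rbfdot", kpar = list(sigma = sig))
    }))
  new("SDMFit", algorithm = algorithm, species = speciesId(train),
      model = model, predictorNames = colnames(X), fold = NA_integer_)
}

#' Predict suitability for new predictor values
#'
#' @param fit an [SDMFit-class].
#' @param X matrix/data.frame of predictor values (columns named as in
#'   `fit@predictorNames`); rows with missing values yield `NA`.
#' @return numeric suitability in \[0, 1\], one value per row of `X`.
#' @export
predictSuitability <- function(fit, X) {
  X <- as.matrix(X)[, fit@predictorNames, drop = FALSE]
  out <- rep(NA_real_, nrow(X))
  ok <- stats::complete.cases(X)
  if (!any(ok)) return(out)
  Xo <- X[ok, , drop = FALSE]
  p <- switch(fit@algorithm,
    glm = stats::predict(fit@model, newdata = as.data.frame(quadFeatures(Xo)),
                         type = "response"),
    maxent_like = drop(stats::predict(fit@model, newx = quadFeatures(Xo),
                                      type = "response")),
    rf = stats::predict(fit@model, Xo, type = "prob")[, "presence"],
    svm = attr(stats::predict(fit@model, Xo, probability = TRUE),
               "probabilities")[, "presence"],
    gau = kernlab::predict(fit@model, Xo, type = "probabilities")[, "presence"])
  out[ok] <- pmin(1, pmax(0, as.numeric(p)))
  out
}

#' Predict a suitability raster
#'
#' Applies a fitted algorithm cell-wise over a predictor stack; nodata
#' cells propagate to nodata, and predictions are clamped to \[0, 1\].
#'
#' @param fit an [SDMFit-class].
#' @param stack a [ClimateStack-class] supplying every predictor the model
#'   expects.
#' @return a suitability [RasterGrid-class].
#' @export
predictMap <- function(fit, stack) {
  missing <- setdiff(fit@predictorNames, layerNames(stack))
  if (length(missing))
    stop("stack is missing predictors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- stackValues(stack, fit@predictorNames)
  p <- predictSuitability(fit, X)
  ref <- stack@layers[[1]]
  withValues(ref, matrix(p, nrow(ref@values), ncol(ref@values)))
}

setMethod("show", "SDMFit", function(object) {
  cat(sprintf("SDMFit: %s for '%s' on %d predictors%s\n", object@algorithm,
              object@species, length(object@predictorNames),
              if (!is.na(object@fold)) sprintf(" (fold %d)", object@fold) else ""))
})

#' Fit one algorithm on every training fold
#'
#' For each fold label `f` the model is trained on all points *not* in `f`
#' (so `f` can serve as the test set). The per-algorithm suitability map is
#' the cell-wise mean of the per-fold prediction maps.
#'
#' @param algorithm one of [sdmAlgorithms()].
#' @param points a [LabeledPoints-class] with folds assigned.
#' @param seed integer seed (per-fold seeds are derived from it).
#' @param background optional background env matrix (see [fitSDM()]).
#' @return list of [SDMFit-class], one per fold, named by fold label.
#' @export
fitAlgorithmFolds <- function(algorithm, points, seed = 1, background = NULL) {
  folds <- sort(unique(pointFolds(points)))
  if (length(folds) < 2L || anyNA(folds))
    stop("points need at least 2 assigned folds", call. = FALSE)
  fits <- lapply(folds, function(f) {
    fit <- fitSDM(algorithm, points[pointFolds(points) != f],
                  seed = deriveSeed(seed, paste0(algorithm, f)),
                  background = background)
    initialize(fit, fold = as.integer(f))
  })
  stats::setNames(fits, as.character(folds))
}

#' Draw uniform background cells from a predictor stack
#'
#' Used by the presence/background (`maxent_like`) algorithm: a uniform
#' sample of non-nodata cells characterizes the available environment.
#'
#' @param stack a [ClimateStack-class].
#' @param n number of background cells (capped at the number available).
#' @param seed integer seed.
#' @return matrix of predictor values, one row per background cell.
#' @export
drawBackground <- function(stack, n = 1000, seed = 1) {
  X <- stackValues(stack)
  ok <- which(stats::complete.cases(X))
  idx <- withSeed(seed, sample(ok, min(n, length(ok))))
  X[idx, , drop = FALSE]
}
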