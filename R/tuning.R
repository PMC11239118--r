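#' @rdname TuningSpec-class
#' @param etaRange,maxDepthRange,subsampleRange,minChildWeightRange,nroundsRange
#'   search ranges (length-2).
#' @param nDrawsStage1,nDrawsStage2 random draws per stage.
#' @param topFraction fraction of stage-1 draws defining the stage-2 box.
#' @export
tuningSpec <- function(etaRange = c(0.01, 0.3), maxDepthRange = c(3, 12),
                       subsampleRange = c(0.7, 1),
                       minChildWeightRange = c(0.5, 1.5),
                       nroundsRange = c(30, 1000),
                       nDrawsStage1 = 100, nDrawsStage2 = 100,
                       topFraction = 0.05) {
  new("TuningSpec", etaRange = etaRange, maxDepthRange = maxDepthRange,
      subsampleRange = subsampleRange,
      minChildWeightRange = minChildWeightRange,
      nroundsRange = nroundsRange,
      nDrawsStage1 = as.integer(nDrawsStage1),
      nDrawsStage2 = as.integer(nDrawsStage2), topFraction = topFraction)
}

# One xgboost fit + prediction. nthread = 1 and an explicit seed keep runs
# reproducible.
.fitPredict <- function(xTrain, yTrain, xPredList, objective, params,
                        xgbSeed) {
  obj <- if (objective == "regression") "reg:squarederror"
         else "binary:logistic"
  # a constant training response admits no model: predict the constant
  # (for binary, the degenerate class probability)
  if (length(unique(yTrain)) < 2) {
    return(lapply(xPredList, function(x) rep(yTrain[1], nrow(x))))
  }
  booster <- xgboost::xgb.train(
    params = list(objective = obj, eta = params$eta,
                  max_depth = as.integer(params$max_depth),
                  subsample = params$subsample,
                  min_child_weight = params$min_child_weight,
                  nthread = 1, seed = as.integer(xgbSeed)),
    data = xgboost::xgb.DMatrix(xTrain, label = yTrain),
    nrounds = as.integer(params$nrounds), verbose = 0)
  lapply(xPredList, function(x) {
    if (!nrow(x)) return(numeric())
    predict(booster, xgboost::xgb.DMatrix(x))
  })
}

.drawParams <- function(n, ranges) {
  data.frame(
    eta = runif(n, ranges$eta[1], ranges$eta[2]),
    max_depth = floor(runif(n, ranges$max_depth[1],
                            ranges$max_depth[2] + 1)),
    subsample = runif(n, ranges$subsample[1], ranges$subsample[2]),
    min_child_weight = runif(n, ranges$min_child_weight[1],
                             ranges$min_child_weight[2]),
    nrounds = floor(runif(n, ranges$nrounds[1], ranges$nrounds[2] + 1)))
}

#' Two-stage random hyperparameter search for the boosted-tree learner
#'
#' Stage 1 draws `nDrawsStage1` parameter sets uniformly from the spec
#' ranges and scores each by cross-validated NRMSE (regression) or
#' misclassification rate (binary). Stage 2 redraws `nDrawsStage2` sets
#' uniformly from the axis-aligned bounding box of the top `topFraction`
#' of stage-1 draws. The overall best set is returned.
#'
#' @param x numeric predictor matrix (complete rows).
#' @param y response vector (numeric, or 0/1 for binary).
#' @param objective "regression" or "binary".
#' @param spec a [TuningSpec-class].
#' @param nFolds cross-validation folds used for scoring (default 5).
#' @param seed integer seed.
#' @return list with `best` (named parameter list incl. `score`) and
#'   `trace` (data.frame of all draws with stage and score).
#' @export
tuneHyperparameters <- function(x, y, objective = c("regression", "binary"),
                                spec = tuningSpec(), nFolds = 5, seed = 1) {
  objective <- match.arg(objective)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2 * nFolds) stop("need at least 2 * nFolds complete rows")
  if (length(unique(y)) < 2) stop("degenerate (constant) response")
  validObject(spec)
  .withSeed(seed, function() {
    folds <- sample(rep(seq_len(nFolds), length.out = n))
    scoreOne <- function(p) {
      preds <- numeric(n)
      for (f in seq_len(nFolds)) {
        tr <- folds != f
        preds[!tr] <- .fitPredict(x[tr, , drop = FALSE], y[tr],
                                  list(x[!tr, , drop = FALSE]), objective, p,
                                  xgbSeed = sample.int(1e9, 1))[[1]]
      }
      if (objective == "regression") {
        nrmse(preds, y)
      } else {
        mean((preds >= 0.5) != y)
      }
    }
    ranges1 <- list(eta = spec@etaRange, max_depth = spec@maxDepthRange,
                    subsample = spec@subsampleRange,
                    min_child_weight = spec@minChildWeightRange,
                    nrounds = spec@nroundsRange)
    d1 <- .drawParams(spec@nDrawsStage1, ranges1)
    s1 <- vapply(seq_len(nrow(d1)), function(i) scoreOne(d1[i, ]), 0)
    top <- order(s1)[seq_len(max(1L, ceiling(spec@topFraction * nrow(d1))))]
    ranges2 <- lapply(names(ranges1), function(nm) range(d1[top, nm]))
    names(ranges2) <- names(ranges1)
    d2 <- .drawParams(spec@nDrawsStage2, ranges2)
    s2 <- vapply(seq_len(nrow(d2)), function(i) scoreOne(d2[i, ]), 0)
    trace <- rbind(cbind(stage = 1L, d1, score = s1),
                   cbind(stage = 2L, d2, score = s2))
    best <- trace[which.min(trace$score), ]
    list(best = list(eta = best$eta, max_depth = as.integer(best$max_depth),
                     subsample = best$subsample,
                     min_child_weight = best$min_child_weight,
                     nrounds = as.integer(best$nrounds),
                     score = best$score),
         trace = trace)
  })
}
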