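#' Imputation reliability metrics
#'
#' The four metrics used to validate imputations against held-out observed
#' values: Pearson correlation, regression slope of imputed on observed
#' (slope > 1 indicates overestimation), normalised root mean square error,
#' and classification accuracy for binary attributes.
#'
#' `nrmse()` divides the RMSE by the population standard deviation of the
#' observed values (same denominator as the squared-error mean), so
#' imputing every entry with the observed mean scores exactly 1 -- the
#' no-skill baseline. Range normalisation is available via
#' `normalization = "range"`.
#'
#' @param imputed,observed numeric vectors of equal length.
#' @param normalization for `nrmse()`: "sd" (default) or "range".
#' @return a single numeric value; degenerate inputs (constant observed
#'   vector where variance is required) return NA with a warning.
#' @name validationMetrics
NULL

#' @rdname validationMetrics
#' @export
#' @examples
#' pearsonR(c(1.1, 1.9, 3.2, 3.8), c(1, 2, 3, 4))
pearsonR <- function(imputed, observed) {
  stopifnot(length(imputed) == length(observed))
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (sd(imputed) == 0 || sd(observed) == 0) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  cor(imputed, observed)
}

#' @rdname validationMetrics
#' @export
regressionSlope <- function(imputed, observed) {
  stopifnot(length(imputed) == length(observed))
  if (var(observed) == 0) {
    warning("zero variance in observed: slope undefined")
    return(NA_real_)
  }
  cov(imputed, observed) / var(observed)
}

#' @rdname validationMetrics
#' @export
nrmse <- function(imputed, observed, normalization = c("sd", "range")) {
  normalization <- match.arg(normalization)
  stopifnot(length(imputed) == length(observed))
  if (length(observed) < 2) stop("need at least 2 pairs")
  rmse <- sqrt(mean((imputed - observed)^2))
  den <- if (normalization == "sd")
    sqrt(mean((observed - mean(observed))^2))
  else diff(range(observed))
  if (den == 0) {
    warning("zero spread in observed: nrmse undefined")
    return(NA_real_)
  }
  rmse / den
}

#' @rdname validationMetrics
#' @export
binaryAccuracy <- function(imputed, observed) {
  if (!length(observed)) stop("empty input")
  stopifnot(length(imputed) == length(observed),
            all(imputed %in% c(0, 1)), all(observed %in% c(0, 1)))
  mean(imputed == observed)
}

#' @importFrom stats cov
NULL

#' Cross-validated reliability of the imputation engine
#'
#' The complete-case subset is partitioned into `nFolds` folds. For each
#' fold and each target attribute, the fold's values for that attribute are
#' hidden, models are trained on the remaining complete rows (per supplied
#' tree), and the hidden cells are imputed with PMM; point estimates
#' (median of draws for continuous, majority call for binary) are scored
#' against the held-back truth. Continuous metrics are computed on the
#' log10 scale.
#'
#' @param table a [TraitTable-class].
#' @param filterSets a [FilterSet-class] or list of them.
#' @param config an [ImputationConfig-class].
#' @param tuned optional per-attribute parameter lists.
#' @param attributes attributes to validate (default: all core attributes).
#' @return list with `report` (data.frame: attribute, fold -- `"pooled"`
#'   rows included --, metric, value, n_test) and `predictions` (data.frame
#'   of per-cell point predictions and truths; the report is a pure
#'   function of it).
#' @export
crossValidate <- function(table, filterSets, config = imputationConfig(),
                          tuned = NULL, attributes = .CORE_ATTRS) {
  stopifnot(is(table, "TraitTable"))
  if (is(filterSets, "FilterSet")) filterSets <- list(filterSets)
  validObject(config)
  d <- traitData(table)
  complete <- which(complete.cases(d[, attributes, drop = FALSE]))
  minRows <- 2L * config@nFolds
  if (length(complete) < minRows)
    stop("need at least ", minRows, " complete-case rows, have ",
         length(complete))
  objectives <- setNames(as.character(ifelse(attributes %in% .CONT_ATTRS,
                                             "regression", "binary")),
                         attributes)
  predRows <- list()
  .withSeed(config@seed, function() {
    folds <- sample(rep(seq_len(config@nFolds),
                        length.out = length(complete)))
    for (a in attributes) {
      params <- if (!is.null(tuned[[a]])) tuned[[a]] else
        .defaultBoostParams()
      yRawAll <- d[[a]][complete]
      for (f in seq_len(config@nFolds)) {
        trRows <- complete[folds != f]
        teRows <- complete[folds == f]
        yRaw <- d[[a]][trRows]
        yModel <- if (objectives[a] == "regression") log10(yRaw) else yRaw
        drawMat <- NULL
        for (t in seq_along(filterSets)) {
          X <- .predictorMatrix(table, filterSets[[t]], a)
          Xf <- .fillColumns(X, trRows)
          pr <- .fitPredict(Xf[trRows, , drop = FALSE], yModel,
                            list(Xf[trRows, , drop = FALSE],
                                 Xf[teRows, , drop = FALSE]),
                            objectives[a], params,
                            xgbSeed = sample.int(1e9, 1))
          dm <- .pmmDraws(pr[[2]], pr[[1]], yRaw, config@kDonors,
                          config@mImputations)
          drawMat <- if (is.null(drawMat)) dm else cbind(drawMat, dm)
        }
        pointEst <- if (objectives[a] == "regression")
          apply(drawMat, 1, median)
        else as.numeric(rowMeans(drawMat) >= 0.5)
        predRows[[length(predRows) + 1L]] <<- data.frame(
          Species = d$Species[teRows], attribute = a, fold = f,
          truth = d[[a]][teRows], predicted = pointEst,
          stringsAsFactors = FALSE)
      }
    }
    NULL
  })
  predictions <- do.call(rbind, predRows)
  report <- validationReport(predictions, objectives)
  list(report = report, predictions = predictions)
}

#' Recompute a validation report from stored predictions
#'
#' @param predictions data.frame as produced by [crossValidate()].
#' @param objectives named character, "regression"/"binary" per attribute.
#' @return tidy data.frame: attribute, fold, metric, value, n_test.
#' @export
validationReport <- function(predictions, objectives) {
  rows <- list()
  addMetrics <- function(a, foldLabel, truth, pred) {
    if (objectives[a] == "regression") {
      lt <- log10(truth); lp <- log10(pred)
      vals <- c(pearson_r = suppressWarnings(pearsonR(lp, lt)),
                slope = suppressWarnings(regressionSlope(lp, lt)),
                nrmse = suppressWarnings(nrmse(lp, lt)))
    } else {
      vals <- c(accuracy = binaryAccuracy(pred, truth))
    }
    data.frame(attribute = a, fold = foldLabel, metric = names(vals),
               value = unname(vals), n_test = length(truth),
               stringsAsFactors = FALSE)
  }
  for (a in unique(predictions$attribute)) {
    pa <- predictions[predictions$attribute == a, ]
    for (f in sort(unique(pa$fold))) {
      pf <- pa[pa$fold == f, ]
      rows[[length(rows) + 1L]] <-
        addMetrics(a, as.character(f), pf$truth, pf$predicted)
    }
    rows[[length(rows) + 1L]] <- addMetrics(a, "pooled", pa$truth,
                                            pa$predicted)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
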