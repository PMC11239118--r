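#' @rdname ImputationConfig-class
#' @param kDonors,mImputations,nFolds,nTrees,seed see slot documentation.
#' @export
imputationConfig <- function(kDonors = 10, mImputations = 10, nFolds = 10,
                             nTrees = NA, seed = 1) {
  new("ImputationConfig", kDonors = as.integer(kDonors),
      mImputations = as.integer(mImputations), nFolds = as.integer(nFolds),
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' One predictive-mean-matching draw
#'
#' The `k` observed entries whose predictions are closest to the missing
#' entry's prediction form the donor pool (ties among equidistant candidates
#' broken by the current RNG stream); one donor is selected uniformly and
#' its observed value returned. PMM therefore always returns an observed
#' value.
#'
#' @param predMissing prediction for the missing entry (scalar).
#' @param predObserved predictions for the observed entries.
#' @param yObserved observed values matching `predObserved`.
#' @param k donor pool size, `1 <= k <= length(predObserved)`.
#' @return one element of `yObserved`.
#' @export
#' @examples
#' set.seed(1)
#' pmmDraw(0.52, c(0.1, 0.5, 0.9), c(10, 20, 30), k = 1) # 20
pmmDraw <- function(predMissing, predObserved, yObserved, k) {
  if (!length(predObserved)) stop("observed pool is empty")
  if (k < 1 || k > length(predObserved))
    stop("'k' must be between 1 and the observed pool size")
  stopifnot(length(yObserved) == length(predObserved))
  d <- abs(predObserved - predMissing)
  donors <- order(d, runif(length(d)))[seq_len(k)]
  yObserved[donors[sample.int(k, 1L)]]
}

# Vectorised PMM: m draws for each of a vector of missing-entry predictions.
.pmmDraws <- function(predMissing, predObserved, yObserved, k, m) {
  nMiss <- length(predMissing)
  out <- matrix(NA_real_, nMiss, m)
  for (i in seq_len(nMiss)) {
    d <- abs(predObserved - predMissing[i])
    donors <- order(d, runif(length(d)))[seq_len(k)]
    out[i, ] <- yObserved[donors[sample.int(k, m, replace = TRUE)]]
  }
  out
}

# Predictor matrix for one target attribute: retained filters of one tree
# plus all other core attributes (continuous log10-transformed to reduce
# skewness). May contain NAs; fill per training fold with .fillColumns.
.predictorMatrix <- function(table, filterSet, target) {
  ids <- speciesIds(table)
  Fm <- filters(filterSet)
  if (!all(ids %in% rownames(Fm)))
    stop("every species in the table must be present in the FilterSet")
  Fm <- Fm[ids, , drop = FALSE]
  d <- traitData(table)
  others <- setdiff(.CORE_ATTRS, target)
  X <- sapply(others, function(a) {
    v <- as.numeric(d[[a]])
    if (a %in% .CONT_ATTRS) log10(v) else v
  })
  X <- matrix(X, nrow = length(ids), dimnames = list(ids, others))
  cbind(Fm, X)
}

# Initialise NA predictor cells by sampling from the training rows'
# observed values of that column (the chained-imputation starting fill):
# filled binary predictors stay in {0,1} support and continuous ones stay
# in range, so tree splits see no out-of-support constants. Draws come
# from the run's seeded stream.
.fillColumns <- function(X, trainIdx) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (!any(nas)) next
    tv <- X[trainIdx, j]
    tv <- tv[!is.na(tv)]
    X[nas, j] <- if (!length(tv)) 0 else
      tv[sample.int(length(tv), sum(nas), replace = TRUE)]
  }
  X
}

.defaultBoostParams <- function() {
  list(eta = 0.1, max_depth = 6L, subsample = 0.9, min_child_weight = 1,
       nrounds = 100L)
}

#' Phylogeny-informed boosted-tree multiple imputation with PMM
#'
#' For each supplied tree's [FilterSet-class], each cross-validation fold
#' and each target attribute, a boosted-tree model is trained on the
#' observed rows outside the fold (predictors: retained phylogenetic
#' filters plus all other attributes, continuous ones log10-transformed);
#' every missing cell then receives `mImputations` predictive-mean-matching
#' draws, so a cell missing throughout accumulates
#' `mImputations x nFolds x nTrees` draws. Binary attributes are modelled
#' with the binary objective and matched on predicted probability; the
#' donor's observed 0/1 is drawn. Observed cells are never altered.
#'
#' @param table a [TraitTable-class].
#' @param filterSets a [FilterSet-class] or list of them (one per tree).
#' @param config an [ImputationConfig-class].
#' @param tuned optional named list of per-attribute parameter lists (as
#'   returned in `tuneHyperparameters()$best`); defaults used otherwise.
#' @param attributes attributes to impute; default: all core attributes
#'   with missing cells. Attributes with fewer than `max(20, 2 * kDonors)`
#'   observed rows are skipped with a warning.
#' @return A [MultipleImputationResult-class].
#' @export
#' @examples
#' cl <- simulateClade(nTips = 80, seed = 3)
#' mis <- imposeMissingness(cladeTraits(cl),
#'                          missingnessSpec("body_length", rate = 0.2),
#'                          seed = 4)
#' fs <- deriveFilters(treeToCovariance(cladeTree(cl)))
#' res <- multiplyImpute(mis$table, fs,
#'                       imputationConfig(kDonors = 5, mImputations = 2,
#'                                        nFolds = 2, seed = 9))
#' head(imputationSummary(res))
multiplyImpute <- function(table, filterSets, config = imputationConfig(),
                           tuned = NULL, attributes = NULL) {
  stopifnot(is(table, "TraitTable"))
  if (is(filterSets, "FilterSet")) filterSets <- list(filterSets)
  validObject(config)
  nTrees <- if (is.na(config@nTrees)) length(filterSets) else config@nTrees
  if (nTrees > length(filterSets))
    stop("config requests more trees than FilterSets supplied")
  filterSets <- filterSets[seq_len(nTrees)]
  d <- traitData(table)
  if (is.null(attributes))
    attributes <- .CORE_ATTRS[colSums(is.na(d[, .CORE_ATTRS])) > 0]
  objectives <- setNames(as.character(ifelse(attributes %in% .CONT_ATTRS,
                                             "regression", "binary")),
                         attributes)
  drawList <- list()
  .withSeed(config@seed, function() {
    for (a in attributes) {
      missIdx <- which(is.na(d[[a]]))
      if (!length(missIdx)) next
      obsIdx <- which(!is.na(d[[a]]))
      floorN <- max(20L, 2L * config@kDonors)
      if (length(obsIdx) < floorN) {
        warning("attribute '", a, "' has fewer than ", floorN,
                " observed rows: skipped")
        next
      }
      yRaw <- d[[a]][obsIdx]
      yModel <- if (objectives[a] == "regression") log10(yRaw) else yRaw
      params <- if (!is.null(tuned[[a]])) tuned[[a]] else
        .defaultBoostParams()
      folds <- sample(rep(seq_len(config@nFolds), length.out =
                            length(obsIdx)))
      for (t in seq_along(filterSets)) {
        X <- .predictorMatrix(table, filterSets[[t]], a)
        for (f in seq_len(config@nFolds)) {
          trRows <- obsIdx[folds != f]
          Xf <- .fillColumns(X, trRows)
          pr <- .fitPredict(Xf[trRows, , drop = FALSE],
                            yModel[folds != f],
                            list(Xf[trRows, , drop = FALSE],
                                 Xf[missIdx, , drop = FALSE]),
                            objectives[a], params,
                            xgbSeed = sample.int(1e9, 1))
          draws <- .pmmDraws(pr[[2]], pr[[1]], yRaw[folds != f],
                             config@kDonors, config@mImputations)
          drawList[[length(drawList) + 1L]] <<- data.frame(
            Species = rep(d$Species[missIdx], config@mImputations),
            attribute = a,
            tree = filterSets[[t]]@treeId,
            fold = f,
            m = rep(seq_len(config@mImputations), each = length(missIdx)),
            value = as.vector(draws),
            stringsAsFactors = FALSE)
        }
      }
    }
    NULL
  })
  draws <- if (length(drawList)) do.call(rbind, drawList) else
    data.frame(Species = character(), attribute = character(),
               tree = character(), fold = integer(), m = integer(),
               value = numeric(), stringsAsFactors = FALSE)
  res <- new("MultipleImputationResult", draws = draws,
             summary = data.frame(), objectives = objectives,
             config = config)
  res@summary <- summarizeImputations(res)
  res
}

#' Point summaries of the imputation draws
#'
#' Continuous cells are summarised by the median of their draws; binary
#' cells by the mean (in `[0,1]`) plus a majority call (`mean >= 0.5`).
#' A pure function of the stored draws: re-running it reproduces the
#' stored summary.
#'
#' @param result a [MultipleImputationResult-class].
#' @return data.frame: `Species`, `attribute`, `n_draws`, `estimate`,
#'   `majority`.
#' @export
summarizeImputations <- function(result) {
  draws <- result@draws
  if (!nrow(draws))
    return(data.frame(Species = character(), attribute = character(),
                      n_draws = integer(), estimate = numeric(),
                      majority = numeric(), stringsAsFactors = FALSE))
  key <- paste(draws$Species, draws$attribute, sep = "\r")
  split_idx <- split(seq_len(nrow(draws)), key)
  rows <- lapply(split_idx, function(i) {
    a <- draws$attribute[i[1]]
    v <- draws$value[i]
    if (result@objectives[a] == "regression") {
      data.frame(Species = draws$Species[i[1]], attribute = a,
                 n_draws = length(v), estimate = median(v),
                 majority = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(Species = draws$Species[i[1]], attribute = a,
                 n_draws = length(v), estimate = mean(v),
                 majority = as.numeric(mean(v) >= 0.5),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$attribute, out$Species), , drop = FALSE]
}

#' @rdname MultipleImputationResult-class
#' @param x a `MultipleImputationResult`.
#' @export
setMethod("imputationDraws", "MultipleImputationResult",
          function(x) x@draws)

#' @rdname MultipleImputationResult-class
#' @export
imputationSummary <- function(x) x@summary

setMethod("show", "MultipleImputationResult", function(object) {
  cat("MultipleImputationResult:", nrow(object@summary), "cells,",
      nrow(object@draws), "draws",
      sprintf("(k=%d, m=%d, folds=%d)\n", object@config@kDonors,
              object@config@mImputations, object@config@nFolds))
  invisible(NULL)
})

#' Fill missing cells of a table with the imputation point summaries
#'
#' Continuous cells receive the median of their draws; binary cells the
#' majority call. Filled cells get provenance `"phylo_imputed"`; observed
#' cells are untouched. Because the schema guarantees every species at
#' least one microhabitat and one activity state, a species whose
#' majority calls would leave such a group all zero has its
#' highest-mean-draw imputed category switched on.
#'
#' @param table the [TraitTable-class] that was imputed.
#' @param result the matching [MultipleImputationResult-class].
#' @return A gap-filled [TraitTable-class].
#' @export
applyImputations <- function(table, result) {
  s <- imputationSummary(result)
  d <- traitData(table)
  p <- provenance(table)
  for (a in unique(s$attribute)) {
    rows <- s[s$attribute == a, ]
    vals <- if (result@objectives[a] == "regression") rows$estimate
            else rows$majority
    i <- match(rows$Species, d$Species)
    fill <- is.na(d[[a]][i])
    d[i[fill], a] <- vals[fill]
    p[i[fill], a] <- "phylo_imputed"
  }
  # repair all-zero category groups among imputed cells
  for (grp in list(.MICRO_ATTRS, .ACT_ATTRS)) {
    bad <- which(rowSums(is.na(d[, grp])) == 0 & rowSums(d[, grp]) == 0)
    for (i in bad) {
      imp <- grp[p[i, grp] == "phylo_imputed"]
      if (!length(imp)) next
      est <- vapply(imp, function(a) {
        r <- s[s$attribute == a & s$Species == d$Species[i], ]
        if (nrow(r)) r$estimate[1] else -Inf
      }, 0)
      d[i, imp[which.max(est)]] <- 1L
    }
  }
  new("TraitTable", data = d, provenance = p)
}

#' Write the imputation draw store as long-format CSV
#'
#' @param result a [MultipleImputationResult-class].
#' @param path output CSV (columns Species, attribute, tree, fold, m,
#'   value).
#' @export
writeImputationDraws <- function(result, path) {
  write.csv(result@draws, path, row.names = FALSE)
  invisible(path)
}
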