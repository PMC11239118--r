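#' TraitTable: a species trait table with per-cell provenance
#'
#' The central data container. `data` holds one row per species with the
#' TetrapodTraits-style columns `Species`, `Genus`, `Family`,
#' `BodyLength_mm`, `BodyMass_g` (positive, possibly NA), the binary activity
#' columns `Diu`, `Noc` and microhabitat columns `Fos`, `Ter`, `Aqu`, `Arb`,
#' `Aer` (0/1, possibly NA), plus any extra columns (e.g. `Assessed`).
#' `provenance` is a species x attribute character matrix over
#' `c("observed", "taxon_imputed", "phylo_imputed", "missing")`;
#' a cell is `"missing"` exactly when the value is NA.
#'
#' @slot data data.frame of trait values, one row per species.
#' @slot provenance character matrix (species x core attributes).
#' @export
setClass("TraitTable",
  representation(data = "data.frame", provenance = "matrix"))

setValidity("TraitTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("Species", "Genus", "Family", .CORE_ATTRS)
  if (!all(need %in% colnames(d)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(d)), collapse = ", ")))
  if (anyDuplicated(d$Species)) msg <- c(msg, "species ids must be unique")
  for (a in .CONT_ATTRS) {
    v <- d[[a]]
    if (any(!is.na(v) & v <= 0))
      msg <- c(msg, paste(a, "must be strictly positive where present"))
  }
  for (a in .BIN_ATTRS) {
    v <- d[[a]]
    if (any(!is.na(v) & !v %in% c(0, 1)))
      msg <- c(msg, paste(a, "must be 0/1 where present"))
  }
  p <- object@provenance
  if (!identical(dim(p), c(nrow(d), length(.CORE_ATTRS))))
    return("provenance must be a species x core-attribute matrix")
  if (!all(p %in% .PROV_LEVELS))
    msg <- c(msg, "unknown provenance level")
  isna <- is.na(as.matrix(d[, .CORE_ATTRS]))
  if (!identical(unname(p == "missing"), unname(isna)))
    msg <- c(msg, "provenance must be 'missing' exactly where the value is NA")
  # a species with fully observed microhabitat must use >= 1 category
  mh <- as.matrix(d[, .MICRO_ATTRS])
  full <- rowSums(is.na(mh)) == 0
  if (any(full & rowSums(mh, na.rm = TRUE) == 0))
    msg <- c(msg, "fully observed microhabitat rows must have >= 1 category")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MissingnessSpec: mechanism, rate and dependence of missing data
#'
#' Missingness operates at the level of composite attributes (`body_length`,
#' `body_mass`, `activity_time`, `microhabitat`, `threat_status`): hiding an
#' attribute hides all of its member columns. Per attribute the mechanism is
#' MCAR (no driver), MAR (driver is an always-observed covariate named in
#' `driver`) or MNAR (driver is the attribute's own true value or score).
#' The cell-level missingness probability is
#' `plogis(qlogis(rate) + coef * z(driver) + sharedGapStrength * u)`,
#' where `u` is a per-species standard-normal latent "poorly known species"
#' factor shared across attributes.
#'
#' @slot attributes character; composite attribute names.
#' @slot mechanism named character, one of MCAR/MAR/MNAR per attribute.
#' @slot rate named numeric in `[0,1]`, base missingness rate per attribute.
#' @slot coef named numeric, logistic slope on the z-scored driver.
#' @slot driver named character; covariate column for MAR attributes, NA else.
#' @slot sharedGapStrength numeric scalar in `[0,1]`.
#' @export
setClass("MissingnessSpec",
  representation(attributes = "character", mechanism = "character",
                 rate = "numeric", coef = "numeric", driver = "character",
                 sharedGapStrength = "numeric"))

setValidity("MissingnessSpec", function(object) {
  msg <- character()
  k <- length(object@attributes)
  if (!all(object@attributes %in% names(.COMPOSITE_ATTRS)))
    msg <- c(msg, paste("attributes must be among:",
                        paste(names(.COMPOSITE_ATTRS), collapse = ", ")))
  if (length(object@mechanism) != k || length(object@rate) != k ||
      length(object@coef) != k || length(object@driver) != k)
    return("per-attribute slots must match the number of attributes")
  if (!all(object@mechanism %in% c("MCAR", "MAR", "MNAR")))
    msg <- c(msg, "mechanism must be MCAR, MAR or MNAR")
  if (any(object@rate < 0 | object@rate > 1))
    msg <- c(msg, "rates must lie in [0, 1]")
  s <- object@sharedGapStrength
  if (length(s) != 1L || is.na(s) || s < 0 || s > 1)
    msg <- c(msg, "sharedGapStrength must be a scalar in [0, 1]")
  bad <- object@mechanism == "MAR" & is.na(object@driver)
  if (any(bad)) msg <- c(msg, "MAR attributes need a driver column")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SimulatedClade: one synthetic clade with complete traits
#'
#' @slot tree ultrametric rooted bifurcating `phylo`, root depth 1.
#' @slot taxonomy data.frame (Species, Genus, Family), one row per tip.
#' @slot traits complete [TraitTable-class] (no missing cells).
#' @slot assemblages binary species x cell membership matrix.
#' @slot seed integer seed used for the simulation.
#' @export
setClass("SimulatedClade",
  representation(tree = "ANY", taxonomy = "data.frame", traits = "TraitTable",
                 assemblages = "matrix", seed = "integer"))

setValidity("SimulatedClade", function(object) {
  msg <- character()
  tips <- object@tree$tip.label
  if (length(tips) != nrow(object@traits@data))
    msg <- c(msg, "tip count must equal trait-table row count")
  if (!setequal(tips, object@taxonomy$Species) ||
      anyDuplicated(object@taxonomy$Species))
    msg <- c(msg, "every tip must appear exactly once in taxonomy")
  g2f <- unique(object@taxonomy[, c("Genus", "Family")])
  if (anyDuplicated(g2f$Genus))
    msg <- c(msg, "each genus must map to exactly one family")
  if (nrow(object@assemblages) &&
      any(rowSums(object@assemblages) < 1))
    msg <- c(msg, "every species must occupy >= 1 assemblage cell")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' FilterSet: phylogenetic eigenvector filters for one tree
#'
#' Eigendecomposition of a phylogenetic covariance matrix; the leading
#' `retained` eigenvectors are the "phylogenetic filters" used as imputation
#' predictors. The full decomposition is stored; [filters()] returns the
#' retained columns.
#'
#' @slot values numeric, all eigenvalues, non-increasing, non-negative.
#' @slot vectors species x p matrix of unit-norm eigenvectors (rows keyed by
#'   species id; sign fixed so each column's largest-magnitude entry is
#'   positive).
#' @slot retained integer, number of leading filters retained.
#' @slot treeId character identifier.
#' @export
setClass("FilterSet",
  representation(values = "numeric", vectors = "matrix", retained = "integer",
                 treeId = "character"))

setValidity("FilterSet", function(object) {
  msg <- character()
  v <- object@values
  if (is.unsorted(rev(v), strictly = FALSE) && any(diff(v) > 1e-8))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(v < -1e-8)) msg <- c(msg, "eigenvalues must be non-negative")
  k <- object@retained
  if (length(k) != 1L || k < 1L || k > ncol(object@vectors))
    msg <- c(msg, "retained must be in 1..ncol(vectors)")
  if (is.null(rownames(object@vectors)))
    msg <- c(msg, "eigenvector rows must be keyed by species id")
  ct <- crossprod(object@vectors)
  if (max(abs(ct - diag(ncol(ct)))) > 1e-8)
    msg <- c(msg, "eigenvector columns must be orthonormal within 1e-8")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' TuningSpec: search ranges for boosted-tree hyperparameters
#'
#' Defaults follow the two-stage random search over learning rate 0.01-0.3,
#' tree depth 3-12, subsample 0.7-1, minimum child weight 0.5-1.5 and 30-1000
#' boosting rounds; the top `topFraction` of stage-1 draws defines the
#' stage-2 sampling box. Desk-scale default is 100 draws per stage
#' (full-scale runs use 1000).
#'
#' @slot etaRange,maxDepthRange,subsampleRange,minChildWeightRange,nroundsRange
#'   numeric length-2 ranges.
#' @slot nDrawsStage1,nDrawsStage2 integer draw counts.
#' @slot topFraction numeric in (0, 1].
#' @export
setClass("TuningSpec",
  representation(etaRange = "numeric", maxDepthRange = "numeric",
                 subsampleRange = "numeric", minChildWeightRange = "numeric",
                 nroundsRange = "numeric", nDrawsStage1 = "integer",
                 nDrawsStage2 = "integer", topFraction = "numeric"))

setValidity("TuningSpec", function(object) {
  msg <- character()
  for (s in c("etaRange", "maxDepthRange", "subsampleRange",
              "minChildWeightRange", "nroundsRange")) {
    r <- slot(object, s)
    if (length(r) != 2L || r[1] > r[2])
      msg <- c(msg, paste(s, "must be an ordered length-2 range"))
  }
  if (object@nDrawsStage1 < 1L || object@nDrawsStage2 < 1L)
    msg <- c(msg, "draw counts must be >= 1")
  tf <- object@topFraction
  if (length(tf) != 1L || tf <= 0 || tf > 1)
    msg <- c(msg, "topFraction must lie in (0, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ImputationConfig: bookkeeping parameters of the multiple-imputation engine
#'
#' Full-scale defaults are 10 donors, 10 imputations and 10 folds (yielding
#' `10 x 10 x nTrees` draws per fully missing cell); desk-scale analyses use
#' smaller values.
#'
#' @slot kDonors integer, donors per predictive-mean-matching draw.
#' @slot mImputations integer, imputations per (tree, fold) model.
#' @slot nFolds integer >= 2, cross-validation folds.
#' @slot nTrees integer, number of filter sets used (NA = all supplied).
#' @slot seed integer master seed.
#' @export
setClass("ImputationConfig",
  representation(kDonors = "integer", mImputations = "integer",
                 nFolds = "integer", nTrees = "integer", seed = "integer"))

setValidity("ImputationConfig", function(object) {
  msg <- character()
  if (object@kDonors < 1L) msg <- c(msg, "kDonors must be >= 1")
  if (object@mImputations < 1L) msg <- c(msg, "mImputations must be >= 1")
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MultipleImputationResult: all draws and point summaries per missing cell
#'
#' @slot draws data.frame with columns `Species`, `attribute`, `tree`,
#'   `fold`, `m`, `value` (one row per imputed draw; draws are observed
#'   donor values).
#' @slot summary data.frame with one row per missing cell: `Species`,
#'   `attribute`, `n_draws`, `estimate` (median of draws for continuous,
#'   mean for binary) and `majority` (binary majority call, NA for
#'   continuous).
#' @slot objectives named character, "regression" or "binary" per attribute.
#' @slot config the [ImputationConfig-class] used.
#' @export
setClass("MultipleImputationResult",
  representation(draws = "data.frame", summary = "data.frame",
                 objectives = "character", config = "ImputationConfig"))

#' CScoreReport: shared-missingness analysis results
#'
#' @slot pairs data.frame, one row per taxon x attribute pair: observed C,
#'   null mean/sd, SES, two-tailed p, pattern class.
#' @slot taxa data.frame, per taxon: median SES across all pairs and across
#'   pairs involving the focal attribute.
#' @slot alpha numeric significance threshold used for classification.
#' @export
setClass("CScoreReport",
  representation(pairs = "data.frame", taxa = "data.frame", alpha = "numeric"))
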