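#' Verticality and nocturnality scores
#'
#' Verticality maps microhabitat use onto `[0,1]`: the mean of the levels
#' of the categories a species uses, with fossorial = 0, terrestrial = 0.5,
#' aquatic = 0.5, arboreal = 1, aerial = 1. This mean-of-levels rule
#' reproduces the canonical anchors (strictly fossorial 0, fossorial +
#' terrestrial 0.25, terrestrial or aquatic 0.5, terrestrial + arboreal
#' 0.75, strictly arboreal or aerial 1) and defines every other
#' combination. Nocturnality is the analogous mean over diurnal = 0,
#' nocturnal = 1 (cathemeral/crepuscular species carry both and score 0.5).
#'
#' Inputs are vectorised; rows where every category is NA return NA, and an
#' explicit all-zero row is an error (the schema guarantees at least one
#' category per species).
#'
#' @param fos,ter,aqu,arb,aer binary (0/1) microhabitat indicators.
#' @param diu,noc binary activity indicators.
#' @return numeric score(s) in `[0,1]`.
#' @export
#' @examples
#' verticalityScore(1, 1, 0, 0, 0) # fossorial + terrestrial: 0.25
#' nocturnalityScore(1, 1)         # cathemeral: 0.5
verticalityScore <- function(fos, ter, aqu, arb, aer) {
  m <- cbind(fos, ter, aqu, arb, aer)
  .scoreRows(m, c(0, 0.5, 0.5, 1, 1))
}

#' @rdname verticalityScore
#' @export
nocturnalityScore <- function(diu, noc) {
  m <- cbind(diu, noc)
  .scoreRows(m, c(0, 1))
}

.scoreRows <- function(m, levels) {
  if (any(!is.na(m) & !m %in% c(0, 1))) stop("categories must be 0/1")
  out <- rep(NA_real_, nrow(m))
  allNA <- rowSums(!is.na(m)) == 0
  nSet <- rowSums(m == 1, na.rm = TRUE)
  if (any(!allNA & nSet == 0))
    stop("at least one category must be set for scored species")
  lv <- matrix(levels, nrow(m), ncol(m), byrow = TRUE)
  sums <- rowSums(lv * (m == 1), na.rm = TRUE)
  out[!allNA] <- sums[!allNA] / nSet[!allNA]
  out
}

#' Geometric mean
#'
#' `10^(mean of log10 values)`; used for per-taxon continuous attribute
#' properties because of its lower sensitivity to outliers.
#'
#' @param values strictly positive numerics.
#' @return positive scalar.
#' @export
#' @examples
#' geometricMean(c(10, 1000)) # 100
geometricMean <- function(values) {
  if (!length(values)) stop("empty input")
  if (any(is.na(values)) || any(values <= 0))
    stop("values must be strictly positive")
  10^mean(log10(values))
}

#' Attribute property of a set of species
#'
#' Continuous attributes are summarised by the geometric mean of the raw
#' values; binary attribute groups by the arithmetic mean of per-species
#' verticality or nocturnality scores.
#'
#' @param values raw values (`kind = "continuous"`) or per-species scores
#'   (`kind = "score"`).
#' @param kind "continuous" or "score".
#' @return scalar property.
#' @export
attributeProperty <- function(values, kind = c("continuous", "score")) {
  kind <- match.arg(kind)
  if (!length(values)) stop("empty input")
  if (kind == "continuous") geometricMean(values) else mean(values)
}

#' Relative change in an attribute property after gap filling
#'
#' The primary convention is the printed formula
#' `1 - (property_comb / property_obs)`, which is negative when gap filling
#' increases the property. Because the verbal reading ("positive values
#' indicate a proportional increase") carries the opposite sign, the
#' negated convention `property_comb / property_obs - 1` is reported
#' alongside it in [changeReport()]; the two are exact negations.
#'
#' @param propObs property from observed data only (non-zero).
#' @param propComb property from observed + imputed data.
#' @return `1 - propComb / propObs`.
#' @export
#' @examples
#' relativeChange(100, 110) # -0.1
relativeChange <- function(propObs, propComb) {
  if (any(propObs == 0)) {
    warning("zero observed property: relative change undefined")
    return(ifelse(propObs == 0, NA_real_, 1 - propComb / propObs))
  }
  1 - propComb / propObs
}

# Per-species scores and availability under a mode: "obs" restricts to
# cells whose provenance is observed; "comb" uses all non-NA cells.
.speciesValues <- function(table, attribute, mode) {
  d <- traitData(table)
  p <- provenance(table)
  if (attribute %in% .CONT_ATTRS) {
    v <- d[[attribute]]
    use <- if (mode == "obs") p[, attribute] == "observed" else !is.na(v)
    list(values = ifelse(use, v, NA), kind = "continuous",
         observed = p[, attribute] == "observed")
  } else if (attribute == "Nocturnality") {
    cols <- .ACT_ATTRS
    haveAll <- rowSums(is.na(d[, cols])) == 0
    use <- if (mode == "obs")
      rowSums(matrix(p[, cols] == "observed", nrow(d))) == length(cols)
    else haveAll
    v <- rep(NA_real_, nrow(d))
    v[use] <- nocturnalityScore(d$Diu[use], d$Noc[use])
    list(values = v, kind = "score",
         observed = rowSums(matrix(p[, cols] == "observed",
                                   nrow(d))) == length(cols))
  } else if (attribute == "Verticality") {
    cols <- .MICRO_ATTRS
    haveAll <- rowSums(is.na(d[, cols])) == 0
    use <- if (mode == "obs")
      rowSums(matrix(p[, cols] == "observed", nrow(d))) == length(cols)
    else haveAll
    v <- rep(NA_real_, nrow(d))
    v[use] <- verticalityScore(d$Fos[use], d$Ter[use], d$Aqu[use],
                               d$Arb[use], d$Aer[use])
    list(values = v, kind = "score",
         observed = rowSums(matrix(p[, cols] == "observed",
                                   nrow(d))) == length(cols))
  } else stop("unknown attribute: ", attribute)
}

# Level-weighted score for fractional category values in [0,1]: reduces to
# the mean-of-levels rule on binary input and lets the probability mass of
# multiple imputations enter the score instead of a hard majority call.
.weightedScore <- function(m, levels) {
  w <- pmax(m, 0)
  tot <- rowSums(w, na.rm = TRUE)
  out <- rowSums(w * matrix(levels, nrow(m), ncol(m), byrow = TRUE),
                 na.rm = TRUE) / tot
  out[tot == 0 | rowSums(!is.na(m)) == 0] <- NA_real_
  out
}

# Fractional category matrix: observed/taxon-imputed cells keep their 0/1
# value; phylo-imputed cells take the mean of their draws from `result`.
.fractionalCategories <- function(filled, cols, result) {
  d <- traitData(filled)
  p <- provenance(filled)
  m <- as.matrix(d[, cols])
  s <- imputationSummary(result)
  for (a in intersect(cols, unique(s$attribute))) {
    rows <- s[s$attribute == a, ]
    i <- match(rows$Species, d$Species)
    imp <- p[i, a] == "phylo_imputed"
    m[i[imp], a] <- rows$estimate[imp]
  }
  m
}

#' Per-taxon change in attribute properties after gap filling
#'
#' For each taxon (genus or family) and attribute, computes the attribute
#' property from observed data only and from the combined observed +
#' imputed data, with the relative change in both sign conventions.
#'
#' With `binaryScores = "expected"` (the default when `result` is given),
#' scores of imputed species are computed from the fractional mean of
#' their imputation draws via the level-weighted score, so the full
#' probability mass of the multiple imputations enters the taxon property;
#' `"majority"` instead uses the majority-called 0/1 values stored in the
#' filled table.
#'
#' @param filled the gap-filled [TraitTable-class] (e.g. from
#'   [applyImputations()]); provenance distinguishes observed from imputed
#'   cells.
#' @param by `"Genus"` or `"Family"` (or any grouping column / vector).
#' @param attributes property attributes: continuous column names and/or
#'   `"Nocturnality"` / `"Verticality"`.
#' @param result optional [MultipleImputationResult-class] supplying
#'   fractional draw means for the expected-score path.
#' @param binaryScores `"expected"` or `"majority"`.
#' @return data.frame: taxon, attribute, n_obs, n_imputed, property_obs,
#'   property_comb, relative_change (`1 - comb/obs`), relative_change_alt
#'   (`comb/obs - 1`), direction.
#' @export
changeReport <- function(filled, by = "Genus",
                         attributes = c("BodyLength_mm", "BodyMass_g",
                                        "Nocturnality", "Verticality"),
                         result = NULL,
                         binaryScores = c("expected", "majority")) {
  stopifnot(is(filled, "TraitTable"))
  binaryScores <- match.arg(binaryScores)
  d <- traitData(filled)
  groups <- if (length(by) == 1L && by %in% colnames(d)) d[[by]]
            else rep_len(by, nrow(d))
  rows <- list()
  for (a in attributes) {
    sv <- .speciesValues(filled, a, "comb")
    if (!is.null(result) && binaryScores == "expected" &&
        a %in% c("Nocturnality", "Verticality")) {
      cols <- if (a == "Nocturnality") .ACT_ATTRS else .MICRO_ATTRS
      lev <- if (a == "Nocturnality") c(0, 1) else c(0, 0.5, 0.5, 1, 1)
      frac <- .fractionalCategories(filled, cols, result)
      sv$values <- .weightedScore(frac, lev)
    }
    svObs <- .speciesValues(filled, a, "obs")
    for (g in unique(groups)) {
      idx <- groups == g
      combVals <- sv$values[idx & !is.na(sv$values)]
      obsVals <- svObs$values[idx & !is.na(svObs$values)]
      nObs <- length(obsVals)
      nImp <- length(combVals) - nObs
      pObs <- if (nObs >= 1) attributeProperty(obsVals, sv$kind) else
        NA_real_
      pComb <- if (length(combVals) >= 1)
        attributeProperty(combVals, sv$kind) else NA_real_
      rc <- if (!is.na(pObs) && pObs != 0 && !is.na(pComb))
        1 - pComb / pObs else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = g, attribute = a, n_obs = nObs, n_imputed = nImp,
        property_obs = pObs, property_comb = pComb,
        relative_change = rc, relative_change_alt = -rc,
        direction = if (is.na(rc) || rc == 0) "none"
                    else if (rc < 0) "increase" else "decrease",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-assemblage attribute properties and completeness
#'
#' For each assemblage cell: the fraction of member species with observed
#' values for the attribute (completeness) and the attribute property over
#' member species with a value under the chosen mode (geometric mean for
#' continuous attributes, mean score for Nocturnality/Verticality, all
#' species weighted equally).
#'
#' @param table a [TraitTable-class] (gap-filled for `mode = "comb"`).
#' @param membership binary species x cell matrix with species row names.
#' @param attribute a continuous column name, `"Nocturnality"` or
#'   `"Verticality"`.
#' @param mode `"obs"` (observed cells only) or `"comb"` (observed +
#'   imputed).
#' @return data.frame: cell, n_species, completeness, average (NA for empty
#'   cells).
#' @export
assemblageProperty <- function(table, membership, attribute,
                               mode = c("obs", "comb")) {
  mode <- match.arg(mode)
  stopifnot(is(table, "TraitTable"))
  ids <- rownames(membership)
  missing <- setdiff(ids, speciesIds(table))
  if (length(missing))
    stop("species in membership absent from table: ",
         paste(missing, collapse = ", "))
  sv <- .speciesValues(table, attribute, mode)
  vals <- sv$values[match(ids, speciesIds(table))]
  obs <- sv$observed[match(ids, speciesIds(table))]
  cells <- colnames(membership)
  if (is.null(cells)) cells <- as.character(seq_len(ncol(membership)))
  rows <- lapply(seq_along(cells), function(j) {
    memb <- membership[, j] == 1
    n <- sum(memb)
    if (n == 0)
      return(data.frame(cell = cells[j], n_species = 0L,
                        completeness = NA_real_, average = NA_real_,
                        stringsAsFactors = FALSE))
    v <- vals[memb]
    v <- v[!is.na(v)]
    avg <- if (!length(v)) NA_real_ else attributeProperty(v, sv$kind)
    data.frame(cell = cells[j], n_species = n,
               completeness = mean(obs[memb]), average = avg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H with tie correction and a chi-square p-value on
#' `length(groups) - 1` degrees of freedom (delegates to
#' [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 non-empty numeric vectors, total n >= 5.
#' @return named numeric `c(H, p)`.
#' @export
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  if (sum(lengths(groups)) < 5) stop("total n must be >= 5")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Spearman rank correlation
#'
#' Product-moment correlation of mid-ranks (ties get average ranks).
#'
#' @param x,y numeric vectors, length >= 3.
#' @return correlation in `[-1, 1]`; NA with a warning for constant input.
#' @export
rankCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: rank correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
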