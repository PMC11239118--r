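#' Specify missingness mechanisms per attribute
#'
#' Builds a [MissingnessSpec-class]. Arguments are recycled across
#' `attributes`. The default dependence coefficient is -1: undersampled
#' species are expected to be the small, low-scoring ones.
#'
#' @param attributes composite attribute names among `body_length`,
#'   `body_mass`, `activity_time`, `microhabitat`, `threat_status`.
#' @param mechanism "MCAR", "MAR" or "MNAR" per attribute.
#' @param rate base missingness rate in `[0,1]` per attribute.
#' @param coef logistic slope linking missingness to the z-scored driver.
#' @param driver for MAR attributes, the name of an always-observed numeric
#'   column of the trait table; ignored (NA) otherwise.
#' @param sharedGapStrength scalar in `[0,1]`, weight of the per-species
#'   latent "poorly known species" factor shared across attributes.
#' @return A [MissingnessSpec-class].
#' @export
#' @examples
#' missingnessSpec(c("body_length", "activity_time"), mechanism = "MCAR",
#'                 rate = 0.2)
missingnessSpec <- function(attributes = c("body_length", "body_mass",
                                           "activity_time", "microhabitat"),
                            mechanism = "MCAR", rate = 0.2, coef = -1,
                            driver = NA_character_, sharedGapStrength = 0) {
  k <- length(attributes)
  new("MissingnessSpec", attributes = attributes,
      mechanism = setNames(rep_len(mechanism, k), attributes),
      rate = setNames(rep_len(rate, k), attributes),
      coef = setNames(rep_len(coef, k), attributes),
      driver = setNames(rep_len(as.character(driver), k), attributes),
      sharedGapStrength = sharedGapStrength)
}

setMethod("show", "MissingnessSpec", function(object) {
  cat("MissingnessSpec (sharedGapStrength =", object@sharedGapStrength, ")\n")
  print(data.frame(mechanism = object@mechanism, rate = object@rate,
                   coef = object@coef, driver = object@driver))
  invisible(NULL)
})

#' Write a MissingnessSpec to JSON
#'
#' @param spec a [MissingnessSpec-class].
#' @param path output file.
#' @export
writeMissingnessSpec <- function(spec, path) {
  jsonlite::write_json(
    list(attributes = spec@attributes, mechanism = unname(spec@mechanism),
         rate = unname(spec@rate), coef = unname(spec@coef),
         driver = unname(spec@driver),
         sharedGapStrength = spec@sharedGapStrength),
    path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

# Driver variable for one composite attribute under MNAR (its own true
# value/score) or MAR (a named observed column).
.missingnessDriver <- function(table, attr, mechanism, driverCol) {
  d <- traitData(table)
  if (mechanism == "MCAR") return(rep(0, nrow(d)))
  if (mechanism == "MAR") {
    if (!driverCol %in% colnames(d))
      stop("MAR driver column not found: ", driverCol)
    v <- d[[driverCol]]
    if (driverCol %in% .CONT_ATTRS) v <- log10(v)
  } else {
    v <- switch(attr,
      body_length = log10(d$BodyLength_mm),
      body_mass = log10(d$BodyMass_g),
      activity_time = nocturnalityScore(d$Diu, d$Noc),
      microhabitat = verticalityScore(d$Fos, d$Ter, d$Aqu, d$Arb, d$Aer),
      threat_status = d$Assessed,
      stop("no MNAR driver defined for attribute ", attr))
  }
  if (anyNA(v))
    stop("invalid configuration: missingness driver for '", attr,
         "' contains missing values")
  as.numeric(v)
}

#' Impose MCAR/MAR/MNAR missingness on a complete trait table
#'
#' For each composite attribute, species are hidden with probability
#' `plogis(qlogis(rate) + coef * z(driver) + sharedGapStrength * u)`, where
#' `u` is a per-species standard-normal latent factor shared across
#' attributes (inducing co-missingness) and the driver depends on the
#' mechanism: nothing for MCAR, an always-observed covariate for MAR, the
#' attribute's own true value (or score) for MNAR. Hiding an attribute sets
#' all of its member columns to NA (`threat_status` sets `Assessed` to 0:
#' the species is unassessed, not unknown).
#'
#' @param table a complete [TraitTable-class] (the ground truth).
#' @param spec a [MissingnessSpec-class].
#' @param seed integer seed or NULL.
#' @return list with elements `table` (the [TraitTable-class] with hidden
#'   cells, provenance `"missing"`) and `mask` (species x attribute logical
#'   matrix of which cells were hidden -- the ground truth for scoring).
#' @export
#' @examples
#' cl <- simulateClade(nTips = 50, seed = 2)
#' mis <- imposeMissingness(cladeTraits(cl),
#'                          missingnessSpec(rate = 0.3), seed = 3)
#' colSums(mis$mask)
imposeMissingness <- function(table, spec, seed = NULL) {
  stopifnot(is(table, "TraitTable"), is(spec, "MissingnessSpec"))
  validObject(spec)
  d <- traitData(table)
  n <- nrow(d)
  attrs <- spec@attributes
  if ("threat_status" %in% attrs && !"Assessed" %in% colnames(d))
    stop("invalid configuration: 'threat_status' requires an Assessed column")
  .withSeed(seed, function() {
    latent <- rnorm(n)
    mask <- matrix(FALSE, n, length(attrs),
                   dimnames = list(d$Species, attrs))
    for (a in attrs) {
      drv <- .missingnessDriver(table, a, spec@mechanism[a], spec@driver[a])
      z <- if (sd(drv) > 0) (drv - mean(drv)) / sd(drv) else rep(0, n)
      lp <- qlogis(spec@rate[a]) + spec@coef[a] * z +
        spec@sharedGapStrength * latent
      mask[, a] <- runif(n) < plogis(lp)
    }
    newData <- d
    for (a in attrs) {
      cols <- .COMPOSITE_ATTRS[[a]]
      if (a == "threat_status") {
        newData[mask[, a], cols] <- 0L
      } else {
        newData[mask[, a], cols] <- NA
      }
    }
    list(table = TraitTable(newData), mask = mask)
  })
}
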