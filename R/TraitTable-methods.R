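#' Construct a TraitTable
#'
#' Builds a [TraitTable-class] from a data.frame with TetrapodTraits-style
#' columns. When `provenance` is NULL, cells are marked `"observed"` where a
#' value is present and `"missing"` where it is NA.
#'
#' @param data data.frame with columns `Species`, `Genus`, `Family`, the two
#'   continuous size columns and the seven binary columns (see
#'   [continuousAttributes()], [binaryAttributes()]). Extra columns (e.g.
#'   `Assessed`) are carried along untouched.
#' @param provenance optional species x attribute character matrix.
#' @return A [TraitTable-class] object.
#' @rdname TraitTable
#' @export
#' @examples
#' cl <- simulateClade(nTips = 20, seed = 1)
#' tt <- cladeTraits(cl)
#' head(traitData(tt))
TraitTable <- function(data, provenance = NULL) {
  data <- as.data.frame(data)
  data$Species <- as.character(data$Species)
  rownames(data) <- NULL
  if (is.null(provenance)) {
    provenance <- ifelse(is.na(as.matrix(data[, .CORE_ATTRS])),
                         "missing", "observed")
  }
  dimnames(provenance) <- list(data$Species, .CORE_ATTRS)
  new("TraitTable", data = data, provenance = provenance)
}

#' @rdname TraitTable
#' @param x a `TraitTable`.
#' @export
setMethod("speciesIds", "TraitTable", function(x) x@data$Species)

#' @rdname TraitTable
#' @export
setMethod("traitData", "TraitTable", function(x) x@data)

#' @rdname TraitTable
#' @export
setMethod("provenance", "TraitTable", function(x) x@provenance)

#' @rdname TraitTable
#' @export
setMethod("isMissing", "TraitTable",
          function(x) x@provenance == "missing")

setMethod("show", "TraitTable", function(object) {
  d <- object@data
  nmiss <- sum(object@provenance == "missing")
  cat("TraitTable with", nrow(d), "species\n")
  cat("  attributes:", paste(.CORE_ATTRS, collapse = ", "), "\n")
  extra <- setdiff(colnames(d), c("Species", "Genus", "Family", .CORE_ATTRS))
  if (length(extra)) cat("  extra columns:", paste(extra, collapse = ", "), "\n")
  cat("  provenance:",
      paste(vapply(.PROV_LEVELS,
                   function(l) sprintf("%s=%d", l, sum(object@provenance == l)),
                   ""), collapse = ", "), "\n")
  invisible(NULL)
})

# Replace cell values + provenance; internal helper shared by the imputers.
.setCells <- function(table, species, attribute, values, prov) {
  d <- table@data
  p <- table@provenance
  i <- match(species, d$Species)
  stopifnot(!anyNA(i))
  d[i, attribute] <- values
  p[i, attribute] <- prov
  new("TraitTable", data = d, provenance = p)
}

#' Read / write a TraitTable as CSV
#'
#' `writeTraitTable()` writes the trait values and a `<path>.provenance.csv`
#' sidecar; `readTraitTable()` restores both (the sidecar is optional).
#'
#' @param table a [TraitTable-class].
#' @param path CSV file path.
#' @return `readTraitTable()` returns a [TraitTable-class].
#' @export
writeTraitTable <- function(table, path) {
  write.csv(table@data, path, row.names = FALSE)
  write.csv(data.frame(Species = speciesIds(table), table@provenance,
                       check.names = FALSE),
            paste0(path, ".provenance.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraitTable
#' @export
readTraitTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".provenance.csv")
  prov <- NULL
  if (file.exists(side)) {
    ps <- read.csv(side, stringsAsFactors = FALSE, check.names = FALSE)
    prov <- as.matrix(ps[, .CORE_ATTRS])
  }
  TraitTable(d, provenance = prov)
}
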