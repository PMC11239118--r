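#' Rule-based (taxonomic) imputation of binary attributes
#'
#' For each genus and each binary attribute, if the share of species
#' observed to have the attribute reaches `threshold` of the genus, species
#' with a missing value for that attribute receive a 1 with provenance
#' `"taxon_imputed"`. Fixed-group overrides (e.g. an order known to be
#' aerial) are applied first. Observed cells are never overwritten, 0s are
#' never imputed, and continuous attributes are never taxon-imputed.
#'
#' @param table a [TraitTable-class].
#' @param threshold proportion in (0, 1], default 0.70.
#' @param overrides optional data.frame with columns `group` (a Genus or
#'   Family label), `attribute` (a binary attribute) and `value` (0/1);
#'   unknown groups are skipped with a warning.
#' @param denominator `"all"` (default; all species in the genus, the
#'   at-least-70%-of-species reading) or `"observed"` (only species with an
#'   observed value).
#' @return The [TraitTable-class] with taxon-imputed cells filled.
#' @export
#' @examples
#' cl <- simulateClade(nTips = 60, nGenera = 6, seed = 5)
#' mis <- imposeMissingness(cladeTraits(cl),
#'                          missingnessSpec("activity_time", rate = 0.2),
#'                          seed = 1)
#' filled <- taxonomicImpute(mis$table)
#' sum(provenance(filled) == "taxon_imputed")
taxonomicImpute <- function(table, threshold = 0.70, overrides = NULL,
                            denominator = c("all", "observed")) {
  stopifnot(is(table, "TraitTable"))
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  denominator <- match.arg(denominator)
  out <- table
  if (!is.null(overrides)) {
    for (r in seq_len(nrow(overrides))) {
      g <- as.character(overrides$group[r])
      a <- as.character(overrides$attribute[r])
      v <- overrides$value[r]
      if (!a %in% .BIN_ATTRS)
        stop("overrides may only target binary attributes: ", a)
      d <- traitData(out)
      inGroup <- d$Genus == g | d$Family == g
      if (!any(inGroup)) {
        warning("override group not found, skipped: ", g)
        next
      }
      fill <- inGroup & is.na(d[[a]])
      if (any(fill))
        out <- .setCells(out, d$Species[fill], a, v, "taxon_imputed")
    }
  }
  d <- traitData(out)
  p <- provenance(out)
  for (g in unique(d$Genus)) {
    rows <- which(d$Genus == g)
    for (a in .BIN_ATTRS) {
      v <- d[rows, a]
      obs <- p[rows, a] == "observed"
      nPos <- sum(obs & !is.na(v) & v == 1)
      den <- if (denominator == "all") length(rows) else sum(obs)
      if (den == 0 || nPos / den < threshold) next
      fill <- rows[is.na(v)]
      if (length(fill))
        out <- .setCells(out, d$Species[fill], a, 1L, "taxon_imputed")
    }
  }
  out
}
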