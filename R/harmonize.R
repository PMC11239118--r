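#' Resolve external record names against a reference species list
#'
#' Applies the four-step taxonomic reconciliation: (1) exact match with the
#' reference; (2) match after updating the record name through the unique
#' synonyms of the source name; (3) match via the unique synonyms of the
#' reference ids themselves (for sources following a newer taxonomy);
#' (4) unresolved records are flagged for manual review. Only unique
#' synonyms (a binomial applied to exactly one valid name) are auto-applied;
#' ambiguous multi-matches are flagged, never matched. Within an attribute,
#' a second record resolving to an already-matched reference id is flagged
#' as a duplicate entry so each data entry is made only once.
#'
#' @param records character vector of names, or a data.frame with a `name`
#'   column and optionally an `attribute` column (duplicates are tracked per
#'   attribute when present).
#' @param reference character vector of valid species ids (unique).
#' @param synonyms data.frame with columns `name`, `valid_name` (and
#'   optionally a logical `unique`; if absent, uniqueness is derived: a name
#'   mapping to exactly one distinct valid name is unique). NULL = no
#'   synonyms.
#' @return data.frame: `name`, `matched_id` (NA if unmatched), `step`
#'   (1-3, or 4 = manual review), `duplicate` (logical), `ambiguous`
#'   (logical).
#' @export
#' @examples
#' ref <- c("Aa bb", "Cc dd")
#' syn <- data.frame(name = "Aa zz", valid_name = "Aa bb")
#' resolveNames(c("Aa bb", "Aa zz", "Ee ff"), ref, syn)
resolveNames <- function(records, reference, synonyms = NULL) {
  if (anyDuplicated(reference)) stop("reference ids must be unique")
  if (is.character(records))
    records <- data.frame(name = records, stringsAsFactors = FALSE)
  nm <- as.character(records$name)
  attrib <- if ("attribute" %in% colnames(records))
    as.character(records$attribute) else rep("", length(nm))

  uniqueSynMap <- function(syn) {
    if (is.null(syn) || !nrow(syn)) return(syn[0, , drop = FALSE])
    syn <- unique(syn[, c("name", "valid_name")])
    if (!is.null(synonyms$unique)) {
      keep <- syn$name %in% synonyms$name[as.logical(synonyms$unique)]
      syn <- syn[keep, , drop = FALSE]
    }
    cnt <- table(syn$name)
    syn[syn$name %in% names(cnt)[cnt == 1L], , drop = FALSE]
  }
  syn <- uniqueSynMap(synonyms)

  matched <- rep(NA_character_, length(nm))
  step <- rep(4L, length(nm))
  ambiguous <- rep(FALSE, length(nm))

  # step 1: exact
  hit <- nm %in% reference
  matched[hit] <- nm[hit]
  step[hit] <- 1L

  if (nrow(syn)) {
    # step 2: record name is a unique synonym of a valid name in the reference
    todo <- which(is.na(matched))
    i <- match(nm[todo], syn$name)
    ok <- !is.na(i) & syn$valid_name[i] %in% reference
    matched[todo[ok]] <- syn$valid_name[i[ok]]
    step[todo[ok]] <- 2L

    # step 3: a reference id is a unique synonym of the (newer) record name
    todo <- which(is.na(matched))
    refSyn <- syn[syn$name %in% reference, , drop = FALSE]
    for (j in todo) {
      cand <- refSyn$name[refSyn$valid_name == nm[j]]
      if (length(cand) == 1L) {
        matched[j] <- cand
        step[j] <- 3L
      } else if (length(cand) > 1L) {
        ambiguous[j] <- TRUE
      }
    }
  }

  duplicate <- rep(FALSE, length(nm))
  key <- paste(attrib, matched, sep = "\r")
  hasId <- !is.na(matched)
  duplicate[hasId] <- duplicated(key[hasId])

  data.frame(name = nm, matched_id = matched, step = step,
             duplicate = duplicate, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' Binarise relative foraging-stratum usage
#'
#' A species is typical of a microhabitat if its relative usage is at least
#' 30% (threshold inclusive).
#'
#' @param usage numeric vector or matrix of relative usages in `[0,1]`.
#' @return integer 0/1 of the same shape.
#' @export
#' @examples
#' binarizeStratumUsage(c(0.35, 0.30, 0.29, 0))
binarizeStratumUsage <- function(usage) {
  if (any(!is.na(usage) & (usage < 0 | usage > 1)))
    stop("usages must lie in [0, 1]")
  out <- (usage >= 0.30) * 1L
  out
}
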