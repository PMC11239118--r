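#' Build missing-data presence-absence matrices per taxon
#'
#' Rows are missing-data indicators for composite attributes (body length,
#' body mass, activity time, microhabitat, threat status when an `Assessed`
#' column is present); columns are the species of one taxon. An entry is 1
#' when the attribute lacks an observed value for that species. By default
#' cells later filled by taxonomic or phylogenetic imputation still count
#' as missing (the analysis concerns gaps in observed data); restrict
#' `missingStatuses` to change that. Taxa with fewer than `minSpecies`
#' species are skipped.
#'
#' @param table a [TraitTable-class].
#' @param attributes composite attribute names (rows of the PAM).
#' @param by grouping column, `"Genus"` (default) or `"Family"`, or a
#'   vector of labels; use a single constant to treat the whole table as
#'   one taxon.
#' @param minSpecies minimum species per taxon (default 2).
#' @param missingStatuses provenance levels counted as missing.
#' @return named list of binary attribute x species matrices.
#' @export
#' @examples
#' cl <- simulateClade(nTips = 40, seed = 1)
#' mis <- imposeMissingness(cladeTraits(cl), missingnessSpec(rate = 0.3),
#'                          seed = 2)
#' pams <- buildMissingPAM(mis$table, by = "Family")
#' pams[[1]]
buildMissingPAM <- function(table,
                            attributes = c("body_length", "body_mass",
                                           "activity_time", "microhabitat"),
                            by = "Genus", minSpecies = 2,
                            missingStatuses = c("missing", "taxon_imputed",
                                                "phylo_imputed")) {
  stopifnot(is(table, "TraitTable"))
  if (!all(attributes %in% names(.COMPOSITE_ATTRS)))
    stop("unknown attribute name(s): ",
         paste(setdiff(attributes, names(.COMPOSITE_ATTRS)), collapse = ", "))
  d <- traitData(table)
  p <- provenance(table)
  groups <- if (length(by) == 1L && by %in% colnames(d)) d[[by]]
            else rep_len(by, nrow(d))
  missRow <- function(a) {
    if (a == "threat_status") {
      if (!"Assessed" %in% colnames(d))
        stop("'threat_status' requires an Assessed column")
      return(as.integer(is.na(d$Assessed) | d$Assessed == 0))
    }
    cols <- .COMPOSITE_ATTRS[[a]]
    as.integer(rowSums(matrix(p[, cols] %in% missingStatuses,
                              nrow = nrow(d))) == length(cols))
  }
  M <- t(vapply(attributes, missRow, integer(nrow(d))))
  dimnames(M) <- list(attributes, d$Species)
  out <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < minSpecies) next
    out[[as.character(g)]] <- M[, cols, drop = FALSE]
  }
  out
}

#' Checkerboard C-score of two binary rows
#'
#' `C = (R_i - S)(R_j - S)` with `R` the row sums and `S` the number of
#' species missing both attributes; equivalently the number of
#' checkerboard-unit species pairs. 0 when the rows are identical.
#'
#' @param rowI,rowJ binary vectors of equal length.
#' @return non-negative number.
#' @export
#' @examples
#' cscorePair(c(1, 1, 0, 0), c(0, 0, 1, 1)) # 4
#' cscorePair(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 1
cscorePair <- function(rowI, rowJ) {
  stopifnot(length(rowI) == length(rowJ))
  s <- sum(rowI == 1 & rowJ == 1)
  (sum(rowI == 1) - s) * (sum(rowJ == 1) - s)
}

#' Null distribution of the C-score under fixed rows / equiprobable columns
#'
#' Each null sample redraws, for each of the two rows, its `R` one-cells
#' uniformly without replacement across species: attribute completeness
#' (row sums) stays fixed while every species is equally likely to show a
#' gap. Draws are independent; the first `burnIn` samples are nevertheless
#' discarded to mirror the conventional randomisation workflow.
#'
#' @param pam binary attribute x species matrix.
#' @param pair length-2 vector of row indices or names.
#' @param iterations retained null samples (default 10000, >= 100).
#' @param burnIn discarded initial samples (default 500).
#' @param seed integer seed or NULL.
#' @return numeric vector of `iterations` null C-scores.
#' @export
nullDistribution <- function(pam, pair, iterations = 10000, burnIn = 500,
                             seed = NULL) {
  if (iterations < 100) stop("'iterations' must be >= 100")
  ri <- pam[pair[1], ]
  rj <- pam[pair[2], ]
  n <- length(ri)
  Ri <- sum(ri == 1)
  Rj <- sum(rj == 1)
  if (Ri > n || Rj > n)
    stop("impossible matrix: row sum exceeds the number of species")
  .withSeed(seed, function() {
    total <- burnIn + iterations
    out <- numeric(total)
    occ <- logical(n)
    for (it in seq_len(total)) {
      si <- sample.int(n, Ri)
      sj <- sample.int(n, Rj)
      occ[] <- FALSE
      occ[si] <- TRUE
      s <- sum(occ[sj])
      out[it] <- (Ri - s) * (Rj - s)
    }
    out[(burnIn + 1L):total]
  })
}

#' Standardised effect size and two-tailed p of an observed C-score
#'
#' `SES = (observed - mean(null)) / sd(null)`; the two-tailed p-value is
#' `2 * min(P(null <= obs), P(null >= obs))` with the observation counted
#' as one of the samples (add-one correction), capped at 1. A degenerate
#' null (sd 0) yields SES NA with p from the same rank rule.
#'
#' @param observed observed C-score.
#' @param nullSamples numeric vector of >= 100 null C-scores.
#' @return named numeric `c(ses, p)`.
#' @export
sesAndP <- function(observed, nullSamples) {
  if (length(nullSamples) < 100) stop("need >= 100 null samples")
  m <- mean(nullSamples)
  s <- sd(nullSamples)
  N <- length(nullSamples)
  pLow <- (sum(nullSamples <= observed) + 1) / (N + 1)
  pHigh <- (sum(nullSamples >= observed) + 1) / (N + 1)
  p <- min(1, 2 * min(pLow, pHigh))
  ses <- if (s == 0) NA_real_ else (observed - m) / s
  c(ses = ses, p = p)
}

#' Classify attribute pairs and aggregate per taxon
#'
#' Pairs are `aggregated` when SES < 0 and p < alpha (shared gaps),
#' `segregated` when SES > 0 and p < alpha, else `random`. Per taxon, the
#' aggregation metric is the median SES across all pairs, and across the
#' pairs involving `focalAttribute` when given (the threat-status
#' restricted median).
#'
#' @param pairRows data.frame with columns `taxon`, `attr_i`, `attr_j`,
#'   `ses`, `p` (as produced by [comissingnessReport()]).
#' @param alpha significance threshold (default 0.05).
#' @param focalAttribute attribute defining the restricted median (default
#'   `"threat_status"`; NA rows when absent from the pairs).
#' @return A [CScoreReport-class].
#' @export
classifyAndAggregate <- function(pairRows, alpha = 0.05,
                                 focalAttribute = "threat_status") {
  stopifnot(nrow(pairRows) >= 1)
  cls <- rep("random", nrow(pairRows))
  sig <- !is.na(pairRows$p) & pairRows$p < alpha & !is.na(pairRows$ses)
  cls[sig & pairRows$ses < 0] <- "aggregated"
  cls[sig & pairRows$ses > 0] <- "segregated"
  pairRows$class <- cls
  taxa <- lapply(split(pairRows, pairRows$taxon), function(px) {
    foc <- px$attr_i == focalAttribute | px$attr_j == focalAttribute
    data.frame(taxon = px$taxon[1],
               n_pairs = nrow(px),
               median_ses = median(px$ses, na.rm = TRUE),
               median_ses_focal = if (any(foc))
                 median(px$ses[foc], na.rm = TRUE) else NA_real_,
               n_aggregated = sum(px$class == "aggregated"),
               n_segregated = sum(px$class == "segregated"),
               stringsAsFactors = FALSE)
  })
  taxa <- do.call(rbind, taxa)
  taxa <- taxa[order(taxa$median_ses), , drop = FALSE]
  rownames(taxa) <- NULL
  new("CScoreReport", pairs = pairRows, taxa = taxa, alpha = alpha)
}

#' Full shared-missingness analysis of a trait table
#'
#' Builds per-taxon missing-data PAMs, computes the observed C-score, null
#' distribution, SES and p for every attribute pair, classifies the
#' patterns and aggregates per-taxon medians.
#'
#' @inheritParams buildMissingPAM
#' @inheritParams nullDistribution
#' @param alpha significance threshold.
#' @param focalAttribute see [classifyAndAggregate()].
#' @param seed integer seed or NULL.
#' @return A [CScoreReport-class].
#' @export
#' @examples
#' cl <- simulateClade(nTips = 60, nGenera = 3, seed = 1)
#' mis <- imposeMissingness(cladeTraits(cl),
#'                          missingnessSpec(rate = 0.3,
#'                                          sharedGapStrength = 0.9),
#'                          seed = 2)
#' rep <- comissingnessReport(mis$table, by = "Family", iterations = 500,
#'                            seed = 3)
#' cscoreTaxa(rep)
comissingnessReport <- function(table,
                                attributes = c("body_length", "body_mass",
                                               "activity_time",
                                               "microhabitat"),
                                by = "Genus", minSpecies = 2,
                                iterations = 10000, burnIn = 500,
                                alpha = 0.05,
                                focalAttribute = "threat_status",
                                seed = NULL) {
  pams <- buildMissingPAM(table, attributes, by, minSpecies)
  if (!length(pams)) stop("no taxon with at least ", minSpecies, " species")
  .withSeed(seed, function() {
    rows <- list()
    for (g in names(pams)) {
      pam <- pams[[g]]
      cmb <- utils::combn(rownames(pam), 2)
      for (j in seq_len(ncol(cmb))) {
        i1 <- cmb[1, j]; i2 <- cmb[2, j]
        obs <- cscorePair(pam[i1, ], pam[i2, ])
        ns <- nullDistribution(pam, c(i1, i2), iterations, burnIn)
        sp <- sesAndP(obs, ns)
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = g, attr_i = i1, attr_j = i2, observed_c = obs,
          null_mean = mean(ns), null_sd = sd(ns), ses = sp[["ses"]],
          p = sp[["p"]], stringsAsFactors = FALSE)
      }
    }
    classifyAndAggregate(do.call(rbind, rows), alpha, focalAttribute)
  })
}

#' @rdname CScoreReport-class
#' @param x a `CScoreReport`.
#' @export
cscorePairs <- function(x) x@pairs

#' @rdname CScoreReport-class
#' @export
cscoreTaxa <- function(x) x@taxa

setMethod("show", "CScoreReport", function(object) {
  cat("CScoreReport:", nrow(object@pairs), "attribute pairs across",
      nrow(object@taxa), "taxa (alpha =", object@alpha, ")\n")
  cat("  pattern classes:",
      paste(names(table(object@pairs$class)), table(object@pairs$class),
            sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

#' Write the pairwise C-score report as CSV
#'
#' @param report a [CScoreReport-class].
#' @param path output CSV.
#' @export
writeCScoreReport <- function(report, path) {
  write.csv(report@pairs, path, row.names = FALSE)
  invisible(path)
}
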