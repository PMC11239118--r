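#' Flag outliers by the interquartile-range criterion
#'
#' Values are log10-transformed and flagged when outside
#' `[q0.25 - 1.5 IQR, q0.75 + 1.5 IQR]`. Quartiles use the linear
#' interpolation convention (`quantile()` type 7).
#'
#' @param values positive numeric vector (NAs allowed, never flagged).
#' @return logical vector (NA where the value is NA). Fewer than 4 non-NA
#'   values: no flags, with a warning.
#' @export
#' @examples
#' flagOutliersIQR(c(10, 11, 12, 13, 14, 10000))
flagOutliersIQR <- function(values) {
  ok <- !is.na(values)
  if (any(values[ok] <= 0)) stop("values must be strictly positive")
  flags <- rep(NA, length(values))
  if (sum(ok) < 4) {
    warning("fewer than 4 values: no outlier flags computed")
    flags[ok] <- FALSE
    return(flags)
  }
  l <- log10(values[ok])
  q <- quantile(l, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  flags[ok] <- l < q[1] - 1.5 * iqr | l > q[2] + 1.5 * iqr
  flags
}

# Siegel repeated-median line fit: robust to up to 50% outliers and exact on
# noise-free majorities (needed so a single wild point is isolated exactly).
.repeatedMedianFit <- function(x, y) {
  n <- length(x)
  med_i <- vapply(seq_len(n), function(i) {
    dx <- x[-i] - x[i]
    s <- (y[-i] - y[i])[dx != 0] / dx[dx != 0]
    if (!length(s)) NA_real_ else median(s)
  }, 0)
  slope <- median(med_i, na.rm = TRUE)
  intercept <- median(y - slope * x)
  c(intercept = intercept, slope = slope)
}

#' Flag species deviating from the group allometric relationship
#'
#' Within each group, a robust (Siegel repeated-median) line of log10 mass
#' on log10 length is fitted; species are flagged where the MAD-standardised
#' absolute residual exceeds `zCut`. Groups with fewer than 5 complete pairs
#' are skipped with a warning. If the residual MAD is zero, collinear data
#' (all residuals zero) yield no flags with a warning, while any exactly
#' deviating points are flagged directly.
#'
#' @param lengths,masses positive numeric vectors (NA allowed).
#' @param groups taxon labels (single group when NULL).
#' @param zCut robust z threshold (default 3.5).
#' @return data.frame: `flagged` (logical, NA where the pair is incomplete)
#'   and `z` (standardised residual).
#' @export
flagOutliersAllometric <- function(lengths, masses, groups = NULL,
                                   zCut = 3.5) {
  n <- length(lengths)
  stopifnot(length(masses) == n)
  if (is.null(groups)) groups <- rep("all", n)
  ok <- !is.na(lengths) & !is.na(masses)
  if (any(lengths[ok] <= 0) || any(masses[ok] <= 0))
    stop("lengths and masses must be strictly positive")
  flagged <- rep(NA, n)
  z <- rep(NA_real_, n)
  for (g in unique(groups)) {
    idx <- which(groups == g & ok)
    if (length(idx) < 5) {
      warning("group '", g, "' has < 5 complete pairs: skipped")
      next
    }
    lx <- log10(lengths[idx]); ly <- log10(masses[idx])
    fit <- .repeatedMedianFit(lx, ly)
    res <- ly - fit[1] - fit[2] * lx
    s <- mad(res)
    if (s == 0) {
      tol <- 1e-8 * max(1, diff(range(ly)))
      if (all(abs(res) <= tol)) {
        warning("group '", g, "': zero residual spread, no flags")
        flagged[idx] <- FALSE
        z[idx] <- 0
      } else {
        flagged[idx] <- abs(res) > tol
        z[idx] <- ifelse(abs(res) > tol, Inf, 0)
      }
    } else {
      z[idx] <- res / s
      flagged[idx] <- abs(z[idx]) > zCut
    }
  }
  data.frame(flagged = flagged, z = z)
}

#' Screen a trait table for size outliers
#'
#' Convenience wrapper combining the IQR screen on body length and mass with
#' the per-family allometric screen. Flagged values are reported, never
#' deleted; removal is a separate explicit action.
#'
#' @param table a [TraitTable-class].
#' @param zCut allometric robust z threshold (default 3.5).
#' @return data.frame: `Species`, `flag_iqr_length`, `flag_iqr_mass`,
#'   `flag_allometry`, `allometry_z`.
#' @export
screenOutliers <- function(table, zCut = 3.5) {
  d <- traitData(table)
  allo <- flagOutliersAllometric(d$BodyLength_mm, d$BodyMass_g,
                                 groups = d$Family, zCut = zCut)
  data.frame(Species = d$Species,
             flag_iqr_length = flagOutliersIQR(d$BodyLength_mm),
             flag_iqr_mass = flagOutliersIQR(d$BodyMass_g),
             flag_allometry = allo$flagged,
             allometry_z = allo$z,
             stringsAsFactors = FALSE)
}
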