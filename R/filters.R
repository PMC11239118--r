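#' Phylogenetic covariance matrix of a rooted tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths (constant for ultrametric trees).
#'
#' @param tree rooted `phylo` with non-negative branch lengths.
#' @return symmetric positive semidefinite species x species matrix.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' treeToCovariance(tr)
treeToCovariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("tree is unrooted: root it first (e.g. ape::root())")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  ape::vcv(tree)
}

#' Broken-stick expected eigenvalue proportions
#'
#' `b_k = (1/p) * sum_{i=k..p} 1/i`; the components sum to 1.
#'
#' @param p number of components (>= 1).
#' @return numeric vector of length `p`.
#' @export
#' @examples
#' brokenStick(3) # 0.6111 0.2778 0.1111
brokenStick <- function(p) {
  if (p < 1) stop("'p' must be >= 1")
  p <- as.integer(p)
  rev(cumsum(1 / seq(p, 1))) / p
}

#' Derive phylogenetic filters from a covariance matrix
#'
#' Eigendecomposes the phylogenetic covariance matrix and retains the
#' leading eigenvectors whose relative eigenvalue exceeds the broken-stick
#' expectation. The default `"sequential"` rule stops at the first
#' component that fails; `"all"` counts every passing component. Retention
#' is floored at 1 so the phylogeny always contributes a predictor. The
#' sign of each eigenvector is fixed so its largest-magnitude loading is
#' positive, making multi-tree runs comparable.
#'
#' @param cov symmetric PSD matrix (e.g. from [treeToCovariance()]), with
#'   species row names.
#' @param rule `"sequential"` (default) or `"all"`.
#' @param treeId identifier stored in the result.
#' @return A [FilterSet-class].
#' @export
#' @examples
#' fs <- deriveFilters(treeToCovariance(simulateTree(20, seed = 1)))
#' nRetained(fs)
deriveFilters <- function(cov, rule = c("sequential", "all"),
                          treeId = "tree1") {
  rule <- match.arg(rule)
  cov <- as.matrix(cov)
  if (max(abs(cov - t(cov))) > 1e-8)
    stop("covariance matrix must be symmetric (within 1e-8)")
  e <- eigen(cov, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-6 * max(abs(vals))))
    stop("matrix is not positive semidefinite")
  vals[vals < 0] <- 0
  props <- vals / sum(vals)
  b <- brokenStick(length(vals))
  if (rule == "sequential") {
    k <- 0L
    while (k < length(vals) && props[k + 1L] > b[k + 1L]) k <- k + 1L
  } else {
    k <- sum(props > b)
  }
  k <- max(1L, as.integer(k))
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  rn <- rownames(cov)
  if (is.null(rn)) rn <- sprintf("sp%04d", seq_len(nrow(cov)))
  dimnames(V) <- list(rn, sprintf("PF%03d", seq_len(ncol(V))))
  new("FilterSet", values = vals, vectors = V, retained = k,
      treeId = as.character(treeId))
}

#' @rdname FilterSet-class
#' @param x a `FilterSet`.
#' @export
setMethod("eigenvalues", "FilterSet", function(x) x@values)

#' @rdname FilterSet-class
#' @export
setMethod("filters", "FilterSet",
          function(x) x@vectors[, seq_len(x@retained), drop = FALSE])

#' @rdname FilterSet-class
#' @export
setMethod("nRetained", "FilterSet", function(x) x@retained)

setMethod("show", "FilterSet", function(object) {
  cat("FilterSet '", object@treeId, "': ", nrow(object@vectors),
      " species, ", object@retained, " of ", length(object@values),
      " filters retained (leading eigenvalue proportion ",
      sprintf("%.3f", object@values[1] / sum(object@values)), ")\n",
      sep = "")
  invisible(NULL)
})

#' Read a Newick tree for filter derivation
#'
#' Requires branch lengths; polytomies are resolved arbitrarily with
#' zero-length branches.
#'
#' @param path Newick file.
#' @return a `phylo`.
#' @export
readTreeNewick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("Newick tree must have branch lengths")
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr, random = FALSE)
  tr
}

#' Write a FilterSet to CSV with a JSON eigenvalue sidecar
#'
#' @param fs a [FilterSet-class].
#' @param path CSV path for the species x filter matrix (retained filters);
#'   eigenvalues and the retention count go to `<path>.json`.
#' @export
writeFilterSet <- function(fs, path) {
  write.csv(data.frame(Species = rownames(fs@vectors), filters(fs),
                       check.names = FALSE), path, row.names = FALSE)
  jsonlite::write_json(list(eigenvalues = fs@values, retained = fs@retained,
                            treeId = fs@treeId),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
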