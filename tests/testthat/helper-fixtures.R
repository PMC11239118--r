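# Shared fixtures: everything is generated in code at test time.

# A tiny hand-built complete trait table (6 species, 2 genera, 1 family).
makeSmallTable <- function() {
  d <- data.frame(
    Species = sprintf("sp%02d", 1:6),
    Genus = rep(c("GenA", "GenB"), each = 3),
    Family = "FamA",
    BodyLength_mm = c(20, 25, 30, 100, 120, 140),
    BodyMass_g = c(0.5, 0.9, 1.4, 40, 70, 110),
    Diu = c(1, 1, 0, 0, 0, 1),
    Noc = c(0, 1, 1, 1, 1, 0),
    Fos = c(0, 0, 0, 0, 1, 0),
    Ter = c(1, 1, 0, 1, 1, 1),
    Aqu = c(0, 0, 1, 0, 0, 0),
    Arb = c(0, 1, 0, 1, 0, 0),
    Aer = c(0, 0, 0, 0, 0, 0),
    Assessed = 1L,
    stringsAsFactors = FALSE)
  TraitTable(d)
}

# Filter sets from the true tree plus branch-length-jittered copies,
# emulating a set of candidate phylogenies for the same clade.
makeFilterSets <- function(tree, nTrees, seed = 1) {
  out <- vector("list", nTrees)
  out[[1]] <- deriveFilters(treeToCovariance(tree), treeId = "tree1")
  if (nTrees > 1) {
    old <- if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    for (t in 2:nTrees) {
      tr <- tree
      tr$edge.length <- tr$edge.length * exp(rnorm(length(tr$edge.length),
                                                   0, 0.2))
      depth <- max(ape::node.depth.edgelength(tr))
      tr$edge.length <- tr$edge.length / depth
      out[[t]] <- deriveFilters(treeToCovariance(tr),
                                treeId = paste0("tree", t))
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  out
}

# Exhaustive null moments of the pairwise C-score for small matrices:
# averages over all C(n, Ri) x C(n, Rj) equally likely configurations.
enumNullMoments <- function(n, Ri, Rj) {
  ci <- utils::combn(n, Ri, simplify = FALSE)
  cj <- utils::combn(n, Rj, simplify = FALSE)
  cs <- unlist(lapply(ci, function(a)
    vapply(cj, function(b) {
      s <- length(intersect(a, b))
      (Ri - s) * (Rj - s)
    }, 0)))
  c(mean = mean(cs), var = mean((cs - mean(cs))^2))
}

# Brute-force C-score: count checkerboard species pairs directly.
bruteCscore <- function(ri, rj) {
  n <- length(ri)
  cnt <- 0L
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (ri[a] == 1 && rj[a] == 0 && ri[b] == 0 && rj[b] == 1) cnt <- cnt + 1L
    if (ri[b] == 1 && rj[b] == 0 && ri[a] == 0 && rj[a] == 1) cnt <- cnt + 1L
  }
  cnt
}
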