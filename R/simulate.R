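#' Simulate an ultrametric phylogeny
#'
#' Simulates a rooted, bifurcating, ultrametric tree under a Yule (pure
#' birth) or birth-death process and rescales branch lengths so the root
#' depth equals 1, which puts Brownian-motion and liability variances on a
#' common scale across replicates.
#'
#' @param nTips number of tips (>= 2).
#' @param model "yule" (default) or "birth-death".
#' @param birth,death speciation and extinction rates (death is forced to 0
#'   under "yule").
#' @param seed integer seed (NULL = use the current RNG stream).
#' @return A `phylo` object with tips labelled `sp0001`, `sp0002`, ...
#' @export
#' @examples
#' tr <- simulateTree(16, seed = 42)
#' ape::is.ultrametric(tr)
simulateTree <- function(nTips, model = c("yule", "birth-death"),
                         birth = 1, death = 0, seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(nTips) || nTips < 2) stop("'nTips' must be >= 2")
  nTips <- as.integer(nTips)
  if (model == "yule") death <- 0
  .withSeed(seed, function() {
    tr <- ape::rphylo(nTips, birth = birth, death = death, fossils = FALSE)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("sp%04d", seq_len(nTips))
    tr
  })
}

#' Assign nested genus and family labels by cutting the tree
#'
#' Cuts an ultrametric tree at the two heights that produce `nGenera` and
#' `nFamilies` monophyletic groups; because both cuts come from the same
#' hierarchy, each genus nests within exactly one family.
#'
#' @param tree ultrametric `phylo`.
#' @param nFamilies,nGenera group counts with
#'   `1 <= nFamilies <= nGenera <= nTips`.
#' @return data.frame with columns `Species`, `Genus`, `Family`, ordered as
#'   `tree$tip.label`.
#' @export
#' @examples
#' tax <- assignTaxonomy(simulateTree(20, seed = 1), nFamilies = 2, nGenera = 5)
#' table(tax$Family)
assignTaxonomy <- function(tree, nFamilies, nGenera) {
  n <- length(tree$tip.label)
  if (nFamilies < 1 || nGenera < nFamilies)
    stop("need 1 <= nFamilies <= nGenera")
  if (nGenera > n)
    stop(sprintf("nGenera = %d infeasible: the achievable maximum is %d tips",
                 nGenera, n))
  if (n == 2) {
    gen <- if (nGenera == 2) c(1L, 2L) else c(1L, 1L)
    fam <- if (nFamilies == 2) c(1L, 2L) else c(1L, 1L)
  } else {
    hc <- stats::as.hclust(ape::as.phylo(tree))
    gen <- stats::cutree(hc, k = nGenera)[tree$tip.label]
    fam <- stats::cutree(hc, k = nFamilies)[tree$tip.label]
  }
  # relabel families by first appearance, genera within family
  fam <- match(fam, unique(fam))
  gen <- match(gen, unique(gen))
  data.frame(Species = tree$tip.label,
             Genus = sprintf("Gen%03d", gen),
             Family = sprintf("Fam%02d", fam),
             stringsAsFactors = FALSE)
}

#' Simulate body length and allometric body mass on a tree
#'
#' log10 body length evolves by Brownian motion; log10 body mass follows the
#' allometric line `a + b * log10(length)` plus Gaussian noise.
#'
#' @param tree `phylo` with branch lengths.
#' @param sigmaBM Brownian-motion standard deviation per unit branch length
#'   (log10 mm units), > 0.
#' @param allometry numeric `c(a, b, s)`: intercept, slope and residual sd of
#'   the log10 mass ~ log10 length relation. The default
#'   `c(-4, 3, 0.05)` encodes isometric mass scaling of a mm-scale animal.
#' @param rootState root log10 body length (default 1.5, i.e. ~32 mm).
#' @param seed integer seed or NULL.
#' @return data.frame: `Species`, `log10_length`, `log10_mass`,
#'   `BodyLength_mm`, `BodyMass_g`.
#' @export
simulateContinuousTraits <- function(tree, sigmaBM = 0.3,
                                     allometry = c(-4, 3, 0.05),
                                     rootState = 1.5, seed = NULL) {
  if (sigmaBM <= 0) stop("'sigmaBM' must be > 0")
  if (length(allometry) != 3 || allometry[3] < 0)
    stop("'allometry' must be c(intercept, slope, sd >= 0)")
  .withSeed(seed, function() {
    logL <- ape::rTraitCont(tree, model = "BM", sigma = sigmaBM,
                            root.value = rootState)
    n <- length(logL)
    logM <- allometry[1] + allometry[2] * logL + rnorm(n, 0, allometry[3])
    data.frame(Species = names(logL), log10_length = unname(logL),
               log10_mass = unname(logM),
               BodyLength_mm = unname(10^logL), BodyMass_g = unname(10^logM),
               stringsAsFactors = FALSE)
  })
}

# Default liability thresholds giving field-realistic prevalences at
# unit liability variance: Diu/Noc ~ 0.5, Ter 0.6, Arb 0.3, Aqu 0.2,
# Fos 0.15, Aer 0.1.
.defaultThresholds <- function(attributes, liabilitySigma) {
  prev <- c(Diu = 0.5, Noc = 0.5, Fos = 0.15, Ter = 0.6, Aqu = 0.2,
            Arb = 0.3, Aer = 0.1)
  th <- qnorm(1 - prev[attributes]) * liabilitySigma
  names(th) <- attributes
  th
}

#' Simulate binary traits under the threshold (liability) model
#'
#' Each attribute has a Brownian-motion liability on the tree (root 0); the
#' binary state is `liability > threshold`. With `repair = TRUE` (the
#' default), all-zero microhabitat rows and all-zero activity rows are
#' repaired by switching on the category whose liability is closest to its
#' threshold, so every species has >= 1 microhabitat and is diurnal and/or
#' nocturnal, as the trait schema guarantees.
#'
#' @param tree `phylo` with branch lengths.
#' @param attributes attribute names (non-empty); defaults to the seven
#'   activity + microhabitat columns.
#' @param liabilitySigma BM sd of the liabilities, > 0.
#' @param thresholds named per-attribute thresholds; default chosen to give
#'   realistic prevalences (see Details).
#' @param repair logical; repair all-zero category groups (default TRUE).
#' @param seed integer seed or NULL.
#' @return integer matrix species x attributes.
#' @export
simulateBinaryTraits <- function(tree, attributes = binaryAttributes(),
                                 liabilitySigma = 1, thresholds = NULL,
                                 repair = TRUE, seed = NULL) {
  if (!length(attributes)) stop("'attributes' must be non-empty")
  if (liabilitySigma <= 0) stop("'liabilitySigma' must be > 0")
  if (is.null(thresholds)) {
    known <- intersect(attributes, .BIN_ATTRS)
    thresholds <- setNames(numeric(length(attributes)), attributes)
    thresholds[known] <- .defaultThresholds(known, liabilitySigma)
  }
  if (!all(attributes %in% names(thresholds)))
    stop("'thresholds' must name every attribute")
  .withSeed(seed, function() {
    n <- length(tree$tip.label)
    liab <- sapply(attributes, function(a)
      ape::rTraitCont(tree, model = "BM", sigma = liabilitySigma,
                      root.value = 0))
    liab <- matrix(liab, nrow = n,
                   dimnames = list(tree$tip.label, attributes))
    th <- thresholds[attributes]
    bin <- t(t(liab) > th) * 1L
    storage.mode(bin) <- "integer"
    if (repair) {
      for (grp in list(.MICRO_ATTRS, .ACT_ATTRS)) {
        g <- intersect(attributes, grp)
        if (length(g) < 1) next
        zero <- rowSums(bin[, g, drop = FALSE]) == 0
        if (any(zero)) {
          excess <- t(t(liab[, g, drop = FALSE]) - th[g])
          pick <- g[max.col(excess[zero, , drop = FALSE], "first")]
          bin[cbind(which(zero), match(pick, attributes))] <- 1L
        }
      }
    }
    bin
  })
}

#' Simulate contiguous-block species ranges over linear grid cells
#'
#' Each species occupies a contiguous block of cells whose width increases
#' monotonically with the rank of `sizeCovariate` (ties share a width), so
#' larger-"ranged" species occupy more cells; every species occupies at
#' least one cell.
#'
#' @param tree `phylo` (supplies species ids and count).
#' @param nCells number of grid cells (>= 1).
#' @param sizeCovariate per-tip numeric driving range size (e.g. log body
#'   length).
#' @param seed integer seed or NULL.
#' @return binary species x cell matrix.
#' @export
simulateRanges <- function(tree, nCells, sizeCovariate, seed = NULL) {
  n <- length(tree$tip.label)
  if (nCells < 1) stop("'nCells' must be >= 1")
  nCells <- as.integer(nCells)
  if (length(sizeCovariate) != n)
    stop("'sizeCovariate' must have one value per tip")
  .withSeed(seed, function() {
    r <- rank(sizeCovariate, ties.method = "average")
    w <- if (n == 1) nCells else
      1L + as.integer(floor((r - 1) / (n - 1) * (nCells - 1)))
    start <- vapply(w, function(wi) sample.int(nCells - wi + 1L, 1L), 1L)
    m <- matrix(0L, n, nCells,
                dimnames = list(tree$tip.label, sprintf("cell%03d", 1:nCells)))
    for (i in seq_len(n)) m[i, start[i]:(start[i] + w[i] - 1L)] <- 1L
    m
  })
}

#' Simulate a complete synthetic clade
#'
#' Bundles tree, nested taxonomy, complete traits (continuous size with
#' allometric mass, threshold-model binary traits, an `Assessed` threat
#' column) and assemblage membership into one [SimulatedClade-class].
#'
#' @param nTips,nFamilies,nGenera,nCells clade dimensions.
#' @param sigmaBM,allometry,rootState see [simulateContinuousTraits()].
#' @param liabilitySigma,thresholds see [simulateBinaryTraits()].
#' @param model,birth,death see [simulateTree()].
#' @param seed integer seed (stored in the object).
#' @return A [SimulatedClade-class].
#' @export
#' @examples
#' cl <- simulateClade(nTips = 30, seed = 7)
#' cl
simulateClade <- function(nTips = 200, nFamilies = 5, nGenera = 25,
                          nCells = 50, sigmaBM = 0.3,
                          allometry = c(-4, 3, 0.05), rootState = 1.5,
                          liabilitySigma = 1, thresholds = NULL,
                          model = "yule", birth = 1, death = 0, seed = 1) {
  nGenera <- min(nGenera, nTips)
  nFamilies <- min(nFamilies, nGenera)
  .withSeed(seed, function() {
    tree <- simulateTree(nTips, model = model, birth = birth, death = death)
    tax <- assignTaxonomy(tree, nFamilies, nGenera)
    cont <- simulateContinuousTraits(tree, sigmaBM, allometry, rootState)
    bin <- simulateBinaryTraits(tree, liabilitySigma = liabilitySigma,
                                thresholds = thresholds)
    asm <- simulateRanges(tree, nCells, cont$log10_length)
    d <- data.frame(tax, cont[match(tax$Species, cont$Species),
                              c("BodyLength_mm", "BodyMass_g")],
                    bin[tax$Species, , drop = FALSE],
                    Assessed = 1L, stringsAsFactors = FALSE)
    rownames(d) <- NULL
    new("SimulatedClade", tree = tree, taxonomy = tax,
        traits = TraitTable(d), assemblages = asm, seed = as.integer(seed))
  })
}

#' @rdname simulateClade
#' @param x a `SimulatedClade`.
#' @export
cladeTree <- function(x) x@tree

#' @rdname simulateClade
#' @export
cladeTaxonomy <- function(x) x@taxonomy

#' @rdname simulateClade
#' @export
cladeTraits <- function(x) x@traits

#' @rdname simulateClade
#' @export
cladeAssemblages <- function(x) x@assemblages

setMethod("show", "SimulatedClade", function(object) {
  cat("SimulatedClade:", length(object@tree$tip.label), "tips,",
      length(unique(object@taxonomy$Genus)), "genera,",
      length(unique(object@taxonomy$Family)), "families,",
      ncol(object@assemblages), "assemblage cells (seed",
      paste0(object@seed, ")"), "\n")
  invisible(NULL)
})
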