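test_that("simulated trees are ultrametric, bifurcating, depth-1 and reproducible", {
  tr <- simulateTree(2, seed = 1)
  depths <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(depths[1], depths[2], tolerance = 1e-12)

  tr16a <- simulateTree(16, seed = 42)
  tr16b <- simulateTree(16, seed = 42)
  expect_identical(ape::write.tree(tr16a), ape::write.tree(tr16b))
  expect_equal(tr16a$Nnode, 15L)
  expect_true(ape::is.binary(tr16a))
  expect_equal(max(ape::node.depth.edgelength(tr16a)), 1, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(tr16a, tol = 1e-9))

  expect_error(simulateTree(1), "nTips")
})

test_that("taxonomy cuts are monophyletic-compatible and nest genus in family", {
  tr <- simulateTree(24, seed = 3)
  tax1 <- assignTaxonomy(tr, 1, 1)
  expect_equal(length(unique(tax1$Genus)), 1L)
  expect_equal(length(unique(tax1$Family)), 1L)

  taxAll <- assignTaxonomy(tr, 4, 24)
  expect_equal(length(unique(taxAll$Genus)), 24L)

  for (s in 1:5) {
    tax <- assignTaxonomy(simulateTree(20, seed = s), 3, 7)
    g2f <- unique(tax[, c("Genus", "Family")])
    expect_false(anyDuplicated(g2f$Genus) > 0)
    expect_equal(length(unique(tax$Genus)), 7L)
    expect_equal(length(unique(tax$Family)), 3L)
  }

  expect_error(assignTaxonomy(tr, 2, 30), "maximum")
})

test_that("continuous traits follow the allometry and the BM covariance structure", {
  tr <- simulateTree(20, seed = 7)
  ct <- simulateContinuousTraits(tr, sigmaBM = 0.3,
                                 allometry = c(-4, 3, 0), seed = 1)
  expect_equal(ct$log10_mass, 3 * ct$log10_length - 4, tolerance = 1e-12)

  ct0 <- simulateContinuousTraits(tr, sigmaBM = 1e-9, seed = 1)
  expect_equal(ct0$log10_length, rep(1.5, 20), tolerance = 1e-6)

  # siblings on short branches resemble each other more than distant tips
  txt <- "((A:0.1,B:0.1):0.9,(C:0.5,D:0.5):0.5);"
  tr4 <- ape::read.tree(text = txt)
  dAB <- dAC <- numeric(200)
  for (i in 1:200) {
    x <- simulateContinuousTraits(tr4, sigmaBM = 1, seed = i)
    v <- setNames(x$log10_length, x$Species)
    dAB[i] <- (v["A"] - v["B"])^2
    dAC[i] <- (v["A"] - v["C"])^2
  }
  expect_lt(mean(dAB), mean(dAC))
})

test_that("threshold-model binary traits honour thresholds, repair and prevalence", {
  tr <- simulateTree(10, seed = 2)
  allOn <- simulateBinaryTraits(tr, "Ter", thresholds = c(Ter = -Inf),
                                seed = 1)
  expect_true(all(allOn[, "Ter"] == 1))
  allOff <- simulateBinaryTraits(tr, "Ter", thresholds = c(Ter = Inf),
                                 repair = FALSE, seed = 1)
  expect_true(all(allOff[, "Ter"] == 0))

  # repair guarantees >= 1 microhabitat and >= 1 activity state
  cl <- simulateClade(nTips = 150, seed = 9)
  d <- traitData(cladeTraits(cl))
  expect_true(all(rowSums(d[, c("Fos", "Ter", "Aqu", "Arb", "Aer")]) >= 1))
  expect_true(all(d$Diu + d$Noc >= 1))

  # prevalence on independent tips matches the liability tail probability
  star <- ape::stree(500, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$root.edge <- 0
  b <- simulateBinaryTraits(star, "Aqu",
                            thresholds = c(Aqu = qnorm(0.8)),
                            repair = FALSE, seed = 11)
  expect_lt(abs(mean(b[, "Aqu"]) - 0.2), 3 * sqrt(0.2 * 0.8 / 500) + 1e-9)
})

test_that("range blocks are contiguous and track the size covariate", {
  tr <- simulateTree(12, seed = 4)
  one <- simulateRanges(tr, 1, rnorm(12), seed = 1)
  expect_true(all(one == 1))

  const <- simulateRanges(tr, 20, rep(2, 12), seed = 1)
  expect_equal(length(unique(rowSums(const))), 1L)

  rc <- vapply(1:50, function(s) {
    cov <- rnorm(40)
    m <- simulateRanges(simulateTree(40, seed = s), 30, cov, seed = s)
    expect_true(all(rowSums(m) >= 1))
    # contiguity: occupied cells form one run
    expect_true(all(apply(m, 1, function(r) {
      occ <- which(r == 1)
      all(diff(occ) == 1)
    })))
    suppressWarnings(rankCorrelation(cov, rowSums(m)))
  }, 0)
  expect_true(all(rc >= 0.9))
})

test_that("imposed missingness honours rates, mechanisms and the shared factor", {
  cl <- simulateClade(nTips = 500, nGenera = 20, seed = 21)
  tt <- cladeTraits(cl)

  none <- imposeMissingness(tt, missingnessSpec(rate = 0, coef = 0), seed = 1)
  expect_equal(sum(none$mask), 0L)

  hid <- imposeMissingness(tt, missingnessSpec("body_length", rate = 1),
                           seed = 1)
  expect_true(all(hid$mask[, "body_length"]))
  expect_true(all(is.na(traitData(hid$table)$BodyLength_mm)))

  # under MCAR, missingness is unrelated to the trait value
  logL <- log10(traitData(tt)$BodyLength_mm)
  rs <- vapply(1:200, function(s) {
    m <- imposeMissingness(tt, missingnessSpec("body_length", rate = 0.3,
                                               coef = 0), seed = s)$mask
    cor(as.numeric(m[, "body_length"]), logL)
  }, 0)
  expect_lt(abs(mean(rs)), 0.05)

  # MNAR with negative coefficient targets small-bodied species
  below <- logL < median(logL)
  hits <- vapply(1:100, function(s) {
    m <- imposeMissingness(tt, missingnessSpec("body_length", "MNAR",
                                               rate = 0.3, coef = -1),
                           seed = s)$mask[, "body_length"]
    mean(m[below]) > mean(m[!below])
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  # the shared latent factor concentrates gaps on the same species
  nMulti <- function(strength, s) {
    m <- imposeMissingness(tt, missingnessSpec(rate = 0.3, coef = 0,
                                               sharedGapStrength = strength),
                           seed = s)$mask
    sum(rowSums(m) >= 2)
  }
  shared <- vapply(1:200, function(s) nMulti(0.9, s), 0)
  indep <- vapply(1:200, function(s) nMulti(0, s + 1000), 0)
  expect_gt(mean(shared), mean(indep))

  # reproducibility of the full generator under a fixed seed
  a <- imposeMissingness(tt, missingnessSpec(rate = 0.3), seed = 5)
  b <- imposeMissingness(tt, missingnessSpec(rate = 0.3), seed = 5)
  expect_identical(a$mask, b$mask)
  expect_identical(traitData(a$table), traitData(b$table))
  c1 <- simulateClade(nTips = 40, seed = 8)
  c2 <- simulateClade(nTips = 40, seed = 8)
  expect_identical(traitData(cladeTraits(c1)), traitData(cladeTraits(c2)))
  expect_identical(ape::write.tree(cladeTree(c1)), ape::write.tree(cladeTree(c2)))
})

test_that("MAR missingness requires a usable driver", {
  cl <- simulateClade(nTips = 30, seed = 2)
  spec <- missingnessSpec("activity_time", "MAR", rate = 0.3,
                          driver = "BodyLength_mm")
  m <- imposeMissingness(cladeTraits(cl), spec, seed = 1)
  expect_true(is.matrix(m$mask))
  # a driver with missing values is an invalid configuration
  tt2 <- m$table
  spec2 <- missingnessSpec("body_mass", "MAR", rate = 0.3, driver = "Diu")
  if (any(is.na(traitData(tt2)$Diu)))
    expect_error(imposeMissingness(tt2, spec2, seed = 1), "driver")
  expect_error(missingnessSpec("body_mass", "MAR", rate = 0.3),
               "driver")
})
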