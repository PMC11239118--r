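test_that("verticality and nocturnality reproduce every anchor value", {
  # microhabitat anchors
  expect_equal(verticalityScore(1, 0, 0, 0, 0), 0)     # strictly fossorial
  expect_equal(verticalityScore(1, 1, 0, 0, 0), 0.25)  # fossorial+terrestrial
  expect_equal(verticalityScore(0, 1, 0, 0, 0), 0.5)   # strictly terrestrial
  expect_equal(verticalityScore(0, 0, 1, 0, 0), 0.5)   # strictly aquatic
  expect_equal(verticalityScore(0, 1, 0, 1, 0), 0.75)  # terrestrial+arboreal
  expect_equal(verticalityScore(0, 0, 0, 1, 0), 1)     # strictly arboreal
  expect_equal(verticalityScore(0, 0, 0, 0, 1), 1)     # strictly aerial
  # unanchored combination defined by the mean-of-levels rule
  expect_equal(verticalityScore(0, 0, 1, 1, 0), 0.75)  # aquatic+arboreal

  expect_equal(nocturnalityScore(1, 0), 0)
  expect_equal(nocturnalityScore(1, 1), 0.5)
  expect_equal(nocturnalityScore(0, 1), 1)

  expect_error(verticalityScore(0, 0, 0, 0, 0), "at least one")
  expect_error(nocturnalityScore(0, 0), "at least one")
  expect_equal(verticalityScore(NA, NA, NA, NA, NA), NA_real_)
})

test_that("attribute properties use geometric / score means", {
  expect_equal(geometricMean(c(10, 1000)), 100)
  expect_equal(geometricMean(42), 42)
  set.seed(1)
  v <- 10^runif(9, 0, 3)
  expect_equal(geometricMean(v), geometricMean(rev(v)))
  expect_error(geometricMean(c(1, -1)), "positive")

  expect_equal(attributeProperty(c(0, 1), "score"), 0.5)
  expect_equal(attributeProperty(100, "continuous"), 100)
  # concatenating equal-property groups preserves the property
  g1 <- c(10, 1000); g2 <- c(50, 200)
  expect_equal(attributeProperty(c(g1, g2), "continuous"),
               attributeProperty(g1, "continuous"))
  s1 <- c(0, 1); s2 <- c(0.5, 0.5)
  expect_equal(attributeProperty(c(s1, s2), "score"),
               attributeProperty(s1, "score"))
})

test_that("relative change follows the printed formula with both conventions", {
  expect_equal(relativeChange(100, 100), 0)
  expect_equal(relativeChange(100, 110), -0.1)
  expect_equal(relativeChange(100, 90), 0.1)
  expect_warning(rc0 <- relativeChange(0, 5))
  expect_true(is.na(rc0))

  cl <- simulateClade(nTips = 40, seed = 6)
  cr <- changeReport(cladeTraits(cl), by = "Family")
  expect_true(all(cr$relative_change == 0, na.rm = TRUE))
  expect_equal(cr$relative_change_alt, -cr$relative_change)
  expect_true(all(cr$n_imputed == 0))
})

test_that("Kruskal-Wallis matches the hand calculation and is rank invariant", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(round(kw["H"], 3)), 3.857)

  same <- kruskalWallis(list(c(1, 5, 9), c(9, 1, 5)))
  expect_equal(unname(same["H"]), 0)

  g <- list(rnorm(8), rnorm(8) + 1, rnorm(8))
  a <- kruskalWallis(g)
  b <- kruskalWallis(lapply(g, function(x) exp(x)))
  expect_equal(a["H"], b["H"])

  expect_error(kruskalWallis(list(1:3)), ">= 2 groups")
  expect_error(kruskalWallis(list(1:3, numeric())), "empty")
})

test_that("rank correlation uses mid-ranks", {
  expect_equal(rankCorrelation(1:5, c(2, 4, 8, 16, 32)), 1)
  expect_equal(rankCorrelation(1:5, -(1:5)^3), -1)
  x <- c(1, 2, 2, 3)
  expect_equal(rankCorrelation(x, x), 1)
  expect_warning(rankCorrelation(rep(1, 4), 1:4), "constant")
})

test_that("assemblage properties match a brute-force recomputation", {
  cl <- simulateClade(nTips = 50, nCells = 12, seed = 19)
  tt <- cladeTraits(cl)
  memb <- cladeAssemblages(cl)
  ap <- assemblageProperty(tt, memb, "BodyLength_mm", "comb")
  d <- traitData(tt)
  for (j in seq_len(ncol(memb))) {
    sp <- rownames(memb)[memb[, j] == 1]
    if (!length(sp)) next
    v <- d$BodyLength_mm[match(sp, d$Species)]
    expect_equal(ap$average[j], geometricMean(v))
    expect_equal(ap$completeness[j], 1)
  }
  # single-species cell equals that species' value
  m1 <- matrix(c(1, rep(0, 49)), ncol = 1,
               dimnames = list(d$Species, "solo"))
  expect_equal(assemblageProperty(tt, m1, "BodyLength_mm", "comb")$average,
               d$BodyLength_mm[1])

  bad <- memb
  rownames(bad)[1] <- "ghost"
  expect_error(assemblageProperty(tt, bad, "BodyLength_mm", "comb"),
               "ghost")
})

test_that("changeReport separates observed-only and combined properties", {
  cl <- simulateClade(nTips = 90, nGenera = 6, seed = 23)
  mis <- imposeMissingness(cladeTraits(cl),
                           missingnessSpec(rate = 0.25), seed = 24)
  fs <- deriveFilters(treeToCovariance(cladeTree(cl)))
  res <- multiplyImpute(mis$table, fs,
                        imputationConfig(kDonors = 5, mImputations = 2,
                                         nFolds = 2, seed = 25))
  filled <- applyImputations(mis$table, res)
  cr <- changeReport(filled, by = "Family")
  # observed-only property ignores imputed cells: recompute one group
  d <- traitData(filled)
  p <- provenance(filled)
  fam <- d$Family == d$Family[1]
  obsVals <- d$BodyLength_mm[fam & p[, "BodyLength_mm"] == "observed"]
  row <- cr[cr$taxon == d$Family[1] & cr$attribute == "BodyLength_mm", ]
  expect_equal(row$property_obs, geometricMean(obsVals))
  expect_equal(row$n_obs, length(obsVals))
  combVals <- d$BodyLength_mm[fam & !is.na(d$BodyLength_mm)]
  expect_equal(row$property_comb, geometricMean(combVals))
  expect_equal(row$relative_change,
               1 - row$property_comb / row$property_obs)
})
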