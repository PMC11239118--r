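smallSpec <- function() tuningSpec(nroundsRange = c(10, 40),
                                   nDrawsStage1 = 8, nDrawsStage2 = 8,
                                   topFraction = 0.25)

test_that("two-stage tuning search is boxed, deterministic and beats the mean", {
  set.seed(3)
  x <- matrix(rnorm(240), 60, 4)
  y <- 2 * x[, 1]
  tun <- tuneHyperparameters(x, y, "regression", smallSpec(), nFolds = 3,
                             seed = 5)
  tr <- tun$trace
  s1 <- tr[tr$stage == 1, ]
  s2 <- tr[tr$stage == 2, ]
  for (p in c("eta", "max_depth", "subsample", "min_child_weight",
              "nrounds")) {
    expect_gte(min(s2[[p]]), min(s1[[p]]))
    expect_lte(max(s2[[p]]), max(s1[[p]]))
  }
  tun2 <- tuneHyperparameters(x, y, "regression", smallSpec(), nFolds = 3,
                              seed = 5)
  expect_identical(tun$best, tun2$best)

  # a pure linear signal must be learned better than mean prediction
  expect_lt(tun$best$score, 1)

  expect_error(tuneHyperparameters(x, rep(1, 60), "regression",
                                   smallSpec()), "constant")
})

test_that("PMM draws nearest-donor observed values with uniform tie-breaking", {
  set.seed(1)
  expect_equal(pmmDraw(0.52, c(0.1, 0.5, 0.9), c(10, 20, 30), k = 1), 20)

  # equidistant donors with k = pool size are selected uniformly
  set.seed(2)
  draws <- replicate(10000, pmmDraw(0, rep(1, 4), 1:4, k = 4))
  freq <- tabulate(draws, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))

  y <- rnorm(20)
  p <- rnorm(20)
  for (i in 1:50) expect_true(pmmDraw(rnorm(1), p, y, k = 5) %in% y)

  expect_error(pmmDraw(1, numeric(), numeric(), 1), "empty")
  expect_error(pmmDraw(1, 1:3, 1:3, 4), "'k'")
})

test_that("the engine books m x folds x trees draws per cell and is deterministic", {
  cl <- simulateClade(nTips = 80, nGenera = 8, seed = 13)
  mis <- imposeMissingness(cladeTraits(cl),
                           missingnessSpec(c("body_length", "activity_time"),
                                           rate = 0.2), seed = 14)
  fsets <- makeFilterSets(cladeTree(cl), 2, seed = 1)
  cfg <- imputationConfig(kDonors = 5, mImputations = 3, nFolds = 2,
                          seed = 31)
  res <- multiplyImpute(mis$table, fsets, cfg)
  s <- imputationSummary(res)
  expect_true(all(s$n_draws == 3 * 2 * 2))

  # PMM keeps continuous estimates inside the observed range
  obs <- traitData(mis$table)$BodyLength_mm
  lens <- s[s$attribute == "BodyLength_mm", ]
  expect_true(all(lens$estimate >= min(obs, na.rm = TRUE)))
  expect_true(all(lens$estimate <= max(obs, na.rm = TRUE)))

  res2 <- multiplyImpute(mis$table, fsets, cfg)
  expect_identical(imputationDraws(res), imputationDraws(res2))

  # a table without gaps yields an empty result and an unchanged table
  full <- multiplyImpute(cladeTraits(cl), fsets, cfg)
  expect_equal(nrow(imputationDraws(full)), 0L)
  filledFull <- applyImputations(cladeTraits(cl), full)
  expect_identical(traitData(filledFull), traitData(cladeTraits(cl)))

  # observed cells are never altered by gap filling
  filled <- applyImputations(mis$table, res)
  keep <- !is.na(traitData(mis$table)$BodyLength_mm)
  expect_identical(traitData(filled)$BodyLength_mm[keep],
                   traitData(mis$table)$BodyLength_mm[keep])
  expect_true(all(provenance(filled)[!keep, "BodyLength_mm"] ==
                    "phylo_imputed"))
})

test_that("attributes with too few observed rows are skipped with a warning", {
  cl <- simulateClade(nTips = 30, seed = 3)
  mis <- imposeMissingness(cladeTraits(cl),
                           missingnessSpec("body_length", rate = 0.8),
                           seed = 4)
  fs <- deriveFilters(treeToCovariance(cladeTree(cl)))
  cfg <- imputationConfig(kDonors = 5, mImputations = 2, nFolds = 2,
                          seed = 1)
  expect_warning(res <- multiplyImpute(mis$table, fs, cfg), "skipped")
  expect_equal(nrow(imputationDraws(res)), 0L)
})

test_that("draw summaries use median / mean-majority and ignore draw order", {
  draws <- data.frame(Species = "s1", attribute = "BodyLength_mm",
                      tree = "t", fold = 1L, m = 1:3, value = c(1, 2, 3))
  res <- new("MultipleImputationResult", draws = draws,
             summary = data.frame(),
             objectives = c(BodyLength_mm = "regression"),
             config = imputationConfig())
  expect_equal(summarizeImputations(res)$estimate, 2)
  res@draws <- draws[c(3, 1, 2), ]
  expect_equal(summarizeImputations(res)$estimate, 2)

  bd <- data.frame(Species = "s1", attribute = "Noc", tree = "t",
                   fold = 1L, m = 1:4, value = c(1, 1, 0, 0))
  resb <- new("MultipleImputationResult", draws = bd,
              summary = data.frame(), objectives = c(Noc = "binary"),
              config = imputationConfig())
  sb <- summarizeImputations(resb)
  expect_equal(sb$estimate, 0.5)
  expect_equal(sb$majority, 1)
})

test_that("phylogenetic filters do not hurt imputation accuracy on average", {
  # average CV NRMSE for body length with true-tree filters vs a
  # no-information star-phylogeny filter, over 20 replicate clades
  deltas <- vapply(1:20, function(s) {
    cl <- simulateClade(nTips = 100, seed = 100 + s, sigmaBM = 0.5,
                        allometry = c(-4, 3, 0.3))
    star <- ape::stree(100, "star")
    star$edge.length <- rep(1, nrow(star$edge))
  star$root.edge <- 0
    star$tip.label <- cladeTree(cl)$tip.label
    cfg <- imputationConfig(kDonors = 5, mImputations = 2, nFolds = 3,
                            seed = 200 + s)
    tun <- list(BodyLength_mm = list(eta = 0.1, max_depth = 4,
                                     subsample = 0.9, min_child_weight = 1,
                                     nrounds = 60))
    withF <- crossValidate(cladeTraits(cl),
                           deriveFilters(treeToCovariance(cladeTree(cl))),
                           cfg, tuned = tun, attributes = "BodyLength_mm")
    noF <- crossValidate(cladeTraits(cl),
                         deriveFilters(treeToCovariance(star)),
                         cfg, tuned = tun, attributes = "BodyLength_mm")
    pick <- function(r) r$report$value[r$report$fold == "pooled" &
                                         r$report$metric == "nrmse"]
    pick(withF) - pick(noF)
  }, 0)
  expect_lte(mean(deltas), 0)
})
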