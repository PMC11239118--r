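test_that("TraitTable validity enforces the schema invariants", {
  tt <- makeSmallTable()
  expect_s4_class(tt, "TraitTable")
  d <- traitData(tt)

  d2 <- d; d2$Species[2] <- d2$Species[1]
  expect_error(TraitTable(d2), "unique")
  d3 <- d; d3$BodyLength_mm[1] <- -5
  expect_error(TraitTable(d3), "positive")
  d4 <- d; d4$Diu[1] <- 2
  expect_error(TraitTable(d4), "0/1")
  d5 <- d; d5[1, c("Fos", "Ter", "Aqu", "Arb", "Aer")] <- 0
  expect_error(TraitTable(d5), "microhabitat")

  # provenance is 'missing' exactly where a value is NA
  d6 <- d; d6$BodyMass_g[3] <- NA
  t6 <- TraitTable(d6)
  expect_equal(sum(isMissing(t6)), 1L)
  expect_equal(provenance(t6)[3, "BodyMass_g"], "missing")
})

test_that("TraitTable round-trips through CSV with provenance", {
  tt <- makeSmallTable()
  mis <- imposeMissingness(tt, missingnessSpec(rate = 0.4), seed = 2)
  f <- tempfile(fileext = ".csv")
  writeTraitTable(mis$table, f)
  back <- readTraitTable(f)
  expect_equal(traitData(back), traitData(mis$table))
  expect_identical(provenance(back), provenance(mis$table))
  unlink(c(f, paste0(f, ".provenance.csv")))
})

test_that("name resolution applies the four steps in order", {
  ref <- c("Aus bus", "Cus dus", "Eus fus")
  syn <- data.frame(
    name = c("Aus zus", "Cus dus", "Gus hus", "Gus hus"),
    valid_name = c("Aus bus", "Cus newname", "Aus bus", "Cus dus"),
    stringsAsFactors = FALSE)

  r <- resolveNames(c("Aus bus", "Aus zus", "Cus newname", "Qus qus"),
                    ref, syn)
  expect_equal(r$step, c(1L, 2L, 3L, 4L))
  expect_equal(r$matched_id, c("Aus bus", "Aus bus", "Cus dus", NA))
  # "Gus hus" maps to two valid names: not a unique synonym, never auto-used
  r2 <- resolveNames("Gus hus", ref, syn)
  expect_true(is.na(r2$matched_id))

  # duplicate entries per attribute are flagged once matched twice
  recs <- data.frame(name = c("Aus bus", "Aus zus", "Aus bus"),
                     attribute = c("len", "len", "mass"))
  r3 <- resolveNames(recs, ref, syn)
  expect_equal(r3$duplicate, c(FALSE, TRUE, FALSE))

  # idempotence: resolving already-matched ids changes nothing
  r4 <- resolveNames(r$matched_id[!is.na(r$matched_id)], ref, syn)
  expect_true(all(r4$step == 1L))
  expect_equal(r4$matched_id, r$matched_id[!is.na(r$matched_id)])

  expect_error(resolveNames("x", c("a", "a")), "unique")
})

test_that("stratum usage binarises at the inclusive 30% threshold", {
  expect_identical(binarizeStratumUsage(c(0.35, 0.30, 0.29, 0, 1)),
                   c(1L, 1L, 0L, 0L, 1L))
  expect_error(binarizeStratumUsage(1.2), "0, 1")
})

test_that("IQR outlier flags match a brute-force oracle and are scale invariant", {
  expect_identical(flagOutliersIQR(rep(7, 10)), rep(FALSE, 10))

  f <- flagOutliersIQR(c(10, 11, 12, 13, 14, 10000))
  expect_identical(which(f), 6L)

  set.seed(42)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    v <- 10^runif(n, 0, sample(1:4, 1))
    got <- flagOutliersIQR(v)
    l <- log10(v)
    q <- quantile(l, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    want <- l < q[1] - 1.5 * iqr | l > q[2] + 1.5 * iqr
    expect_identical(got, want)
    expect_identical(flagOutliersIQR(v * 1000), want)
  }

  expect_warning(flagOutliersIQR(c(1, 2, 3)), "fewer than 4")
})

test_that("allometric screen flags only genuine deviations", {
  l <- c(10, 20, 40, 80, 160, 320)
  m <- 10^(-4 + 3 * log10(l))
  expect_warning(out <- flagOutliersAllometric(l, m), "zero residual")
  expect_true(all(!out$flagged))

  m2 <- m; m2[4] <- m2[4] * 1000
  out2 <- flagOutliersAllometric(l, m2)
  expect_identical(which(out2$flagged), 4L)

  # unit changes never alter the flags
  set.seed(7)
  l3 <- 10^runif(30, 1, 3)
  m3 <- 10^(-4 + 3 * log10(l3) + rnorm(30, 0, 0.1))
  m3[5] <- m3[5] * 1e4
  a <- flagOutliersAllometric(l3, m3)
  b <- flagOutliersAllometric(l3 / 10, m3 * 1000)
  expect_identical(a$flagged, b$flagged)

  expect_warning(flagOutliersAllometric(l[1:4], m[1:4]), "< 5 complete")
})

test_that("taxonomic imputation applies the genus-share rule without overwriting", {
  d <- data.frame(
    Species = sprintf("sp%02d", 1:20),
    Genus = rep(c("GenHigh", "GenLow"), each = 10),
    Family = "FamA",
    BodyLength_mm = 50, BodyMass_g = 10,
    Diu = 0, Noc = 1, Fos = 0, Ter = 1, Aqu = 0, Arb = 0, Aer = 0,
    stringsAsFactors = FALSE)
  # GenHigh: 8 observed Noc=1, 2 missing -> 8/10 >= 0.70, fill both
  d$Noc[9:10] <- NA
  # GenLow: 6 observed Noc=1, 4 missing -> 6/10 < 0.70, leave missing
  d$Noc[17:20] <- NA
  tt <- TraitTable(d)
  out <- taxonomicImpute(tt)
  od <- traitData(out)
  expect_equal(od$Noc[9:10], c(1L, 1L))
  expect_true(all(provenance(out)[9:10, "Noc"] == "taxon_imputed"))
  expect_true(all(is.na(od$Noc[17:20])))

  # threshold 1 with any unobserved species: no imputation possible
  none <- taxonomicImpute(tt, threshold = 1)
  expect_true(all(is.na(traitData(none)$Noc[c(9:10, 17:20)])))

  # observed cells are never modified
  expect_identical(od$Noc[1:8], d$Noc[1:8])
  expect_true(all(provenance(out)[1:8, "Noc"] == "observed"))

  # observed-only denominator fills GenLow too (6/6 >= 0.70)
  alt <- taxonomicImpute(tt, denominator = "observed")
  expect_equal(traitData(alt)$Noc[17:20], rep(1L, 4))

  expect_warning(taxonomicImpute(tt, overrides = data.frame(
    group = "NoSuchGenus", attribute = "Aer", value = 1)), "not found")

  # overrides fill missing cells in the named group first
  d2 <- d
  d2$Aer <- NA
  tt2 <- TraitTable(d2)
  ov <- taxonomicImpute(tt2, overrides = data.frame(
    group = "GenHigh", attribute = "Aer", value = 1))
  expect_equal(traitData(ov)$Aer[1:10], rep(1L, 10))
  expect_true(all(provenance(ov)[1:10, "Aer"] == "taxon_imputed"))
})
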