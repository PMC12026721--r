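test_that("per-genotype scores follow the power-oriented table", {
  expect_identical(scoreGenotype("ACE", "DD"), 2L)
  expect_identical(scoreGenotype("PPARA", "GG"), 0L)
  expect_identical(scoreGenotype("CKM", "AG"), 1L)
  for (loc in names(oracleScoreTable))
    for (g in names(oracleScoreTable[[loc]]))
      expect_identical(scoreGenotype(loc, g),
                       as.integer(oracleScoreTable[[loc]][[g]]))
})

test_that("genotype labels are validated and order-normalized", {
  expect_identical(normalizeGenotype("ACE", "DI"), "ID")
  expect_identical(normalizeGenotype("CKM", "GA"), "AG")
  expect_identical(scoreGenotype("ACE", "DI"), 1L)
  expect_error(scoreGenotype("ACE", "DX"), "unknown allele symbol 'X'")
  expect_error(scoreGenotype("NOPE", "DD"), "unknown locus 'NOPE'")
  expect_error(normalizeGenotype("PPARA", "C"), "two allele symbols")
})

test_that("genotype score sums the three loci and checks completeness", {
  expect_identical(genotypeScore(c(ACE = "DD", PPARA = "CG", CKM = "AA")), 3L)
  expect_identical(genotypeScore(c(ACE = "II", PPARA = "GG", CKM = "AA")), 0L)
  expect_identical(genotypeScore(c(ACE = "DD", PPARA = "CC", CKM = "GG")), 6L)
  expect_error(genotypeScore(c(ACE = "DD", CKM = "AA")),
               "missing locus/loci: PPARA")
  expect_error(genotypeScore(c(ACE = "DD", ACE = "II", PPARA = "CG",
                               CKM = "AA")),
               "duplicate locus")
})

test_that("GS equals the brute-force sum for all 27 profiles", {
  for (profile in allProfiles()) {
    oracle <- sum(vapply(names(profile), function(loc)
      oracleScoreTable[[loc]][[profile[[loc]]]], numeric(1)))
    expect_identical(genotypeScore(profile), as.integer(oracle))
  }
})

test_that("TGS is GS * 100/6 on the centesimal lattice, ties up", {
  expect_equal(totalGeneticScore(3), 50)
  expect_equal(totalGeneticScore(0), 0)
  expect_equal(totalGeneticScore(6), 100)
  expect_equal(totalGeneticScore(4), 66.67)
  expect_equal(vapply(0:6, totalGeneticScore, numeric(1)),
               c(0, 16.67, 33.33, 50, 66.67, 83.33, 100))
  expect_error(totalGeneticScore(7), "0..6")
  expect_error(totalGeneticScore(-1), "0..6")
  expect_error(totalGeneticScore(2.5), "0..6")
})

test_that("TGS is strictly monotone and het substitution adds exactly 1", {
  tgs <- vapply(0:6, totalGeneticScore, numeric(1))
  expect_true(all(diff(tgs) > 0))
  for (profile in allProfiles()) {
    for (loc in names(profile)) {
      labs <- genotypeLabels(getLocus(loc))
      if (profile[[loc]] == labs[3L]) {  # endurance homozygote -> het
        upgraded <- profile
        upgraded[[loc]] <- labs[2L]
        expect_identical(genotypeScore(upgraded), genotypeScore(profile) + 1L)
      }
    }
  }
})

test_that("reversing the scheme maps GS to 6-GS and TGS to 100-TGS", {
  rev <- reverseScheme(powerScheme())
  for (profile in allProfiles()) {
    gs <- genotypeScore(profile)
    expect_identical(genotypeScore(profile, rev), 6L - gs)
    expect_equal(totalGeneticScore(genotypeScore(profile, rev)),
                 100 - totalGeneticScore(gs))
  }
})

test_that("metabolism classification matches the score-to-energy-system map", {
  expect_identical(classifyMetabolism(2), "Anaerobic")
  expect_identical(classifyMetabolism(1), "Mixed")
  expect_identical(classifyMetabolism(0), "Aerobic")
  expect_error(classifyMetabolism(3), "0, 1 or 2")
  # all 9 genotypes: homozygous power -> anaerobic, het -> mixed,
  # homozygous endurance -> aerobic
  wanted <- c("Anaerobic", "Mixed", "Aerobic")
  for (loc in names(builtinLoci()))
    expect_identical(
      vapply(genotypeLabels(getLocus(loc)), function(g)
        classifyMetabolism(scoreGenotype(loc, g)), character(1),
        USE.NAMES = FALSE),
      wanted)
})

test_that("orientation bands split the GS range 0-1 / 2-4 / 5-6", {
  expect_identical(classifyTgsOrientation(50), "mixed")
  expect_identical(classifyTgsOrientation(100), "power")
  expect_identical(classifyTgsOrientation(0), "aerobic")
  bands <- vapply(0:6, function(gs)
    classifyTgsOrientation(totalGeneticScore(gs)), character(1))
  expect_identical(bands, c("aerobic", "aerobic", "mixed", "mixed", "mixed",
                            "power", "power"))
  expect_error(classifyTgsOrientation(50, thresholds = c(70, 30)),
               "0 < low < high < 100")
  expect_error(classifyTgsOrientation(120), "\\[0, 100\\]")
})

test_that("scheme validity rejects out-of-range and non-intermediate scores", {
  bad <- powerScheme()
  expect_error({ bad@scoreMap$ACE[["ID"]] <- 2L; validObject(bad) },
               "strictly between")
  bad2 <- powerScheme()
  expect_error({ bad2@scoreMap$CKM[["GG"]] <- 5L; validObject(bad2) },
               "\\{0,1,2\\}")
})

test_that("tgsProfile assembles scores, TGS and orientation", {
  res <- tgsProfile(c(ACE = "DD", PPARA = "CG", CKM = "AA"))
  expect_identical(res$gs, 3L)
  expect_equal(res$tgs, 50)
  expect_identical(res$orientation, "mixed")
  expect_identical(res$perLocusScores, c(ACE = 2L, PPARA = 1L, CKM = 0L))
})
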