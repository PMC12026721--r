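test_that("cohort genotype frequencies reproduce the reference results", {
  co <- cohortFromGenotypeCounts()
  expect_identical(nAthletes(co), 24L)
  ace <- genotypeFrequencies(co, "ACE")
  expect_equal(genotypePct(ace), c(DD = 25, ID = 66.67, II = 8.33))
  expect_equal(allelePct(ace), c(D = 58.33, I = 41.67))
  ppara <- genotypeFrequencies(co, "PPARA")
  expect_equal(genotypePct(ppara), c(CC = 0, CG = 45.83, GG = 54.17))
  expect_equal(allelePct(ppara), c(C = 22.92, G = 77.08))
  ckm <- genotypeFrequencies(co, "CKM")
  expect_equal(genotypePct(ckm), c(GG = 8.33, AG = 29.17, AA = 62.50))
  expect_equal(allelePct(ckm), c(G = 22.92, A = 77.08))
})

test_that("reference counts round-trip through their printed percentages", {
  ref <- referenceGenotypeCounts()
  expect_identical(unname(sapply(ref, sum)), rep(24L, 3))
  for (loc in names(ref)) {
    pct <- genotypePct(frequencyTable(ref[[loc]], loc))
    expect_identical(countsFromPercentages(pct, 24)[names(ref[[loc]])],
                     ref[[loc]])
  }
})

test_that("missing genotypes error with athlete ids unless dropped", {
  co <- cohortFromGenotypeCounts()
  df <- athleteTable(co)
  df$ace_genotype[c(3, 5)] <- NA
  co2 <- Cohort(df)
  expect_error(genotypeFrequencies(co2, "ACE"), "A03, A05")
  expect_message(
    ft <- genotypeFrequencies(co2, "ACE", dropMissing = TRUE),
    "dropping 2")
  expect_identical(ft@n, 22L)
})

test_that("cohort validity catches duplicates, bad sex and bad labels", {
  df <- athleteTable(cohortFromGenotypeCounts())
  bad <- df; bad$athlete_id[2] <- bad$athlete_id[1]
  expect_error(Cohort(bad), "duplicate athlete_id")
  bad <- df; bad$sex[1] <- "U"
  expect_error(Cohort(bad), "sex must be F or M")
  bad <- df; bad$age_years[1] <- -3
  expect_error(Cohort(bad), "age_years")
  bad <- df; bad$ckm_genotype[1] <- "ZZ"
  expect_error(Cohort(bad), "unknown allele symbol")
})

test_that("BMI is derived from mass and height", {
  co <- makeCohort(list(c(ACE = "ID", PPARA = "CG", CKM = "AG")))
  expect_equal(unname(bmi(co)), 70 / 1.75^2)
})

test_that("per-athlete scoring and the orientation distribution agree", {
  co <- makeCohort(list(
    c(ACE = "II", PPARA = "GG", CKM = "AA"),   # GS 0 -> aerobic
    c(ACE = "DD", PPARA = "CG", CKM = "AA"),   # GS 3 -> mixed
    c(ACE = "DD", PPARA = "CC", CKM = "GG")))  # GS 6 -> power
  scored <- scoreCohort(co)
  expect_identical(scored$gs, c(0L, 3L, 6L))
  expect_equal(scored$tgs, c(0, 50, 100))
  expect_identical(scored$orientation, c("aerobic", "mixed", "power"))
  dist <- tgsDistribution(co)
  expect_identical(dist$table$count, c(1L, 1L, 1L))
  expect_equal(dist$table$pct, c(33.33, 33.33, 33.33))
  expect_equal(dist$meanTgs, 50)
  # homogeneous cohort collapses to one class
  mono <- makeCohort(rep(list(c(ACE = "DD", PPARA = "CC", CKM = "GG")), 4))
  dmono <- tgsDistribution(mono)
  expect_equal(dmono$table$pct[dmono$table$orientation == "power"], 100)
})

test_that("training summaries use the sample SD to one decimal", {
  co <- makeCohort(rep(list(c(ACE = "ID", PPARA = "CG", CKM = "AG")), 3),
                   technique = 300)
  s <- summarizeTraining(co)
  expect_equal(s$mean_min_wk[s$modality == "technique"], 300)
  expect_equal(s$sd_min_wk[s$modality == "technique"], 0)
  co2 <- makeCohort(rep(list(c(ACE = "ID", PPARA = "CG", CKM = "AG")), 2),
                    strength = c(100, 300))
  s2 <- summarizeTraining(co2)
  expect_equal(s2$mean_min_wk[s2$modality == "strength"], 200)
  expect_equal(s2$sd_min_wk[s2$modality == "strength"], 141.4)
  expect_error(summarizeTraining(Cohort(athleteTable(co)[0, ])),
               "empty")
})

test_that("the full report reproduces the reference cohort verbatim", {
  rep <- runReport(cohortFromGenotypeCounts())
  expect_identical(rep$n, 24L)
  expect_equal(allelePct(rep$frequencies$ACE), c(D = 58.33, I = 41.67))
  expect_equal(genotypePct(rep$frequencies$PPARA)[["GG"]], 54.17)
  expect_equal(genotypePct(rep$frequencies$CKM)[["AA"]], 62.50)
  expect_equal(sum(rep$orientation$count), 24L)
  expect_true(all(rep$hweP >= 0 & rep$hweP <= 1))
  expect_equal(rep$training$mean_min_wk, c(367.3, 188.5, 134.8))
  txt <- capture.output(print(rep))
  expect_true(any(grepl("D 58.33% / I 41.67%", txt)))
  out <- tempfile(fileext = ".json")
  writeReportJson(rep, out)
  parsed <- jsonlite::read_json(out)
  expect_equal(parsed$frequencies$ACE$allele_pct$D, 58.33)
})

test_that("a single power-homozygous athlete reports TGS 100, power", {
  co <- makeCohort(list(c(ACE = "DD", PPARA = "CC", CKM = "GG")))
  rep <- runReport(co)
  expect_equal(rep$athletes$tgs, 100)
  expect_identical(rep$athletes$orientation, "power")
})
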