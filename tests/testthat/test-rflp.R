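# expected digestion patterns, written out literally
digestOracle <- list(
  ACE = list(DD = 319, ID = c(319, 597), II = 597),
  PPARA = list(CC = c(216, 50), CG = c(266, 216, 50), GG = 266),
  CKM = list(GG = 359, AG = c(359, 206, 153), AA = c(206, 153))
)

test_that("expected fragment sets reproduce the digestion key", {
  for (loc in names(digestOracle))
    for (g in names(digestOracle[[loc]]))
      expect_setequal(expectedFragments(loc, g), digestOracle[[loc]][[g]])
  # heterozygote = union of the homozygote patterns
  for (loc in names(digestOracle)) {
    labs <- genotypeLabels(getLocus(loc))
    expect_setequal(expectedFragments(loc, labs[2L]),
                    union(expectedFragments(loc, labs[1L]),
                          expectedFragments(loc, labs[3L])))
  }
})

test_that("genotypes are called from clean and noisy band patterns", {
  expect_identical(callGenotype("ACE", 319), "DD")
  expect_identical(callGenotype("CKM", c(206, 153)), "AA")
  expect_identical(callGenotype("ACE", c(321, 594)), "ID")
  expect_identical(callGenotype("PPARA", c(264, 218, 52)), "CG")
  # duplicates collapse to a set
  expect_identical(callGenotype("ACE", c(319, 319, 597)), "ID")
})

test_that("calling is the exact inverse of the digestion key at tolerance 0", {
  for (loc in names(digestOracle))
    for (g in names(digestOracle[[loc]]))
      expect_identical(
        callGenotype(loc, digestOracle[[loc]][[g]], toleranceBp = 0),
        g)
})

test_that("unmatchable patterns raise no_call with the nearest candidate", {
  err <- tryCatch(callGenotype("ACE", 450), tgs_no_call = identity)
  expect_s3_class(err, "tgs_no_call")
  expect_identical(err$nearest, "DD")  # 450 is 131 bp from 319, 147 from 597
  expect_match(conditionMessage(err), "nearest")
  # an AG pattern whose 153 bp band dropped out is still nearest to AG
  err2 <- tryCatch(callGenotype("CKM", c(359, 206)), tgs_no_call = identity)
  expect_s3_class(err2, "tgs_no_call")
  expect_identical(err2$nearest, "AG")
})

test_that("over-wide tolerance raises an ambiguous call listing candidates", {
  err <- tryCatch(callGenotype("ACE", 450, toleranceBp = 300),
                  tgs_ambiguous_call = identity)
  expect_s3_class(err, "tgs_ambiguous_call")
  expect_setequal(err$candidates, c("DD", "II"))
})

test_that("a CG pattern missing its 266 bp band is indistinguishable from CC", {
  # documented hazard: presence of the uncut 266 bp product is the only
  # band separating PPARA CG from CC
  expect_identical(callGenotype("PPARA", c(216, 50)), "CC")
})

test_that("allowMissingSmallest recovers a pattern lacking the smallest band", {
  expect_error(callGenotype("PPARA", c(266, 216)), class = "tgs_no_call")
  expect_identical(
    callGenotype("PPARA", c(266, 216), allowMissingSmallest = TRUE), "CG")
  # must not create ambiguity where a full match exists
  expect_identical(
    callGenotype("PPARA", 266, allowMissingSmallest = TRUE), "GG")
})

test_that("fragment simulation is seeded, truncated and exact at zero noise", {
  expect_setequal(simulateFragments("PPARA", "GG", 0), 266)
  expect_setequal(simulateFragments("CKM", "AG", 0, seed = 7),
                  c(359, 206, 153))
  a <- simulateFragments("ACE", "ID", noiseSdBp = 2, seed = 1)
  b <- simulateFragments("ACE", "ID", noiseSdBp = 2, seed = 1)
  expect_identical(a, b)
  expect_true(all(abs(sort(a) - c(319, 597)) < 8))  # within 4 sd
  expect_true(all(simulateFragments("PPARA", "CC", noiseSdBp = 500,
                                    seed = 3) >= 1))
  expect_error(simulateFragments("ACE", "ID", noiseSdBp = -1),
               "non-negative")
})

test_that("caller inverts the simulator when tolerance covers the noise", {
  # tolerance of 5 sd: the perturbed bands essentially never escape it
  for (loc in names(digestOracle))
    for (g in names(digestOracle[[loc]]))
      for (seed in 1:40) {
        obs <- simulateFragments(loc, g, noiseSdBp = 2, seed = seed)
        expect_identical(callGenotype(loc, obs, toleranceBp = 10), g)
      }
})

test_that("batch calling records per-row status instead of stopping", {
  frg <- data.frame(
    athlete_id = c("A1", "A1", "A2", "A2", "A3"),
    locus = c("ACE", "CKM", "PPARA", "ACE", "PPARA"),
    fragments_bp = c("319;597", "206;153", "266;216;50", "450", "266;216"),
    stringsAsFactors = FALSE
  )
  out <- callRflpBatch(frg)
  expect_identical(out$called_genotype, c("ID", "AA", "CG", NA, NA))
  expect_identical(out$call_status, c("ok", "ok", "ok", "no_call", "no_call"))
  out2 <- callRflpBatch(frg, allowMissingSmallest = TRUE)
  expect_identical(out2$called_genotype[5], "CG")
  expect_identical(out2$call_status[5], "ok_missing_smallest")
  expect_error(callRflpBatch(frg[, 1:2]), "missing column")
})
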