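# brute-force HWE exact-test oracle: enumerates genotype triples with the
# observed allele counts, weights them by the multinomial coefficient times
# 2^het, normalizes numerically, and sums the triples no more probable than
# the observed one
hweOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  triples <- do.call(rbind, lapply(0:n, function(aa) {
    ab <- nA - 2 * aa
    bb <- n - aa - ab
    if (ab < 0 || bb < 0) NULL else c(aa, ab, bb)
  }))
  w <- exp(lfactorial(n) - lfactorial(triples[, 1]) - lfactorial(triples[, 2]) -
             lfactorial(triples[, 3]) + triples[, 2] * log(2))
  p <- w / sum(w)
  pObs <- p[triples[, 2] == nAB]
  min(1, sum(p[p <= pObs * (1 + 1e-12)]))
}

# per-genotype score table written out literally, as an oracle independent
# of the ScoringScheme machinery
oracleScoreTable <- list(
  ACE = c(DD = 2, ID = 1, II = 0),
  PPARA = c(CC = 2, CG = 1, GG = 0),
  CKM = c(GG = 2, AG = 1, AA = 0)
)

# all 27 three-locus profiles
allProfiles <- function() {
  grid <- expand.grid(ACE = names(oracleScoreTable$ACE),
                      PPARA = names(oracleScoreTable$PPARA),
                      CKM = names(oracleScoreTable$CKM),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ]))
}

# tiny hand-built cohort from a list of named profiles
makeCohort <- function(profiles, technique = 300, strength = 200,
                       aerobic = 100) {
  n <- length(profiles)
  Cohort(data.frame(
    athlete_id = sprintf("X%02d", seq_len(n)),
    sex = rep(c("F", "M"), length.out = n),
    age_years = 25, body_mass_kg = 70, height_cm = 175,
    ace_genotype = vapply(profiles, `[[`, character(1), "ACE"),
    ppara_genotype = vapply(profiles, `[[`, character(1), "PPARA"),
    ckm_genotype = vapply(profiles, `[[`, character(1), "CKM"),
    technique_min_wk = rep_len(technique, n),
    strength_min_wk = rep_len(strength, n),
    aerobic_min_wk = rep_len(aerobic, n),
    stringsAsFactors = FALSE
  ))
}
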