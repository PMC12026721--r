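#' @include AllClasses.R cohort.R
NULL

# truncated-normal sampling by rejection: exact and fast enough at cohort
# scale; guards against pathological bounds with a large cap
rtruncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    tries <- tries + 1L
    if (tries > 10000L)
      tgsStop("truncation bounds reject essentially all mass")
  }
  out[seq_len(n)]
}

#' Generator spec mirroring the reference elite point-fighting cohort
#'
#' The default [CohortSpec-class]: 24 athletes (12 women, 12 men),
#' per-locus genotype probabilities equal to the reference cohort's
#' genotype frequencies (ACE II .0833 / ID .6667 / DD .25; PPARA CC 0 /
#' CG .4583 / GG .5417; CKM AA .625 / AG .2917 / GG .0833), age
#' 22.1 +/- 5.8 y, body mass 66.1 +/- 15.4 kg, height 173.0 +/- 9.5 cm,
#' and weekly training minutes technique 367.3 +/- 153.1, strength
#' 188.5 +/- 122.3, aerobic 134.8 +/- 95.5. Variables are generated
#' independently (marginals only); truncation bounds are plausible
#' elite-athlete ranges (age >= 14, height 140-210 cm, mass 40-120 kg,
#' minutes >= 0).
#'
#' @param n cohort size (default 24; the sex split scales
#'   proportionally).
#' @param seed integer seed stored in the spec.
#' @return a [CohortSpec-class].
#' @export
#' @examples
#' pfCohortSpec()
pfCohortSpec <- function(n = 24, seed = 1) {
  n <- as.integer(n)
  nF <- as.integer(round(n / 2))
  new("CohortSpec",
    n = n,
    sexSplit = c(nF, n - nF),
    genotypeProbs = list(
      ACE = c(DD = 0.25, ID = 0.6667, II = 0.0833) / 1.0000,
      PPARA = c(CC = 0.0, CG = 0.4583, GG = 0.5417),
      CKM = c(GG = 0.0833, AG = 0.2917, AA = 0.625)
    ),
    anthropometry = list(
      age_years = c(mean = 22.1, sd = 5.8, lower = 14, upper = 60),
      body_mass_kg = c(mean = 66.1, sd = 15.4, lower = 40, upper = 120),
      height_cm = c(mean = 173.0, sd = 9.5, lower = 140, upper = 210)
    ),
    training = list(
      technique_min_wk = c(mean = 367.3, sd = 153.1),
      strength_min_wk = c(mean = 188.5, sd = 122.3),
      aerobic_min_wk = c(mean = 134.8, sd = 95.5)
    ),
    seed = as.integer(seed))
}

#' @describeIn CohortSpec-class draw a cohort from the spec. One integer
#'   seed fully determines the output; genotypes and continuous variables
#'   use independent sub-streams, so adding a variable cannot perturb the
#'   genotype draws. Genotype probabilities given as `powerAlleleFreq`
#'   expand to Hardy-Weinberg proportions p^2 / 2pq / q^2.
#' @param spec a `CohortSpec`.
#' @param seed optional override of the spec's stored seed.
#' @export
setMethod("simulateCohort", "CohortSpec", function(spec, seed = NULL) {
  seed <- if (is.null(seed)) spec@seed else as.integer(seed)
  n <- spec@n
  genos <- list()
  set.seed(subSeed(seed, 1L))
  for (loc in names(genotypeColumn)) {
    p <- spec@genotypeProbs[[loc]]
    if (identical(names(p), "powerAlleleFreq")) {
      labs <- genotypeLabels(getLocus(loc))
      q <- unname(p)
      p <- stats::setNames(c(q^2, 2 * q * (1 - q), (1 - q)^2), labs)
    }
    p <- p / sum(p)
    genos[[genotypeColumn[[loc]]]] <-
      sample(names(p), n, replace = TRUE, prob = p)
  }
  set.seed(subSeed(seed, 2L))
  cont <- list()
  for (v in names(spec@anthropometry)) {
    par <- spec@anthropometry[[v]]
    cont[[v]] <- round(rtruncNorm(n, par[["mean"]], par[["sd"]],
                                  par[["lower"]], par[["upper"]]), 1)
  }
  for (v in names(spec@training)) {
    par <- spec@training[[v]]
    cont[[v]] <- round(rtruncNorm(n, par[["mean"]], par[["sd"]], lower = 0), 1)
  }
  Cohort(data.frame(
    athlete_id = sprintf("S%03d", seq_len(n)),
    sex = rep(c("F", "M"), times = spec@sexSplit),
    age_years = cont$age_years,
    body_mass_kg = cont$body_mass_kg,
    height_cm = cont$height_cm,
    ace_genotype = genos$ace_genotype,
    ppara_genotype = genos$ppara_genotype,
    ckm_genotype = genos$ckm_genotype,
    technique_min_wk = cont$technique_min_wk,
    strength_min_wk = cont$strength_min_wk,
    aerobic_min_wk = cont$aerobic_min_wk,
    stringsAsFactors = FALSE
  ))
})

#' Simulate genotype counts under Hardy-Weinberg proportions
#'
#' Draws one multinomial sample of genotype counts with probabilities
#' p^2 / 2pq / q^2, where p is the power-allele frequency. Used to
#' calibrate [hweExactTest()] under the null.
#'
#' @param locus a [Locus-class] or locus name.
#' @param powerAlleleFreq power-allele frequency p in \[0, 1\].
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return named integer vector of genotype counts (canonical label
#'   order).
#' @export
#' @examples
#' simulateFromAlleleFreqs("ACE", 0.5, 24, seed = 1)
simulateFromAlleleFreqs <- function(locus, powerAlleleFreq, n, seed = NULL) {
  locus <- getLocus(locus)
  if (!is.numeric(powerAlleleFreq) || powerAlleleFreq < 0 || powerAlleleFreq > 1)
    tgsStop("powerAlleleFreq must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- powerAlleleFreq
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stats::setNames(as.integer(stats::rmultinom(1L, n, probs)),
                  genotypeLabels(locus))
}
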