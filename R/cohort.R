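#' @include AllClasses.R frequencies.R scoring.R
NULL

#' @describeIn Cohort-class number of athletes.
#' @param x a `Cohort`.
#' @export
setMethod("nAthletes", "Cohort", function(x) nrow(x@records))

#' @describeIn Cohort-class the records as a data.frame.
#' @export
setMethod("athleteTable", "Cohort", function(x) x@records)

#' @describeIn Cohort-class athlete identifiers, in record order.
#' @export
setMethod("athleteIds", "Cohort", function(x) x@records$athlete_id)

#' Body-mass index of every athlete
#'
#' BMI is derived, never stored: mass in kg divided by squared height in
#' metres.
#'
#' @param cohort a [Cohort-class].
#' @return named numeric vector of BMI (kg m^-2) keyed by athlete id.
#' @export
bmi <- function(cohort) {
  df <- athleteTable(cohort)
  stats::setNames(df$body_mass_kg / (df$height_cm / 100)^2, df$athlete_id)
}

# genotype column for a locus, erroring (or dropping) on missing values
cohortGenotypes <- function(cohort, locus, dropMissing = FALSE) {
  locus <- getLocus(locus)
  df <- athleteTable(cohort)
  g <- df[[genotypeColumn[[locusName(locus)]]]]
  if (anyNA(g)) {
    if (!dropMissing)
      tgsStop(sprintf("athlete(s) %s not genotyped at %s",
                      paste(df$athlete_id[is.na(g)], collapse = ", "),
                      locusName(locus)))
    message(sprintf("dropping %d athlete(s) without a %s genotype: %s",
                    sum(is.na(g)), locusName(locus),
                    paste(df$athlete_id[is.na(g)], collapse = ", ")))
    g <- g[!is.na(g)]
  }
  g
}

#' @describeIn Cohort-class genotype and allele frequency table at one
#'   locus. Missing genotypes raise an error naming the athletes unless
#'   `dropMissing = TRUE`, which excludes them from the denominator and
#'   logs the exclusion.
#' @param locus a [Locus-class] or locus name.
#' @param dropMissing drop ungenotyped athletes instead of erroring.
#' @export
setMethod("genotypeFrequencies", "Cohort",
  function(x, locus, dropMissing = FALSE) {
    locus <- getLocus(locus)
    if (nAthletes(x) == 0L) tgsStop("cohort is empty")
    g <- cohortGenotypes(x, locus, dropMissing)
    if (length(g) == 0L)
      tgsStop(sprintf("no genotyped athletes remain at %s", locusName(locus)))
    labs <- genotypeLabels(locus)
    counts <- vapply(labs, function(l) sum(g == l), integer(1))
    frequencyTable(counts, locus)
  })

#' @describeIn Cohort-class mean and sample standard deviation
#'   (n - 1 denominator) of weekly training minutes per modality,
#'   reported to 1 decimal.
#' @export
setMethod("summarizeTraining", "Cohort", function(x) {
  if (nAthletes(x) == 0L) tgsStop("cohort is empty")
  df <- athleteTable(x)
  cols <- c(technique = "technique_min_wk", strength = "strength_min_wk",
            aerobic = "aerobic_min_wk")
  out <- do.call(rbind, lapply(names(cols), function(m) {
    v <- df[[cols[[m]]]]
    if (anyNA(v)) tgsStop(sprintf("missing %s training minutes", m))
    data.frame(modality = m,
               mean_min_wk = roundHalfUp(mean(v), 1),
               sd_min_wk = if (length(v) > 1L) roundHalfUp(stats::sd(v), 1) else 0,
               row.names = NULL)
  }))
  out
})

#' @describeIn Cohort-class per-athlete genotype score, TGS and
#'   orientation under a scoring scheme.
#' @param scheme a [ScoringScheme-class].
#' @param thresholds orientation bounds, see [classifyTgsOrientation()].
#' @export
setMethod("scoreCohort", "Cohort",
  function(x, scheme = powerScheme(), thresholds = defaultThresholds()) {
    df <- athleteTable(x)
    if (nrow(df) == 0L) tgsStop("cohort is empty")
    res <- lapply(seq_len(nrow(df)), function(i) {
      profile <- stats::setNames(
        as.character(df[i, genotypeColumn]), names(genotypeColumn))
      if (anyNA(profile))
        tgsStop(sprintf("athlete %s not genotyped at %s", df$athlete_id[i],
                        paste(names(profile)[is.na(profile)], collapse = ", ")))
      tgsProfile(profile, scheme, thresholds)
    })
    data.frame(
      athlete_id = df$athlete_id,
      gs = vapply(res, `[[`, integer(1), "gs"),
      tgs = vapply(res, `[[`, numeric(1), "tgs"),
      orientation = vapply(res, `[[`, character(1), "orientation"),
      row.names = NULL
    )
  })

#' @describeIn Cohort-class distribution of TGS orientation classes:
#'   count and 2-decimal percentage per class, plus the mean TGS.
#' @export
setMethod("tgsDistribution", "Cohort",
  function(x, scheme = powerScheme(), thresholds = defaultThresholds()) {
    scored <- scoreCohort(x, scheme, thresholds)
    classes <- c("aerobic", "mixed", "power")
    counts <- vapply(classes, function(cl)
      sum(scored$orientation == cl), integer(1))
    list(
      table = data.frame(
        orientation = classes,
        count = counts,
        pct = roundHalfUp(counts / nrow(scored) * 100, 2),
        row.names = NULL),
      meanTgs = roundHalfUp(mean(scored$tgs), 2)
    )
  })

#' Genotype counts of the reference elite point-fighting cohort
#'
#' The integer genotype counts of the published 24-athlete elite
#' point-fighting cohort, recovered from its printed 2-decimal
#' percentages with [countsFromPercentages()] (each count round-trips to
#' the printed percentage): ACE II 2 / ID 16 / DD 6, PPARA CC 0 / CG 11 /
#' GG 13, CKM AA 15 / AG 7 / GG 2.
#'
#' @return named list of named integer count vectors, one per locus.
#' @export
#' @examples
#' alleleFrequencies(referenceGenotypeCounts()$ACE, "ACE")
referenceGenotypeCounts <- function() {
  list(
    ACE = countsFromPercentages(c(DD = 25.00, ID = 66.67, II = 8.33), 24),
    PPARA = countsFromPercentages(c(CC = 0.00, CG = 45.83, GG = 54.17), 24),
    CKM = countsFromPercentages(c(GG = 8.33, AG = 29.17, AA = 62.50), 24)
  )
}

#' Deterministic cohort with given per-locus genotype counts
#'
#' Builds a minimal cohort whose marginal genotype counts at each locus
#' equal `counts` exactly. Genotypes are dealt to athletes in a fixed
#' order, so the joint three-locus distribution is arbitrary; only the
#' marginals are meaningful. Anthropometrics and training minutes are
#' filled with cohort-level constants and exist so the object validates.
#'
#' @param counts named list per locus of named genotype count vectors, as
#'   from [referenceGenotypeCounts()]; all loci must give the same total.
#' @return a [Cohort-class].
#' @export
cohortFromGenotypeCounts <- function(counts = referenceGenotypeCounts()) {
  ns <- vapply(counts, sum, numeric(1))
  if (length(unique(ns)) != 1L)
    tgsStop("per-locus counts must sum to the same cohort size")
  n <- as.integer(ns[[1L]])
  cols <- lapply(names(genotypeColumn), function(loc) {
    cnt <- counts[[loc]]
    if (is.null(cnt)) tgsStop(sprintf("missing counts for %s", loc))
    rep(names(cnt), times = cnt)
  })
  names(cols) <- genotypeColumn[names(genotypeColumn)]
  Cohort(data.frame(
    athlete_id = sprintf("A%02d", seq_len(n)),
    sex = rep(c("F", "M"), length.out = n),
    age_years = 22.1, body_mass_kg = 66.1, height_cm = 173.0,
    cols,
    technique_min_wk = 367.3, strength_min_wk = 188.5,
    aerobic_min_wk = 134.8,
    stringsAsFactors = FALSE
  ))
}
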