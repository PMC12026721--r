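#' @include AllGenerics.R
NULL

#' Locus: a biallelic performance marker
#'
#' Each marker carries a designated power-predisposing and a designated
#' endurance-predisposing allele, plus the display label used for the
#' heterozygote (the field convention writes the ACE heterozygote "ID",
#' not "DI").
#'
#' @slot name locus name, one of `"ACE"`, `"PPARA"`, `"CKM"`.
#' @slot powerAllele single-character allele symbol associated with
#'   power/strength phenotypes.
#' @slot enduranceAllele single-character allele symbol associated with
#'   endurance/aerobic phenotypes.
#' @slot hetLabel canonical two-character heterozygote label.
#'
#' @seealso [builtinLoci()], [getLocus()]
#' @export
setClass("Locus",
  representation(
    name = "character",
    powerAllele = "character",
    enduranceAllele = "character",
    hetLabel = "character"
  )
)

setValidity("Locus", function(object) {
  msg <- character()
  for (s in c("name", "powerAllele", "enduranceAllele", "hetLabel")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || !nzchar(v))
      msg <- c(msg, sprintf("'%s' must be a single non-empty string", s))
  }
  if (length(msg)) return(msg)
  if (nchar(object@powerAllele) != 1L || nchar(object@enduranceAllele) != 1L)
    msg <- c(msg, "allele symbols must be single characters")
  if (object@powerAllele == object@enduranceAllele)
    msg <- c(msg, "power and endurance alleles must differ")
  if (nchar(object@hetLabel) != 2L ||
      !setequal(strsplit(object@hetLabel, "")[[1]],
                c(object@powerAllele, object@enduranceAllele)))
    msg <- c(msg, "hetLabel must contain exactly the two allele symbols")
  if (length(msg)) msg else TRUE
})

#' @rdname Locus-class
#' @param name,powerAllele,enduranceAllele,hetLabel see slots.
#' @export
Locus <- function(name, powerAllele, enduranceAllele, hetLabel) {
  new("Locus", name = name, powerAllele = powerAllele,
      enduranceAllele = enduranceAllele, hetLabel = hetLabel)
}

#' ScoringScheme: genotype-to-score map
#'
#' Maps every genotype at every covered locus to an integer score in
#' \{0, 1, 2\}. The shipped power-oriented scheme gives 2 to the
#' power-allele homozygote, 1 to the heterozygote and 0 to the
#' endurance-allele homozygote; [reverseScheme()] derives the
#' endurance-oriented mirror.
#'
#' @slot name scheme name.
#' @slot scoreMap named list, one element per locus name, each a named
#'   integer vector mapping canonical genotype labels to scores.
#'
#' @seealso [powerScheme()], [scoreGenotype()]
#' @export
setClass("ScoringScheme",
  representation(name = "character", scoreMap = "list")
)

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (is.null(names(object@scoreMap)) || anyNA(names(object@scoreMap)))
    msg <- c(msg, "scoreMap must be a named list keyed by locus name")
  for (loc in names(object@scoreMap)) {
    sm <- object@scoreMap[[loc]]
    if (!is.numeric(sm) || is.null(names(sm)) || length(sm) != 3L) {
      msg <- c(msg, sprintf("scoreMap[['%s']] must map 3 genotype labels", loc))
      next
    }
    if (!all(sm %in% 0:2))
      msg <- c(msg, sprintf("scores for %s must lie in {0,1,2}", loc))
    lx <- tryCatch(getLocus(loc), error = function(e) NULL)
    if (!is.null(lx)) {
      labs <- genotypeLabels(lx)
      if (!setequal(names(sm), labs)) {
        msg <- c(msg, sprintf("scoreMap[['%s']] must cover %s", loc,
                              paste(labs, collapse = ", ")))
      } else {
        hom <- sort(sm[labs[c(1L, 3L)]])
        het <- sm[[labs[2L]]]
        if (!(het > hom[1L] && het < hom[2L]))
          msg <- c(msg, sprintf(
            "heterozygote score for %s must lie strictly between homozygote scores", loc))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' DigestKey: expected restriction-fragment lengths per genotype
#'
#' Encodes the enzymatic-digestion key used to read genotypes off a gel:
#' for each genotype at a locus, the set of restriction-fragment lengths
#' (bp) the digest produces. Heterozygote patterns are the union of the two
#' homozygote patterns.
#'
#' @slot locusName locus this key belongs to.
#' @slot enzyme restriction enzyme name, or `"not required"` when the PCR
#'   product length alone is diagnostic (ACE I/D).
#' @slot fragments named list mapping genotype label to a numeric vector of
#'   expected fragment lengths in bp.
#'
#' @seealso [digestKey()], [expectedFragments()], [callGenotype()]
#' @export
setClass("DigestKey",
  representation(locusName = "character", enzyme = "character",
                 fragments = "list")
)

setValidity("DigestKey", function(object) {
  msg <- character()
  loc <- tryCatch(getLocus(object@locusName), error = function(e) NULL)
  if (is.null(loc)) return("unknown locus")
  labs <- genotypeLabels(loc)
  if (!setequal(names(object@fragments), labs))
    return(sprintf("fragments must cover genotypes %s", paste(labs, collapse = ", ")))
  for (fr in object@fragments)
    if (!is.numeric(fr) || any(fr <= 0)) msg <- c(msg, "fragment lengths must be > 0")
  hetSet <- sort(object@fragments[[labs[2L]]])
  homUnion <- sort(union(object@fragments[[labs[1L]]], object@fragments[[labs[3L]]]))
  if (!identical(as.numeric(hetSet), as.numeric(homUnion)))
    msg <- c(msg, "heterozygote fragment set must equal the union of the homozygote sets")
  if (length(msg)) msg else TRUE
})

#' PcrProtocol: amplification metadata for one locus
#'
#' Thermocycling parameters and primer pair used to amplify the target
#' region before digestion. Stored for provenance; no in-silico PCR is
#' performed.
#'
#' @slot locusName locus name.
#' @slot forwardPrimer,reversePrimer primer sequences (A/C/G/T only).
#' @slot denaturation,annealing,extension numeric `c(celsius, seconds)`.
#' @slot cycles number of amplification cycles.
#' @export
setClass("PcrProtocol",
  representation(
    locusName = "character",
    forwardPrimer = "character",
    reversePrimer = "character",
    denaturation = "numeric",
    annealing = "numeric",
    extension = "numeric",
    cycles = "integer"
  )
)

setValidity("PcrProtocol", function(object) {
  msg <- character()
  for (p in c(object@forwardPrimer, object@reversePrimer))
    if (grepl("[^ACGT]", p)) msg <- c(msg, sprintf("primer '%s' has non-ACGT characters", p))
  if (object@cycles <= 0L) msg <- c(msg, "cycles must be > 0")
  for (s in c("denaturation", "annealing", "extension"))
    if (length(slot(object, s)) != 2L || any(slot(object, s) <= 0))
      msg <- c(msg, sprintf("'%s' must be c(celsius, seconds), both > 0", s))
  if (length(msg)) msg else TRUE
})

#' FrequencyTable: per-locus genotype and allele frequencies
#'
#' Genotype counts and 2-decimal percentages plus allele counts and
#' percentages for one locus in a cohort. Zero-count genotypes are kept.
#'
#' @slot locus the [Locus-class].
#' @slot genotypeCounts named integer vector (all three genotypes).
#' @slot genotypePct named numeric vector, percentages to 2 decimals.
#' @slot alleleCounts named integer vector (both alleles); sums to `2 * n`.
#' @slot allelePct named numeric vector summing to 100.00 after
#'   largest-remainder reconciliation.
#' @slot n cohort size.
#'
#' @seealso [genotypeFrequencies()], [alleleFrequencies()]
#' @export
setClass("FrequencyTable",
  representation(
    locus = "Locus",
    genotypeCounts = "integer",
    genotypePct = "numeric",
    alleleCounts = "integer",
    allelePct = "numeric",
    n = "integer"
  )
)

setValidity("FrequencyTable", function(object) {
  msg <- character()
  if (sum(object@genotypeCounts) != object@n)
    msg <- c(msg, "genotype counts must sum to n")
  if (sum(object@alleleCounts) != 2L * object@n)
    msg <- c(msg, "allele counts must sum to 2n")
  if (abs(sum(object@genotypePct) - 100) > 0.02)
    msg <- c(msg, "genotype percentages must sum to 100 up to rounding")
  if (abs(sum(object@allelePct) - 100) > 1e-9)
    msg <- c(msg, "allele percentages must sum to exactly 100.00")
  het <- hetLabel(object@locus)
  for (a in names(object@alleleCounts)) {
    hom <- paste0(a, a)
    expect <- 2L * object@genotypeCounts[[hom]] + object@genotypeCounts[[het]]
    if (object@alleleCounts[[a]] != expect)
      msg <- c(msg, sprintf("allele count for %s inconsistent with genotype counts", a))
  }
  if (length(msg)) msg else TRUE
})

#' Cohort: validated athlete records
#'
#' One row per athlete: identifier, sex, anthropometrics, canonical
#' three-locus genotype labels and weekly training minutes by modality.
#' BMI is always derived from mass and height, never stored.
#'
#' @slot records data.frame with columns `athlete_id`, `sex`, `age_years`,
#'   `body_mass_kg`, `height_cm`, `ace_genotype`, `ppara_genotype`,
#'   `ckm_genotype`, `technique_min_wk`, `strength_min_wk`,
#'   `aerobic_min_wk`.
#'
#' @seealso [Cohort()], [readCohortCsv()], [simulateCohort()]
#' @export
setClass("Cohort", representation(records = "data.frame"))

cohortColumns <- c(
  "athlete_id", "sex", "age_years", "body_mass_kg", "height_cm",
  "ace_genotype", "ppara_genotype", "ckm_genotype",
  "technique_min_wk", "strength_min_wk", "aerobic_min_wk"
)

genotypeColumn <- c(ACE = "ace_genotype", PPARA = "ppara_genotype",
                    CKM = "ckm_genotype")

setValidity("Cohort", function(object) {
  df <- object@records
  missing <- setdiff(cohortColumns, names(df))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  msg <- character()
  dup <- df$athlete_id[duplicated(df$athlete_id)]
  if (length(dup))
    msg <- c(msg, sprintf("duplicate athlete_id: %s",
                          paste(unique(dup), collapse = ", ")))
  bad <- !df$sex %in% c("F", "M")
  if (any(bad))
    msg <- c(msg, sprintf("sex must be F or M (athlete %s)",
                          paste(df$athlete_id[bad], collapse = ", ")))
  for (col in c("age_years", "body_mass_kg", "height_cm",
                "technique_min_wk", "strength_min_wk", "aerobic_min_wk")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.na(v) & v < 0))
      msg <- c(msg, sprintf("'%s' must be numeric and >= 0", col))
  }
  for (loc in names(genotypeColumn)) {
    labs <- c(genotypeLabels(getLocus(loc)), NA)
    v <- df[[genotypeColumn[[loc]]]]
    bad <- !v %in% labs
    if (any(bad))
      msg <- c(msg, sprintf("invalid %s genotype '%s' (athlete %s)", loc,
                            v[bad][1L], df$athlete_id[bad][1L]))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Cohort-class
#' @param records data.frame of athlete records; genotype labels are
#'   normalized (either allele order accepted) before validation.
#' @export
Cohort <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (loc in names(genotypeColumn)) {
    col <- genotypeColumn[[loc]]
    if (col %in% names(records))
      records[[col]] <- vapply(records[[col]], function(g) {
        if (is.na(g)) NA_character_ else normalizeGenotype(loc, g)
      }, character(1))
  }
  rownames(records) <- NULL
  new("Cohort", records = records)
}

#' CohortSpec: parameters for the synthetic-cohort generator
#'
#' Defines the statistical structure a simulated cohort should have:
#' size and sex split, per-locus genotype probabilities (or allele
#' frequency under Hardy-Weinberg proportions), truncated-normal
#' parameters for anthropometrics and weekly training minutes, and a seed.
#'
#' @slot n cohort size.
#' @slot sexSplit integer `c(female, male)`, summing to `n`.
#' @slot genotypeProbs named list per locus: either a named probability
#'   vector over the three genotype labels (summing to 1) or a single
#'   value named `powerAlleleFreq` to draw genotypes from Hardy-Weinberg
#'   proportions p^2 / 2pq / q^2.
#' @slot anthropometry named list per variable (`age_years`,
#'   `body_mass_kg`, `height_cm`), each `c(mean, sd, lower, upper)`.
#' @slot training named list per modality (`technique_min_wk`,
#'   `strength_min_wk`, `aerobic_min_wk`), each `c(mean, sd)`; samples are
#'   truncated at 0.
#' @slot seed integer seed fully determining the generated cohort.
#'
#' @seealso [pfCohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    n = "integer",
    sexSplit = "integer",
    genotypeProbs = "list",
    anthropometry = "list",
    training = "list",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(object@sexSplit) != 2L || sum(object@sexSplit) != object@n)
    msg <- c(msg, "sexSplit must be c(female, male) summing to n")
  for (loc in names(genotypeColumn)) {
    p <- object@genotypeProbs[[loc]]
    if (is.null(p)) { msg <- c(msg, sprintf("missing genotype probabilities for %s", loc)); next }
    if (identical(names(p), "powerAlleleFreq")) {
      if (p < 0 || p > 1) msg <- c(msg, sprintf("%s allele frequency outside [0,1]", loc))
    } else {
      labs <- genotypeLabels(getLocus(loc))
      if (!setequal(names(p), labs) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, sprintf(
          "%s genotype probabilities must cover %s and sum to 1", loc,
          paste(labs, collapse = ", ")))
    }
  }
  for (v in c(object@anthropometry, object@training))
    if (v[["sd"]] < 0) msg <- c(msg, "all SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "Locus", function(object) {
  cat(sprintf("Locus %s: power allele %s, endurance allele %s (heterozygote %s)\n",
              object@name, object@powerAllele, object@enduranceAllele,
              object@hetLabel))
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme '%s'\n", object@name))
  for (loc in names(object@scoreMap)) {
    sm <- object@scoreMap[[loc]]
    cat(sprintf("  %-6s %s\n", loc,
                paste(sprintf("%s=%d", names(sm), sm), collapse = "  ")))
  }
})

setMethod("show", "DigestKey", function(object) {
  cat(sprintf("DigestKey for %s (enzyme: %s)\n", object@locusName, object@enzyme))
  for (g in names(object@fragments))
    cat(sprintf("  %s: %s bp\n", g,
                paste(object@fragments[[g]], collapse = " + ")))
})

setMethod("show", "FrequencyTable", function(object) {
  cat(sprintf("FrequencyTable for %s (n = %d)\n", object@locus@name, object@n))
  cat("  genotypes: ",
      paste(sprintf("%s %d (%.2f%%)", names(object@genotypeCounts),
                    object@genotypeCounts, object@genotypePct), collapse = ", "),
      "\n", sep = "")
  cat("  alleles:   ",
      paste(sprintf("%s %d (%.2f%%)", names(object@alleleCounts),
                    object@alleleCounts, object@allelePct), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "Cohort", function(object) {
  df <- object@records
  cat(sprintf("Cohort of %d athletes (%d F / %d M)\n", nrow(df),
              sum(df$sex == "F"), sum(df$sex == "M")))
  if (nrow(df)) {
    cat(sprintf("  age %.1f +/- %.1f y, mass %.1f +/- %.1f kg, height %.1f +/- %.1f cm\n",
                mean(df$age_years), stats::sd(df$age_years),
                mean(df$body_mass_kg), stats::sd(df$body_mass_kg),
                mean(df$height_cm), stats::sd(df$height_cm)))
  }
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: n = %d (%d F / %d M), seed = %d\n", object@n,
              object@sexSplit[1L], object@sexSplit[2L], object@seed))
  for (loc in names(object@genotypeProbs)) {
    p <- object@genotypeProbs[[loc]]
    cat(sprintf("  %-6s %s\n", loc,
                paste(sprintf("%s=%.4f", names(p), p), collapse = " ")))
  }
})
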