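#' @include loci.R
NULL

#' The power-oriented scoring scheme
#'
#' The default additive scheme: 2 for the homozygote of the
#' power-predisposing allele, 1 for the heterozygote, 0 for the homozygote
#' of the endurance-predisposing allele, at every locus.
#'
#' @return a [ScoringScheme-class].
#' @export
#' @examples
#' powerScheme()
powerScheme <- function() {
  scoreMap <- lapply(builtinLoci(), function(loc) {
    labs <- genotypeLabels(loc)
    stats::setNames(c(2L, 1L, 0L), labs)
  })
  new("ScoringScheme", name = "power-oriented", scoreMap = scoreMap)
}

#' Reverse a scoring scheme
#'
#' Swaps the homozygote scores (2 <-> 0) at every locus, turning the
#' power-oriented scheme into its endurance-oriented mirror. For every
#' profile the genotype score maps to `6 - GS` and the TGS to `100 - TGS`.
#'
#' @param scheme a [ScoringScheme-class].
#' @return the reversed [ScoringScheme-class].
#' @export
reverseScheme <- function(scheme) {
  stopifnot(is(scheme, "ScoringScheme"))
  scoreMap <- lapply(scheme@scoreMap, function(sm) 2L - sm)
  new("ScoringScheme", name = paste0("reversed ", scheme@name),
      scoreMap = scoreMap)
}

#' Score one genotype
#'
#' @param locus a [Locus-class] or locus name.
#' @param genotype genotype label (allele order irrelevant).
#' @param scheme a [ScoringScheme-class]; defaults to [powerScheme()].
#' @return integer score in \{0, 1, 2\}.
#' @export
#' @examples
#' scoreGenotype("ACE", "DD")    # 2
#' scoreGenotype("PPARA", "GG")  # 0
#' scoreGenotype("CKM", "AG")    # 1
scoreGenotype <- function(locus, genotype, scheme = powerScheme()) {
  locus <- getLocus(locus)
  label <- normalizeGenotype(locus, genotype)
  sm <- scheme@scoreMap[[locusName(locus)]]
  if (is.null(sm))
    tgsStop(sprintf("scheme '%s' does not cover locus %s", scheme@name,
                    locusName(locus)))
  as.integer(sm[[label]])
}

#' Genotype score (GS) of a three-locus profile
#'
#' Sums the per-locus scores of a complete profile; with the shipped
#' scheme the result ranges from 0 (endurance-homozygous throughout) to 6
#' (power-homozygous throughout).
#'
#' @param profile named character vector or list mapping each locus name
#'   (`ACE`, `PPARA`, `CKM`) to a genotype label.
#' @param scheme a [ScoringScheme-class].
#' @return integer GS in 0..6.
#' @export
#' @examples
#' genotypeScore(c(ACE = "DD", PPARA = "CG", CKM = "AA"))  # 3
genotypeScore <- function(profile, scheme = powerScheme()) {
  profile <- unlist(profile)
  wanted <- names(builtinLoci())
  missing <- setdiff(wanted, names(profile))
  if (length(missing))
    tgsStop(sprintf("profile is missing locus/loci: %s",
                    paste(missing, collapse = ", ")))
  dup <- names(profile)[duplicated(names(profile))]
  if (length(dup))
    tgsStop(sprintf("duplicate locus/loci in profile: %s",
                    paste(unique(dup), collapse = ", ")))
  extra <- setdiff(names(profile), wanted)
  if (length(extra))
    tgsStop(sprintf("unknown locus/loci in profile: %s",
                    paste(extra, collapse = ", ")))
  sum(vapply(wanted, function(loc)
    scoreGenotype(loc, profile[[loc]], scheme), integer(1)))
}

#' Total Genetic Score (TGS)
#'
#' Rescales a genotype score to the centesimal scale: TGS = GS * 100 / 6,
#' reported to two decimals (ties rounded up). With three loci the
#' attainable values are 0, 16.67, 33.33, 50, 66.67, 83.33 and 100.
#'
#' @param gs integer genotype score in 0..6.
#' @return TGS percentage, rounded to 2 decimals.
#' @export
#' @examples
#' totalGeneticScore(3)  # 50
totalGeneticScore <- function(gs) {
  if (!is.numeric(gs) || length(gs) != 1L || is.na(gs) || gs != as.integer(gs) ||
      gs < 0 || gs > 6)
    tgsStop(sprintf("gs must be an integer in 0..6, got %s",
                    paste(gs, collapse = ",")))
  roundHalfUp(gs * 100 / 6, 2)
}

#' Metabolism involved in a per-locus score
#'
#' Maps the per-genotype score to the energy system it reflects:
#' power-allele homozygote (2) to anaerobic, heterozygote (1) to mixed
#' anaerobic/aerobic, endurance-allele homozygote (0) to aerobic.
#'
#' @param score integer in \{0, 1, 2\}.
#' @return one of `"Anaerobic"`, `"Mixed"`, `"Aerobic"`.
#' @export
classifyMetabolism <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      !score %in% 0:2)
    tgsStop(sprintf("score must be 0, 1 or 2, got %s",
                    paste(score, collapse = ",")))
  c("Aerobic", "Mixed", "Anaerobic")[score + 1L]
}

#' Default TGS-orientation thresholds
#'
#' Band bounds on the centesimal scale placing GS 0-1 in the aerobic band,
#' GS 2-4 in the mixed band and GS 5-6 in the power band: symmetric
#' tertiles of the attainable TGS lattice. The bounds are a package
#' convention (configurable), not an established cut-off.
#'
#' @return numeric `c(low, high)`.
#' @export
defaultThresholds <- function() c(low = 33.33, high = 66.67)

#' Classify TGS orientation
#'
#' @param tgs TGS percentage in \[0, 100\] (compared after 2-decimal
#'   rounding).
#' @param thresholds numeric `c(low, high)` with `0 < low < high < 100`;
#'   `tgs < low` is aerobic, `low <= tgs <= high` mixed, `tgs > high`
#'   power.
#' @return one of `"aerobic"`, `"mixed"`, `"power"`.
#' @export
#' @examples
#' classifyTgsOrientation(50)   # "mixed"
#' classifyTgsOrientation(100)  # "power"
classifyTgsOrientation <- function(tgs, thresholds = defaultThresholds()) {
  if (!is.numeric(thresholds) || length(thresholds) != 2L ||
      !(0 < thresholds[1L] && thresholds[1L] < thresholds[2L] &&
        thresholds[2L] < 100))
    tgsStop("thresholds must satisfy 0 < low < high < 100",
            class = "tgs_config_error")
  if (!is.numeric(tgs) || length(tgs) != 1L || is.na(tgs) || tgs < 0 || tgs > 100)
    tgsStop(sprintf("tgs must lie in [0, 100], got %s", paste(tgs, collapse = ",")))
  tgs <- roundHalfUp(tgs, 2)
  if (tgs < thresholds[1L] - 1e-9) "aerobic"
  else if (tgs > thresholds[2L] + 1e-9) "power"
  else "mixed"
}

#' Score a full profile
#'
#' Convenience wrapper computing per-locus scores, GS, TGS and the
#' orientation class for one athlete profile.
#'
#' @inheritParams genotypeScore
#' @param thresholds orientation band bounds, see
#'   [classifyTgsOrientation()].
#' @return list with `perLocusScores` (named integer), `gs`, `tgs` and
#'   `orientation`.
#' @export
#' @examples
#' tgsProfile(c(ACE = "DD", PPARA = "CG", CKM = "AA"))
tgsProfile <- function(profile, scheme = powerScheme(),
                       thresholds = defaultThresholds()) {
  profile <- unlist(profile)
  gs <- genotypeScore(profile, scheme)
  perLocus <- vapply(names(builtinLoci()), function(loc)
    scoreGenotype(loc, profile[[loc]], scheme), integer(1))
  tgs <- totalGeneticScore(gs)
  list(perLocusScores = perLocus, gs = gs, tgs = tgs,
       orientation = classifyTgsOrientation(tgs, thresholds))
}
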