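#' @include AllClasses.R
NULL

.builtinLoci <- list(
  ACE   = Locus("ACE",   powerAllele = "D", enduranceAllele = "I", hetLabel = "ID"),
  PPARA = Locus("PPARA", powerAllele = "C", enduranceAllele = "G", hetLabel = "CG"),
  CKM   = Locus("CKM",   powerAllele = "G", enduranceAllele = "A", hetLabel = "AG")
)

#' Built-in performance marker loci
#'
#' The three markers of the panel: ACE I/D (D = power, I = endurance),
#' PPARalpha C/G (C = power, G = endurance) and CKM A/G (G = power,
#' A = aerobic capacity).
#'
#' @return named list of [Locus-class] objects.
#' @export
#' @examples
#' builtinLoci()
builtinLoci <- function() .builtinLoci

#' Look up a built-in locus by name
#'
#' @param locus a [Locus-class] object (returned as is) or one of
#'   `"ACE"`, `"PPARA"`, `"CKM"`.
#' @return a [Locus-class].
#' @export
getLocus <- function(locus) {
  if (is(locus, "Locus")) return(locus)
  if (!is.character(locus) || length(locus) != 1L || !locus %in% names(.builtinLoci))
    tgsStop(sprintf("unknown locus '%s' (expected one of %s)",
                    paste(locus, collapse = ","),
                    paste(names(.builtinLoci), collapse = ", ")))
  .builtinLoci[[locus]]
}

#' @describeIn Locus-class locus name.
#' @param x a `Locus`.
#' @export
setMethod("locusName", "Locus", function(x) x@name)

#' @describeIn Locus-class power-predisposing allele symbol.
#' @export
setMethod("powerAllele", "Locus", function(x) x@powerAllele)

#' @describeIn Locus-class endurance-predisposing allele symbol.
#' @export
setMethod("enduranceAllele", "Locus", function(x) x@enduranceAllele)

#' @describeIn Locus-class canonical heterozygote label.
#' @export
setMethod("hetLabel", "Locus", function(x) x@hetLabel)

#' @describeIn Locus-class the three canonical genotype labels, ordered
#'   power homozygote, heterozygote, endurance homozygote (e.g.
#'   `c("DD", "ID", "II")` for ACE).
#' @export
setMethod("genotypeLabels", "Locus", function(x) {
  c(strrep(x@powerAllele, 2), x@hetLabel, strrep(x@enduranceAllele, 2))
})

#' Normalize a genotype label
#'
#' Validates a genotype label against a locus and returns the canonical
#' form. Allele order is irrelevant on input ("DI" and "ID" denote the
#' same unordered allele pair); homozygotes must be the doubled symbol and
#' heterozygotes normalize to the locus display label.
#'
#' @param locus a [Locus-class] or locus name.
#' @param label two-character genotype label.
#' @return canonical label, one of [genotypeLabels()].
#' @export
#' @examples
#' normalizeGenotype("ACE", "DI")  # "ID"
normalizeGenotype <- function(locus, label) {
  locus <- getLocus(locus)
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      nchar(label) != 2L)
    tgsStop(sprintf("genotype label for %s must be two allele symbols, got '%s'",
                    locusName(locus), paste(label, collapse = ",")))
  alleles <- strsplit(label, "")[[1]]
  valid <- c(powerAllele(locus), enduranceAllele(locus))
  bad <- setdiff(alleles, valid)
  if (length(bad))
    tgsStop(sprintf("unknown allele symbol '%s' for locus %s (alleles: %s)",
                    bad[1L], locusName(locus), paste(valid, collapse = "/")))
  if (alleles[1L] == alleles[2L]) label else hetLabel(locus)
}

#' PCR protocols for the genotyping panel
#'
#' Primer pairs and thermocycling parameters used to amplify each marker
#' before restriction digestion. Temperatures are degrees Celsius, times
#' seconds.
#'
#' @return named list of [PcrProtocol-class] objects.
#' @export
pcrProtocols <- function() {
  list(
    ACE = new("PcrProtocol", locusName = "ACE",
      forwardPrimer = "GCCCTGCAGGTGTCTGCAGCATGT",
      reversePrimer = "GGATGGCTCTCCCCGCCTTGTCTC",
      denaturation = c(celsius = 94, seconds = 30),
      annealing = c(celsius = 56, seconds = 45),
      extension = c(celsius = 72, seconds = 60),
      cycles = 35L),
    PPARA = new("PcrProtocol", locusName = "PPARA",
      forwardPrimer = "ACAATCACTCCTTAAATATGGTGG",
      reversePrimer = "AAGTAGGGACAGACAGGACCAGTA",
      denaturation = c(celsius = 94, seconds = 30),
      annealing = c(celsius = 59, seconds = 30),
      extension = c(celsius = 72, seconds = 30),
      cycles = 35L),
    CKM = new("PcrProtocol", locusName = "CKM",
      forwardPrimer = "GGGATGCTCAGACTCACAGA",
      reversePrimer = "AACTTGAATTTAGCCCAACG",
      denaturation = c(celsius = 94, seconds = 40),
      annealing = c(celsius = 53, seconds = 45),
      extension = c(celsius = 72, seconds = 60),
      cycles = 30L)
  )
}
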