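#' @include AllClasses.R loci.R
NULL

#' Build a FrequencyTable from genotype counts
#'
#' Computes 2-decimal genotype percentages, allele counts
#' (2 x homozygotes + heterozygotes) and allele percentages reconciled to
#' sum to exactly 100.00 (largest remainder).
#'
#' @param counts named integer vector of genotype counts; all three
#'   canonical labels of the locus, any order; zero counts allowed.
#' @param locus a [Locus-class] or locus name.
#' @return a [FrequencyTable-class].
#' @export
#' @examples
#' frequencyTable(c(II = 2, ID = 16, DD = 6), "ACE")
frequencyTable <- function(counts, locus) {
  locus <- getLocus(locus)
  labs <- genotypeLabels(locus)
  if (is.null(names(counts)))
    tgsStop("genotype counts must be named by genotype label")
  names(counts) <- vapply(names(counts), function(g)
    normalizeGenotype(locus, g), character(1))
  if (!setequal(union(names(counts), labs), labs) || anyDuplicated(names(counts)))
    tgsStop(sprintf("counts must be keyed by the %s genotypes %s",
                    locusName(locus), paste(labs, collapse = ", ")))
  full <- stats::setNames(integer(3), labs)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) tgsStop("genotype counts must be non-negative")
  n <- sum(full)
  if (n == 0L) tgsStop("genotype counts are all zero")
  alleles <- c(powerAllele(locus), enduranceAllele(locus))
  alleleCounts <- stats::setNames(vapply(alleles, function(a)
    2L * full[[paste0(a, a)]] + full[[hetLabel(locus)]], integer(1)), alleles)
  new("FrequencyTable",
      locus = locus,
      genotypeCounts = full,
      genotypePct = roundHalfUp(full / n * 100, 2),
      alleleCounts = alleleCounts,
      allelePct = stats::setNames(reconcilePct(alleleCounts / (2 * n) * 100),
                                  alleles),
      n = as.integer(n))
}

#' @describeIn FrequencyTable-class genotype counts.
#' @param x a `FrequencyTable`.
#' @export
setMethod("genotypeCounts", "FrequencyTable", function(x) x@genotypeCounts)

#' @describeIn FrequencyTable-class genotype percentages (2 decimals).
#' @export
setMethod("genotypePct", "FrequencyTable", function(x) x@genotypePct)

#' @describeIn FrequencyTable-class allele counts (sum to 2n).
#' @export
setMethod("alleleCounts", "FrequencyTable", function(x) x@alleleCounts)

#' @describeIn FrequencyTable-class allele percentages (sum to 100.00).
#' @export
setMethod("allelePct", "FrequencyTable", function(x) x@allelePct)

#' Allele frequencies from genotype counts
#'
#' Allele percentage = (2 x homozygotes + heterozygotes) / 2n x 100,
#' reported to 2 decimals with the pair reconciled to sum to 100.00.
#'
#' @inheritParams frequencyTable
#' @return named numeric vector of allele percentages, power allele first.
#' @export
#' @examples
#' alleleFrequencies(c(II = 2, ID = 16, DD = 6), "ACE")  # D 58.33, I 41.67
alleleFrequencies <- function(counts, locus) {
  allelePct(frequencyTable(counts, locus))
}

#' Reconstruct genotype counts from printed percentages
#'
#' Inverts 2-decimal genotype percentages at a known cohort size:
#' `count = round(pct * n / 100)`, accepted only when the counts sum to
#' `n` and each count reproduces its percentage within half a count
#' (`|count * 100/n - pct| <= 50/n`). Useful for recovering the integer
#' counts behind published frequency tables.
#'
#' @param pct named numeric vector of genotype percentages.
#' @param n cohort size.
#' @return named integer vector of counts.
#' @export
#' @examples
#' countsFromPercentages(c(ID = 66.67, DD = 25, II = 8.33), 24)
countsFromPercentages <- function(pct, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n))
    tgsStop("n must be a positive integer")
  if (!is.numeric(pct) || is.null(names(pct)) || any(pct < 0 | pct > 100))
    tgsStop("pct must be a named numeric vector of percentages in [0, 100]")
  counts <- roundHalfUp(pct * n / 100, 0)
  resid <- counts * 100 / n - pct
  bad <- abs(resid) > 50 / n + 1e-9
  if (sum(counts) != n || any(bad)) {
    detail <- paste(sprintf("%s: pct %.2f -> count %d (back %.2f%%)",
                            names(pct), pct, as.integer(counts),
                            counts * 100 / n), collapse = "; ")
    tgsStop(sprintf(
      "percentages are inconsistent with n = %d (no integer counts reproduce them): %s",
      n, detail))
  }
  stats::setNames(as.integer(counts), names(pct))
}

#' Exact Hardy-Weinberg equilibrium test for a biallelic marker
#'
#' Conditional exact test: given the observed allele counts, enumerates
#' every compatible heterozygote count, computes its probability under
#' Hardy-Weinberg proportions
#' \deqn{P(n_{AB} \mid n, n_A) = \frac{n!\, n_A!\, n_B!\, 2^{n_{AB}}}
#'   {n_{AA}!\, n_{AB}!\, n_{BB}!\, (2n)!}}
#' and sums the probabilities of all configurations no more probable than
#' the observed one (two-sided).
#'
#' @param counts genotype counts: a named vector over the three canonical
#'   labels of `locus`, or an unnamed length-3 vector
#'   `c(homozygote1, heterozygote, homozygote2)`.
#' @param locus optional [Locus-class] or name, required when `counts`
#'   is named by genotype label.
#' @return the exact two-sided p-value.
#' @export
#' @examples
#' hweExactTest(c(II = 2, ID = 16, DD = 6), "ACE")
hweExactTest <- function(counts, locus = NULL) {
  if (!is.null(names(counts)) && !is.null(locus)) {
    ft <- frequencyTable(counts, locus)
    labs <- genotypeLabels(ft@locus)
    counts <- as.integer(genotypeCounts(ft)[labs])
  } else {
    if (length(counts) != 3L || any(counts < 0) || anyNA(counts))
      tgsStop("counts must be three non-negative genotype counts")
    counts <- as.integer(counts)
  }
  n <- sum(counts)
  if (n < 1L) tgsStop("need at least one genotyped individual")
  nAB <- counts[2L]
  nA <- 2L * counts[1L] + nAB
  nB <- 2L * n - nA
  hets <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
  logp <- lfactorial(n) + lfactorial(nA) + lfactorial(nB) - lfactorial(2L * n) +
    hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2)
  p <- exp(logp)
  pObs <- p[hets == nAB]
  min(1, sum(p[p <= pObs * (1 + 1e-12)]))
}
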