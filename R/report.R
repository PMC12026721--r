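#' @include cohort.R io.R
NULL

#' Full cohort report
#'
#' The end-to-end descriptive-genetics report: per locus, genotype and
#' allele frequency tables with a Hardy-Weinberg exact p-value; per
#' athlete, GS, TGS and orientation; the orientation distribution with
#' mean TGS; and training-volume summaries.
#'
#' @param cohort a [Cohort-class].
#' @param scheme a [ScoringScheme-class].
#' @param thresholds orientation bounds, see [classifyTgsOrientation()].
#' @param dropMissing forwarded to [genotypeFrequencies()].
#' @return a `tgsReport`: a list with elements `n`, `scheme`,
#'   `thresholds`, `frequencies` (named list of [FrequencyTable-class]),
#'   `hweP` (named numeric), `athletes` (data.frame), `orientation`
#'   (data.frame), `meanTgs` and `training` (data.frame).
#' @export
#' @examples
#' runReport(cohortFromGenotypeCounts())
runReport <- function(cohort, scheme = powerScheme(),
                      thresholds = defaultThresholds(), dropMissing = FALSE) {
  if (nAthletes(cohort) == 0L) tgsStop("cohort is empty")
  freqs <- lapply(names(genotypeColumn), function(loc)
    genotypeFrequencies(cohort, loc, dropMissing = dropMissing))
  names(freqs) <- names(genotypeColumn)
  hweP <- vapply(freqs, function(ft)
    hweExactTest(genotypeCounts(ft), ft@locus), numeric(1))
  dist <- tgsDistribution(cohort, scheme, thresholds)
  structure(list(
    n = nAthletes(cohort),
    scheme = scheme@name,
    thresholds = unname(thresholds),
    frequencies = freqs,
    hweP = hweP,
    athletes = scoreCohort(cohort, scheme, thresholds),
    orientation = dist$table,
    meanTgs = dist$meanTgs,
    training = summarizeTraining(cohort)
  ), class = "tgsReport")
}

#' @export
print.tgsReport <- function(x, ...) {
  cat(sprintf("TGS cohort report (n = %d, scheme: %s, bands: %.2f / %.2f)\n",
              x$n, x$scheme, x$thresholds[1L], x$thresholds[2L]))
  for (loc in names(x$frequencies)) {
    ft <- x$frequencies[[loc]]
    cat(sprintf("\n%s (HWE exact p = %.4f)\n", loc, x$hweP[[loc]]))
    gd <- genotypeCounts(ft); gp <- genotypePct(ft)
    for (g in names(gd))
      cat(sprintf("  %s  %2d  %6.2f%%\n", g, gd[[g]], gp[[g]]))
    ad <- alleleCounts(ft); ap <- allelePct(ft)
    cat("  alleles: ",
        paste(sprintf("%s %.2f%%", names(ad), ap), collapse = " / "),
        "\n", sep = "")
  }
  cat("\nOrientation distribution (mean TGS ", sprintf("%.2f", x$meanTgs),
      "):\n", sep = "")
  for (i in seq_len(nrow(x$orientation)))
    cat(sprintf("  %-8s %2d  %6.2f%%\n", x$orientation$orientation[i],
                x$orientation$count[i], x$orientation$pct[i]))
  cat("\nTraining minutes per week (mean +/- SD):\n")
  for (i in seq_len(nrow(x$training)))
    cat(sprintf("  %-10s %6.1f +/- %5.1f\n", x$training$modality[i],
                x$training$mean_min_wk[i], x$training$sd_min_wk[i]))
  invisible(x)
}

# plain-list rendering of a report for JSON output
reportToList <- function(report) {
  freqs <- lapply(report$frequencies, function(ft) list(
    n = ft@n,
    genotype_counts = as.list(genotypeCounts(ft)),
    genotype_pct = as.list(genotypePct(ft)),
    allele_counts = as.list(alleleCounts(ft)),
    allele_pct = as.list(allelePct(ft))
  ))
  list(
    n = report$n,
    scheme = report$scheme,
    thresholds = report$thresholds,
    frequencies = freqs,
    hwe_p = as.list(report$hweP),
    athletes = report$athletes,
    orientation = report$orientation,
    mean_tgs = report$meanTgs,
    training = report$training
  )
}

#' Write a report as JSON
#'
#' Machine-readable rendering of [runReport()] output.
#'
#' @param report a `tgsReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReportJson <- function(report, path) {
  stopifnot(inherits(report, "tgsReport"))
  jsonlite::write_json(reportToList(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
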