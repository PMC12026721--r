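#' @include utils.R
NULL

#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @export
setGeneric("powerAllele", function(x) standardGeneric("powerAllele"))

#' @export
setGeneric("enduranceAllele", function(x) standardGeneric("enduranceAllele"))

#' @export
setGeneric("hetLabel", function(x) standardGeneric("hetLabel"))

#' @export
setGeneric("genotypeLabels", function(x) standardGeneric("genotypeLabels"))

#' @export
setGeneric("nAthletes", function(x) standardGeneric("nAthletes"))

#' @export
setGeneric("athleteTable", function(x) standardGeneric("athleteTable"))

#' @export
setGeneric("athleteIds", function(x) standardGeneric("athleteIds"))

#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))

#' @export
setGeneric("genotypePct", function(x) standardGeneric("genotypePct"))

#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' @export
setGeneric("allelePct", function(x) standardGeneric("allelePct"))

#' @export
setGeneric("genotypeFrequencies",
  function(x, locus, ...) standardGeneric("genotypeFrequencies"))

#' @export
setGeneric("summarizeTraining", function(x) standardGeneric("summarizeTraining"))

#' @export
setGeneric("scoreCohort",
  function(x, scheme = powerScheme(), thresholds = defaultThresholds())
    standardGeneric("scoreCohort"))

#' @export
setGeneric("tgsDistribution",
  function(x, scheme = powerScheme(), thresholds = defaultThresholds())
    standardGeneric("tgsDistribution"))

#' @export
setGeneric("simulateCohort", function(spec, seed = NULL)
  standardGeneric("simulateCohort"))
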