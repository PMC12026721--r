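#' @include loci.R
NULL

.digestKeys <- local({
  keys <- list(
    ACE = list(enzyme = "not required",
               fragments = list(DD = 319, ID = c(319, 597), II = 597)),
    PPARA = list(enzyme = "TaqI",
                 fragments = list(CC = c(216, 50), CG = c(266, 216, 50),
                                  GG = 266)),
    CKM = list(enzyme = "NcoI",
               fragments = list(GG = 359, AG = c(359, 206, 153),
                                AA = c(206, 153)))
  )
  lapply(names(keys), function(loc)
    new("DigestKey", locusName = loc, enzyme = keys[[loc]]$enzyme,
        fragments = keys[[loc]]$fragments)) |>
    stats::setNames(names(keys))
})

#' Enzymatic-digestion key for a locus
#'
#' The built-in key for the panel: ACE needs no digestion (amplicon length
#' is diagnostic: DD 319 bp, II 597 bp), PPARA is cut with TaqI (CC
#' 216+50, GG 266) and CKM with NcoI (GG 359, AA 206+153); heterozygotes
#' show the union of the two homozygote patterns.
#'
#' @param locus a [Locus-class] or locus name.
#' @return a [DigestKey-class].
#' @export
#' @examples
#' digestKey("PPARA")
digestKey <- function(locus) {
  .digestKeys[[locusName(getLocus(locus))]]
}

#' Expected restriction fragments for a genotype
#'
#' @inheritParams digestKey
#' @param genotype genotype label (allele order irrelevant).
#' @return numeric vector of fragment lengths in bp, decreasing.
#' @export
#' @examples
#' expectedFragments("ACE", "ID")  # 597 319
expectedFragments <- function(locus, genotype) {
  locus <- getLocus(locus)
  label <- normalizeGenotype(locus, genotype)
  sort(digestKey(locus)@fragments[[label]], decreasing = TRUE)
}

# bijective tolerance match of two fragment-length sets; both are sets
# (duplicates collapsed); returns TRUE only when every observed length is
# within +/- tol of exactly one expected length and vice versa
matchFragmentSets <- function(observed, expected, tol) {
  observed <- sort(unique(observed))
  expected <- sort(unique(expected))
  if (length(observed) != length(expected)) return(FALSE)
  if (any(abs(observed - expected) > tol)) return(FALSE)
  for (o in observed) if (sum(abs(expected - o) <= tol) != 1L) return(FALSE)
  for (e in expected) if (sum(abs(observed - e) <= tol) != 1L) return(FALSE)
  TRUE
}

# symmetric nearest-band distance used to report the closest candidate on
# a failed call: every band is charged its gap to the other set's nearest
fragmentSetDistance <- function(observed, expected) {
  observed <- unique(observed); expected <- unique(expected)
  sum(vapply(observed, function(o) min(abs(expected - o)), numeric(1))) +
    sum(vapply(expected, function(e) min(abs(observed - e)), numeric(1)))
}

#' Call a genotype from observed fragment lengths
#'
#' Inverse lookup of the digestion key: returns the unique genotype whose
#' expected fragment set matches the observed lengths, each observed band
#' pairing with exactly one expected band within `toleranceBp`. Observed
#' lengths are treated as a set; duplicates are collapsed.
#'
#' Small fragments can run off a gel: with `allowMissingSmallest = TRUE` a
#' pattern lacking only the smallest expected band (e.g. the 50 bp TaqI
#' product of PPARA) is still called, provided the call stays unambiguous.
#' Note the documented hazard that a PPARA CG observation missing its
#' 266 bp band is indistinguishable from CC and is called CC.
#'
#' @inheritParams digestKey
#' @param observedBp numeric vector of observed fragment lengths (bp),
#'   all positive.
#' @param toleranceBp non-negative sizing tolerance in bp (default 5, a
#'   typical agarose-gel sizing uncertainty).
#' @param allowMissingSmallest permit a call when only the smallest
#'   expected fragment is absent (default `FALSE`).
#' @return canonical genotype label. Failure raises a classed condition:
#'   `tgs_no_call` (no candidate matches; carries the `nearest` candidate)
#'   or `tgs_ambiguous_call` (several match; carries `candidates`).
#' @export
#' @examples
#' callGenotype("ACE", c(321, 594))  # "ID"
callGenotype <- function(locus, observedBp, toleranceBp = 5,
                         allowMissingSmallest = FALSE) {
  locus <- getLocus(locus)
  if (!is.numeric(observedBp) || length(observedBp) == 0L ||
      any(!is.finite(observedBp)) || any(observedBp <= 0))
    tgsStop("observed fragment lengths must be a non-empty positive numeric vector")
  if (!is.numeric(toleranceBp) || length(toleranceBp) != 1L || toleranceBp < 0)
    tgsStop("toleranceBp must be a single non-negative number")
  key <- digestKey(locus)
  candidates <- names(key@fragments)
  hits <- candidates[vapply(candidates, function(g)
    matchFragmentSets(observedBp, key@fragments[[g]], toleranceBp), logical(1))]
  if (length(hits) == 0L && allowMissingSmallest) {
    hits <- candidates[vapply(candidates, function(g) {
      fr <- key@fragments[[g]]
      length(fr) > 1L &&
        matchFragmentSets(observedBp, fr[fr != min(fr)], toleranceBp)
    }, logical(1))]
  }
  if (length(hits) == 1L) return(hits)
  if (length(hits) == 0L) {
    dist <- vapply(candidates, function(g)
      fragmentSetDistance(observedBp, key@fragments[[g]]), numeric(1))
    nearest <- candidates[which.min(dist)]
    stop(structure(
      class = c("tgs_no_call", "error", "condition"),
      list(message = sprintf(
        "no %s genotype matches bands [%s] at tolerance %g bp (nearest: %s)",
        locusName(locus), paste(sort(unique(observedBp)), collapse = ", "),
        toleranceBp, nearest),
        call = NULL, nearest = nearest)))
  }
  stop(structure(
    class = c("tgs_ambiguous_call", "error", "condition"),
    list(message = sprintf(
      "ambiguous %s call at tolerance %g bp: candidates %s",
      locusName(locus), toleranceBp, paste(hits, collapse = ", ")),
      call = NULL, candidates = hits)))
}

#' Simulate a gel observation for a genotype
#'
#' Perturbs the expected fragment lengths with seeded Gaussian sizing
#' noise, truncated below at 1 bp. With `noiseSdBp = 0` the expected set
#' is returned exactly.
#'
#' @inheritParams expectedFragments
#' @param noiseSdBp non-negative noise standard deviation in bp.
#' @param seed optional integer seed.
#' @return numeric vector of observed lengths, one per expected fragment.
#' @export
#' @examples
#' simulateFragments("CKM", "AG", noiseSdBp = 2, seed = 1)
simulateFragments <- function(locus, genotype, noiseSdBp = 0, seed = NULL) {
  if (!is.numeric(noiseSdBp) || length(noiseSdBp) != 1L || noiseSdBp < 0)
    tgsStop("noiseSdBp must be a single non-negative number")
  expected <- expectedFragments(locus, genotype)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pmax(1, expected + stats::rnorm(length(expected), sd = noiseSdBp))
}

#' Batch genotype calling from a fragment table
#'
#' Calls every row of a table of gel reads and records the outcome instead
#' of stopping at the first failure. This is the engine behind the
#' `call-rflp` command.
#'
#' @param fragments data.frame with columns `athlete_id`, `locus` and
#'   `fragments_bp` (semicolon-separated lengths, e.g. `"319;597"`).
#' @inheritParams callGenotype
#' @return the input with `called_genotype` (NA when not callable) and
#'   `call_status` (`"ok"`, `"ok_missing_smallest"`, `"no_call"`,
#'   `"ambiguous"`) appended.
#' @export
callRflpBatch <- function(fragments, toleranceBp = 5,
                          allowMissingSmallest = FALSE) {
  need <- c("athlete_id", "locus", "fragments_bp")
  missing <- setdiff(need, names(fragments))
  if (length(missing))
    tgsStop(sprintf("fragment table is missing column(s): %s",
                    paste(missing, collapse = ", ")))
  out <- fragments
  out$called_genotype <- NA_character_
  out$call_status <- NA_character_
  for (i in seq_len(nrow(out))) {
    lens <- suppressWarnings(
      as.numeric(strsplit(as.character(out$fragments_bp[i]), ";")[[1]]))
    if (length(lens) == 0L || anyNA(lens))
      tgsStop(sprintf("row %d: cannot parse fragments_bp '%s'", i,
                      out$fragments_bp[i]))
    res <- tryCatch({
      g <- callGenotype(out$locus[i], lens, toleranceBp = toleranceBp,
                        allowMissingSmallest = FALSE)
      list(g = g, status = "ok")
    },
    tgs_no_call = function(e) {
      if (allowMissingSmallest) {
        tryCatch(list(g = callGenotype(out$locus[i], lens,
                                       toleranceBp = toleranceBp,
                                       allowMissingSmallest = TRUE),
                      status = "ok_missing_smallest"),
                 tgs_no_call = function(e2) list(g = NA_character_, status = "no_call"),
                 tgs_ambiguous_call = function(e2) list(g = NA_character_, status = "ambiguous"))
      } else list(g = NA_character_, status = "no_call")
    },
    tgs_ambiguous_call = function(e) list(g = NA_character_, status = "ambiguous"))
    out$called_genotype[i] <- res$g
    out$call_status[i] <- res$status
  }
  out
}
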