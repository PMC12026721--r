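#' @include cohort.R
NULL

#' Read a cohort CSV
#'
#' Fixed dialect: UTF-8, comma-delimited, header row, `.` decimal.
#' Genotype labels are normalized (either allele order accepted) and the
#' resulting cohort is validated; problems are reported with the
#' offending row.
#'
#' @param path path to a CSV with the columns listed under
#'   [Cohort-class].
#' @return a [Cohort-class].
#' @export
readCohortCsv <- function(path) {
  if (!file.exists(path))
    tgsStop(sprintf("cohort file not found: %s", path), class = "tgs_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  unknown <- setdiff(names(df), cohortColumns)
  if (length(unknown))
    tgsStop(sprintf("unknown column(s) in %s: %s", path,
                    paste(unknown, collapse = ", ")))
  missing <- setdiff(cohortColumns, names(df))
  if (length(missing))
    tgsStop(sprintf("missing column(s) in %s: %s", path,
                    paste(missing, collapse = ", ")))
  numCols <- c("age_years", "body_mass_kg", "height_cm",
               "technique_min_wk", "strength_min_wk", "aerobic_min_wk")
  for (col in numCols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])))
    if (length(bad))
      tgsStop(sprintf("row %d: cannot parse %s '%s'", bad[1L], col,
                      df[[col]][bad[1L]]))
    df[[col]] <- v
  }
  for (loc in names(genotypeColumn)) {
    col <- genotypeColumn[[loc]]
    df[[col]][!nzchar(trimws(df[[col]]))] <- NA_character_
    for (i in seq_len(nrow(df))) {
      if (is.na(df[[col]][i])) next
      df[[col]][i] <- tryCatch(normalizeGenotype(loc, trimws(df[[col]][i])),
        tgs_validation_error = function(e)
          tgsStop(sprintf("row %d: %s", i, conditionMessage(e))))
    }
  }
  dup <- df$athlete_id[duplicated(df$athlete_id)]
  if (length(dup)) {
    rows <- which(df$athlete_id %in% dup)
    tgsStop(sprintf("duplicate athlete_id '%s' (rows %s)", unique(dup)[1L],
                    paste(rows, collapse = ", ")))
  }
  Cohort(df)
}

#' Write a cohort CSV
#'
#' Canonical dialect (UTF-8, comma, header, `.` decimal); the inverse of
#' [readCohortCsv()] on canonical files.
#'
#' @param cohort a [Cohort-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(is(cohort, "Cohort"))
  utils::write.csv(athleteTable(cohort), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration file
#'
#' Plain-text `key = value` lines; `#` starts a comment. Recognized keys:
#' `scheme` (`power` or `endurance`), `threshold_low`, `threshold_high`,
#' `tolerance_bp`, `seed`. Unknown keys and malformed numbers are
#' errors; omitted keys take the package defaults.
#'
#' @param path path to the config file; `NULL` returns the defaults.
#' @return list with `scheme` (a [ScoringScheme-class]), `thresholds`,
#'   `toleranceBp` and `seed`.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- list(scheme = powerScheme(), thresholds = defaultThresholds(),
              toleranceBp = 5, seed = 1L)
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    tgsStop(sprintf("config file not found: %s", path), class = "tgs_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  num <- function(key, v) {
    x <- suppressWarnings(as.numeric(trimws(v)))
    if (is.na(x)) tgsStop(sprintf("config: '%s' is not a number for %s", v, key),
                          class = "tgs_config_error")
    x
  }
  for (pair in kv) {
    if (length(pair) != 2L)
      tgsStop(sprintf("config: cannot parse line '%s'",
                      paste(pair, collapse = "=")), class = "tgs_config_error")
    key <- trimws(pair[1L]); val <- trimws(pair[2L])
    switch(key,
      scheme = {
        cfg$scheme <- switch(val,
          power = powerScheme(),
          endurance = reverseScheme(powerScheme()),
          tgsStop(sprintf("config: unknown scheme '%s'", val),
                  class = "tgs_config_error"))
      },
      threshold_low = cfg$thresholds[1L] <- num(key, val),
      threshold_high = cfg$thresholds[2L] <- num(key, val),
      tolerance_bp = cfg$toleranceBp <- num(key, val),
      seed = cfg$seed <- as.integer(num(key, val)),
      tgsStop(sprintf("config: unknown key '%s'", key),
              class = "tgs_config_error"))
  }
  if (!(0 < cfg$thresholds[1L] && cfg$thresholds[1L] < cfg$thresholds[2L] &&
        cfg$thresholds[2L] < 100))
    tgsStop("config: thresholds must satisfy 0 < low < high < 100",
            class = "tgs_config_error")
  cfg
}
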