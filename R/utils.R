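#' Controlled vocabularies
#'
#' Enumerated values used throughout the package: compound classes, link
#' types, Therapeutic Target Database (TTD) development statuses, protein
#' biochemical families and subcellular compartments.
#'
#' @name vocabularies
#' @aliases compoundClasses linkTypes ttdStatuses proteinFamilies
#'   subcellularLocations
NULL

#' @rdname vocabularies
#' @return `compoundClasses()`: the two compound classes.
#' @export
compoundClasses <- function() c("herbal_ingredient", "western_drug")

#' @rdname vocabularies
#' @return `linkTypes()`: the two compound-target link types.
#' @export
linkTypes <- function() c("direct", "indirect")

#' @rdname vocabularies
#' @return `ttdStatuses()`: the four TTD development stages plus `"absent"`
#'   (target not recorded in TTD).
#' @export
ttdStatuses <- function() {
  c("successful", "clinical_trial", "research", "discontinued", "absent")
}

#' @rdname vocabularies
#' @return `proteinFamilies()`: the biochemical family categories.
#' @export
proteinFamilies <- function() {
  c("enzyme", "channel_transporter", "receptor", "factor_regulator",
    "structure", "binding", "other")
}

#' @rdname vocabularies
#' @return `subcellularLocations()`: the compartment categories.
#' @export
subcellularLocations <- function() {
  c("plasma_membrane", "cytoplasm", "nucleus", "blood", "other")
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, the convention used for every printed
#' percentage and ratio in the package's report tables (so that e.g. 2.375
#' rounds to 2.38 at two decimals, where [base::round()] would give 2.37).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' roundHalfUp(2.375, 2) # 2.38
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage with the package rounding convention, printed to 1 decimal
pctHalfUp <- function(count, denominator, digits = 1) {
  roundHalfUp(100 * count / denominator, digits)
}

# internal: stop() with call. = FALSE
fail <- function(...) stop(..., call. = FALSE)

# internal: check a character vector only uses allowed tokens
checkTokens <- function(x, allowed, what) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    fail("unknown ", what, " value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  invisible(TRUE)
}

# internal: split a ";"-delimited cell into a trimmed character vector
splitListCell <- function(x) {
  out <- lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  lapply(out, function(v) v[nzchar(v)])
}

# internal: join a list column back into ";"-delimited cells
joinListCell <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}
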