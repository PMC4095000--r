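#' Accessors for the package's S4 containers
#'
#' Small accessor generics: use these instead of reaching into slots.
#'
#' @param x the object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x, ...) standardGeneric("compoundIds"))

#' @rdname accessors
#' @export
setGeneric("targetIds", function(x, ...) standardGeneric("targetIds"))

#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x, ...) standardGeneric("pathwayIds"))

#' @rdname accessors
#' @export
setGeneric("compoundLinks", function(x, ...) standardGeneric("compoundLinks"))

#' @rdname accessors
#' @export
setGeneric("annotationTable", function(x, ...)
  standardGeneric("annotationTable"))

#' @rdname accessors
#' @export
setGeneric("pathwayMembers", function(x, ...)
  standardGeneric("pathwayMembers"))

#' @rdname accessors
#' @export
setGeneric("pathwayCategory", function(x, ...)
  standardGeneric("pathwayCategory"))

#' Direct / all target extraction
#'
#' `directTargets()` returns the distinct target ids linked with
#' `link_type == "direct"`; `allTargets()` returns the distinct target ids
#' over both link types. Both optionally restrict to one compound class.
#'
#' @param x a [CompoundTable-class] or [CvdDataset-class].
#' @param compoundClass optional class filter, one of
#'   `"herbal_ingredient"`, `"western_drug"`.
#' @param ... passed to methods.
#' @return character vector of distinct target ids (sorted).
#' @export
setGeneric("directTargets", function(x, compoundClass = NULL, ...)
  standardGeneric("directTargets"))

#' @rdname directTargets
#' @export
setGeneric("allTargets", function(x, compoundClass = NULL, ...)
  standardGeneric("allTargets"))
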