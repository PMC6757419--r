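#' Identifier and slot accessors
#'
#' `mirnaIds()` and `diseaseIds()` return the ordered identifier lists of
#' an object; `nMirna()`/`nDisease()` their lengths; `simIds()` and
#' `simKind()` the identifiers and kind tag of a [SimilarityMatrix-class];
#' `scoreStage()` the stage tag of a [ScoreMatrix-class];
#' `transferWr()`/`transferWd()` the two weight matrices of a
#' [TransferWeights-class].
#'
#' @param x an object of the appropriate class.
#' @return A character vector, integer, matrix or character scalar as
#'   appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("nMirna", function(x) standardGeneric("nMirna"))

#' @rdname accessors
#' @export
setGeneric("nDisease", function(x) standardGeneric("nDisease"))

#' @rdname accessors
#' @export
setGeneric("simIds", function(x) standardGeneric("simIds"))

#' @rdname accessors
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))

#' @rdname accessors
#' @export
setGeneric("scoreStage", function(x) standardGeneric("scoreStage"))

#' @rdname accessors
#' @export
setGeneric("transferWr", function(x) standardGeneric("transferWr"))

#' @rdname accessors
#' @export
setGeneric("transferWd", function(x) standardGeneric("transferWd"))
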