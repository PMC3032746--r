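#' Accessors for FmoSystem, Molecule and PlsModel objects
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an \linkS4class{FmoSystem}, \linkS4class{Molecule} or
#'   \linkS4class{PlsModel} object, as appropriate.
#' @return \code{fmoFragments} and \code{fmoPairs} return data.frames;
#'   \code{ligandIndex} the designated ligand fragment index (or \code{NA});
#'   \code{atoms} and \code{bonds} data.frames; \code{nComponents} an
#'   integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fmoFragments", function(x) standardGeneric("fmoFragments"))
#' @rdname accessors
#' @export
setMethod("fmoFragments", "FmoSystem", function(x) x@fragments)

#' @rdname accessors
#' @export
setGeneric("fmoPairs", function(x) standardGeneric("fmoPairs"))
#' @rdname accessors
#' @export
setMethod("fmoPairs", "FmoSystem", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("ligandIndex", function(x) standardGeneric("ligandIndex"))
#' @rdname accessors
#' @export
setMethod("ligandIndex", "FmoSystem", function(x) x@ligandIndex)

#' @rdname accessors
#' @export
setGeneric("ligandIndex<-", function(x, value) standardGeneric("ligandIndex<-"))
#' @rdname accessors
#' @param value replacement value.
#' @export
setMethod("ligandIndex<-", "FmoSystem", function(x, value) {
  x@ligandIndex <- as.integer(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "Molecule", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setMethod("bonds", "Molecule", function(x) x@bonds)

#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setMethod("nComponents", "PlsModel", function(x) x@nComponents)

#' @rdname accessors
#' @export
setMethod("coef", "PlsModel", function(object, ...) {
  c(stats::setNames(object@intercept, "(Intercept)"),
    stats::setNames(object@coefficients, object@columns))
})

#' @rdname accessors
#' @param object a \linkS4class{PlsModel}.
#' @param ... unused.
#' @export
setMethod("fitted", "PlsModel", function(object, ...) object@fitted)
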