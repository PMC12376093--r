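#' Accessor generics
#'
#' Small accessor family used across the package instead of direct slot
#' access: \code{waveAxis} returns the wavenumber axis (cm^-1),
#' \code{specValues} the per-point values, \code{specRole} the role tag,
#' \code{validMask} the logical validity mask, and \code{specMeta} the
#' provenance list. \code{pumpAxis}, \code{probeAxis} and
#' \code{signalMatrix} access the 2D container.
#'
#' @param x an object of the matching class.
#' @return the slot contents (see the class documentation).
#' @name accessors
#' @aliases waveAxis specValues specRole validMask specMeta
#'   pumpAxis probeAxis signalMatrix
#' @examples
#' s <- spectrum1d(c(1600, 1610, 1620), c(0.1, 0.2, 0.3), role = "od")
#' waveAxis(s)
#' specValues(s)
NULL

#' @rdname accessors
#' @export
setGeneric("waveAxis", function(x) standardGeneric("waveAxis"))

#' @rdname accessors
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))

#' @rdname accessors
#' @export
setGeneric("specRole", function(x) standardGeneric("specRole"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("specMeta", function(x) standardGeneric("specMeta"))

#' @rdname accessors
#' @export
setGeneric("pumpAxis", function(x) standardGeneric("pumpAxis"))

#' @rdname accessors
#' @export
setGeneric("probeAxis", function(x) standardGeneric("probeAxis"))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
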