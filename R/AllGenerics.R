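#' @include AllClasses.R
NULL

#' Accessors for GenomeAnnotation and BinnedTrack
#'
#' @param x a [GenomeAnnotation-class] or [BinnedTrack-class] object.
#' @name accessors
#' @return The corresponding slot content: data.frames for
#'   \code{chromosomes}, \code{origins} and \code{centromeres}; character
#'   for \code{mitoNames} and \code{trackStage}; the named value list for
#'   \code{trackValues}; a single number for \code{binWidth}.
NULL

#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))
#' @rdname accessors
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))
#' @rdname accessors
#' @export
setGeneric("mitoNames", function(x) standardGeneric("mitoNames"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("trackStage", function(x) standardGeneric("trackStage"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname accessors
setMethod("chromosomes", "GenomeAnnotation", function(x) x@chromosomes)
#' @rdname accessors
setMethod("origins", "GenomeAnnotation", function(x) x@origins)
#' @rdname accessors
setMethod("centromeres", "GenomeAnnotation", function(x) x@centromeres)
#' @rdname accessors
setMethod("mitoNames", "GenomeAnnotation", function(x) x@mitoNames)
#' @rdname accessors
setMethod("trackValues", "BinnedTrack", function(x) x@values)
#' @rdname accessors
setMethod("trackStage", "BinnedTrack", function(x) x@stage)
#' @rdname accessors
setMethod("binWidth", "BinnedTrack", function(x) x@binWidth)

#' Rolling mean smoothing
#'
#' Centered moving average, applied per chromosome for tracks. See the
#' method documentation in [rollingMean()].
#'
#' @param x numeric vector or [BinnedTrack-class].
#' @param window odd window size in bins.
#' @export
setGeneric("rollingMean", function(x, window) standardGeneric("rollingMean"))
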