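#' @include AllClasses.R
NULL

#' Accessors for panel-backed objects
#'
#' `snpIds()`, `snpChrom()`, `snpPos()`, `isMapped()` extract the marker
#' map columns; `panel()` the underlying [SnpPanel-class]; `calls()` the
#' raw call matrix; `codes()` the parent-of-origin code matrix;
#' `sampleNames()` the sample columns; `chromLengths()` the named vector
#' of chromosome physical lengths.
#'
#' @param x a nilscan object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("snpChrom", function(x) standardGeneric("snpChrom"))

#' @rdname accessors
#' @export
setGeneric("snpPos", function(x) standardGeneric("snpPos"))

#' @rdname accessors
#' @export
setGeneric("isMapped", function(x) standardGeneric("isMapped"))

#' @rdname accessors
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("parentAlleles", function(x) standardGeneric("parentAlleles"))

#' @rdname accessors
#' @export
setGeneric("trueIntervals", function(x) standardGeneric("trueIntervals"))

#' @rdname accessors
#' @export
setGeneric("trueGenotypes", function(x) standardGeneric("trueGenotypes"))

#' @rdname accessors
#' @export
setGeneric("trueDrag", function(x) standardGeneric("trueDrag"))
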