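#' Accessors for package classes
#'
#' \code{blocks} returns the block GRanges of a \linkS4class{HaploblockSet};
#' \code{referenceGenome} and \code{queryGenome} its genome labels;
#' \code{hbParams} its parameters; \code{chromLengths} its chromosome-length
#' vector. \code{genomePanel} and \code{orthogroups} access an
#' \linkS4class{OrthogroupTable}; \code{alignmentRecords} the record
#' data.frame of an \linkS4class{AlignmentSet}.
#'
#' @param x the object.
#' @return The slot value (see Details of each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname accessors
#' @export
setMethod("blocks", "HaploblockSet", function(x) x@blocks)

#' @rdname accessors
#' @export
setGeneric("referenceGenome", function(x) standardGeneric("referenceGenome"))

#' @rdname accessors
#' @export
setMethod("referenceGenome", "HaploblockSet", function(x) x@referenceGenome)

#' @rdname accessors
#' @export
setGeneric("queryGenome", function(x) standardGeneric("queryGenome"))

#' @rdname accessors
#' @export
setMethod("queryGenome", "HaploblockSet", function(x) x@queryGenome)

#' @rdname accessors
#' @export
setGeneric("hbParams", function(x) standardGeneric("hbParams"))

#' @rdname accessors
#' @export
setMethod("hbParams", "HaploblockSet", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setMethod("chromLengths", "HaploblockSet", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setGeneric("genomePanel", function(x) standardGeneric("genomePanel"))

#' @rdname accessors
#' @export
setMethod("genomePanel", "OrthogroupTable", function(x) x@panel)

#' @rdname accessors
#' @export
setGeneric("orthogroups", function(x) standardGeneric("orthogroups"))

#' @rdname accessors
#' @export
setMethod("orthogroups", "OrthogroupTable", function(x) x@groups)

#' @rdname accessors
#' @export
setGeneric("alignmentRecords",
           function(x) standardGeneric("alignmentRecords"))

#' @rdname accessors
#' @export
setMethod("alignmentRecords", "AlignmentSet", function(x) x@records)
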