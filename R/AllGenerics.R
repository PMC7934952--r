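#' Accessors for Methylome and AnnotationSet objects
#'
#' \code{methCalls} returns the call \code{GRanges}; \code{methLevel} the
#' per-call fractional methylation \eqn{m/(m+u)}; \code{cpgCoverage} the
#' per-call read depth \eqn{m+u}; \code{sampleId}, \code{sampleSex} and
#' \code{sampleTissue} the sample metadata. \code{annoGenes},
#' \code{annoPromoters}, \code{annoGeneBodies} and \code{annoIntergenic}
#' return the components of an \code{AnnotationSet}.
#'
#' @param x a \code{Methylome} or \code{AnnotationSet}.
#' @return See each accessor's description.
#' @name accessors
#' @examples
#' m <- Methylome("s", 10, m = 3, u = 1)
#' methLevel(m)     # 0.75
#' cpgCoverage(m)   # 4
NULL

#' @rdname accessors
#' @export
setGeneric("methCalls", function(x) standardGeneric("methCalls"))
#' @rdname accessors
#' @export
setGeneric("methLevel", function(x) standardGeneric("methLevel"))
#' @rdname accessors
#' @export
setGeneric("cpgCoverage", function(x) standardGeneric("cpgCoverage"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("sampleSex", function(x) standardGeneric("sampleSex"))
#' @rdname accessors
#' @export
setGeneric("sampleTissue", function(x) standardGeneric("sampleTissue"))

#' @rdname accessors
#' @export
setGeneric("annoGenes", function(x) standardGeneric("annoGenes"))
#' @rdname accessors
#' @export
setGeneric("annoPromoters", function(x) standardGeneric("annoPromoters"))
#' @rdname accessors
#' @export
setGeneric("annoGeneBodies", function(x) standardGeneric("annoGeneBodies"))
#' @rdname accessors
#' @export
setGeneric("annoIntergenic", function(x) standardGeneric("annoIntergenic"))

#' @rdname accessors
setMethod("methCalls", "Methylome", function(x) x@calls)
#' @rdname accessors
setMethod("methLevel", "Methylome", function(x) {
    m <- mcols(x@calls)$m; u <- mcols(x@calls)$u
    m / (m + u)
})
#' @rdname accessors
setMethod("cpgCoverage", "Methylome",
    function(x) mcols(x@calls)$m + mcols(x@calls)$u)
#' @rdname accessors
setMethod("sampleId", "Methylome", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleSex", "Methylome", function(x) x@sex)
#' @rdname accessors
setMethod("sampleTissue", "Methylome", function(x) x@tissue)

#' @rdname accessors
setMethod("annoGenes", "AnnotationSet", function(x) x@genes)
#' @rdname accessors
setMethod("annoPromoters", "AnnotationSet", function(x) x@promoters)
#' @rdname accessors
setMethod("annoGeneBodies", "AnnotationSet", function(x) x@geneBodies)
#' @rdname accessors
setMethod("annoIntergenic", "AnnotationSet", function(x) x@intergenic)
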