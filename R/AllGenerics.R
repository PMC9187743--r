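#' Gene identifiers held by an object
#'
#' @param x a [GeneAnnotation-class], [DifferentialTable-class] or
#'   [GeneSetCollection-class].
#' @return character vector of gene ids (for a collection, the union over
#'   all sets).
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneAnnotation", function(x) x$gene_id)

#' @rdname geneIds
#' @export
setMethod("geneIds", "DifferentialTable", function(x) x$gene_id)

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneSetCollection",
    function(x) unique(unlist(as.list(x), use.names = FALSE)))

#' Contrast name of a differential table
#'
#' @param x a [DifferentialTable-class].
#' @return single string.
#' @export
setGeneric("contrastName", function(x) standardGeneric("contrastName"))

#' @rdname contrastName
#' @export
setMethod("contrastName", "DifferentialTable", function(x) x@contrastName)

#' Pileup positions of a CAGE track
#'
#' @param x a [CageTrack-class].
#' @return `GRanges` of width-1 stranded anchors with integer `score` counts.
#' @export
setGeneric("pileupPositions", function(x) standardGeneric("pileupPositions"))

#' @rdname pileupPositions
#' @export
setMethod("pileupPositions", "CageTrack", function(x) x@positions)
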