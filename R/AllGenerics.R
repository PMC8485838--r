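#' @include AllClasses.R
NULL

#' Accessors for cpPhylogeo classes
#'
#' `sampleIDs()` returns sample names, `alnLength()` the alignment width in bp,
#' `seqMatrix()` the character matrix (samples x columns), `partitions()` the
#' region spans, `sampleData()` the attached metadata. For [HaplotypeTable]:
#' `hapLabels()`, `hapSequences()`, `hapCounts()` and `nSamples()`. For
#' [HaploNetwork]: `networkNodes()` and `networkEdges()`.
#'
#' @param x A cpPhylogeo object.
#' @param value Replacement value.
#' @return The slot contents documented above.
#' @name accessors
#' @aliases sampleIDs alnLength seqMatrix partitions sampleData sampleData<-
#'   hapLabels hapSequences hapCounts nSamples networkNodes networkEdges
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("alnLength", function(x) standardGeneric("alnLength"))
#' @rdname accessors
#' @export
setGeneric("seqMatrix", function(x) standardGeneric("seqMatrix"))
#' @rdname accessors
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))
#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setGeneric("sampleData<-", function(x, value) standardGeneric("sampleData<-"))
#' @rdname accessors
#' @export
setGeneric("hapLabels", function(x) standardGeneric("hapLabels"))
#' @rdname accessors
#' @export
setGeneric("hapSequences", function(x) standardGeneric("hapSequences"))
#' @rdname accessors
#' @export
setGeneric("hapCounts", function(x) standardGeneric("hapCounts"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
setMethod("sampleIDs", "HaploAlignment", function(x) names(x@seqs))
#' @rdname accessors
setMethod("alnLength", "HaploAlignment", function(x) Biostrings::width(x@seqs)[1])
#' @rdname accessors
setMethod("seqMatrix", "HaploAlignment", function(x) as.matrix(x@seqs))
#' @rdname accessors
setMethod("partitions", "HaploAlignment", function(x) x@partitions)
#' @rdname accessors
setMethod("sampleData", "HaploAlignment", function(x) x@sampleData)
#' @rdname accessors
setMethod("sampleData<-", "HaploAlignment", function(x, value) {
  stopifnot(is.data.frame(value))
  miss <- setdiff(names(x@seqs), value$sample_id)
  if (length(miss))
    stop("metadata missing for samples: ", paste(miss, collapse = ", "))
  extra <- setdiff(value$sample_id, names(x@seqs))
  if (length(extra))
    message("metadata rows with unknown sample ids ignored: ",
            paste(extra, collapse = ", "))
  x@sampleData <- value[match(names(x@seqs), value$sample_id), , drop = FALSE]
  rownames(x@sampleData) <- NULL
  validObject(x)
  x
})
#' @rdname accessors
setMethod("hapLabels", "HaplotypeTable", function(x) names(x@sequences))
#' @rdname accessors
setMethod("hapSequences", "HaplotypeTable", function(x) x@sequences)
#' @rdname accessors
setMethod("hapCounts", "HaplotypeTable", function(x) x@counts)
#' @rdname accessors
setMethod("nSamples", "HaplotypeTable", function(x) sum(x@counts))
#' @rdname accessors
setMethod("networkNodes", "HaploNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "HaploNetwork", function(x) x@edges)
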