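#' @rdname accessors
#' @export
setGeneric("pm", function(object) standardGeneric("pm"))

#' @rdname accessors
#' @export
setGeneric("mm", function(object) standardGeneric("mm"))

#' @rdname accessors
#' @export
setGeneric("probeSets", function(object) standardGeneric("probeSets"))

#' @rdname accessors
#' @export
setGeneric("probesPerSet", function(object) standardGeneric("probesPerSet"))

#' @rdname accessors
#' @export
setGeneric("annotation", function(object) standardGeneric("annotation"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("methodTag", function(object) standardGeneric("methodTag"))

#' @rdname accessors
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("detectionPvalues",
           function(object) standardGeneric("detectionPvalues"))

#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))

#' Accessors for boutiquenorm data objects
#'
#' \code{pm}/\code{mm} return the linear-scale perfect-match and mismatch
#' intensity matrices of a \linkS4class{ProbeLevelMatrix};
#' \code{probeSets} the probe-set identifiers in block order;
#' \code{probesPerSet} the number of probe pairs per probe set;
#' \code{annotation} the attached \linkS4class{ProbeSetAnnotation};
#' \code{exprValues} the log2 expression matrix of an
#' \linkS4class{ExpressionMatrix}; \code{methodTag} its normalization tag;
#' \code{calls}/\code{detectionPvalues} the call and p-value matrices of a
#' \linkS4class{DetectionCalls}; \code{sampleMeta} the sample sheet of any
#' of these as a plain data.frame.
#'
#' @param object a boutiquenorm data object.
#' @return See description; matrices keep probe-set ids as rownames and
#'   sample ids as colnames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("pm", "ProbeLevelMatrix",
          function(object) assay(object, "pm"))

#' @rdname accessors
#' @export
setMethod("mm", "ProbeLevelMatrix",
          function(object) assay(object, "mm"))

#' @rdname accessors
#' @export
setMethod("probeSets", "ProbeLevelMatrix", function(object)
  unique(as.character(rowData(object)$probeset_id)))

#' @rdname accessors
#' @export
setMethod("probeSets", "ExpressionMatrix", function(object) rownames(object))

#' @rdname accessors
#' @export
setMethod("probeSets", "DetectionCalls", function(object) rownames(object))

#' @rdname accessors
#' @export
setMethod("probesPerSet", "ProbeLevelMatrix",
          function(object) object@probesPerSet)

#' @rdname accessors
#' @export
setMethod("annotation", "ProbeLevelMatrix",
          function(object) object@annotation)

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(object) assay(object, "exprs"))

#' @rdname accessors
#' @export
setMethod("methodTag", "ExpressionMatrix", function(object) object@methodTag)

#' @rdname accessors
#' @export
setMethod("calls", "DetectionCalls", function(object) assay(object, "call"))

#' @rdname accessors
#' @export
setMethod("detectionPvalues", "DetectionCalls",
          function(object) assay(object, "pvalue"))

#' @rdname accessors
#' @export
setMethod("sampleMeta", "SummarizedExperiment", function(object) {
  df <- as.data.frame(colData(object))
  rownames(df) <- NULL
  df
})
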