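#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.SPECIES <- c("arabidopsis", "medicago")
.CATEGORIES <- c("defl", "meg", "marker", "invariant", "control")
.SUFFIX_CLASSES <- c(unique = "_at", shared = "_s_at", cross_hyb = "_x_at")
.METHOD_TAGS <- c("raw_summary", "rma", "sbq", "rmaps", "rims")
.SAMPLE_COLS <- c("sample_id", "tissue", "condition",
                  "replicate_group", "replicate_index")

#' Error helper: all validation failures carry a distinct condition class
#' @noRd
bnStop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "boutiquenorm_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

#' Parameters of the Present/Marginal/Absent detection call
#'
#' Thresholds for the one-sided signed-rank detection test applied to
#' discrimination scores \eqn{R_i = (PM_i - MM_i)/(PM_i + MM_i)}.  A probe
#' set is called Present when the detection p-value is below \code{alpha1},
#' Marginal when it lies in \code{[alpha1, alpha2)} and Absent otherwise.
#' \code{tau} is the discrimination threshold subtracted from the scores
#' before testing.  The default \code{alpha1 = 0.05} is the value
#' recommended for probe sets of 11 probe pairs; \code{alpha2} and
#' \code{tau} are the conventional MAS5 defaults.
#'
#' @param alpha1 Present threshold, in (0, alpha2).
#' @param alpha2 Marginal threshold, in (alpha1, 0.5).
#' @param tau discrimination threshold, non-negative.
#' @return A \code{DetectionParams} object.
#' @examples
#' DetectionParams()
#' DetectionParams(alpha1 = 0.04)
#' @export
DetectionParams <- function(alpha1 = 0.05, alpha2 = 0.065, tau = 0.015) {
  new("DetectionParams", alpha1 = alpha1, alpha2 = alpha2, tau = tau)
}

#' @rdname DetectionParams
#' @export
setClass("DetectionParams",
  representation(alpha1 = "numeric", alpha2 = "numeric", tau = "numeric"),
  prototype(alpha1 = 0.05, alpha2 = 0.065, tau = 0.015),
  validity = function(object) {
    if (length(object@alpha1) != 1L || length(object@alpha2) != 1L ||
        length(object@tau) != 1L)
      return("alpha1, alpha2 and tau must be scalars")
    if (!(object@alpha1 > 0 && object@alpha1 < object@alpha2 &&
          object@alpha2 < 0.5))
      return("need 0 < alpha1 < alpha2 < 0.5")
    if (object@tau < 0) return("tau must be >= 0")
    TRUE
  })

#' Analysis thresholds shared by the downstream operations
#'
#' @param invariant_cv_threshold genes with coefficient of variation
#'   strictly below this (linear scale) count as invariant; default 0.10.
#' @param coexpression_r2_threshold minimum squared Pearson correlation for
#'   the co-expression screen; default 0.70.
#' @param de_alpha significance level applied to BH-adjusted q-values.
#' @param expressed_rule_min_present minimum number of Present calls among a
#'   tissue's replicates for a gene to count as expressed there (default 2,
#'   i.e. 2 of 3 replicates).
#' @param random_seed integer seed recorded for reproducibility.
#' @return An \code{AnalysisConfig} object.
#' @examples
#' analysisConfig()
#' @export
analysisConfig <- function(invariant_cv_threshold = 0.10,
                           coexpression_r2_threshold = 0.70,
                           de_alpha = 0.05,
                           expressed_rule_min_present = 2L,
                           random_seed = 1L) {
  new("AnalysisConfig",
      invariant_cv_threshold = invariant_cv_threshold,
      coexpression_r2_threshold = coexpression_r2_threshold,
      de_alpha = de_alpha,
      expressed_rule_min_present = as.integer(expressed_rule_min_present),
      random_seed = as.integer(random_seed))
}

#' @rdname analysisConfig
#' @export
setClass("AnalysisConfig",
  representation(invariant_cv_threshold = "numeric",
                 coexpression_r2_threshold = "numeric",
                 de_alpha = "numeric",
                 expressed_rule_min_present = "integer",
                 random_seed = "integer"),
  prototype(invariant_cv_threshold = 0.10, coexpression_r2_threshold = 0.70,
            de_alpha = 0.05, expressed_rule_min_present = 2L,
            random_seed = 1L),
  validity = function(object) {
    thr <- c(object@invariant_cv_threshold, object@coexpression_r2_threshold,
             object@de_alpha)
    if (any(thr <= 0 | thr >= 1))
      return("thresholds must lie strictly in (0, 1)")
    if (object@expressed_rule_min_present < 1L)
      return("expressed_rule_min_present must be >= 1")
    TRUE
  })

#' Probe-set annotation for a boutique array
#'
#' One row per probe set: identity, species, functional category
#' (defensin-like, maternally-expressed, marker, invariant or control) and
#' the cross-hybridization suffix class encoded in Affymetrix-style probe
#' set names (\code{_at} unique, \code{_s_at} shared, \code{_x_at}
#' cross-hybridizing).
#'
#' @export
setClass("ProbeSetAnnotation", contains = "DFrame",
  validity = function(object) {
    need <- c("probeset_id", "species", "category", "suffix_class", "gene_ids")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
      return(paste("missing annotation column(s):",
                   paste(miss, collapse = ", ")))
    if (anyDuplicated(object$probeset_id))
      return("probeset_id values must be unique")
    if (!all(object$species %in% .SPECIES))
      return(paste("species must be one of:", paste(.SPECIES, collapse = ", ")))
    if (!all(object$category %in% .CATEGORIES))
      return(paste("category must be one of:",
                   paste(.CATEGORIES, collapse = ", ")))
    if (!all(object$suffix_class %in% names(.SUFFIX_CLASSES)))
      return(paste("suffix_class must be one of:",
                   paste(names(.SUFFIX_CLASSES), collapse = ", ")))
    TRUE
  })

#' Construct a ProbeSetAnnotation
#'
#' @param probeset_id character vector of unique probe-set identifiers.
#' @param species \code{"arabidopsis"} or \code{"medicago"} (recycled).
#' @param category functional category per probe set; one of \code{"defl"},
#'   \code{"meg"}, \code{"marker"}, \code{"invariant"}, \code{"control"}.
#' @param suffix_class \code{"unique"}, \code{"shared"} or
#'   \code{"cross_hyb"}; if missing, inferred from the probe-set id suffix
#'   (\code{_s_at}, \code{_x_at}, else unique).
#' @param gene_ids character vector of semicolon-delimited gene identifiers
#'   interrogated by each probe set (defaults to the probe-set id stem).
#' @return A \code{ProbeSetAnnotation}.
#' @examples
#' probeSetAnnotation(c("AT1G01010_at", "AT1G01020_s_at"),
#'                    category = c("defl", "invariant"))
#' @export
probeSetAnnotation <- function(probeset_id,
                               species = "arabidopsis",
                               category = "defl",
                               suffix_class = NULL,
                               gene_ids = NULL) {
  probeset_id <- as.character(probeset_id)
  if (is.null(suffix_class)) {
    suffix_class <- rep("unique", length(probeset_id))
    suffix_class[grepl("_s_at$", probeset_id)] <- "shared"
    suffix_class[grepl("_x_at$", probeset_id)] <- "cross_hyb"
  }
  if (is.null(gene_ids)) gene_ids <- sub("(_[sx])?_at$", "", probeset_id)
  df <- DataFrame(probeset_id = probeset_id,
                  species = rep_len(as.character(species), length(probeset_id)),
                  category = rep_len(as.character(category), length(probeset_id)),
                  suffix_class = rep_len(as.character(suffix_class),
                                         length(probeset_id)),
                  gene_ids = as.character(gene_ids))
  rownames(df) <- probeset_id
  new("ProbeSetAnnotation", df)
}

#' Probe-level intensities for a boutique array experiment
#'
#' A \linkS4class{SummarizedExperiment} with linear-scale \code{pm} and
#' \code{mm} assays (probes in rows, arrays in columns), stored
#' probe-set-major: each probe set occupies a contiguous block of
#' \code{probesPerSet} rows.  Row metadata carries \code{probeset_id} and
#' \code{probe_index}; column metadata carries the sample sheet
#' (\code{sample_id}, \code{tissue}, \code{condition},
#' \code{replicate_group}, \code{replicate_index}).  Intensities must be
#' strictly positive and finite; log2 transforms are applied inside
#' operations, never at rest.
#'
#' @export
setClass("ProbeLevelMatrix", contains = "SummarizedExperiment",
  representation(probesPerSet = "integer", annotation = "ProbeSetAnnotation"),
  validity = function(object) {
    if (!all(c("pm", "mm") %in% assayNames(object)))
      return("assays 'pm' and 'mm' are required")
    pmv <- assay(object, "pm"); mmv <- assay(object, "mm")
    if (!all(is.finite(pmv)) || !all(is.finite(mmv)))
      return("intensities must be finite")
    if (any(pmv <= 0) || any(mmv <= 0))
      return("intensities must be strictly positive")
    rd <- rowData(object)
    if (!all(c("probeset_id", "probe_index") %in% colnames(rd)))
      return("rowData must have probeset_id and probe_index")
    k <- object@probesPerSet
    ids <- as.character(rd$probeset_id)
    if (nrow(object) %% k != 0L)
      return("probe rows must be a multiple of probesPerSet")
    blocks <- matrix(ids, nrow = k)
    if (!all(blocks == rep(blocks[1L, ], each = k)))
      return("probes must be stored probe-set-major in contiguous blocks")
    if (anyDuplicated(blocks[1L, ]))
      return("probe sets must occupy a single contiguous block each")
    if (!all(rd$probe_index == rep(seq_len(k), ncol(blocks))))
      return("probe_index must run 1..probesPerSet within each block")
    missing <- setdiff(blocks[1L, ], object@annotation$probeset_id)
    if (length(missing))
      return(paste("probe set(s) absent from annotation:",
                   paste(utils::head(missing, 5L), collapse = ", ")))
    cd <- colData(object)
    mc <- setdiff(.SAMPLE_COLS, colnames(cd))
    if (length(mc))
      return(paste("missing sample column(s):", paste(mc, collapse = ", ")))
    if (anyDuplicated(paste(cd$replicate_group, cd$replicate_index)))
      return("(replicate_group, replicate_index) pairs must be unique")
    TRUE
  })

#' Construct a ProbeLevelMatrix
#'
#' @param pm,mm numeric matrices of linear-scale perfect-match and mismatch
#'   intensities, probes x arrays, probe-set-major row order.
#' @param annotation a \linkS4class{ProbeSetAnnotation} covering every probe
#'   set present.
#' @param samples a data.frame of sample metadata with columns
#'   \code{sample_id}, \code{tissue}, \code{condition},
#'   \code{replicate_group}, \code{replicate_index}; one row per array.
#' @param probeset_id character vector giving, in order, the probe set of
#'   each block of \code{probes_per_set} rows.
#' @param probes_per_set number of probe pairs per probe set (default 11).
#' @return A validated \code{ProbeLevelMatrix}.
#' @export
probeLevelMatrix <- function(pm, mm, annotation, samples, probeset_id,
                             probes_per_set = 11L) {
  probes_per_set <- as.integer(probes_per_set)
  if (!is.matrix(pm) || !is.matrix(mm) || !identical(dim(pm), dim(mm)))
    bnStop("bn_dim_error", "pm and mm must be matrices of identical shape")
  rd <- DataFrame(probeset_id = rep(probeset_id, each = probes_per_set),
                  probe_index = rep(seq_len(probes_per_set),
                                    length(probeset_id)))
  if (nrow(rd) != nrow(pm))
    bnStop("bn_dim_error",
           sprintf("pm has %d rows but %d probe sets x %d probes expected",
                   nrow(pm), length(probeset_id), probes_per_set))
  samples <- as.data.frame(samples)
  cd <- DataFrame(samples)
  rownames(cd) <- samples$sample_id
  dimnames(pm) <- dimnames(mm) <-
    list(paste(rd$probeset_id, rd$probe_index, sep = "."), samples$sample_id)
  se <- SummarizedExperiment(assays = list(pm = pm, mm = mm),
                             rowData = rd, colData = cd)
  new("ProbeLevelMatrix", se, probesPerSet = probes_per_set,
      annotation = annotation)
}

#' Summarized log2 expression for a boutique array experiment
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{exprs} assay of
#' log2 expression values (probe sets x arrays), tagged with the
#' normalization method that produced it (\code{raw_summary}, \code{rma},
#' \code{sbq}, \code{rmaps} or \code{rims}).
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment",
  representation(methodTag = "character"),
  validity = function(object) {
    if (!"exprs" %in% assayNames(object))
      return("assay 'exprs' is required")
    if (!all(is.finite(assay(object, "exprs"))))
      return("expression values must be finite")
    if (length(object@methodTag) != 1L ||
        !object@methodTag %in% .METHOD_TAGS)
      return(paste("methodTag must be one of:",
                   paste(.METHOD_TAGS, collapse = ", ")))
    cd <- colData(object)
    mc <- setdiff(.SAMPLE_COLS, colnames(cd))
    if (length(mc))
      return(paste("missing sample column(s):", paste(mc, collapse = ", ")))
    TRUE
  })

#' Construct an ExpressionMatrix
#'
#' @param exprs numeric matrix of log2 expression, probe sets x arrays, with
#'   probe-set ids as rownames.
#' @param samples data.frame of sample metadata (see
#'   \code{\link{probeLevelMatrix}}); defaults to a minimal sheet derived
#'   from the column names.
#' @param method_tag normalization tag; one of \code{"raw_summary"},
#'   \code{"rma"}, \code{"sbq"}, \code{"rmaps"}, \code{"rims"}.
#' @return An \code{ExpressionMatrix}.
#' @export
expressionMatrix <- function(exprs, samples = NULL,
                             method_tag = "raw_summary") {
  exprs <- as.matrix(exprs)
  if (is.null(samples)) {
    ids <- colnames(exprs)
    if (is.null(ids)) ids <- paste0("S", seq_len(ncol(exprs)))
    samples <- data.frame(sample_id = ids, tissue = "unknown",
                          condition = "unknown", replicate_group = ids,
                          replicate_index = 1L)
  }
  samples <- as.data.frame(samples)
  cd <- DataFrame(samples); rownames(cd) <- samples$sample_id
  colnames(exprs) <- samples$sample_id
  se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
  new("ExpressionMatrix", se, methodTag = method_tag)
}

#' Present/Marginal/Absent detection calls
#'
#' A \linkS4class{SummarizedExperiment} holding the \code{call} matrix
#' (\code{"P"}, \code{"M"} or \code{"A"}) and the matching \code{pvalue}
#' matrix of exact one-sided signed-rank detection p-values, probe sets x
#' arrays, together with the \linkS4class{DetectionParams} used.
#'
#' @export
setClass("DetectionCalls", contains = "SummarizedExperiment",
  representation(params = "DetectionParams"),
  validity = function(object) {
    if (!all(c("call", "pvalue") %in% assayNames(object)))
      return("assays 'call' and 'pvalue' are required")
    cl <- assay(object, "call"); p <- assay(object, "pvalue")
    if (!all(cl %in% c("P", "M", "A")))
      return("calls must be 'P', 'M' or 'A'")
    if (any(p < 0 | p > 1)) return("p-values must lie in [0, 1]")
    a1 <- object@params@alpha1; a2 <- object@params@alpha2
    want <- ifelse(p < a1, "P", ifelse(p < a2, "M", "A"))
    if (!all(want == cl))
      return("calls inconsistent with p-values and thresholds")
    TRUE
  })

#' Ground truth of a simulated boutique-array experiment
#'
#' Records everything the generator knows: the noise-free log2 expression
#' per gene and condition, which genes were shifted and by how much, the
#' per-probe affinities, and the generator configuration, so that
#' parameter-recovery tests can compare estimates against truth.
#'
#' @export
setClass("SimulationTruth",
  representation(trueExpression = "matrix", sampleExpression = "matrix",
                 shifted = "character", silent = "character",
                 effects = "numeric", affinities = "numeric",
                 config = "list"))

setMethod("show", "ProbeSetAnnotation", function(object) {
  cat("ProbeSetAnnotation with", nrow(object), "probe sets\n")
  tab <- table(object$category)
  cat("  categories:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ProbeLevelMatrix", function(object) {
  cat("ProbeLevelMatrix:", nrow(object) / object@probesPerSet,
      "probe sets x", ncol(object), "arrays (",
      object@probesPerSet, "probe pairs/set )\n")
  cat("  replicate groups:",
      paste(unique(colData(object)$replicate_group), collapse = ", "), "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix [", object@methodTag, "]: ", nrow(object),
      " probe sets x ", ncol(object), " arrays\n", sep = "")
})

setMethod("show", "DetectionCalls", function(object) {
  cl <- assay(object, "call")
  cat("DetectionCalls:", nrow(object), "probe sets x", ncol(object),
      "arrays\n")
  cat(sprintf("  P: %d  M: %d  A: %d  (alpha1=%g, alpha2=%g, tau=%g)\n",
              sum(cl == "P"), sum(cl == "M"), sum(cl == "A"),
              object@params@alpha1, object@params@alpha2,
              object@params@tau))
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@trueExpression), "genes x",
      ncol(object@trueExpression), "conditions;",
      length(object@shifted), "shifted,", length(object@silent),
      "silent genes\n")
})
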