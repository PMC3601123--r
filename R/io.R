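## Tab-separated interchange formats.  All numeric values are written with
## 17 significant digits so write/read round-trips are exact for doubles.

.fmtNum <- function(x) sprintf("%.17g", x)

.checkHeader <- function(got, want, what) {
  if (!identical(got, want))
    bnStop("bn_malformed_header",
           sprintf("malformed %s header: expected columns [%s], got [%s]",
                   what, paste(want, collapse = ", "),
                   paste(got, collapse = ", ")))
}

#' Read and write probe-level intensity tables
#'
#' The probe-level dialect is long-format TSV with columns
#' \code{probeset_id, probe_index, sample_id, pm, mm}, one row per probe
#' per array, linear-scale intensities, \code{#}-prefixed comment lines
#' ignored.  Probe sets are ordered as in the annotation; probes within a
#' probe set by \code{probe_index}.
#'
#' @param path file path.
#' @param annotation a \linkS4class{ProbeSetAnnotation}; every probe set in
#'   the file must appear in it.
#' @param samples optional sample metadata data.frame; if omitted a minimal
#'   sheet is derived from the sample ids in the file.
#' @param probes_per_set probe pairs per probe set (default 11).
#' @return \code{readProbeLevel}: a validated
#'   \linkS4class{ProbeLevelMatrix}.
#' @export
readProbeLevel <- function(path, annotation, samples = NULL,
                           probes_per_set = 11L) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  .checkHeader(colnames(tab),
               c("probeset_id", "probe_index", "sample_id", "pm", "mm"),
               "probe-level")
  if (any(!is.finite(tab$pm)) || any(!is.finite(tab$mm)) ||
      any(tab$pm <= 0) || any(tab$mm <= 0))
    bnStop("bn_nonpositive_intensity",
           "probe intensities must be strictly positive and finite")
  unknown <- setdiff(unique(tab$probeset_id), annotation$probeset_id)
  if (length(unknown))
    bnStop("bn_unknown_probeset",
           paste("probe set(s) not in annotation:",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  k <- as.integer(probes_per_set)
  sets <- intersect(annotation$probeset_id, unique(tab$probeset_id))
  cnt <- table(tab$probeset_id)
  sample_ids <- unique(tab$sample_id)
  if (any(cnt != k * length(sample_ids)) ||
      any(tab$probe_index < 1L | tab$probe_index > k))
    bnStop("bn_probe_count_error",
           sprintf("every probe set needs exactly %d probes per array", k))
  if (is.null(samples)) {
    samples <- data.frame(sample_id = sample_ids, tissue = "unknown",
                          condition = "unknown",
                          replicate_group = sample_ids, replicate_index = 1L)
  } else {
    samples <- as.data.frame(samples)
    sample_ids <- samples$sample_id
  }
  rowpos <- (match(tab$probeset_id, sets) - 1L) * k + tab$probe_index
  colpos <- match(tab$sample_id, sample_ids)
  if (anyDuplicated(cbind(rowpos, colpos)))
    bnStop("bn_probe_count_error",
           "duplicate (probeset_id, probe_index, sample_id) rows")
  pmm <- mmm <- matrix(NA_real_, length(sets) * k, length(sample_ids))
  pmm[cbind(rowpos, colpos)] <- tab$pm
  mmm[cbind(rowpos, colpos)] <- tab$mm
  if (anyNA(pmm) || anyNA(mmm))
    bnStop("bn_probe_count_error",
           "file does not cover every probe x array combination")
  probeLevelMatrix(pmm, mmm, annotation = annotation, samples = samples,
                   probeset_id = sets, probes_per_set = k)
}

#' @rdname readProbeLevel
#' @param plm a \linkS4class{ProbeLevelMatrix} to write.
#' @export
writeProbeLevel <- function(plm, path) {
  rd <- rowData(plm)
  n <- ncol(plm)
  df <- data.frame(
    probeset_id = rep(as.character(rd$probeset_id), n),
    probe_index = rep(rd$probe_index, n),
    sample_id = rep(colnames(plm), each = nrow(plm)),
    pm = .fmtNum(as.vector(pm(plm))),
    mm = .fmtNum(as.vector(mm(plm))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write probe-set annotation tables
#'
#' Annotation TSV: columns \code{probeset_id, species, category,
#' suffix_class, gene_ids}, with \code{gene_ids} semicolon-delimited.
#'
#' @param path file path.
#' @return \code{readAnnotation}: a \linkS4class{ProbeSetAnnotation}.
#' @export
readAnnotation <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  .checkHeader(colnames(tab),
               c("probeset_id", "species", "category", "suffix_class",
                 "gene_ids"), "annotation")
  probeSetAnnotation(tab$probeset_id, species = tab$species,
                     category = tab$category,
                     suffix_class = tab$suffix_class,
                     gene_ids = tab$gene_ids)
}

#' @rdname readAnnotation
#' @param annot a \linkS4class{ProbeSetAnnotation} to write.
#' @export
writeAnnotation <- function(annot, path) {
  df <- as.data.frame(annot)[, c("probeset_id", "species", "category",
                                 "suffix_class", "gene_ids")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata tables
#'
#' Sample TSV: columns \code{sample_id, tissue, condition, replicate_group,
#' replicate_index}, one row per array.
#'
#' @param path file path.
#' @return \code{readSampleMeta}: a data.frame.
#' @export
readSampleMeta <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  .checkHeader(colnames(tab), .SAMPLE_COLS, "sample metadata")
  tab
}

#' @rdname readSampleMeta
#' @param samples a data.frame of sample metadata to write.
#' @export
writeSampleMeta <- function(samples, path) {
  utils::write.table(as.data.frame(samples)[, .SAMPLE_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write summarized expression matrices
#'
#' Expression TSV: a \code{# method=<tag>} comment line recording the
#' normalization method, then a header of \code{probeset_id} plus sample
#' ids, and one row of log2 expression per probe set.
#'
#' @param path file path.
#' @param samples optional sample metadata data.frame; defaults to a
#'   minimal sheet derived from the column names.
#' @return \code{readExpression}: an \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, samples = NULL) {
  lines <- readLines(path)
  methline <- grep("^# *method=", lines, value = TRUE)
  tag <- if (length(methline)) sub("^# *method=", "", methline[1L])
         else "raw_summary"
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(tab)[1L] != "probeset_id")
    bnStop("bn_malformed_header",
           "expression table must start with a probeset_id column")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$probeset_id
  expressionMatrix(m, samples = samples, method_tag = tag)
}

#' @rdname readExpression
#' @param expr an \linkS4class{ExpressionMatrix} to write.
#' @export
writeExpression <- function(expr, path) {
  m <- exprValues(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method=", methodTag(expr)), con)
  writeLines(paste(c("probeset_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(x) paste(.fmtNum(x), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read and write detection-call tables
#'
#' Calls TSV: long-format columns \code{probeset_id, sample_id, call,
#' pvalue}.
#'
#' @param path file path.
#' @param params the \linkS4class{DetectionParams} under which the calls
#'   were made (needed to re-validate call/p-value consistency on read).
#' @return \code{readDetectionCalls}: a \linkS4class{DetectionCalls}.
#' @export
readDetectionCalls <- function(path, params = DetectionParams()) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  .checkHeader(colnames(tab),
               c("probeset_id", "sample_id", "call", "pvalue"), "calls")
  sets <- unique(tab$probeset_id)
  ids <- unique(tab$sample_id)
  cl <- matrix(NA_character_, length(sets), length(ids),
               dimnames = list(sets, ids))
  p <- matrix(NA_real_, length(sets), length(ids),
              dimnames = list(sets, ids))
  idx <- cbind(match(tab$probeset_id, sets), match(tab$sample_id, ids))
  cl[idx] <- tab$call
  p[idx] <- tab$pvalue
  samples <- data.frame(sample_id = ids, tissue = "unknown",
                        condition = "unknown", replicate_group = ids,
                        replicate_index = 1L)
  cd <- DataFrame(samples); rownames(cd) <- ids
  se <- SummarizedExperiment(assays = list(call = cl, pvalue = p),
                             colData = cd)
  new("DetectionCalls", se, params = params)
}

#' @rdname readDetectionCalls
#' @param det a \linkS4class{DetectionCalls} to write.
#' @export
writeDetectionCalls <- function(det, path) {
  cl <- calls(det)
  df <- data.frame(probeset_id = rep(rownames(cl), ncol(cl)),
                   sample_id = rep(colnames(cl), each = nrow(cl)),
                   call = as.vector(cl),
                   pvalue = .fmtNum(as.vector(detectionPvalues(det))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a replicate-group scaling report
#'
#' Scaling report TSV: columns \code{replicate_group, offset_log2, anchor,
#' anchor_n}, one row per replicate group, recording the additive log2
#' offset applied by \code{\link{rmapsNormalize}} or
#' \code{\link{rimsNormalize}} and the anchor statistic used.
#'
#' @param report a scaling-report data.frame.
#' @param path file path.
#' @export
writeScalingReport <- function(report, path) {
  utils::write.table(report[, c("replicate_group", "offset_log2", "anchor",
                                "anchor_n")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
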