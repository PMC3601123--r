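## Evaluation harness: how closely does a boutique-subset normalization
## track whole-array reference RMA?

#' Compare a boutique normalization to whole-array reference RMA
#'
#' Computes, over the shared probe sets and arrays (matched by id), the
#' pooled Pearson correlation of all log2 expression pairs, per-category
#' correlations (defl, invariant, marker when an annotation is supplied),
#' per-array correlations, the root-mean-square difference and the number
#' of compared values, plus a scatter-point table for plotting.
#'
#' @param test an \linkS4class{ExpressionMatrix} (e.g. SBQ on the boutique
#'   subset).
#' @param reference an \linkS4class{ExpressionMatrix} whose probe sets are
#'   a superset of the test's (e.g. whole-array RMA).
#' @param annot optional \linkS4class{ProbeSetAnnotation} for per-category
#'   correlations.
#' @return An object of class \code{ComparisonReport}: a list with
#'   \code{overall_r}, \code{per_category_r}, \code{per_array_r},
#'   \code{rms}, \code{n}, \code{method_tag} and \code{scatter}.
#' @export
compareToReference <- function(test, reference, annot = NULL) {
  sets <- intersect(probeSets(test), probeSets(reference))
  ids <- intersect(colnames(test), colnames(reference))
  if (length(sets) == 0L || length(ids) == 0L)
    bnStop("bn_empty_intersection",
           "test and reference share no probe sets or arrays")
  tm <- exprValues(test)[sets, ids, drop = FALSE]
  rm_ <- exprValues(reference)[sets, ids, drop = FALSE]
  category <- if (is.null(annot)) rep(NA_character_, length(sets))
              else as.character(annot$category)[match(sets,
                                                      annot$probeset_id)]
  scatter <- data.frame(probeset_id = rep(sets, length(ids)),
                        sample_id = rep(ids, each = length(sets)),
                        category = rep(category, length(ids)),
                        test = as.vector(tm), reference = as.vector(rm_))
  per_category <- if (is.null(annot)) NULL else
    vapply(split(scatter, scatter$category), function(s)
      stats::cor(s$test, s$reference), numeric(1))
  per_array <- vapply(ids, function(j)
    stats::cor(tm[, j], rm_[, j]), numeric(1))
  structure(list(overall_r = stats::cor(as.vector(tm), as.vector(rm_)),
                 per_category_r = per_category,
                 per_array_r = per_array,
                 rms = sqrt(mean((tm - rm_)^2)),
                 n = length(tm),
                 method_tag = methodTag(test),
                 scatter = scatter),
            class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat(sprintf("ComparisonReport [%s vs reference]: r = %.4f, RMS = %.4f, n = %d\n",
              x$method_tag, x$overall_r, x$rms, x$n))
  if (!is.null(x$per_category_r)) {
    cat("  per category:",
        paste(names(x$per_category_r),
              sprintf("%.4f", x$per_category_r), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Average biological replicates
#'
#' Arithmetic mean of log2 expression within each replicate group (the
#' conventional step before cross-platform comparison); output has one
#' column per replicate group.  Idempotent on already-averaged data.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @return An \linkS4class{ExpressionMatrix} with one column per replicate
#'   group, same method tag.
#' @export
replicateAverage <- function(expr) {
  m <- exprValues(expr)
  cd <- colData(expr)
  groups <- unique(as.character(cd$replicate_group))
  out <- matrix(vapply(groups, function(g)
    rowMeans(m[, cd$replicate_group == g, drop = FALSE]),
    numeric(nrow(m))), nrow = nrow(m))
  dimnames(out) <- list(rownames(m), groups)
  first <- match(groups, as.character(cd$replicate_group))
  samples <- data.frame(sample_id = groups,
                        tissue = as.character(cd$tissue)[first],
                        condition = as.character(cd$condition)[first],
                        replicate_group = groups, replicate_index = 1L)
  expressionMatrix(out, samples = samples, method_tag = methodTag(expr))
}

#' Per-array raw intensity density profiles
#'
#' Gaussian kernel density estimates of log2(PM) per array on a shared
#' 512-point grid spanning the pooled intensity range (padded by three
#' bandwidths), with bandwidth by Silverman's rule.  The low-intensity
#' background mode shows up as a large peak in these curves; arrays whose
#' curves differ markedly violate the quantile-normalization assumption.
#'
#' @param plm a \linkS4class{ProbeLevelMatrix}.
#' @return A list with \code{x} (grid) and \code{y} (512 x arrays matrix of
#'   densities); each column integrates to 1 on the grid (trapezoid rule,
#'   within 1e-3).
#' @export
intensityDensity <- function(plm) {
  lx <- log2(pm(plm))
  bw <- apply(lx, 2L, stats::bw.nrd0)
  pad <- 3 * max(bw)
  lo <- min(lx) - pad
  hi <- max(lx) + pad
  y <- vapply(seq_len(ncol(lx)), function(j)
    stats::density(lx[, j], bw = bw[j], n = 512L, from = lo, to = hi)$y,
    numeric(512L))
  colnames(y) <- colnames(lx)
  list(x = seq(lo, hi, length.out = 512L), y = y)
}

#' Run all three boutique normalizations and rank them against a reference
#'
#' The package's normalization-evaluation experiment as one call: SBQ,
#' RMAPS and RIMS are each run on a boutique probe-level subset, and each
#' result is compared to a whole-array reference RMA expression matrix.
#' RMAPS requires at least one probe set called Absent in every array; if
#' none exists its entry is \code{NA} with a message.
#'
#' @param subset_plm the boutique \linkS4class{ProbeLevelMatrix}.
#' @param reference an \linkS4class{ExpressionMatrix} of whole-array RMA
#'   values covering the subset's probe sets.
#' @param stable_ids stable-gene ids used by SBQ (and, by default, RIMS).
#' @param invariant_ids invariant-gene ids for RIMS; defaults to
#'   \code{stable_ids}.
#' @param params \linkS4class{DetectionParams} for the detection calls
#'   behind RMAPS.
#' @return A list with \code{summary} (data.frame of method and pooled r)
#'   and \code{reports} (named list of \code{ComparisonReport}s).
#' @export
compareNormalizations <- function(subset_plm, reference, stable_ids,
                                  invariant_ids = stable_ids,
                                  params = DetectionParams()) {
  annot <- annotation(subset_plm)
  raw <- rmaSummarize(subset_plm, normalize = FALSE)
  reports <- list()
  reports$sbq <- compareToReference(sbqNormalize(raw, stable_ids),
                                    reference, annot)
  det <- mas5Detection(subset_plm, params)
  reports["rmaps"] <- list(tryCatch({
    rmaps <- rmapsNormalize(subset_plm, det)$expr
    compareToReference(rmaps, reference, annot)
  }, bn_empty_absent_set = function(e) {
    message("RMAPS skipped: ", conditionMessage(e))
    NULL
  }))
  reports$rims <- compareToReference(
    rimsNormalize(subset_plm, invariant_ids)$expr, reference, annot)
  summary <- data.frame(
    method = names(reports),
    overall_r = vapply(reports, function(r)
      if (is.null(r)) NA_real_ else r$overall_r, numeric(1)),
    row.names = NULL)
  list(summary = summary, reports = reports)
}
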