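## The three boutique-array normalization schemes.  All operate on log2
## summaries; RMAPS/RIMS additionally re-run RMA within replicate groups
## (where the distributional assumptions still hold) before rescaling.

## Rank-map one column onto a sorted reference, averaging tied runs.
.rankMap <- function(v, ref) {
  out <- numeric(length(v))
  ord <- order(v)
  s <- v[ord]
  grp <- cumsum(!duplicated(s))
  out[ord] <- stats::ave(ref, grp, FUN = mean)
  out
}

#' Stable-gene based quantile (SBQ) normalization
#'
#' Quantile normalization anchored only on a designated set of stable
#' genes, for boutique arrays where most genes may shift together and
#' whole-distribution matching would erase real biology.  The reference
#' distribution is the across-array mean of the sorted stable-gene values.
#' Per array, each stable gene is mapped to the reference value at its
#' within-array stable-gene rank (ties averaged); every other gene is
#' mapped by monotone piecewise-linear interpolation between the (observed
#' value, reference value) anchor pairs of that array's stable genes.
#' Values outside the stable range are shifted by the boundary anchor's
#' offset, so the per-array map is monotone on the whole line.
#'
#' @param expr an \linkS4class{ExpressionMatrix} of summarized log2 values
#'   (typically \code{rmaSummarize(plm, normalize = FALSE)}).
#' @param stable_ids probe-set ids of the stable genes (at least 10, all
#'   present in \code{expr}).
#' @return An \linkS4class{ExpressionMatrix} tagged \code{"sbq"}.
#' @seealso \code{\link{selectInvariants}} to derive a stable set from a
#'   coefficient-of-variation screen.
#' @export
sbqNormalize <- function(expr, stable_ids) {
  m <- exprValues(expr)
  if (!all(stable_ids %in% rownames(m)))
    bnStop("bn_unknown_probeset",
           "stable_ids must all be present in the expression matrix")
  if (length(stable_ids) < 10L)
    bnStop("bn_too_few_stable",
           "SBQ needs at least 10 stable genes to anchor the reference")
  if (!all(is.finite(m)))
    bnStop("bn_numerical_domain", "expression values must be finite")
  S <- m[stable_ids, , drop = FALSE]
  ref <- rowMeans(apply(S, 2L, sort))
  out <- m
  stable <- rownames(m) %in% stable_ids
  for (j in seq_len(ncol(m))) {
    v <- S[, j]
    out[stable, j] <- .rankMap(v, ref)[match(rownames(m)[stable], stable_ids)]
    ## anchor pairs: sorted observed stable values -> tie-averaged reference
    s <- sort(v)
    y <- .rankMap(v, ref)[order(v)]
    keep <- !duplicated(s)
    xu <- s[keep]; yu <- y[keep]
    x <- m[!stable, j]
    if (length(xu) == 1L) {
      mapped <- x + (yu - xu)
    } else {
      mapped <- stats::approx(xu, yu, xout = x, rule = 2L)$y
      lo <- x < xu[1L]; hi <- x > xu[length(xu)]
      mapped[lo] <- x[lo] + (yu[1L] - xu[1L])
      mapped[hi] <- x[hi] + (yu[length(yu)] - xu[length(xu)])
    }
    out[!stable, j] <- mapped
  }
  expressionMatrix(out, samples = sampleMeta(expr), method_tag = "sbq")
}

## Shared engine for RMAPS/RIMS: per-replicate-group RMA, then one additive
## log2 offset per group aligning the group's anchor median to the grand
## median of that statistic across groups.
.groupScaledRma <- function(plm, anchor_ids, anchor_label, tag,
                            background = TRUE) {
  cd <- colData(plm)
  groups <- unique(as.character(cd$replicate_group))
  per_group <- lapply(groups, function(g) {
    idx <- which(cd$replicate_group == g)
    rmaSummarize(plm[, idx], background = background, normalize = TRUE)
  })
  sets <- probeSets(plm)
  anchor_ids <- intersect(sets, anchor_ids)
  med <- vapply(per_group, function(e)
    stats::median(exprValues(e)[anchor_ids, , drop = FALSE]), numeric(1))
  target <- stats::median(med)
  offsets <- target - med
  if (length(groups) == 1L) offsets[] <- 0
  expr <- matrix(NA_real_, length(sets), ncol(plm),
                 dimnames = list(sets, colnames(plm)))
  for (i in seq_along(groups)) {
    idx <- which(cd$replicate_group == groups[i])
    expr[, idx] <- exprValues(per_group[[i]]) + offsets[i]
  }
  report <- data.frame(replicate_group = groups, offset_log2 = offsets,
                       anchor = anchor_label, anchor_n = length(anchor_ids))
  list(expr = expressionMatrix(expr, samples = sampleMeta(plm),
                               method_tag = tag),
       report = report)
}

#' RMA with median absent-probe-set scaling (RMAPS)
#'
#' Runs RMA separately within each biological replicate group (within which
#' the probe-intensity distribution assumptions hold), then rescales each
#' group's log2 expression by a single additive constant so that the median
#' over the probe sets called Absent in every array of every condition is
#' equal across groups (to the grand median of that statistic).
#'
#' @param plm a \linkS4class{ProbeLevelMatrix}.
#' @param detection a \linkS4class{DetectionCalls} for the same probe sets
#'   and arrays (see \code{\link{mas5Detection}}).
#' @param background apply background correction within each group's RMA
#'   (default TRUE; small fixtures may disable it).
#' @return A list with components \code{expr} (an
#'   \linkS4class{ExpressionMatrix} tagged \code{"rmaps"}) and
#'   \code{report} (the per-group scaling report).
#' @export
rmapsNormalize <- function(plm, detection, background = TRUE) {
  cl <- calls(detection)
  absent <- rownames(cl)[rowSums(cl == "A") == ncol(cl)]
  if (length(absent) == 0L)
    bnStop("bn_empty_absent_set", paste(
      "no probe set is Absent across all sampled conditions;",
      "RMAPS is inapplicable to this experiment (consider RIMS or SBQ)"))
  .groupScaledRma(plm, absent, "absent_median", "rmaps",
                  background = background)
}

#' RMA with invariant median scaling (RIMS)
#'
#' Runs RMA separately within each biological replicate group, then
#' rescales each group's log2 expression by a single additive constant so
#' that the median over a designated set of invariant genes is equal
#' across groups (to the grand median of that statistic).
#'
#' @param plm a \linkS4class{ProbeLevelMatrix}.
#' @param invariant_ids probe-set ids of the invariant genes (at least 10,
#'   all present on the array).
#' @param background apply background correction within each group's RMA.
#' @return A list with components \code{expr} (tagged \code{"rims"}) and
#'   \code{report}, as for \code{\link{rmapsNormalize}}.
#' @export
rimsNormalize <- function(plm, invariant_ids, background = TRUE) {
  sets <- probeSets(plm)
  if (!all(invariant_ids %in% sets))
    bnStop("bn_unknown_probeset",
           "invariant_ids must all be present on the array")
  if (length(invariant_ids) < 10L)
    bnStop("bn_too_few_stable", "RIMS needs at least 10 invariant genes")
  .groupScaledRma(plm, invariant_ids, "invariant_median", "rims",
                  background = background)
}

#' Select invariant probe sets by coefficient of variation
#'
#' Returns the probe sets whose coefficient of variation (sample standard
#' deviation divided by mean) across all arrays is strictly below
#' \code{cv_threshold}.  By default the CV is computed on the linear scale
#' (\code{2^log2}); \code{scale = "log2"} computes it on the log2 values
#' directly.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with at least 3 arrays.
#' @param cv_threshold strict upper bound on the CV (default 0.10).
#' @param scale \code{"linear"} (default) or \code{"log2"}.
#' @return Character vector of selected probe-set ids.
#' @export
selectInvariants <- function(expr, cv_threshold = 0.10,
                             scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  m <- exprValues(expr)
  if (ncol(m) < 3L)
    bnStop("bn_too_few_arrays", "CV screening needs at least 3 arrays")
  if (scale == "linear") m <- 2^m
  cv <- apply(m, 1L, stats::sd) / rowMeans(m)
  rownames(m)[cv < cv_threshold]
}

#' Median-scale expression rows for heat maps
#'
#' Subtracts each probe-set row's median log2 value, so every row has
#' median 0 and heat-map colors show deviation from a gene's typical
#' level rather than absolute abundance.
#'
#' @param expr an \linkS4class{ExpressionMatrix} or a numeric matrix of
#'   log2 values.
#' @return A numeric matrix with all row medians equal to 0.
#' @export
medianScaleRows <- function(expr) {
  m <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  m - apply(m, 1L, stats::median)
}
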