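## Detection-based cataloging, differential expression, co-expression,
## clustering and reference-gene stability.

#' Detection-based expression catalog
#'
#' Classifies each probe set by the tissues in which it is expressed.  A
#' probe set counts as expressed in a tissue when it is called Present in
#' at least \code{expressed_rule_min_present} of that tissue's replicates
#' (capped at the tissue's replicate count, so a single-replicate tissue
#' needs one Present call).  Class labels partition the probe sets:
#' \code{constitutive} (expressed in every tissue), \code{unique_to_one_tissue},
#' \code{multi_tissue} and \code{not_expressed}.
#'
#' @param det a \linkS4class{DetectionCalls} whose sample metadata carries
#'   a \code{tissue} column.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return An object of class \code{ExpressionCatalog}: a list with
#'   \code{expressed} (logical probe sets x tissues matrix), \code{class}
#'   (character vector) and \code{unique_tissue} (tissue name for
#'   unique-class probe sets, else \code{NA}).
#' @export
catalogExpression <- function(det, config = analysisConfig()) {
  cl <- calls(det)
  tissue <- as.character(colData(det)$tissue)
  tissues <- unique(tissue)
  if (any(vapply(tissues, function(t) sum(tissue == t), 0L) < 1L))
    bnStop("bn_empty_tissue", "every tissue needs at least one array")
  rule <- config@expressed_rule_min_present
  expressed <- matrix(vapply(tissues, function(t) {
    idx <- which(tissue == t)
    rowSums(cl[, idx, drop = FALSE] == "P") >= min(rule, length(idx))
  }, logical(nrow(cl))), nrow = nrow(cl))
  dimnames(expressed) <- list(rownames(cl), tissues)
  ntis <- rowSums(expressed)
  class <- ifelse(ntis == 0L, "not_expressed",
           ifelse(ntis == length(tissues), "constitutive",
           ifelse(ntis == 1L, "unique_to_one_tissue", "multi_tissue")))
  unique_tissue <- rep(NA_character_, nrow(cl))
  one <- class == "unique_to_one_tissue"
  unique_tissue[one] <- tissues[apply(expressed[one, , drop = FALSE], 1L,
                                      which.max)]
  structure(list(expressed = expressed, class = class,
                 unique_tissue = unique_tissue),
            class = "ExpressionCatalog")
}

#' @export
print.ExpressionCatalog <- function(x, ...) {
  cat("ExpressionCatalog:", nrow(x$expressed), "probe sets x",
      ncol(x$expressed), "tissues\n")
  print(table(x$class))
  invisible(x)
}

#' Counts for every region of an expression set diagram
#'
#' Given named groups of tissues, counts the probe sets falling in each
#' region of the Venn diagram of "expressed in at least one tissue of the
#' group" sets.  Region counts sum to the size of the union.
#'
#' @param catalog an \code{ExpressionCatalog} from
#'   \code{\link{catalogExpression}}.
#' @param tissue_sets a named list (at most 4 entries) of tissue-name
#'   character vectors.
#' @return A data.frame with one 0/1 indicator column per set and a
#'   \code{count} column, one row per non-empty region combination.
#' @export
vennCounts <- function(catalog, tissue_sets) {
  if (length(tissue_sets) > 4L)
    bnStop("bn_too_many_sets", "at most 4 named sets are supported")
  tissues <- colnames(catalog$expressed)
  unknown <- setdiff(unlist(tissue_sets), tissues)
  if (length(unknown))
    bnStop("bn_unknown_tissue",
           paste("unknown tissue(s):", paste(unknown, collapse = ", ")))
  member <- vapply(tissue_sets, function(ts)
    rowSums(catalog$expressed[, ts, drop = FALSE]) > 0L,
    logical(nrow(catalog$expressed)))
  k <- length(tissue_sets)
  grid <- as.matrix(expand.grid(rep(list(c(1L, 0L)), k)))[-2^k, , drop = FALSE]
  colnames(grid) <- names(tissue_sets)
  count <- apply(grid, 1L, function(g)
    sum(colSums(t(member) == g) == k))
  data.frame(grid, count = count, check.names = FALSE)
}

## Two-sample t p-value tolerant of zero-variance degenerate groups.
.tTestP <- function(x, y, var_equal) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Per-probe-set differential expression with BH correction
#'
#' Two groups: two-sided t-test per probe set; more than two: one-way
#' ANOVA.  Raw p-values are adjusted by the Benjamini-Hochberg step-up
#' procedure and flagged significant at \code{q < de_alpha}.
#'
#' The default is the classical pooled-variance t-test: at three
#' replicates per group its four degrees of freedom are guaranteed,
#' whereas the Welch correction's Satterthwaite df can drop toward two
#' and, at the stringent per-test levels BH induces, costs a large
#' fraction of power for no realistic robustness gain on log2 microarray
#' summaries.  Set \code{var_equal = FALSE} for Welch.
#'
#' @param expr an \linkS4class{ExpressionMatrix} of log2 values.
#' @param groups either the name of a sample-metadata column (default
#'   \code{"condition"}) or a vector of group labels, one per array; every
#'   group needs at least 2 replicates.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param var_equal pool the group variances (default TRUE).
#' @return A data.frame (one row per probe set): \code{probeset_id}, group
#'   means (\code{mean_<level>}), \code{log2fc} (second level minus first,
#'   \code{NA} for more than two groups), \code{pvalue}, \code{qvalue} and
#'   \code{significant}.
#' @export
differentialExpression <- function(expr, groups = "condition",
                                   config = analysisConfig(),
                                   var_equal = TRUE) {
  m <- exprValues(expr)
  if (length(groups) == 1L && is.character(groups))
    groups <- as.character(colData(expr)[[groups]])
  g <- factor(groups)
  if (length(g) != ncol(m))
    bnStop("bn_dim_error", "need one group label per array")
  if (any(table(g) < 2L))
    bnStop("bn_too_few_replicates",
           "every group needs at least 2 replicates")
  lev <- levels(g)
  means <- vapply(lev, function(l) rowMeans(m[, g == l, drop = FALSE]),
                  numeric(nrow(m)))
  if (length(lev) == 2L) {
    p <- apply(m, 1L, function(x)
      .tTestP(x[g == lev[1L]], x[g == lev[2L]], var_equal))
    log2fc <- means[, 2L] - means[, 1L]
  } else {
    p <- apply(m, 1L, function(x) {
      if (all(stats::ave(x, g, FUN = stats::sd) == 0)) {
        if (max(tapply(x, g, mean)) - min(tapply(x, g, mean)) == 0) 1 else 0
      } else {
        stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
      }
    })
    log2fc <- NA_real_
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(probeset_id = rownames(m), means, log2fc = log2fc,
                    pvalue = p, qvalue = q,
                    significant = q < config@de_alpha,
                    row.names = NULL, check.names = FALSE)
  colnames(out)[1L + seq_along(lev)] <- paste0("mean_", lev)
  out
}

#' Screen for genes co-expressed with a seed probe set
#'
#' Computes the Pearson correlation of every other probe set with the seed
#' across all arrays and returns those with \eqn{r^2} at or above the
#' configured threshold and \eqn{r > 0} (co-regulation means same-direction
#' change; anti-correlated genes are excluded), sorted by \eqn{r}
#' descending.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with at least 3 arrays.
#' @param seed_probeset id of the seed probe set.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A data.frame with columns \code{probeset_id}, \code{r} and
#'   \code{r2}.
#' @export
coexpressionScreen <- function(expr, seed_probeset,
                               config = analysisConfig()) {
  m <- exprValues(expr)
  if (!seed_probeset %in% rownames(m))
    bnStop("bn_unknown_probeset",
           paste("seed probe set not found:", seed_probeset))
  if (ncol(m) < 3L)
    bnStop("bn_too_few_arrays", "co-expression needs at least 3 arrays")
  seed <- m[seed_probeset, ]
  if (stats::sd(seed) == 0)
    bnStop("bn_zero_variance", "seed probe set has zero variance")
  others <- m[rownames(m) != seed_probeset, , drop = FALSE]
  r <- suppressWarnings(as.vector(stats::cor(t(others), seed)))
  r[is.na(r)] <- 0           # zero-variance candidates cannot co-vary
  keep <- r > 0 & r^2 >= config@coexpression_r2_threshold
  out <- data.frame(probeset_id = rownames(others)[keep], r = r[keep],
                    r2 = r[keep]^2, row.names = NULL)
  out[order(-out$r), , drop = FALSE]
}

#' Average-linkage clustering with Pearson distance
#'
#' Agglomerative (UPGMA) clustering of probe-set expression profiles using
#' distance \eqn{d = 1 - r} with \eqn{r} the Pearson correlation across
#' arrays.  Rows are processed in lexicographic id order so the merge
#' sequence is deterministic; a zero-variance row's correlations are
#' defined as 0 (distance 1) with a warning.
#'
#' @param expr an \linkS4class{ExpressionMatrix} or numeric matrix (rows =
#'   probe sets) with at least 2 rows.
#' @return A list with \code{tree} (an \code{\link[stats]{hclust}} object),
#'   \code{leaf_order} (row ids in dendrogram order) and \code{dist} (the
#'   \code{1 - r} distance matrix).
#' @export
clusterExpression <- function(expr) {
  m <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  if (nrow(m) < 2L)
    bnStop("bn_too_few_rows", "clustering needs at least 2 rows")
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  m <- m[order(rownames(m)), , drop = FALSE]
  novar <- apply(m, 1L, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(m)))
  if (any(novar)) {
    warning("zero-variance row(s): correlations set to 0 (distance 1)")
    r[novar, ] <- 0; r[, novar] <- 0
  }
  diag(r) <- 1
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  list(tree = hc, leaf_order = rownames(m)[hc$order], dist = 1 - r)
}

#' Reference-gene stability ranking (pairwise-variation M)
#'
#' For each candidate reference gene \eqn{j}, computes the stability value
#' \eqn{M_j}: the mean over all other candidates \eqn{k} of the standard
#' deviation of the per-sample log2 expression ratios
#' \eqn{A_{jk} = \log_2(x_j/x_k)}.  Genes whose expression tracks the
#' others up to a constant factor have \eqn{M = 0}; lower M means more
#' stable.  Operates on linear-scale values (an
#' \linkS4class{ExpressionMatrix}, being log2, is exponentiated first).
#' Optionally records the iterative exclusion order obtained by repeatedly
#' dropping the least stable gene.
#'
#' @param x numeric matrix of positive linear-scale values (genes x
#'   samples, at least 3 of each) or an \linkS4class{ExpressionMatrix}.
#' @param iterative also compute the stepwise exclusion ranking (default
#'   FALSE).
#' @return A data.frame sorted ascending in \code{M} with columns
#'   \code{gene}, \code{M} and \code{rank}; if \code{iterative}, an
#'   attribute \code{exclusion_order} lists genes from least to most
#'   stable.
#' @export
genormStability <- function(x, iterative = FALSE) {
  m <- if (is(x, "ExpressionMatrix")) 2^exprValues(x) else as.matrix(x)
  if (nrow(m) < 3L || ncol(m) < 3L)
    bnStop("bn_too_few_values",
           "stability ranking needs >= 3 genes and >= 3 samples")
  if (any(m <= 0) || !all(is.finite(m)))
    bnStop("bn_nonpositive_intensity",
           "expression values must be strictly positive and finite")
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  mval <- function(sub) {
    lm2 <- log2(sub)
    vapply(seq_len(nrow(sub)), function(j) {
      v <- vapply(setdiff(seq_len(nrow(sub)), j), function(k)
        stats::sd(lm2[j, ] - lm2[k, ]), numeric(1))
      mean(v)
    }, numeric(1))
  }
  M <- mval(m)
  out <- data.frame(gene = rownames(m), M = M, row.names = NULL)
  out <- out[order(out$M), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (iterative) {
    excl <- character(0)
    cur <- m
    while (nrow(cur) > 2L) {
      Mi <- mval(cur)
      worst <- which.max(Mi)
      excl <- c(excl, rownames(cur)[worst])
      cur <- cur[-worst, , drop = FALSE]
    }
    attr(out, "exclusion_order") <- c(excl, rownames(cur))
  }
  out
}
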