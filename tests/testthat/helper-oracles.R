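# Independent oracles, coded from first principles and kept deliberately
# separate from the package implementations they check.

# Iterative median-polish sweep, run to convergence.
oracleMedpolish <- function(block, iters = 500L) {
  overall <- 0
  rowe <- rep(0, nrow(block))
  cole <- rep(0, ncol(block))
  res <- block
  for (i in seq_len(iters)) {
    rm_ <- apply(res, 1L, median)
    res <- res - rm_
    rowe <- rowe + rm_
    cm <- median(cole)
    cole <- cole - cm
    overall <- overall + cm
    cm_ <- apply(res, 2L, median)
    res <- res - rep(cm_, each = nrow(res))
    cole <- cole + cm_
    rm2 <- median(rowe)
    rowe <- rowe - rm2
    overall <- overall + rm2
  }
  list(overall = overall, row = rowe, col = cole, residuals = res)
}

# Exact one-sided signed-rank p-value by full enumeration of sign vectors.
oracleSignedRankP <- function(scores, tau) {
  d <- scores - tau
  d <- d[abs(d) > 1e-12]
  n <- length(d)
  if (n == 0L) return(1)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  mean(w_all >= w_obs - 1e-9)
}

# Benjamini-Hochberg step-up, straight from the definition.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  for (i in seq_len(n)) q[i] <- min(sorted[i:n])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Exhaustive UPGMA on a symmetric distance matrix with labelled rows:
# returns the sequence of merge heights and merged member sets.
oracleUPGMA <- function(d) {
  clusters <- as.list(rownames(d))
  names(clusters) <- rownames(d)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, bh)
    merges <- c(merges, list(merged))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# Textbook Pearson correlation from raw sums.
oraclePearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Posterior mean of the exponential signal given the observation, by
# numerical quadrature over the convolution posterior on [0, o].
oracleBgPosteriorMean <- function(o, alpha, mu, sigma) {
  f <- function(s) exp(-alpha * s) * dnorm(o - s, mu, sigma)
  num <- integrate(function(s) s * f(s), 0, o, rel.tol = 1e-10)$value
  den <- integrate(f, 0, o, rel.tol = 1e-10)$value
  num / den
}

# geNorm stability values from the pairwise-sd definition.
oracleGenormM <- function(x) {
  l <- log2(x)
  n <- nrow(x)
  vapply(seq_len(n), function(j) {
    mean(vapply(setdiff(seq_len(n), j),
                function(k) sd(l[j, ] - l[k, ]), numeric(1)))
  }, numeric(1))
}
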