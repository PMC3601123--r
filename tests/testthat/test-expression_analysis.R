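# Catalogs, Venn regions, differential expression, co-expression,
# clustering and reference-gene stability.

# Hand-built DetectionCalls: calls matrix + tissue assignment.
mkCalls <- function(cl, tissue) {
  p <- matrix(ifelse(cl == "P", 0.01, 0.5), nrow(cl), ncol(cl),
              dimnames = dimnames(cl))
  ids <- paste0("arr", seq_len(ncol(cl)))
  colnames(cl) <- colnames(p) <- ids
  reps <- stats::ave(seq_along(tissue), tissue, FUN = seq_along)
  samples <- data.frame(sample_id = ids, tissue = tissue,
                        condition = tissue, replicate_group = tissue,
                        replicate_index = reps)
  cd <- S4Vectors::DataFrame(samples)
  rownames(cd) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(call = cl, pvalue = p), colData = cd)
  new("DetectionCalls", se, params = DetectionParams())
}

test_that("expression catalog applies the 2-of-3 Present rule and classes", {
  tissue <- rep(c("root", "leaf", "flower"), each = 3)
  cl <- rbind(
    everywhere = rep("P", 9),
    rootonly   = c("P", "P", "A", rep("A", 6)),
    rootleaf   = c("P", "P", "P", "P", "A", "P", "A", "A", "A"),
    oneofthree = c("P", "A", "A", rep("A", 6)),
    silent     = rep("A", 9))
  cat_ <- catalogExpression(mkCalls(cl, tissue))
  expect_identical(unname(cat_$class),
                   c("constitutive", "unique_to_one_tissue", "multi_tissue",
                     "not_expressed", "not_expressed"))
  expect_identical(cat_$unique_tissue[2], "root")
  expect_true(cat_$expressed["rootonly", "root"])
  expect_false(cat_$expressed["oneofthree", "root"])   # 1 of 3 < rule
  # a single-replicate tissue needs only its one Present call
  cl1 <- rbind(g = c("P", "A", "A", "P"))
  cat1 <- catalogExpression(mkCalls(cl1, c("root", "root", "root", "seed")))
  expect_true(cat1$expressed["g", "seed"])
})

test_that("venn regions partition the union and police tissue names", {
  tissue <- rep(c("t1", "t2"), each = 3)
  cl <- rbind(a = c("P", "P", "P", "A", "A", "A"),
              b = c("P", "P", "A", "P", "P", "A"),
              c = c("A", "A", "A", "P", "P", "P"),
              d = rep("A", 6),
              e = c("P", "P", "P", "A", "A", "A"))
  cat_ <- catalogExpression(mkCalls(cl, tissue))
  vc <- vennCounts(cat_, list(S1 = "t1", S2 = "t2"))
  expect_identical(sum(vc$count), 4L)                # union: a, b, c, e
  expect_identical(vc$count[vc$S1 == 1 & vc$S2 == 1], 1L)   # b
  expect_identical(vc$count[vc$S1 == 1 & vc$S2 == 0], 2L)   # a, e
  expect_identical(vc$count[vc$S1 == 0 & vc$S2 == 1], 1L)   # c
  # identical sets: all mass in the intersection
  vc2 <- vennCounts(cat_, list(X = "t1", Y = "t1"))
  expect_identical(vc2$count[vc2$X == 1 & vc2$Y == 1], 3L)
  expect_identical(sum(vc2$count), 3L)
  expect_error(vennCounts(cat_, list(A = "nosuch")),
               class = "bn_unknown_tissue")

  # region counts invariant to probe-set and tissue order
  shuf <- cl[c(3, 1, 5, 2, 4), ]
  vc3 <- vennCounts(catalogExpression(mkCalls(shuf, tissue)),
                    list(S1 = "t1", S2 = "t2"))
  expect_identical(vc3$count, vc$count)
})

test_that("BH q-values match the step-up oracle and keep monotonicity", {
  e <- tinyExpr(rbind(g1 = c(0, 0, 0, 5, 5, 5),
                      g2 = c(1, 2, 1, 1, 2, 1),
                      g3 = c(0, 1, 0, 2, 3, 2),
                      g4 = rnorm(6)),
                conditions = rep(c("a", "b"), each = 3))
  de <- differentialExpression(e, "condition")
  expect_equal(de$qvalue, oracleBH(de$pvalue))
  expect_true(all(de$qvalue >= de$pvalue))
  expect_equal(de$log2fc[1], 5)

  # worked BH example
  expect_equal(oracleBH(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04, 0.5), "BH"),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))

  # q is monotone in the rank order of p, on random vectors
  set.seed(15)
  for (i in 1:10) {
    p <- runif(50)^2
    q <- oracleBH(p)
    expect_equal(stats::p.adjust(p, "BH"), q)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("identical groups are never significant; ANOVA handles k groups", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 6), 4, 6, byrow = TRUE)
  rownames(m) <- paste0("g", 1:4)
  de <- differentialExpression(tinyExpr(m, rep(c("a", "b"), each = 3)),
                               "condition")
  expect_true(all(de$pvalue == 1))
  expect_false(any(de$significant))

  set.seed(16)
  m3 <- matrix(rnorm(6 * 9), 6, 9)
  m3[1, 7:9] <- m3[1, 7:9] + 10
  rownames(m3) <- paste0("g", 1:6)
  e3 <- tinyExpr(m3, rep(c("a", "b", "c"), each = 3))
  de3 <- differentialExpression(e3, "condition")
  expect_true(is.na(de3$log2fc[1]))
  expect_lt(de3$pvalue[1], 0.01)
  # cross-check one row against stats::oneway.test directly
  g <- factor(rep(c("a", "b", "c"), each = 3))
  expect_equal(de3$pvalue[2],
               stats::oneway.test(m3[2, ] ~ g, var.equal = TRUE)$p.value)
  expect_error(
    differentialExpression(e3, c("a", "a", "a", "a", "b", "b", "b", "b",
                                 "c")),
    class = "bn_too_few_replicates")
})

test_that("null simulation keeps the raw-p and q false-positive rates
           calibrated", {
  set.seed(17)
  n <- 1000
  m <- matrix(rnorm(n * 6, sd = 0.25), n, 6)
  rownames(m) <- sprintf("g%04d", seq_len(n))
  de <- differentialExpression(tinyExpr(m, rep(c("a", "b"), each = 3)),
                               "condition")
  expect_lt(abs(mean(de$pvalue < 0.05) - 0.05), 0.02)
  expect_lte(sum(de$qvalue < 0.05), 2L)
})

test_that("co-expression screen ranks by r with the positive-sign rule", {
  seed <- c(1, 2, 3, 4)
  m <- rbind(seedg = seed, same = seed, anti = -seed,
             close = c(1, 2, 3, 5), flat = c(2, 2, 2, 2),
             noise = c(4, 1, 3, 2))
  res <- coexpressionScreen(tinyExpr(m), "seedg")
  expect_identical(res$probeset_id[1], "same")
  expect_equal(res$r[1], 1)
  expect_false("anti" %in% res$probeset_id)    # r = -1 excluded by sign
  expect_false("flat" %in% res$probeset_id)
  expect_true("close" %in% res$probeset_id)
  expect_equal(res$r[res$probeset_id == "close"],
               oraclePearson(seed, c(1, 2, 3, 5)), tolerance = 1e-12)
  expect_error(coexpressionScreen(tinyExpr(m), "flat"),
               class = "bn_zero_variance")
  expect_error(coexpressionScreen(tinyExpr(m), "nosuch"),
               class = "bn_unknown_probeset")
})

test_that("UPGMA clustering matches the exhaustive oracle", {
  set.seed(18)
  base <- rnorm(6)
  m <- rbind(a = base + rnorm(6, sd = 0.1),
             b = base + rnorm(6, sd = 0.1),
             c = -base + rnorm(6, sd = 0.4),
             d = rnorm(6))
  cl <- clusterExpression(m)
  orc <- oracleUPGMA(cl$dist)
  expect_equal(sort(cl$tree$height), sort(orc$heights), tolerance = 1e-12)
  # first oracle merge is the closest pair; it must appear in the tree
  first <- orc$merges[[1]]
  h1 <- cl$tree$height[1]
  expect_equal(h1, orc$heights[1], tolerance = 1e-12)
  expect_identical(sort(cl$tree$labels[-cl$tree$merge[1, ]]), first)
  # leaf count and merge count
  expect_identical(length(cl$leaf_order), 4L)
  expect_identical(nrow(cl$tree$merge), 3L)

  # identical rows merge first at height zero
  m2 <- rbind(x = base, y = base, z = rev(base), w = rnorm(6))
  cl2 <- clusterExpression(m2)
  expect_equal(cl2$tree$height[1], 0, tolerance = 1e-12)
  expect_identical(sort(cl2$tree$labels[-cl2$tree$merge[1, ]]),
                   c("x", "y"))

  expect_warning(clusterExpression(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "zero-variance")
  expect_error(clusterExpression(m[1, , drop = FALSE]),
               class = "bn_too_few_rows")
})

test_that("stability ranking reproduces the pairwise-sd definition", {
  # constant-ratio genes: all M = 0
  x <- rbind(a = c(1, 2, 4), b = 2 * c(1, 2, 4), c = 10 * c(1, 2, 4))
  st <- genormStability(x)
  expect_equal(st$M, rep(0, 3))

  set.seed(19)
  y <- matrix(2^rnorm(12, 6), 4, 3)
  rownames(y) <- letters[1:4]
  st2 <- genormStability(y)
  want <- sort(oracleGenormM(y))
  expect_equal(st2$M, want, tolerance = 1e-12)
  expect_identical(st2$rank, 1:4)

  # gene-wise scale factors leave M untouched
  y2 <- y * c(1, 7, 0.2, 100)
  expect_equal(genormStability(y2)$M, st2$M, tolerance = 1e-12)

  # a noisy gene always ranks below a constant-ratio core
  set.seed(20)
  for (i in 1:5) {
    core <- 2^matrix(rep(rnorm(5, 8), each = 4) + rep(rnorm(4), 5), 4, 5)
    rownames(core) <- paste0("c", 1:4)
    noisy <- rbind(core, n1 = core[1, ] * 2^rnorm(5, sd = 0.3))
    stn <- genormStability(noisy)
    expect_identical(stn$gene[nrow(stn)], "n1")
  }

  expect_error(genormStability(x - 5), class = "bn_nonpositive_intensity")
  expect_error(genormStability(x[1:2, ]), class = "bn_too_few_values")
})

test_that("iterative exclusion drops the least stable gene first", {
  set.seed(30)
  core <- 2^matrix(rep(rnorm(6, 8), each = 3) + rep(rnorm(3), 6), 3, 6)
  rownames(core) <- paste0("c", 1:3)
  noisy <- rbind(core, bad = core[1, ] * 2^rnorm(6, sd = 0.5))
  st <- genormStability(noisy, iterative = TRUE)
  expect_identical(attr(st, "exclusion_order")[1], "bad")
})
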