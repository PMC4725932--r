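test_that("rpkm follows 1e9 * C / (N * L) and its scale cancellations", {
  expect_equal(rpkm(0, 1000, 1e7), 0)
  expect_equal(rpkm(100, 1000, 1e7), 10)
  ## doubling both count and library size leaves RPKM unchanged
  expect_equal(rpkm(200, 1000, 2e7), rpkm(100, 1000, 1e7))
  expect_error(rpkm(10, 0, 1e6), "lengths")
  expect_error(rpkm(10, 100, 0), "library")
  ## matrix form with explicit library sizes
  m <- matrix(c(10, 20, 30, 60), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- rpkm(m, c(500, 1000), c(1e6, 2e6))
  expect_equal(out["g1", "s1"], 1e9 * 10 / (1e6 * 500))
  expect_equal(out["g2", "s2"], 1e9 * 60 / (2e6 * 1000))
})

test_that("TMM factors are 1 for identical or uniformly scaled columns", {
  set.seed(21)
  x <- matrix(rpois(4000, rlnorm(2000, 3, 1)), ncol = 2)
  x[, 2] <- x[, 1]
  expect_equal(unname(as.numeric(tmmFactors(x))), c(1, 1))
  y <- cbind(x[, 1], 3 * x[, 1])
  expect_equal(unname(as.numeric(tmmFactors(y))), c(1, 1))
})

test_that("TMM on a spiked subset matches the loop oracle and edgeR", {
  set.seed(22)
  base <- rlnorm(1000, 4, 1)
  a <- rpois(1000, base)
  b <- rpois(1000, base)
  b[1:50] <- rpois(50, 4 * base[1:50])   # 50 genes at 4x in sample 2
  m <- cbind(s1 = a, s2 = b)
  f <- tmmFactors(m, refSample = 1)
  expect_equal(unname(as.numeric(f)), oracleTMM(m, ref = 1),
               tolerance = 1e-9)
  ## geometric mean 1 invariant
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  ## column scaling invariance: exact without precision weights (which
  ## depend on absolute counts), tight with them
  m2 <- cbind(s1 = 2L * a, s2 = b)
  expect_equal(as.numeric(tmmFactors(m2, refSample = 1,
                                     doWeighting = FALSE)),
               as.numeric(tmmFactors(m, refSample = 1,
                                     doWeighting = FALSE)),
               tolerance = 1e-12)
  expect_equal(as.numeric(tmmFactors(m2, refSample = 1)),
               as.numeric(f), tolerance = 1e-3)
  ## independent cross-check against edgeR's implementation
  fe <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  expect_equal(unname(as.numeric(tmmFactors(m))), fe, tolerance = 1e-9)
})

test_that("TMM warns and falls back when too few genes survive the trim", {
  m <- cbind(s1 = c(5L, 8L, 13L, 4L), s2 = c(9L, 3L, 20L, 7L))
  expect_warning(f <- tmmFactors(m), "fewer than")
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("Audic-Claverie p matches the direct-summation oracle", {
  expect_equal(acPvalue(0, 0, 1e6, 1e6), 1)
  expect_equal(acPvalue(5, 20, 1e6, 1e6), oracleAC(5, 20, 1e6, 1e6),
               tolerance = 1e-9)
  ## grid of counts at three library-size ratios
  for (ratio in c(1, 2, 10)) {
    for (x in c(0, 1, 7, 23)) for (y in c(0, 2, 15, 40)) {
      expect_equal(acPvalue(x, y, 1e6, ratio * 1e6),
                   oracleAC(x, y, 1e6, ratio * 1e6), tolerance = 1e-9)
    }
  }
  ## exchange near-symmetry: swapping orientation shifts the discrete tail
  ## by one predictive term, so at equal library sizes the two orientations
  ## agree within dbinom(x, x+y, 1/2)
  set.seed(23)
  for (i in 1:20) {
    x <- rpois(1, 30); y <- rpois(1, 10)
    p1 <- acPvalue(x, y, 1e6, 1e6); p2 <- acPvalue(y, x, 1e6, 1e6)
    expect_lte(abs(p1 - p2), dbinom(x, x + y, 0.5) + 1e-12)
  }
  expect_error(acPvalue(1.5, 2, 1e6, 1e6), "integers")
})

test_that("BH adjustment equals the naive oracle and the hand example", {
  expect_equal(bhAdjust(0.037), 0.037)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(24)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracleBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
})

test_that("deContrast calls nothing when the libraries are identical", {
  set.seed(25)
  a <- rpois(3000, rlnorm(3000, 2, 1.2))
  m <- cbind(A = a, B = a)
  rownames(m) <- sprintf("g%04d", 1:3000)
  res <- deContrast(m, "A", "B")
  expect_true(all(res$call[res$tested] == "ns"))
  expect_error(deContrast(m, "A", "A"), "must differ")
  ## zero-in-both genes are excluded from testing and from BH
  m2 <- m; m2[1:10, ] <- 0L
  res2 <- deContrast(m2, "A", "B")
  expect_true(all(is.na(res2$p[1:10])))
  expect_equal(sum(res2$tested), sum(rowSums(m2) > 0))
})

test_that("deContrast recovers a strong single-gene signal", {
  set.seed(26)
  base <- rpois(2000, rlnorm(2000, 3, 1))
  m <- cbind(A = base, B = rpois(2000, base + 1))
  m[1, "A"] <- 0L; m[1, "B"] <- 50L
  rownames(m) <- sprintf("g%04d", 1:2000)
  res <- deContrast(m, "A", "B")
  expect_equal(res$call[1], "up")
  expect_lt(res$padj[1], 1e-6)
  ## ratio uses the 0.5 pseudocount, so it is finite
  expect_true(is.finite(res$ratio[1]))
  ## unsatisfiable ratio threshold -> no calls at all
  res2 <- deContrast(m, "A", "B", ratioThreshold = Inf)
  expect_true(all(res2$call[res2$tested] == "ns"))
})

test_that("deContrast recall and false calls behave on simulated truth", {
  cs <- simulateCounts(countSimSpec(nGenes = 5000), seed = 27)
  res <- deContrast(cs$se, "A", "B")
  tr <- cs$truth
  called <- !is.na(res$call) & res$call != "ns"
  expect_gt(sum(called & tr$isDE) / sum(tr$isDE), 0.9)
  expect_lte(sum(called & !tr$isDE), 2)
  ## direction agrees with truth for called DE genes
  up <- res$call == "up" & !is.na(res$call)
  expect_true(all(tr$direction[up & tr$isDE] == "up"))
})

test_that("venn partition matches set algebra and brute-force enumeration", {
  mk <- function(up, down) list(up = up, down = down)
  ## disjoint sets
  v <- vennPartition(list(A = mk(c("a", "b"), character()),
                          B = mk(c("c"), "d")))
  expect_equal(unname(v$partition["A&B"]), 0)
  expect_equal(v$unionSize, 4)
  ## {a,b,c} vs {b,c,d}: common 2, uniques 1 and 1
  v2 <- vennPartition(list(A = mk(c("a", "b", "c"), character()),
                           B = mk(c("b", "c", "d"), character())))
  expect_equal(unname(v2$partition[c("A", "B", "A&B")]), c(1, 1, 2))
  expect_equal(sum(v2$partition), v2$unionSize)

  ## three contrasts against exhaustive membership enumeration
  set.seed(28)
  pool <- sprintf("g%02d", 1:40)
  sets <- lapply(1:3, function(i) {
    s <- sample(pool, 15)
    mk(s[1:8], s[9:15])
  })
  names(sets) <- c("A", "B", "C")
  v3 <- vennPartition(sets)
  varied <- lapply(sets, function(s) union(s$up, s$down))
  expected <- setNames(integer(length(v3$partition)), names(v3$partition))
  for (g in Reduce(union, varied)) {
    memb <- names(varied)[vapply(varied, function(s) g %in% s, logical(1))]
    region <- paste(memb, collapse = "&")
    expected[region] <- expected[region] + 1L
  }
  expect_equal(v3$partition, expected)
  expect_equal(sum(v3$partition), length(Reduce(union, varied)))
  ## direction-split commonality is consistent with the undirected common set
  expect_true(all(v3$commonUp %in% v3$commonVaried))
  expect_true(all(v3$commonDown %in% v3$commonVaried))
  expect_error(vennPartition(sets[1]), "2 or 3")
})
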