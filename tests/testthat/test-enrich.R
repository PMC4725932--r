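## tiny OBO fixture: mf root with two branches, one grandchild, an obsolete
## term and a part_of relationship that must be ignored
writeToyOBO <- function() {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0003674", "name: molecular_function",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0003824", "name: catalytic activity",
    "namespace: molecular_function",
    "is_a: GO:0003674 ! molecular_function", "",
    "[Term]", "id: GO:0016787", "name: hydrolase activity",
    "namespace: molecular_function",
    "is_a: GO:0003824 ! catalytic activity", "",
    "[Term]", "id: GO:0005488", "name: binding",
    "namespace: molecular_function",
    "is_a: GO:0003674 ! molecular_function",
    "relationship: part_of GO:0003674", "",
    "[Term]", "id: GO:9999999", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of", "name: part of"), path)
  path
}

test_that("the OBO reader keeps is_a edges and drops obsolete terms", {
  expect_warning(ont <- readOBO(writeToyOBO()), "non-is_a")
  expect_setequal(ont$terms$id,
                  c("GO:0003674", "GO:0003824", "GO:0016787", "GO:0005488"))
  expect_equal(ont$parents[["GO:0016787"]], "GO:0003824")
  expect_equal(ont$parents[["GO:0003674"]], character(0))
  expect_equal(ont$terms$name[ont$terms$id == "GO:0005488"], "binding")
})

test_that("term levels count is_a edges from the namespace root", {
  suppressWarnings(ont <- readOBO(writeToyOBO()))
  lev <- termLevels(ont)
  expect_equal(unname(lev[c("GO:0003674", "GO:0003824", "GO:0016787")]),
               c(0L, 1L, 2L))
  ## diamond: shortest vs longest path
  ont2 <- ontologyFromEdges(
    c("root", "a", "b", "c"),
    list(root = character(), a = "root", b = "a", c = c("root", "b")))
  expect_equal(unname(termLevels(ont2)[["c"]]), 1L)
  expect_equal(unname(termLevels(ont2, mode = "longest")[["c"]]), 3L)
  ## cycles are an error
  bad <- ontologyFromEdges(c("p", "q"), list(p = "q", q = "p"))
  expect_error(termLevels(bad), "cycle")
})

test_that("propagation adds exactly the brute-force ancestors", {
  ## chain: gene annotated at the leaf gains parent and root
  ont <- ontologyFromEdges(c("root", "B", "A"),
                           list(root = character(), B = "root", A = "B"))
  out <- propagateAnnotations(list(g1 = "A"), ont)
  expect_setequal(out$g1, c("A", "B", "root"))
  ## a term with no parents is unchanged
  out2 <- propagateAnnotations(list(g1 = "root"), ont)
  expect_equal(out2$g1, "root")
  ## random DAG vs brute-force ancestor enumeration
  set.seed(61)
  ids <- sprintf("t%02d", 1:30)
  parents <- setNames(vector("list", 30), ids)
  parents[[1]] <- character()
  for (i in 2:30)
    parents[[i]] <- sample(ids[seq_len(i - 1)],
                           sample(seq_len(min(2, i - 1)), 1))
  ont3 <- ontologyFromEdges(ids, parents)
  ann <- list(gA = sample(ids, 3), gB = sample(ids, 2))
  out3 <- propagateAnnotations(ann, ont3)
  for (g in names(ann)) {
    want <- unique(c(ann[[g]],
                     unlist(lapply(ann[[g]], oracleAncestors, parents))))
    expect_setequal(out3[[g]], want)
  }
  ## unknown terms survive with a warning
  expect_warning(out4 <- propagateAnnotations(list(g1 = c("A", "zz")), ont),
                 "not in ontology")
  expect_true("zz" %in% out4$g1)
})

test_that("Fisher branch equals the doubled hypergeometric tail oracle", {
  ## list 10 (5 with term), background 100 (10 with term)
  bg <- sprintf("g%03d", 1:100)
  withTerm <- bg[1:10]
  lst <- c(bg[1:5], bg[11:15])   # 5 with the term, 5 without
  ann <- data.frame(gene_id = withTerm, term_id = "T1")
  out <- enrichTerms(lst, bg, ann, minCount = 1, propagate = FALSE)
  upper <- sum(dhyper(5:10, 10, 90, 10))
  lower <- sum(dhyper(0:5, 10, 90, 10))
  expect_equal(out$test, "fisher")
  expect_equal(out$p, min(1, 2 * min(lower, upper)), tolerance = 1e-12)
  expect_equal(out$k, 5); expect_equal(out$K, 10)
  expect_equal(out$expected, 10 * 10 / 100)
  expect_equal(out$direction, "over")
})

test_that("chi-square branch equals the hand Sum((O-E)^2/E) formula", {
  ## 2x2 table: k=20, n=100, K=80, N=1000 (all expected cells >= 5)
  bg <- sprintf("g%04d", 1:1000)
  withTerm <- c(bg[1:20], bg[101:160])      # 80 genes with the term
  lst <- bg[1:100]                          # 20 of them in the list
  ann <- data.frame(gene_id = withTerm, term_id = "T1")
  out <- enrichTerms(lst, bg, ann, minCount = 1, propagate = FALSE)
  O <- c(20, 80, 60, 840)
  E <- c(100 * 80, 100 * 920, 900 * 80, 900 * 920) / 1000
  expect_equal(out$test, "chi-square")
  expect_equal(out$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(out$p, pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE))
})

test_that("chi-square tracks Fisher for well-filled near-null tables", {
  ## the chi-square approximation is reliable near the bulk of the
  ## distribution; compare there (far tails diverge for any cell size)
  bg <- sprintf("g%05d", 1:10000)
  ann <- data.frame(gene_id = bg[1:1000], term_id = "T1")  # K = 1000
  for (k in c(205, 215)) {
    lst <- c(bg[1:k], bg[1001:(1000 + 2000 - k)])          # n = 2000
    chi <- enrichTerms(lst, bg, ann, minCount = 1, propagate = FALSE)
    pF <- min(1, 2 * min(phyper(k, 1000, 9000, 2000),
                         phyper(k - 1, 1000, 9000, 2000,
                                lower.tail = FALSE)))
    expect_equal(chi$test, "chi-square")
    expect_lt(abs(chi$p - pF) / pF, 0.10)
  }
})

test_that("null and error behavior of enrichment", {
  bg <- sprintf("g%03d", 1:100)
  ann <- data.frame(gene_id = bg[1:30], term_id = "T1")
  ## gene list = background: k/n = K/N, no signal
  out <- enrichTerms(bg, bg, ann, minCount = 1, propagate = FALSE)
  expect_equal(out$k, out$K)
  expect_gt(out$p, 0.999)
  ## list outside background errors naming the offenders
  expect_error(enrichTerms(c("nope", bg[1]), bg, ann, propagate = FALSE),
               "nope")
  ## empty list errors
  expect_error(enrichTerms(character(), bg, ann, propagate = FALSE),
               "non-empty")
})

test_that("level filtering keeps exactly the terms at the requested depth", {
  suppressWarnings(ont <- readOBO(writeToyOBO()))
  bg <- sprintf("g%03d", 1:60)
  ann <- rbind(
    data.frame(gene_id = bg[1:20], term_id = "GO:0016787"),
    data.frame(gene_id = bg[21:40], term_id = "GO:0005488"))
  lst <- bg[1:15]
  all <- enrichTerms(lst, bg, ann, minCount = 1, ontology = ont)
  ## propagation pushed annotations to the root (level 0) and level 1
  expect_setequal(all$term_id,
                  c("GO:0003674", "GO:0003824", "GO:0016787", "GO:0005488"))
  l1 <- enrichTerms(lst, bg, ann, minCount = 1, ontology = ont, level = 1)
  expect_setequal(l1$term_id, c("GO:0003824", "GO:0005488"))
  ## a level with no terms yields an empty table, not an error
  l9 <- levelFilter(all, 9)
  expect_equal(nrow(l9), 0)
})

test_that("a spiked term is detected and detection strengthens with odds", {
  set.seed(62)
  genes <- sprintf("g%04d", 1:4000)
  isDE <- seq_along(genes) <= 150
  fdrOf <- function(odds, seed) {
    ann <- simulateAnnotation(genes, isDE, nTerms = 20, genesPerTerm = 80,
                              spikedTerms = 1, spikeOdds = odds, seed = seed)
    out <- enrichTerms(genes[isDE], genes, ann$annotations,
                       propagate = FALSE)
    out$fdr[out$term_id == ann$spiked]
  }
  expect_lt(fdrOf(10, 1), 0.05)
  ## monotone power: stronger spikes give (weakly) smaller mean FDR
  weak <- mean(vapply(1:5, function(s) fdrOf(2, s), numeric(1)))
  strong <- mean(vapply(1:5, function(s) fdrOf(8, s), numeric(1)))
  expect_lte(strong, weak)
})
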