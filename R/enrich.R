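#' @include AllClasses.R
NULL

#' Read a minimal OBO ontology
#'
#' Parses \code{[Term]} stanzas of an OBO file, keeping id, name, namespace
#' and \code{is_a} parents. Obsolete terms are dropped; relationship types
#' other than \code{is_a} (e.g. part_of) are ignored with a warning.
#'
#' @param path path to an OBO file.
#' @return list with \code{terms} (data.frame id, name, namespace) and
#'   \code{parents} (named list: term id -> character vector of is_a parent
#'   ids).
#' @export
readOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  inTerm <- FALSE
  terms <- list(); cur <- NULL
  sawOtherRel <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id))
      terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character())
      inTerm <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {           # other stanza type
      terms <- flush(cur, terms)
      cur <- NULL; inTerm <- FALSE
      next
    }
    if (!inTerm || !nzchar(ln)) next
    if (grepl("^id: ", ln)) cur$id <- sub("^id: ", "", ln)
    else if (grepl("^name: ", ln)) cur$name <- sub("^name: ", "", ln)
    else if (grepl("^namespace: ", ln))
      cur$namespace <- sub("^namespace: ", "", ln)
    else if (grepl("^is_a: ", ln))
      cur$parents <- c(cur$parents,
                       sub(" !.*$", "", sub("^is_a: ", "", ln)))
    else if (grepl("^relationship: ", ln)) sawOtherRel <- TRUE
    else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  if (sawOtherRel)
    warning("non-is_a relationships present in OBO file; ignored")
  ids <- names(terms)
  list(
    terms = data.frame(
      id = ids,
      name = vapply(terms, function(t) t$name %||% NA_character_,
                    character(1)),
      namespace = vapply(terms, function(t) t$namespace %||% NA_character_,
                         character(1)),
      row.names = NULL),
    parents = lapply(terms, `[[`, "parents"))
}

#' Build an ontology from edge lists
#'
#' Convenience constructor for synthetic ontologies: the same structure
#' [readOBO()] returns, from explicit is_a edges.
#'
#' @param ids term ids.
#' @param parents named list id -> character vector of parent ids.
#' @param names optional term names (default = ids).
#' @param namespace namespace label applied to all terms.
#' @return ontology list (\code{terms}, \code{parents}).
#' @export
ontologyFromEdges <- function(ids, parents, names = ids,
                              namespace = "synthetic") {
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) as.character(p %||% character()))
  list(terms = data.frame(id = ids, name = names, namespace = namespace,
                          row.names = NULL),
       parents = parents)
}

## Ancestor closure (excluding the term itself) for every term, with cycle
## detection. Memoized DFS.
.ancestorClosure <- function(parents) {
  anc <- vector("list", length(parents))
  names(anc) <- names(parents)
  state <- setNames(integer(length(parents)), names(parents)) # 0/1/2
  visit <- function(id) {
    if (state[[id]] == 2L) return(anc[[id]])
    if (state[[id]] == 1L) stop("cycle detected in ontology at term ", id,
                                call. = FALSE)
    state[[id]] <<- 1L
    ps <- parents[[id]]
    ps <- ps[ps %in% names(parents)]
    out <- ps
    for (p in ps) out <- union(out, visit(p))
    anc[[id]] <<- out
    state[[id]] <<- 2L
    out
  }
  for (id in names(parents)) visit(id)
  anc
}

#' Ontology term levels
#'
#' Level of a term = number of is_a edges on the shortest (default) or
#' longest path to its namespace root (a term without parents). Roots have
#' level 0, their direct children level 1, and so on; this is the depth
#' scale on which "level 3" molecular-function terms are selected.
#'
#' @param ontology ontology list from [readOBO()] / [ontologyFromEdges()].
#' @param mode \code{"shortest"} (default) or \code{"longest"} path.
#' @return named integer vector of levels.
#' @export
termLevels <- function(ontology, mode = c("shortest", "longest")) {
  mode <- match.arg(mode)
  parents <- ontology$parents
  .ancestorClosure(parents)  # cycle check
  agg <- if (mode == "shortest") min else max
  lev <- setNames(rep(NA_integer_, length(parents)), names(parents))
  depth <- function(id) {
    if (!is.na(lev[[id]])) return(lev[[id]])
    ps <- parents[[id]]
    ps <- ps[ps %in% names(parents)]
    d <- if (!length(ps)) 0L
         else 1L + agg(vapply(ps, depth, integer(1)))
    lev[[id]] <<- as.integer(d)
    d
  }
  for (id in names(parents)) depth(id)
  lev
}

## annotations as named list gene -> character terms, from list or 2-col df
.annotationList <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
    split(as.character(annotations$term_id),
          as.character(annotations$gene_id))
  } else if (is.list(annotations)) {
    lapply(annotations, as.character)
  } else stop("annotations must be a data.frame or a named list")
}

#' Propagate annotations up the ontology
#'
#' True-path propagation: every gene annotated to a term is also annotated
#' to all of that term's is_a ancestors, up to and including the namespace
#' root. Terms absent from the ontology are kept unpropagated with a
#' warning; a cyclic ontology is an error.
#'
#' @param annotations data.frame (gene_id, term_id) or named list
#'   gene -> term ids.
#' @param ontology ontology list from [readOBO()] / [ontologyFromEdges()].
#' @return named list gene -> character vector of term ids (closed under
#'   is_a ancestry).
#' @export
propagateAnnotations <- function(annotations, ontology) {
  ann <- .annotationList(annotations)
  anc <- .ancestorClosure(ontology$parents)
  known <- names(ontology$parents)
  missing <- setdiff(unique(unlist(ann)), known)
  if (length(missing))
    warning("term(s) not in ontology kept unpropagated: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) " ...")
  lapply(ann, function(terms) {
    terms <- unique(terms)
    extra <- unlist(anc[intersect(terms, known)], use.names = FALSE)
    union(terms, extra)
  })
}

## Two-sided Fisher probability by the smaller-tail-doubling rule on the
## hypergeometric distribution of k (list genes with the term).
.fisherDoubling <- function(k, K, n, N) {
  lower <- phyper(k, K, N - K, n)
  upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' GO-term enrichment of a gene list against a background
#'
#' For every term annotated to at least \code{minCount} background genes, a
#' 2x2 table (in list / out of list x has term / lacks term) is tested:
#' chi-square (without continuity correction) when all four expected counts
#' are at least 5, otherwise a two-sided Fisher exact test (smaller tail
#' doubled). P values are BH-adjusted across the tested terms.
#'
#' @param geneList character vector of genes of interest; must be a subset
#'   of \code{background}.
#' @param background character vector: the annotated gene universe.
#' @param annotations data.frame (gene_id, term_id) or named list
#'   gene -> term ids.
#' @param minCount minimum background genes per tested term (default 3).
#' @param ontology optional ontology list; enables propagation, term names
#'   and levels.
#' @param propagate propagate annotations up is_a edges first (default TRUE
#'   when an ontology is supplied).
#' @param level optional single level; when given, only terms at that
#'   ontology level are retained (after testing), see [levelFilter()].
#' @param levelMode passed to [termLevels()].
#' @return data.frame: term_id, name, namespace, level, k, n, K, N,
#'   expected, statistic, test, direction, p, fdr, sorted by p.
#' @export
enrichTerms <- function(geneList, background, annotations, minCount = 3,
                        ontology = NULL, propagate = !is.null(ontology),
                        level = NULL, levelMode = "shortest") {
  geneList <- unique(as.character(geneList))
  background <- unique(as.character(background))
  if (!length(geneList) || !length(background))
    stop("gene list and background must be non-empty")
  off <- setdiff(geneList, background)
  if (length(off))
    stop("gene list not contained in background: ",
         paste(head(off, 10), collapse = ", "),
         if (length(off) > 10) " ...")
  ann <- .annotationList(annotations)
  if (propagate) {
    if (is.null(ontology)) stop("propagation requires an ontology")
    ann <- propagateAnnotations(ann, ontology)
  }
  ann <- ann[intersect(names(ann), background)]
  gene2terms <- ann
  term2genes <- split(
    rep(names(gene2terms), lengths(gene2terms)),
    unlist(gene2terms, use.names = FALSE))
  K <- lengths(term2genes)
  tested <- names(K)[K >= minCount]
  if (!length(tested))
    return(data.frame(term_id = character(), name = character(),
                      namespace = character(), level = integer(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), expected = numeric(),
                      statistic = numeric(), test = character(),
                      direction = character(), p = numeric(),
                      fdr = numeric()))
  N <- length(background)
  n <- length(geneList)
  k <- vapply(term2genes[tested],
              function(g) sum(g %in% geneList), integer(1))
  Kt <- K[tested]
  e11 <- n * Kt / N; e12 <- n * (N - Kt) / N
  e21 <- (N - n) * Kt / N; e22 <- (N - n) * (N - Kt) / N
  useFisher <- e11 < 5 | e12 < 5 | e21 < 5 | e22 < 5
  stat <- rep(NA_real_, length(tested))
  p <- numeric(length(tested))
  o11 <- k; o12 <- n - k; o21 <- Kt - k; o22 <- N - n - Kt + k
  chi <- (o11 - e11)^2 / e11 + (o12 - e12)^2 / e12 +
    (o21 - e21)^2 / e21 + (o22 - e22)^2 / e22
  stat[!useFisher] <- chi[!useFisher]
  p[!useFisher] <- pchisq(chi[!useFisher], df = 1, lower.tail = FALSE)
  p[useFisher] <- .fisherDoubling(k[useFisher], Kt[useFisher], n, N)
  out <- data.frame(
    term_id = tested, name = NA_character_, namespace = NA_character_,
    level = NA_integer_,
    k = k, n = n, K = as.integer(Kt), N = N, expected = e11,
    statistic = stat,
    test = ifelse(useFisher, "fisher", "chi-square"),
    direction = ifelse(k >= e11, "over", "under"),
    p = p, fdr = bhAdjust(p),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(ontology)) {
    idx <- match(out$term_id, ontology$terms$id)
    out$name <- ontology$terms$name[idx]
    out$namespace <- ontology$terms$namespace[idx]
    lev <- termLevels(ontology, levelMode)
    out$level <- unname(lev[out$term_id])
    if (!is.null(level)) out <- levelFilter(out, level)
  }
  out[order(out$p), ]
}

#' Filter enrichment rows by ontology level
#'
#' Keeps rows whose \code{level} equals the requested level. An empty result
#' is returned (not an error) when no term sits at that level.
#'
#' @param rows data.frame from [enrichTerms()] (must carry a level column).
#' @param level requested level (integer scalar).
#' @return filtered data.frame.
#' @export
levelFilter <- function(rows, level) {
  stopifnot(is.data.frame(rows), "level" %in% names(rows),
            length(level) == 1L)
  rows[!is.na(rows$level) & rows$level == level, , drop = FALSE]
}
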