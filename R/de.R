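#' @include AllClasses.R
NULL

#' Assemble a count experiment
#'
#' Wraps a genes x samples integer count matrix and per-gene lengths into a
#' \link[SummarizedExperiment]{SummarizedExperiment} with assay
#' \code{"counts"} and \code{rowData} column \code{length_bp}; the standard
#' container the DE functions consume.
#'
#' @param counts nonnegative integer matrix, genes x samples, with row and
#'   column names.
#' @param lengths positive per-gene lengths in bp.
#' @param secretory optional logical/0-1 vector flagging genes predicted to
#'   encode secreted proteins (carried through to DE output).
#' @return A \code{SummarizedExperiment}.
#' @export
countExperiment <- function(counts, lengths, secretory = NULL) {
  counts <- as.matrix(counts)
  .assertCount(counts, "counts")
  if (length(lengths) != nrow(counts) || any(lengths <= 0))
    stop("lengths must be positive, one per gene")
  if (any(colSums(counts) <= 0)) stop("library sizes must be > 0")
  rd <- S4Vectors::DataFrame(length_bp = as.numeric(lengths))
  if (!is.null(secretory)) rd$secretory <- as.logical(secretory)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd)
}

.countsOf <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

.lengthsOf <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::rowData(x)$length_bp
  else NULL
}

#' Reads per kilobase per million mapped reads
#'
#' \eqn{RPKM = 10^9 \cdot C / (N \cdot L)} with C the gene count, N the
#' library size and L the gene length in bp.
#'
#' @param counts count vector or genes x samples matrix.
#' @param lengths gene lengths in bp (> 0).
#' @param librarySizes per-sample library sizes (> 0); defaults to column
#'   sums when \code{counts} is a matrix.
#' @return RPKM values, same shape as \code{counts}.
#' @export
rpkm <- function(counts, lengths, librarySizes = NULL) {
  if (is.matrix(counts)) {
    if (is.null(librarySizes)) librarySizes <- colSums(counts)
    if (any(librarySizes <= 0)) stop("library sizes must be > 0")
    if (any(lengths <= 0)) stop("gene lengths must be > 0")
    1e9 * sweep(sweep(counts, 1, lengths, "/"), 2, librarySizes, "/")
  } else {
    if (is.null(librarySizes)) stop("librarySizes required for vector input")
    if (any(librarySizes <= 0)) stop("library sizes must be > 0")
    if (any(lengths <= 0)) stop("gene lengths must be > 0")
    1e9 * counts / (librarySizes * lengths)
  }
}

## Upper-quartile of nonzero count proportions, used only to pick the TMM
## reference sample.
.uqProportion <- function(counts) {
  apply(counts, 2, function(x) {
    quantile(x[x > 0] / sum(x), 0.75, names = FALSE, type = 7)
  })
}

## One pairwise TMM factor (sample vs reference).
.tmmPair <- function(obs, ref, logratioTrim, sumTrim, doWeighting, minGenes) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  nO <- sum(obs); nR <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / nO) / (r / nR))
  A <- 0.5 * log2((o / nO) * (r / nR))
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; o <- o[fin]; r <- r[fin]
  if (!length(M)) return(1)
  if (max(abs(M)) < 1e-6) return(1)     # identical proportions
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
  rkM <- rank(M); rkA <- rank(A)
  keep2 <- rkM >= loM & rkM <= hiM & rkA >= loA & rkA <= hiA
  if (sum(keep2) < minGenes) {
    warning("fewer than ", minGenes,
            " genes survive the TMM trim; falling back to untrimmed mean")
    keep2 <- rep(TRUE, n)
  }
  w <- if (doWeighting)
    1 / ((nO - o) / (nO * o) + (nR - r) / (nR * r)) else rep(1, n)
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors: per sample, log2 relative
#' proportion ratios (M) against a reference sample are trimmed (30% of the M
#' tails, 5% of the A tails by default), averaged with precision weights, and
#' exponentiated; factors are rescaled to geometric mean 1. Genes with a zero
#' in either sample of a pair are dropped. The reference is the sample whose
#' upper-quartile proportion is closest to the mean upper-quartile, unless
#' given.
#'
#' @param x count matrix (genes x samples, >= 2 samples) or a
#'   \code{SummarizedExperiment} from [countExperiment()].
#' @param refSample reference column name or index (optional).
#' @param logratioTrim fraction trimmed from each M tail (default 0.3).
#' @param sumTrim fraction trimmed from each A tail (default 0.05).
#' @param doWeighting precision-weight the trimmed mean (default TRUE).
#' @param minGenes fewer surviving genes than this triggers a warning and an
#'   untrimmed fallback (default 20).
#' @return named numeric vector of factors with attribute
#'   \code{"refSample"}; multiply by library sizes for effective sizes
#'   ([effectiveLibrarySizes()]).
#' @export
tmmFactors <- function(x, refSample = NULL, logratioTrim = 0.3,
                       sumTrim = 0.05, doWeighting = TRUE, minGenes = 20) {
  counts <- .countsOf(x)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  .assertCount(counts, "counts")
  if (is.null(refSample)) {
    uq <- .uqProportion(counts)
    refSample <- which.min(abs(uq - mean(uq)))
  } else if (is.character(refSample)) {
    refSample <- match(refSample, colnames(counts))
    if (is.na(refSample)) stop("refSample not found among columns")
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    .tmmPair(counts[, j], counts[, refSample], logratioTrim, sumTrim,
             doWeighting, minGenes), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "refSample") <- refSample
  f
}

#' @rdname tmmFactors
#' @param factors TMM factors from [tmmFactors()].
#' @return \code{effectiveLibrarySizes}: named numeric, library size times
#'   factor per sample.
#' @export
effectiveLibrarySizes <- function(x, factors) {
  counts <- .countsOf(x)
  colSums(counts) * as.numeric(factors)[seq_len(ncol(counts))]
}

#' Audic-Claverie two-library count test
#'
#' Exact replicate-free test of a count difference between two libraries.
#' With x reads in a library of size N1, the probability of observing k reads
#' in a library of size N2 is
#' \deqn{p(k|x) = (N2/N1)^k (x+k)! / (x! k! (1+N2/N1)^{x+k+1}),}
#' the negative-binomial predictive with size x+1 and success probability
#' N1/(N1+N2), through which the tails are evaluated in log-safe form.
#' The reported two-sided p doubles the smaller of the two cumulative tails
#' at y (the tail pointing away from the expectation x N2/N1), capped at 1.
#'
#' @param x,y observed counts (nonnegative integers, vectorized).
#' @param N1,N2 (effective) library sizes of the two samples.
#' @return two-sided p values in [0, 1].
#' @export
acPvalue <- function(x, y, N1, N2) {
  .assertCount(x, "x"); .assertCount(y, "y")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library sizes must be > 0")
  prob <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; preserves input order, monotone in p-rank,
#' capped at 1.
#'
#' @param p p values in [0, 1] (NA not allowed).
#' @return adjusted p values, same order as input.
#' @export
bhAdjust <- function(p) {
  .assertProb(p, "p values")
  p.adjust(p, method = "BH")
}

#' Replicate-free differential expression between two libraries
#'
#' Per gene: the Audic-Claverie test on raw counts with TMM-effective library
#' sizes, BH adjustment across tested genes, an expression ratio on
#' TMM-normalized counts-per-million with pseudocount 0.5 (or on RPKM), and
#' an up/down/ns call at the ratio and adjusted-p thresholds. Genes with zero
#' counts in both samples are untestable and excluded from the test and the
#' BH denominator.
#'
#' @param x count matrix or \code{SummarizedExperiment} ([countExperiment()]).
#' @param sampleA,sampleB column names or indices of the two libraries
#'   (B is compared against A; ratio = B/A).
#' @param factors TMM factors for all samples of \code{x}; computed with
#'   [tmmFactors()] when NULL.
#' @param ratioThreshold minimum fold change, either direction (default 2).
#' @param alpha adjusted-p cut-off (default 0.001).
#' @param ratioOn compute the ratio on \code{"cpm"} (TMM-normalized
#'   counts-per-million, default) or \code{"rpkm"}.
#' @param pseudocount added to both normalized abundances before the ratio
#'   (default 0.5); never applied to the p values.
#' @return data.frame: gene_id, countA, countB, cpmA, cpmB, ratio, p, padj,
#'   call (up/down/ns; NA for untested genes), tested, secretory (when
#'   annotated).
#' @export
deContrast <- function(x, sampleA, sampleB, factors = NULL,
                       ratioThreshold = 2, alpha = 0.001,
                       ratioOn = c("cpm", "rpkm"), pseudocount = 0.5) {
  ratioOn <- match.arg(ratioOn)
  counts <- .countsOf(x)
  if (is.character(sampleA)) sampleA <- match(sampleA, colnames(counts))
  if (is.character(sampleB)) sampleB <- match(sampleB, colnames(counts))
  if (is.na(sampleA) || is.na(sampleB)) stop("sample not found")
  if (sampleA == sampleB)
    stop("the two samples of a contrast must differ")
  if (is.null(factors)) factors <- tmmFactors(counts)
  effN <- effectiveLibrarySizes(counts, factors)
  cA <- counts[, sampleA]; cB <- counts[, sampleB]
  nA <- effN[sampleA]; nB <- effN[sampleB]
  tested <- (cA + cB) > 0
  p <- rep(NA_real_, nrow(counts))
  p[tested] <- acPvalue(cA[tested], cB[tested], nA, nB)
  padj <- rep(NA_real_, nrow(counts))
  padj[tested] <- bhAdjust(p[tested])
  if (ratioOn == "cpm") {
    abA <- cA / nA * 1e6
    abB <- cB / nB * 1e6
  } else {
    lens <- .lengthsOf(x)
    if (is.null(lens)) stop("ratioOn = 'rpkm' needs gene lengths")
    abA <- rpkm(cA, lens, nA)
    abB <- rpkm(cB, lens, nB)
  }
  ratio <- (abB + pseudocount) / (abA + pseudocount)
  call <- rep(NA_character_, nrow(counts))
  call[tested] <- "ns"
  sig <- tested & !is.na(padj) & padj < alpha
  call[sig & ratio >= ratioThreshold] <- "up"
  call[sig & ratio <= 1 / ratioThreshold] <- "down"
  out <- data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    countA = cA, countB = cB, cpmA = abA, cpmB = abB,
    ratio = ratio, p = p, padj = padj, call = call, tested = tested,
    stringsAsFactors = FALSE)
  if (is(x, "SummarizedExperiment") &&
      "secretory" %in% names(SummarizedExperiment::rowData(x)))
    out$secretory <- SummarizedExperiment::rowData(x)$secretory
  rownames(out) <- NULL
  out
}

## up/down sets from a deContrast result (or pass-through for list(up, down))
.deSets <- function(res) {
  if (is.data.frame(res))
    list(up = res$gene_id[!is.na(res$call) & res$call == "up"],
         down = res$gene_id[!is.na(res$call) & res$call == "down"])
  else if (is.list(res) && all(c("up", "down") %in% names(res)))
    list(up = as.character(res$up), down = as.character(res$down))
  else stop("each contrast must be a deContrast result or list(up=, down=)")
}

#' Direction-aware Venn partition of DE contrasts
#'
#' For 2 or 3 contrasts: counts of every membership region of the Venn
#' diagram over the "varied" (up or down) gene sets, plus the direction-split
#' commonality — genes commonly up in all contrasts, commonly down in all,
#' and commonly varied (in the up-or-down set of every contrast).
#'
#' @param contrasts named list of 2-3 [deContrast()] results (or
#'   \code{list(up=, down=)} pairs).
#' @return list with elements \code{partition} (named region counts; names
#'   like "A", "A&B"), \code{unionSize}, \code{perContrast} (up/down/varied
#'   counts), \code{commonUp}, \code{commonDown}, \code{commonVaried}
#'   (character vectors of gene ids).
#' @export
vennPartition <- function(contrasts) {
  k <- length(contrasts)
  if (k < 2L || k > 3L) stop("vennPartition supports 2 or 3 contrasts")
  nms <- names(contrasts) %||% LETTERS[seq_len(k)]
  if (is.null(names(contrasts))) names(contrasts) <- nms
  sets <- lapply(contrasts, .deSets)
  varied <- lapply(sets, function(s) union(s$up, s$down))
  uni <- Reduce(union, varied)
  member <- vapply(varied, function(s) uni %in% s, logical(length(uni)))
  if (length(uni) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row)
    paste(nms[row], collapse = "&"))
  regions <- unlist(lapply(seq_len(k), function(m)
    combn(nms, m, paste, collapse = "&")))
  partition <- setNames(integer(length(regions)), regions)
  tab <- table(pattern)
  partition[names(tab)] <- as.integer(tab)
  list(
    partition = partition,
    unionSize = length(uni),
    perContrast = data.frame(
      contrast = nms,
      up = vapply(sets, function(s) length(s$up), integer(1)),
      down = vapply(sets, function(s) length(s$down), integer(1)),
      varied = vapply(varied, length, integer(1)),
      row.names = NULL),
    commonUp = Reduce(intersect, lapply(sets, `[[`, "up")),
    commonDown = Reduce(intersect, lapply(sets, `[[`, "down")),
    commonVaried = Reduce(intersect, varied))
}
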