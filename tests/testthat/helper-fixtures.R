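## Shared fixtures and independent oracles used across test files.

## A DemographySchedules object from bare lx/mx vectors (all survivors
## booked as adults so the s_xj row-sum invariant holds).
makeSched <- function(lx, mx) {
  sxj <- matrix(0, length(lx), 5,
                dimnames = list(NULL, c("N1", "N2", "N3", "N4", "Adult")))
  sxj[, "Adult"] <- lx
  new("DemographySchedules", lx = lx, mx = mx, sxj = sxj,
      maxAge = length(lx) - 1L)
}

## An individual that is adult from `adultAge` on; offspring given per day.
makeIndividual <- function(deathAge, offspring, adultAge = NULL) {
  if (is.null(adultAge)) {
    entries <- c(N1 = 0L)
  } else {
    entries <- as.integer(round(seq(0, adultAge, length.out = 5)))
    entries[5] <- as.integer(adultAge)
    entries <- cummax(entries)
    names(entries) <- c("N1", "N2", "N3", "N4", "Adult")
    entries <- entries[entries <= deathAge]
  }
  list(stageEntry = entries, deathAge = as.integer(deathAge),
       offspring = as.integer(offspring))
}

makeCohort <- function(individuals, host = "") {
  AphidCohort(sprintf("i%02d", seq_along(individuals)),
              lapply(individuals, `[[`, "stageEntry"),
              vapply(individuals, `[[`, integer(1), "deathAge"),
              lapply(individuals, `[[`, "offspring"),
              host)
}

## Independent Euler-Lotka root oracle: dense grid to find a sign change,
## then naive bisection to 1e-10. Never calls the package solver.
oracleEulerLotka <- function(lx, mx, lower = -1, upper = 3) {
  f <- function(r) sum(exp(-r * seq_along(lx)) * lx * mx) - 1
  grid <- seq(lower, upper, by = 0.001)
  fg <- vapply(grid, f, numeric(1))
  i <- which(fg[-1] * fg[-length(fg)] <= 0)[1]
  lo <- grid[i]; hi <- grid[i + 1]
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## Direct log-space summation oracle for the Audic-Claverie two-sided p:
## term-by-term tail sums of the printed formula, doubling the smaller tail.
oracleAC <- function(x, y, N1, N2) {
  logTerm <- function(k) {
    k * log(N2 / N1) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1p(N2 / N1)
  }
  lower <- sum(exp(logTerm(0:y)))
  ## upper tail: sum outward from y far past the predictive mean, where the
  ## remaining mass is negligible at the 1e-9 comparison scale
  kMax <- ceiling(max(y, (x + 1) * N2 / N1)) + 2000
  upper <- sum(exp(logTerm(y:kMax)))
  min(1, 2 * min(lower, upper))
}

## Naive O(m^2) Benjamini-Hochberg oracle.
oracleBH <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])
    cand <- vapply(seq_len(m), function(j) {
      rj <- sum(p <= p[j])
      if (p[j] >= p[i]) m * p[j] / rj else Inf
    }, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

## Plain-loop TMM oracle: same trim rules, written independently with
## sorting instead of ranks, one pair at a time.
oracleTMM <- function(counts, ref) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  libs <- colSums(counts)
  fs <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    o <- counts[, j]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / libs[j]) / (r / libs[ref]))
    A <- 0.5 * log2((o / libs[j]) * (r / libs[ref]))
    if (length(M) == 0 || max(abs(M)) < 1e-6) { fs[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    w <- 1 / ((libs[j] - o) / (libs[j] * o) + (libs[ref] - r) /
                (libs[ref] * r))
    num <- 0; den <- 0
    for (g in seq_len(n)) {
      if (rM[g] >= loM && rM[g] <= hiM && rA[g] >= loA && rA[g] <= hiA) {
        num <- num + w[g] * M[g]
        den <- den + w[g]
      }
    }
    fs[j] <- 2^(num / den)
  }
  fs / exp(mean(log(fs)))
}

## Brute-force ancestor enumeration on an explicit edge list.
oracleAncestors <- function(term, parents) {
  out <- character()
  frontier <- parents[[term]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- unique(unlist(parents[frontier]))
    frontier <- setdiff(frontier, out)
  }
  out
}
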