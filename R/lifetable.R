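#' @include AllClasses.R
NULL

## ---- internal cohort matrices -------------------------------------------
## aliveMat[i, x+1] = 1 if individual i is alive at age x; offMat the daily
## offspring, zero-padded past death. Both n x (maxAge+1). These are the
## fast path used by buildSchedules and the bootstrap.
.cohortMatrices <- function(cohort) {
  n <- length(cohort@ids)
  A <- max(cohort@deathAge)
  alive <- matrix(0, n, A + 1L)
  off <- matrix(0, n, A + 1L)
  for (i in seq_len(n)) {
    da <- cohort@deathAge[i]
    alive[i, seq_len(da + 1L)] <- 1
    off[i, seq_len(da + 1L)] <- cohort@offspring[[i]]
  }
  adultEntry <- vapply(cohort@stageEntry, function(s)
    if ("Adult" %in% names(s)) s[["Adult"]] else NA_integer_, integer(1))
  list(alive = alive, off = off, adultEntry = adultEntry,
       deathAge = cohort@deathAge, n = n, maxAge = A)
}

## Schedules from column sums of (a subset of) the cohort matrices. The
## denominator of l_x is always the resample size n; m_x is per-capita among
## survivors and set to 0 where no one is alive.
.schedulesFromCounts <- function(aliveCounts, offCounts, n) {
  lx <- aliveCounts / n
  mx <- ifelse(aliveCounts > 0, offCounts / aliveCounts, 0)
  list(lx = lx, mx = mx)
}

#' Build demographic schedules from a cohort
#'
#' Computes the age-specific survival rate \eqn{l_x} (fraction of the initial
#' cohort alive at age x), the age-specific fecundity \eqn{m_x} (mean
#' offspring per surviving individual at age x, 0 where none is alive), and
#' the age-stage occupancy matrix \eqn{s_{xj}} (fraction of the initial
#' cohort alive and in stage j at age x), from daily individual records.
#'
#' @param cohort an [AphidCohort-class].
#' @return A [DemographySchedules-class] with ages 0..max observed death age.
#' @examples
#' co <- AphidCohort(c("a", "b"),
#'   list(c(N1 = 0L, N2 = 1L, N3 = 1L, N4 = 1L, Adult = 1L),
#'        c(N1 = 0L, N2 = 1L, N3 = 2L, N4 = 2L, Adult = 2L)),
#'   c(1L, 3L), list(c(0L, 2L), c(0L, 0L, 4L, 0L)))
#' survivalSchedule(buildSchedules(co))  # 1 1 0.5 0.5
#' @export
buildSchedules <- function(cohort) {
  stopifnot(is(cohort, "AphidCohort"))
  validObject(cohort)
  m <- .cohortMatrices(cohort)
  sch <- .schedulesFromCounts(colSums(m$alive), colSums(m$off), m$n)
  ## stage of individual i at age x: last stage entered at or before x
  sxj <- matrix(0, m$maxAge + 1L, length(STAGES),
                dimnames = list(NULL, STAGES))
  for (i in seq_len(m$n)) {
    se <- cohort@stageEntry[[i]]
    for (x in 0:cohort@deathAge[i]) {
      j <- max(which(se <= x))
      sxj[x + 1L, j] <- sxj[x + 1L, j] + 1
    }
  }
  new("DemographySchedules", lx = sch$lx, mx = sch$mx, sxj = sxj / m$n,
      maxAge = m$maxAge)
}

.lxmx <- function(x) {
  if (is(x, "DemographySchedules")) x@lx * x@mx
  else stop("expected a DemographySchedules object")
}

#' Net reproductive rate R0
#'
#' \eqn{R_0 = \sum_x l_x m_x}: the mean number of offspring an individual of
#' the initial cohort produces over its lifetime (early-dying individuals
#' included). Equals total offspring / cohort size exactly on integer data.
#'
#' @param sched a [DemographySchedules-class].
#' @return numeric scalar.
#' @export
netReproductiveRate <- function(sched) sum(.lxmx(sched))

## Euler-Lotka discount ages: with ages indexed from 0, the exponent is
## (x+1) under the age-stage life-table convention ("x+1", default) or x
## under the classical textbook indexing ("x").
.elExponents <- function(nAges, convention) {
  convention <- match.arg(convention, c("x+1", "x"))
  if (convention == "x+1") seq_len(nAges) else seq_len(nAges) - 1
}

#' Euler-Lotka residual
#'
#' \eqn{\sum_x e^{-r(x+1)} l_x m_x - 1} at a candidate growth rate r
#' (exponent x under \code{convention = "x"}).
#'
#' @param r candidate intrinsic rate of increase (day^-1).
#' @param sched a [DemographySchedules-class].
#' @param convention exponent convention, \code{"x+1"} (default) or
#'   \code{"x"}; the age-stage life-table literature uses (x+1) with ages
#'   counted from 0.
#' @return numeric scalar, zero at the true r.
#' @export
eulerLotkaResidual <- function(r, sched, convention = "x+1") {
  lm <- .lxmx(sched)
  expo <- .elExponents(length(lm), convention)
  sum(exp(-r * expo) * lm) - 1
}

.solveIntrinsicRate <- function(lxmx, convention = "x+1", tol = 1e-12) {
  if (sum(lxmx) <= 0)
    stop("no reproduction, r undefined", call. = FALSE)
  expo <- .elExponents(length(lxmx), convention)
  keep <- lxmx > 0
  lm <- lxmx[keep]; ex <- expo[keep]
  f <- function(r) sum(exp(-r * ex) * lm) - 1  # strictly decreasing in r
  lo <- -1; hi <- 2; w <- hi - lo
  nDouble <- 0L
  while (f(lo) < 0) {           # root below lo: push lo down, doubling
    lo <- lo - w; w <- 2 * w
    nDouble <- nDouble + 1L
    if (nDouble > 60L) stop("bisection bracket expansion failed")
  }
  nDouble <- 0L
  while (f(hi) > 0) {           # root above hi: push hi up, doubling
    hi <- hi + w; w <- 2 * w
    nDouble <- nDouble + 1L
    if (nDouble > 60L) stop("bisection bracket expansion failed")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  if (abs(f(r)) > 1e-10)
    stop("Euler-Lotka residual did not converge below 1e-10")
  r
}

#' Intrinsic rate of increase by bisection of the Euler-Lotka equation
#'
#' Solves \eqn{\sum_x e^{-r(x+1)} l_x m_x = 1} for r by bisection, with the
#' initial bracket \eqn{[-1, 2]} day^-1 expanded by doubling until the
#' residual changes sign. The residual at the returned root is below 1e-10.
#'
#' @inheritParams eulerLotkaResidual
#' @param tol bisection tolerance on r (default 1e-12).
#' @return numeric scalar r (day^-1).
#' @examples
#' co <- AphidCohort("a", list(c(N1 = 0L, N2 = 0L, N3 = 0L, N4 = 0L,
#'                               Adult = 0L)), 0L, list(3L))
#' solveIntrinsicRate(buildSchedules(co))  # log(3)
#' @export
solveIntrinsicRate <- function(sched, convention = "x+1", tol = 1e-12) {
  .solveIntrinsicRate(.lxmx(sched), convention, tol)
}

#' Finite rate of increase
#'
#' \eqn{\lambda = e^r}: the factor by which the population multiplies per day
#' at the stable age-stage distribution.
#'
#' @param r intrinsic rate of increase (day^-1).
#' @return numeric, day^-1.
#' @export
finiteRate <- function(r) {
  stopifnot(all(is.finite(r)))
  exp(r)
}

#' Mean generation time
#'
#' \eqn{T = \ln(R_0)/r}: the time a population at the stable age-stage
#' distribution needs to grow R0-fold.
#'
#' @param R0 net reproductive rate (> 0).
#' @param r intrinsic rate of increase (nonzero).
#' @return numeric, days.
#' @export
meanGenerationTime <- function(R0, r) {
  stopifnot(all(R0 > 0))
  if (any(r == 0)) stop("T undefined at replacement (r = 0)", call. = FALSE)
  log(R0) / r
}

#' Developmental and adult period statistics
#'
#' Nymph period = adult entry age (days from birth to first adult day),
#' adult period = death age - adult entry age + 1 (the entry day counts),
#' both averaged over individuals that reached adulthood; total longevity =
#' death age + 1, over all individuals.
#'
#' @param cohort an [AphidCohort-class].
#' @return data.frame with columns parameter, mean, n. Nymph/adult rows carry
#'   NA and n = 0 when no individual reached adulthood.
#' @export
stagePeriodStats <- function(cohort) {
  stopifnot(is(cohort, "AphidCohort"))
  m <- .cohortMatrices(cohort)
  ad <- which(!is.na(m$adultEntry))
  nymph <- if (length(ad)) mean(m$adultEntry[ad]) else NA_real_
  adult <- if (length(ad))
    mean(m$deathAge[ad] - m$adultEntry[ad] + 1) else NA_real_
  data.frame(
    parameter = c("nymphPeriod", "adultPeriod", "totalLongevity"),
    mean = c(nymph, adult, mean(m$deathAge + 1)),
    n = c(length(ad), length(ad), m$n))
}

## Parameter vector for one (re)sampled index set, using precomputed
## matrices. Returns named numeric; r/lambda/T are NA when the resample has
## zero total offspring (degenerate) or r == 0 exactly (T only).
.paramsForIndex <- function(m, idx, convention) {
  aliveC <- colSums(m$alive[idx, , drop = FALSE])
  offC <- colSums(m$off[idx, , drop = FALSE])
  n <- length(idx)
  R0 <- sum(offC) / n
  r <- lambda <- Tg <- NA_real_
  if (R0 > 0) {
    r <- .solveIntrinsicRate(offC / n, convention)
    lambda <- exp(r)
    Tg <- if (r != 0) log(R0) / r else NA_real_
  }
  ae <- m$adultEntry[idx]; da <- m$deathAge[idx]
  ad <- which(!is.na(ae))
  c(R0 = R0, r = r, lambda = lambda, T = Tg,
    nymphPeriod = if (length(ad)) mean(ae[ad]) else NA_real_,
    adultPeriod = if (length(ad)) mean(da[ad] - ae[ad] + 1) else NA_real_,
    totalLongevity = mean(da + 1))
}

#' Population parameters with bootstrap standard errors
#'
#' Resamples n individuals with replacement B times, recomputes every
#' population parameter per resample, and reports the standard deviation over
#' valid resamples as the standard error. Point estimates come from the
#' original cohort, not the bootstrap mean. Resamples with zero total
#' offspring leave r, lambda and T undefined; they are dropped from those
#' summaries and counted in the \code{nDegenerate} slot.
#'
#' @param cohort an [AphidCohort-class].
#' @param B number of bootstrap replicates (>= 2), default 2000.
#' @param seed integer seed for the resampling stream (optional).
#' @param convention Euler-Lotka exponent convention, see
#'   [solveIntrinsicRate()].
#' @return A [PopulationParameters-class].
#' @export
bootstrapPopulationParameters <- function(cohort, B = 2000, seed = NULL,
                                          convention = "x+1") {
  stopifnot(is(cohort, "AphidCohort"), B >= 2)
  validObject(cohort)
  m <- .cohortMatrices(cohort)
  point <- .paramsForIndex(m, seq_len(m$n), convention)
  boot <- .withSeed(seed, {
    vapply(seq_len(B),
           function(b) .paramsForIndex(
             m, sample.int(m$n, m$n, replace = TRUE), convention),
           numeric(length(PARAM_NAMES)))
  })
  nDegen <- sum(is.na(boot["r", ]))
  if (nDegen == B)
    stop("all bootstrap resamples were degenerate (zero total offspring)",
         call. = FALSE)
  se <- apply(boot, 1, sd, na.rm = TRUE)
  se[is.na(se)] <- NA_real_
  new("PopulationParameters",
      estimates = point, se = se[PARAM_NAMES],
      n = m$n,
      nAdults = sum(!is.na(m$adultEntry)),
      B = as.integer(B), nDegenerate = as.integer(nDegen),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      host = cohort@host)
}

#' Life-table comparison report
#'
#' Long-format mean +/- SE table for one or more host-plant cohorts, in the
#' customary row order (R0, r, lambda, T, then periods). r and lambda are
#' formatted to 2 decimals, periods and T to 1; full-precision numeric
#' columns are retained so the report round-trips losslessly through
#' [writeLifeTableReport()] / [readLifeTableReport()].
#'
#' @param ... one or more [PopulationParameters-class] objects (or a single
#'   list of them).
#' @return data.frame with columns host, parameter, estimate, se, formatted.
#' @export
lifeTableReport <- function(...) {
  params <- list(...)
  if (length(params) == 1L && is.list(params[[1]]) &&
      !is(params[[1]], "PopulationParameters"))
    params <- params[[1]]
  stopifnot(length(params) >= 1L,
            all(vapply(params, is, logical(1), "PopulationParameters")))
  digits <- c(R0 = 1, r = 2, lambda = 2, T = 1,
              nymphPeriod = 1, adultPeriod = 1, totalLongevity = 1)
  seDigits <- c(R0 = 2, r = 3, lambda = 3, T = 2,
                nymphPeriod = 2, adultPeriod = 2, totalLongevity = 2)
  rows <- lapply(seq_along(params), function(i) {
    p <- params[[i]]
    host <- if (nzchar(p@host)) p@host else paste0("cohort", i)
    data.frame(
      host = host, parameter = PARAM_NAMES,
      estimate = unname(p@estimates[PARAM_NAMES]),
      se = unname(p@se[PARAM_NAMES]),
      formatted = sprintf("%.*f ± %.*f",
                          digits[PARAM_NAMES], p@estimates[PARAM_NAMES],
                          seDigits[PARAM_NAMES], p@se[PARAM_NAMES]))
  })
  do.call(rbind, rows)
}

#' @rdname lifeTableReport
#' @param report a report data.frame from [lifeTableReport()].
#' @param path file path for the TSV report.
#' @export
writeLifeTableReport <- function(report, path) {
  rep2 <- report
  ## full precision so read-back reproduces the numbers exactly
  rep2$estimate <- sprintf("%.17g", rep2$estimate)
  rep2$se <- sprintf("%.17g", rep2$se)
  .writeTSV(rep2, path)
}

#' @rdname lifeTableReport
#' @export
readLifeTableReport <- function(path) {
  out <- .readTSV(path, colClasses = c("character", "character", "numeric",
                                       "numeric", "character"))
  out
}
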