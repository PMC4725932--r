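#' @include AllClasses.R
NULL

## Discretized gamma pmf on 1..maxDur days: interior mass from consecutive
## CDF differences, boundary days absorb the tails, so durations are always
## >= 1 and capped.
.discGammaPmf <- function(shape, scale, maxDur) {
  k <- seq_len(maxDur)
  p <- pgamma(k, shape = shape, scale = scale) -
    pgamma(k - 1, shape = shape, scale = scale)
  p[1] <- pgamma(1, shape = shape, scale = scale)
  p[maxDur] <- 1 - pgamma(maxDur - 1, shape = shape, scale = scale)
  p / sum(p)
}

## Triangular fecundity profile over adult age t (days since adult entry):
## ramps from 0 at t = -? no: f(0) > 0, peaks at `peak`, back to 0 at `width`.
.triangleCurve <- function(t, fMax, peak, width) {
  up <- if (peak > 0) fMax * pmin(1, t / peak) else rep(fMax, length(t))
  down <- fMax * (width - t) / (width - peak)
  f <- ifelse(t <= peak, up, down)
  pmax(0, ifelse(t >= width, 0, f))
}

#' Cohort simulation specification
#'
#' Parameters of the stage-structured individual-based cohort generator:
#' per-instar discretized-gamma durations, stage-dependent daily survival,
#' and a triangular (optionally double-peaked) adult fecundity curve. The
#' defaults emulate a cohort of 80 pea aphids followed daily on a favorable
#' host: four nymphal instars of about 1.9 days each (nymph period about
#' 7.4 d), high nymphal and moderate adult daily survival, and a fecundity
#' peak of 9 nymphs/day a few days into adulthood.
#'
#' @param n cohort size (default 80).
#' @param stageShape,stageScale gamma shape/scale per instar N1..N4 (days).
#' @param survivalNymph,survivalAdult daily survival probabilities in (0, 1].
#' @param fecundityMax peak offspring per day (>= 0).
#' @param fecundityPeak adult age (days since adult entry) of the peak.
#' @param fecundityWidth adult age at which fecundity returns to 0.
#' @param secondPeak optional list(fMax, peak, width) added to the curve
#'   (double-peaked reproduction).
#' @param maxStageDuration cap on any single instar duration (days).
#' @param maxAge hard longevity cap in days (default 200).
#' @return validated spec (list of class \code{cohortSimSpec}).
#' @export
cohortSimSpec <- function(n = 80,
                          stageShape = rep(8, 4),
                          stageScale = rep(1.85 / 8, 4),
                          survivalNymph = 0.98,
                          survivalAdult = 0.94,
                          fecundityMax = 9,
                          fecundityPeak = 4,
                          fecundityWidth = 20,
                          secondPeak = NULL,
                          maxStageDuration = 15,
                          maxAge = 200) {
  stopifnot(n >= 1, length(stageShape) == 4, length(stageScale) == 4,
            all(stageShape > 0), all(stageScale > 0),
            survivalNymph > 0, survivalNymph <= 1,
            survivalAdult > 0, survivalAdult <= 1,
            fecundityMax >= 0, fecundityPeak >= 0,
            fecundityWidth > fecundityPeak,
            maxStageDuration >= 1, maxAge >= 4)
  if (!is.null(secondPeak))
    stopifnot(all(c("fMax", "peak", "width") %in% names(secondPeak)),
              secondPeak$width > secondPeak$peak)
  structure(list(n = as.integer(n), stageShape = stageShape,
                 stageScale = stageScale, survivalNymph = survivalNymph,
                 survivalAdult = survivalAdult, fecundityMax = fecundityMax,
                 fecundityPeak = fecundityPeak,
                 fecundityWidth = fecundityWidth, secondPeak = secondPeak,
                 maxStageDuration = as.integer(maxStageDuration),
                 maxAge = as.integer(maxAge)),
            class = c("cohortSimSpec", "list"))
}

.fecundityCurve <- function(spec, t) {
  f <- .triangleCurve(t, spec$fecundityMax, spec$fecundityPeak,
                      spec$fecundityWidth)
  if (!is.null(spec$secondPeak))
    f <- f + .triangleCurve(t, spec$secondPeak$fMax, spec$secondPeak$peak,
                            spec$secondPeak$width)
  f
}

## Analytic expected schedules implied by a cohortSimSpec: pmf of the adult
## entry age by convolving the four instar pmfs, then survival products.
.expectedSchedules <- function(spec) {
  pmfs <- lapply(1:4, function(j)
    .discGammaPmf(spec$stageShape[j], spec$stageScale[j],
                  spec$maxStageDuration))
  ## convolution over day-valued durations; pA[a+1] = P(adult entry = a)
  pA <- c(1)  # point mass at 0 before adding instars
  for (p in pmfs) {
    newLen <- length(pA) + length(p)
    out <- numeric(newLen)
    for (k in seq_along(p))
      out[seq_along(pA) + k] <- out[seq_along(pA) + k] + pA * p[k]
    pA <- out
  }
  ## pA indexed so that pA[a + 1] = P(A = a), a = 0..length-1
  aVals <- seq_along(pA) - 1L
  cap <- spec$maxAge
  qN <- spec$survivalNymph; qA <- spec$survivalAdult
  x <- 0:cap
  lx <- numeric(cap + 1L)
  fx <- numeric(cap + 1L)  # E[f(x - A); alive at x]
  for (ai in which(pA > 0)) {
    a <- aVals[ai]; pa <- pA[ai]
    surv <- qN^pmin(x, a) * qA^pmax(0, x - a)
    lx <- lx + pa * surv
    t <- x - a
    fadult <- ifelse(t >= 0, .fecundityCurve(spec, pmax(t, 0)), 0)
    fx <- fx + pa * surv * fadult
  }
  mx <- ifelse(lx > 0, fx / lx, 0)
  list(lx = lx, mx = mx, adultEntryPmf = setNames(pA, aVals))
}

#' Simulate an aphid cohort with known demographic truth
#'
#' Draws individual life histories from a [cohortSimSpec()]: instar
#' durations from discretized gammas, geometric daily survival within the
#' nymph and adult phases (capped at \code{maxAge}), and daily offspring
#' Poisson around the triangular fecundity curve (adult days only). The
#' analytic expectation of the cohort's schedules, and the intrinsic rate
#' they imply, are returned alongside as ground truth.
#'
#' @param spec a [cohortSimSpec()].
#' @param seed integer seed (optional; the generator is deterministic under
#'   it).
#' @param host host label stamped on the cohort.
#' @return list with \code{cohort} ([AphidCohort-class]) and \code{truth}
#'   (list: lx, mx, R0, r — r is NA when the spec implies no reproduction).
#' @export
simulateCohort <- function(spec, seed = NULL, host = "synthetic") {
  stopifnot(inherits(spec, "cohortSimSpec"))
  truthSched <- .expectedSchedules(spec)
  R0true <- sum(truthSched$lx * truthSched$mx)
  rTrue <- if (R0true > 0)
    .solveIntrinsicRate(truthSched$lx * truthSched$mx) else NA_real_
  sim <- .withSeed(seed, {
    n <- spec$n
    durs <- vapply(1:4, function(j) {
      pmf <- .discGammaPmf(spec$stageShape[j], spec$stageScale[j],
                           spec$maxStageDuration)
      sample.int(spec$maxStageDuration, n, replace = TRUE, prob = pmf)
    }, integer(n))
    if (n == 1L) durs <- matrix(durs, nrow = 1)
    A <- rowSums(durs)
    ## transitions survived within each phase (Inf when survival prob is 1)
    survN <- if (spec$survivalNymph >= 1) rep(Inf, n)
             else stats::rgeom(n, 1 - spec$survivalNymph)
    survA <- if (spec$survivalAdult >= 1) rep(Inf, n)
             else stats::rgeom(n, 1 - spec$survivalAdult)
    deathAge <- ifelse(survN < A, survN, A + survA)
    deathAge <- pmin(deathAge, spec$maxAge)
    ids <- sprintf("ind%04d", seq_len(n))
    stageEntry <- vector("list", n)
    offspring <- vector("list", n)
    for (i in seq_len(n)) {
      entries <- c(0L, cumsum(durs[i, ]))
      names(entries) <- STAGES
      keep <- entries <= deathAge[i]
      stageEntry[[i]] <- entries[keep]
      off <- integer(deathAge[i] + 1L)
      if (deathAge[i] >= A[i]) {
        t <- 0:(deathAge[i] - A[i])
        off[A[i] + 1L + t] <- rpois(length(t), .fecundityCurve(spec, t))
      }
      offspring[[i]] <- off
    }
    AphidCohort(ids, stageEntry, as.integer(deathAge), offspring, host)
  })
  list(cohort = sim,
       truth = list(lx = truthSched$lx, mx = truthSched$mx,
                    R0 = R0true, r = rTrue))
}

#' Count simulation specification
#'
#' Parameters of the two-library pooled RNA-seq count generator. Defaults:
#' 5000 genes, log-normal baseline expression, two libraries of 10 million
#' reads (pooled salivary-gland scale), 4% of genes differentially expressed
#' at 4-fold, split evenly between directions.
#'
#' @param nGenes number of genes.
#' @param meanlog,sdlog log-normal baseline relative expression.
#' @param lengthMeanlog,lengthSdlog log-normal gene length (bp).
#' @param librarySizes named numeric, reads per library (two samples).
#' @param deFraction fraction of genes differentially expressed in [0, 1].
#' @param foldChange fold change of DE genes (> 0).
#' @param directionMix fraction of DE genes upregulated in the second sample.
#' @return validated spec (list of class \code{countSimSpec}).
#' @export
countSimSpec <- function(nGenes = 5000, meanlog = 0, sdlog = 1.5,
                         lengthMeanlog = log(1500), lengthSdlog = 0.45,
                         librarySizes = c(A = 1e7, B = 1e7),
                         deFraction = 0.04, foldChange = 4,
                         directionMix = 0.5) {
  stopifnot(nGenes >= 1, sdlog >= 0, length(librarySizes) == 2,
            all(librarySizes > 0), deFraction >= 0, deFraction <= 1,
            foldChange > 0, directionMix >= 0, directionMix <= 1)
  if (is.null(names(librarySizes))) names(librarySizes) <- c("A", "B")
  structure(list(nGenes = as.integer(nGenes), meanlog = meanlog,
                 sdlog = sdlog, lengthMeanlog = lengthMeanlog,
                 lengthSdlog = lengthSdlog, librarySizes = librarySizes,
                 deFraction = deFraction, foldChange = foldChange,
                 directionMix = directionMix),
            class = c("countSimSpec", "list"))
}

#' Simulate a two-library count matrix with known DE truth
#'
#' Per gene a baseline relative expression is drawn once; per sample, counts
#' are Poisson with mean proportional to the library size (the sampling
#' model the Audic-Claverie test assumes). DE genes have their relative
#' expression multiplied by the fold change in the second sample, after
#' which that sample's means are rescaled to its library size, so column
#' sums match the requested sizes in expectation.
#'
#' @param spec a [countSimSpec()].
#' @param seed integer seed (optional).
#' @return list with \code{se} (a \code{SummarizedExperiment} from
#'   [countExperiment()]) and \code{truth} (data.frame gene_id, length_bp,
#'   isDE, direction, trueFC).
#' @export
simulateCounts <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "countSimSpec"))
  .withSeed(seed, {
    g <- spec$nGenes
    base <- rlnorm(g, spec$meanlog, spec$sdlog)
    lens <- pmax(100, round(rlnorm(g, spec$lengthMeanlog, spec$lengthSdlog)))
    nDE <- round(spec$deFraction * g)
    deIdx <- if (nDE > 0) sample.int(g, nDE) else integer()
    up <- if (nDE > 0)
      deIdx[seq_len(round(spec$directionMix * nDE))] else integer()
    down <- setdiff(deIdx, up)
    fc <- rep(1, g)
    fc[up] <- spec$foldChange
    fc[down] <- 1 / spec$foldChange
    propA <- base / sum(base)
    propB <- base * fc / sum(base * fc)
    N <- spec$librarySizes
    counts <- cbind(rpois(g, propA * N[1]), rpois(g, propB * N[2]))
    dimnames(counts) <- list(sprintf("gene%05d", seq_len(g)), names(N))
    truth <- data.frame(
      gene_id = rownames(counts), length_bp = lens,
      isDE = seq_len(g) %in% deIdx,
      direction = ifelse(seq_len(g) %in% up, "up",
                         ifelse(seq_len(g) %in% down, "down", "none")),
      trueFC = fc, stringsAsFactors = FALSE)
    list(se = countExperiment(counts, lens), truth = truth)
  })
}

#' EPG simulation specification
#'
#' Parameters of the semi-Markov waveform generator: a transition matrix
#' over the six codes, log-normal dwell times per code, a fixed recording
#' length (5 h) and the number of recordings in the group. Defaults mimic a
#' colony feeding adequately on its host: pathway activity interspersed with
#' long phloem-ingestion (E2) bouts.
#'
#' @param transition 6x6 row-stochastic matrix with dimnames
#'   \code{c("np","C","E1","E2","F","G")}.
#' @param dwellMeanlog,dwellSdlog named per-code log-normal dwell parameters
#'   (seconds).
#' @param duration recording length in seconds (default 18000 = 5 h).
#' @param nRecordings recordings in the group (default 30).
#' @param initialState waveform at recording start (default "np").
#' @return validated spec (list of class \code{epgSimSpec}).
#' @export
epgSimSpec <- function(transition = NULL,
                       dwellMeanlog = c(np = log(600), C = log(500),
                                        E1 = log(120), E2 = log(2000),
                                        F = log(300), G = log(400)),
                       dwellSdlog = c(np = 0.6, C = 0.6, E1 = 0.6,
                                      E2 = 0.6, F = 0.6, G = 0.6),
                       duration = 18000, nRecordings = 30,
                       initialState = "np") {
  if (is.null(transition)) {
    transition <- matrix(0, 6, 6, dimnames = list(EPG_CODES, EPG_CODES))
    transition["np", "C"] <- 1
    transition["C", c("np", "E1", "F", "G")] <- c(0.3, 0.4, 0.2, 0.1)
    transition["E1", c("E2", "C")] <- c(0.7, 0.3)
    transition["E2", c("C", "E1")] <- c(0.6, 0.4)
    transition["F", c("C", "np")] <- c(0.8, 0.2)
    transition["G", c("C", "np")] <- c(0.7, 0.3)
  }
  stopifnot(is.matrix(transition),
            identical(dimnames(transition), list(EPG_CODES, EPG_CODES)),
            all(transition >= 0),
            max(abs(rowSums(transition) - 1)) < 1e-9,
            identical(sort(names(dwellMeanlog)), sort(EPG_CODES)),
            identical(sort(names(dwellSdlog)), sort(EPG_CODES)),
            all(is.finite(dwellMeanlog)), all(dwellSdlog >= 0),
            duration > 0, nRecordings >= 1,
            initialState %in% EPG_CODES)
  structure(list(transition = transition, dwellMeanlog = dwellMeanlog,
                 dwellSdlog = dwellSdlog, duration = duration,
                 nRecordings = as.integer(nRecordings),
                 initialState = initialState),
            class = c("epgSimSpec", "list"))
}

#' Simulate EPG waveform recordings
#'
#' Alternating-state renewal process: waveform states follow the transition
#' matrix, dwell times are log-normal, and the sequence is truncated at the
#' recording length, so intervals tile each recording without gaps and the
#' per-code time ratios sum to 1.
#'
#' @param spec an [epgSimSpec()].
#' @param seed integer seed (optional).
#' @param group group label for the recordings.
#' @param idPrefix prefix for recording ids (default the group label).
#' @return An [EPGExperiment-class].
#' @export
simulateEPG <- function(spec, seed = NULL, group = "group1",
                        idPrefix = group) {
  stopifnot(inherits(spec, "epgSimSpec"))
  .withSeed(seed, {
    rows <- vector("list", spec$nRecordings)
    for (rec in seq_len(spec$nRecordings)) {
      id <- sprintf("%s_r%03d", idPrefix, rec)
      t <- 0
      state <- spec$initialState
      starts <- ends <- numeric(0)
      codes <- character(0)
      iter <- 0L
      while (t < spec$duration) {
        iter <- iter + 1L
        if (iter > 1e6) stop("recording failed to reach its duration; ",
                             "check dwell-time parameters")
        dwell <- rlnorm(1, spec$dwellMeanlog[[state]],
                        spec$dwellSdlog[[state]])
        e <- min(t + dwell, spec$duration)
        starts <- c(starts, t); ends <- c(ends, e); codes <- c(codes, state)
        t <- e
        if (t >= spec$duration) break
        state <- sample(EPG_CODES, 1, prob = spec$transition[state, ])
      }
      rows[[rec]] <- data.frame(recording_id = id, group = group,
                                code = codes, start_s = starts,
                                end_s = ends, stringsAsFactors = FALSE)
    }
    EPGExperiment(do.call(rbind, rows), duration = spec$duration)
  })
}

#' Simulate GO-style annotations with spiked enrichment truth
#'
#' Assigns terms to genes at random, with designated terms over-represented
#' among true-DE genes at a stated odds ratio; the resulting annotation is
#' ground truth for the enrichment stage.
#'
#' @param geneIDs character vector of gene ids (the background universe).
#' @param deTruth logical vector along \code{geneIDs}: TRUE for true-DE
#'   genes (the spike target set).
#' @param nTerms number of terms.
#' @param genesPerTerm expected background genes per term.
#' @param spikedTerms number of terms spiked among DE genes.
#' @param spikeOdds odds ratio of term membership for DE genes in spiked
#'   terms (1 = no enrichment; must be > 0).
#' @param seed integer seed (optional).
#' @return list with \code{annotations} (data.frame gene_id, term_id),
#'   \code{terms} (all term ids) and \code{spiked} (spiked term ids).
#' @export
simulateAnnotation <- function(geneIDs, deTruth, nTerms = 50,
                               genesPerTerm = 100, spikedTerms = 3,
                               spikeOdds = 10, seed = NULL) {
  stopifnot(length(deTruth) == length(geneIDs), is.logical(deTruth),
            nTerms >= 1, spikedTerms >= 0, spikedTerms <= nTerms)
  if (spikeOdds <= 0) stop("spikeOdds must be > 0")
  p <- genesPerTerm / length(geneIDs)
  if (p <= 0 || p >= 1)
    stop("genesPerTerm must be in (0, nGenes)")
  if (spikeOdds != 1 && spikedTerms > 0 && !any(deTruth))
    stop("spike targets must exist in the DE truth")
  oddsDE <- spikeOdds * p / (1 - p)
  pDE <- oddsDE / (1 + oddsDE)
  .withSeed(seed, {
    terms <- sprintf("T%03d", seq_len(nTerms))
    spiked <- terms[seq_len(spikedTerms)]
    rows <- lapply(terms, function(tm) {
      pr <- ifelse(deTruth & tm %in% spiked, pDE, p)
      hit <- runif(length(geneIDs)) < pr
      if (!any(hit)) return(NULL)
      data.frame(gene_id = geneIDs[hit], term_id = tm,
                 stringsAsFactors = FALSE)
    })
    list(annotations = do.call(rbind, rows), terms = terms,
         spiked = spiked)
  })
}
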