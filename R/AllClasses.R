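#' @import methods
#' @importFrom stats aggregate anova aov p.adjust pchisq pgamma phyper
#'   pnbinom quantile rgeom rlnorm rpois runif sd setNames t.test var
#' @importFrom utils combn head read.table write.table
NULL

## Ordered developmental stages of a parthenogenetic aphid cohort.
STAGES <- c("N1", "N2", "N3", "N4", "Adult")

## The six EPG waveform codes analysed: non-probing, pathway/probing,
## phloem salivation, phloem ingestion, derailed stylet, xylem drinking.
EPG_CODES <- c("np", "C", "E1", "E2", "F", "G")

#' Cohort of individually followed aphids
#'
#' Daily life histories of a cohort reared one individual per leaf: for each
#' aphid, the age (in days, day of birth = age 0) at which it first entered
#' each developmental stage, the age of its last day alive, and the number of
#' nymphs it deposited on each day of life.
#'
#' @slot ids character, one unique label per individual.
#' @slot stageEntry list of named integer vectors; names are an initial run of
#'   \code{c("N1","N2","N3","N4","Adult")}, values the age of first day in
#'   that stage. An individual dying as a nymph simply lacks later entries.
#' @slot deathAge integer, age in days of the last day alive.
#' @slot offspring list of integer vectors of length \code{deathAge + 1};
#'   nymphs deposited at each age. Zero before adult entry.
#' @slot host character scalar, host-plant label.
#'
#' @seealso [AphidCohort()] for the constructor, [buildSchedules()],
#'   [bootstrapPopulationParameters()].
#' @export
setClass("AphidCohort",
  representation(
    ids        = "character",
    stageEntry = "list",
    deathAge   = "integer",
    offspring  = "list",
    host       = "character"
  )
)

setValidity("AphidCohort", function(object) {
  n <- length(object@ids)
  if (n < 1L) return("cohort must contain at least one individual")
  if (anyDuplicated(object@ids)) return("individual ids must be unique")
  if (length(object@stageEntry) != n || length(object@deathAge) != n ||
      length(object@offspring) != n)
    return("ids, stageEntry, deathAge and offspring must have equal length")
  if (length(object@host) != 1L) return("host must be a single label")
  for (i in seq_len(n)) {
    da <- object@deathAge[i]
    if (is.na(da) || da < 0L)
      return(sprintf("individual '%s': death age must be >= 0", object@ids[i]))
    se <- object@stageEntry[[i]]
    nm <- names(se)
    if (length(se) < 1L || !identical(nm, STAGES[seq_along(se)]))
      return(sprintf(
        "individual '%s': stage entries must be an initial run of %s",
        object@ids[i], paste(STAGES, collapse = ",")))
    if (se[["N1"]] != 0L)
      return(sprintf("individual '%s': N1 entry age must be 0", object@ids[i]))
    if (is.unsorted(se))
      return(sprintf("individual '%s': stage entry ages must be nondecreasing",
                     object@ids[i]))
    if (any(se > da))
      return(sprintf("individual '%s': stage entry after death", object@ids[i]))
    off <- object@offspring[[i]]
    if (length(off) != da + 1L)
      return(sprintf("individual '%s': offspring must have length death_age+1",
                     object@ids[i]))
    if (any(is.na(off)) || any(off < 0) || any(off != round(off)))
      return(sprintf("individual '%s': offspring must be nonnegative integers",
                     object@ids[i]))
    adultAt <- if ("Adult" %in% nm) se[["Adult"]] else da + 1L
    if (adultAt > 0L && any(off[seq_len(min(adultAt, da + 1L))] > 0))
      return(sprintf("individual '%s': offspring recorded before adulthood",
                     object@ids[i]))
  }
  TRUE
})

#' Construct an AphidCohort
#'
#' @param ids character vector of unique individual labels.
#' @param stageEntry list of named integer vectors (see class slots).
#' @param deathAge integer vector of last-day-alive ages.
#' @param offspring list of daily offspring count vectors.
#' @param host host-plant label.
#' @return An [AphidCohort-class] object.
#' @examples
#' AphidCohort("a1", list(c(N1 = 0L, N2 = 2L)), 3L, list(c(0L, 0L, 0L, 0L)))
#' @export
AphidCohort <- function(ids, stageEntry, deathAge, offspring, host = "") {
  new("AphidCohort",
      ids = as.character(ids),
      stageEntry = lapply(stageEntry, function(x) {
        y <- as.integer(x); names(y) <- names(x); y
      }),
      deathAge = as.integer(deathAge),
      offspring = lapply(offspring, as.integer),
      host = as.character(host))
}

setMethod("show", "AphidCohort", function(object) {
  nAd <- sum(vapply(object@stageEntry, function(s) "Adult" %in% names(s),
                    logical(1)))
  cat("AphidCohort:", length(object@ids), "individuals",
      if (nzchar(object@host)) paste0("on '", object@host, "'") else "",
      "\n  reached adulthood:", nAd,
      "\n  max death age:", max(object@deathAge), "days\n")
})

#' Demographic schedules of a cohort
#'
#' Age-indexed survival (\code{l_x}), per-capita fecundity among survivors
#' (\code{m_x}) and age-stage occupancy (\code{s_xj}: fraction of the initial
#' cohort alive and in stage j at age x), the quantities the Euler-Lotka
#' machinery consumes.
#'
#' @slot lx numeric, fraction of the initial cohort alive at each age 0..maxAge.
#' @slot mx numeric, mean offspring per surviving individual at each age.
#' @slot sxj numeric matrix (maxAge+1) x 5, stage occupancy fractions.
#' @slot maxAge integer, oldest observed age.
#' @export
setClass("DemographySchedules",
  representation(lx = "numeric", mx = "numeric", sxj = "matrix",
                 maxAge = "integer"))

setValidity("DemographySchedules", function(object) {
  A <- object@maxAge
  if (length(object@lx) != A + 1L || length(object@mx) != A + 1L)
    return("lx and mx must have length maxAge + 1")
  if (abs(object@lx[1] - 1) > 1e-12) return("l_0 must equal 1")
  if (any(diff(object@lx) > 1e-12)) return("l_x must be non-increasing")
  if (any(object@lx < -1e-12 | object@lx > 1 + 1e-12))
    return("l_x must lie in [0, 1]")
  if (any(object@mx < 0)) return("m_x must be nonnegative")
  if (any(object@mx[object@lx == 0] != 0))
    return("m_x must be 0 wherever no individual is alive")
  if (nrow(object@sxj) != A + 1L || ncol(object@sxj) != length(STAGES))
    return("sxj must be (maxAge+1) x 5")
  if (max(abs(rowSums(object@sxj) - object@lx)) > 1e-12)
    return("row sums of s_xj must equal l_x")
  TRUE
})

setMethod("show", "DemographySchedules", function(object) {
  cat("DemographySchedules: ages 0 -", object@maxAge, "days\n",
      " R0 =", round(sum(object@lx * object@mx), 3),
      " final l_x =", round(object@lx[object@maxAge + 1L], 4), "\n")
})

#' Population growth parameters with bootstrap uncertainty
#'
#' Point estimates from an observed cohort plus bootstrap standard errors:
#' net reproductive rate R0, intrinsic rate of increase r, finite rate
#' lambda = exp(r), mean generation time T = ln(R0)/r, and stage-period means.
#'
#' @slot estimates named numeric: R0, r, lambda, T, nymphPeriod, adultPeriod,
#'   totalLongevity.
#' @slot se named numeric, bootstrap standard errors for the same quantities.
#' @slot n integer, cohort size.
#' @slot nAdults integer, individuals that reached adulthood.
#' @slot B integer, bootstrap replicates.
#' @slot nDegenerate integer, resamples with zero total offspring that were
#'   dropped from the r/lambda/T summaries.
#' @slot seed integer (NA if none supplied).
#' @slot host character, host-plant label.
#' @export
setClass("PopulationParameters",
  representation(estimates = "numeric", se = "numeric", n = "integer",
                 nAdults = "integer", B = "integer", nDegenerate = "integer",
                 seed = "integer", host = "character"))

PARAM_NAMES <- c("R0", "r", "lambda", "T",
                 "nymphPeriod", "adultPeriod", "totalLongevity")

setValidity("PopulationParameters", function(object) {
  if (!identical(names(object@estimates), PARAM_NAMES) ||
      !identical(names(object@se), PARAM_NAMES))
    return("estimates and se must be named R0, r, lambda, T, nymphPeriod, adultPeriod, totalLongevity")
  est <- object@estimates
  if (is.finite(est[["r"]]) && is.finite(est[["lambda"]]) &&
      abs(est[["lambda"]] - exp(est[["r"]])) >
        1e-12 * max(1, abs(est[["lambda"]])))
    return("lambda must equal exp(r)")
  if (is.finite(est[["T"]]) && is.finite(est[["R0"]]) && est[["R0"]] > 1 &&
      is.finite(est[["r"]]) && est[["r"]] != 0 &&
      abs(est[["T"]] - log(est[["R0"]]) / est[["r"]]) >
        1e-10 * max(1, abs(est[["T"]])))
    return("T must equal ln(R0)/r")
  if (any(object@se < 0, na.rm = TRUE)) return("standard errors must be >= 0")
  TRUE
})

setMethod("show", "PopulationParameters", function(object) {
  cat("PopulationParameters",
      if (nzchar(object@host)) paste0("('", object@host, "')"), "\n")
  est <- object@estimates; se <- object@se
  for (p in PARAM_NAMES)
    cat(sprintf("  %-15s %8.4f +/- %.4f\n", p, est[[p]], se[[p]]))
  cat("  n =", object@n, "(", object@nAdults, "adults ), B =", object@B,
      ", degenerate resamples:", object@nDegenerate, "\n")
})

#' Set of EPG waveform recordings
#'
#' Timed, non-overlapping waveform intervals from fixed-length electrical
#' penetration graph recordings, grouped by treatment. The waveform vocabulary
#' is the six codes analysed for aphids: np (non-probing), C (pathway),
#' E1 (phloem salivation), E2 (phloem ingestion), F (derailed stylet),
#' G (xylem ingestion).
#'
#' @slot intervals data.frame with columns recording_id, group, code,
#'   start_s, end_s (seconds from recording start).
#' @slot recordings data.frame with columns recording_id, group: the roster
#'   of recordings, so a recording without any annotated interval still
#'   exists (and scores ratio 0 everywhere, unannotated 1).
#' @slot duration numeric, nominal recording length in seconds (default 5 h).
#' @slot codes character, allowed waveform vocabulary.
#' @export
setClass("EPGExperiment",
  representation(intervals = "data.frame", recordings = "data.frame",
                 duration = "numeric", codes = "character"))

setValidity("EPGExperiment", function(object) {
  iv <- object@intervals
  need <- c("recording_id", "group", "code", "start_s", "end_s")
  if (!all(need %in% names(iv)))
    return(paste("intervals must have columns", paste(need, collapse = ", ")))
  if (!all(c("recording_id", "group") %in% names(object@recordings)))
    return("recordings must have columns recording_id, group")
  if (anyDuplicated(object@recordings$recording_id))
    return("recording ids must be unique in the roster")
  if (nrow(iv) && !all(iv$recording_id %in% object@recordings$recording_id))
    return("intervals refer to recordings missing from the roster")
  if (length(object@duration) != 1L || object@duration <= 0)
    return("duration must be a positive scalar")
  bad <- setdiff(unique(iv$code), object@codes)
  if (length(bad))
    return(paste("unknown waveform code(s):", paste(bad, collapse = ", "),
                 "- extend 'codes' to allow them"))
  if (nrow(iv)) {
    if (any(iv$start_s < 0 | iv$end_s > object@duration + 1e-9))
      return("intervals must lie within [0, duration]")
    if (any(iv$start_s >= iv$end_s))
      return("intervals must satisfy start_s < end_s")
    for (id in unique(iv$recording_id)) {
      sub <- iv[iv$recording_id == id, , drop = FALSE]
      o <- order(sub$start_s)
      s <- sub$start_s[o]; e <- sub$end_s[o]
      ov <- which(s[-1] < e[-length(e)] - 1e-9)
      if (length(ov))
        return(sprintf(
          "recording '%s': overlapping intervals [%g,%g] and [%g,%g]",
          id, s[ov[1]], e[ov[1]], s[ov[1] + 1L], e[ov[1] + 1L]))
    }
  }
  TRUE
})

#' Construct an EPGExperiment
#'
#' @param intervals data.frame with columns recording_id, group, code
#'   (synonym: waveform), start_s, end_s.
#' @param duration nominal recording length in seconds; default 18000 (5 h).
#' @param recordings optional roster data.frame (recording_id, group); lets
#'   recordings without annotated intervals exist. Defaults to the
#'   recordings present in \code{intervals}.
#' @param allowExtraCodes if TRUE, waveform codes outside the six-code
#'   vocabulary are accepted instead of rejected.
#' @return An [EPGExperiment-class] object.
#' @export
EPGExperiment <- function(intervals, duration = 18000, recordings = NULL,
                          allowExtraCodes = FALSE) {
  if ("waveform" %in% names(intervals) && !"code" %in% names(intervals))
    names(intervals)[names(intervals) == "waveform"] <- "code"
  intervals$recording_id <- as.character(intervals$recording_id)
  intervals$group <- as.character(intervals$group)
  intervals$code <- as.character(intervals$code)
  if (is.null(recordings))
    recordings <- unique(intervals[, c("recording_id", "group")])
  recordings$recording_id <- as.character(recordings$recording_id)
  recordings$group <- as.character(recordings$group)
  rownames(recordings) <- NULL
  codes <- EPG_CODES
  if (allowExtraCodes)
    codes <- union(codes, unique(intervals$code))
  new("EPGExperiment", intervals = as.data.frame(intervals),
      recordings = as.data.frame(recordings),
      duration = as.numeric(duration), codes = codes)
}

setMethod("show", "EPGExperiment", function(object) {
  cat("EPGExperiment:", nrow(object@recordings), "recordings in",
      length(unique(object@recordings$group)), "group(s),",
      nrow(object@intervals), "intervals, duration", object@duration, "s\n")
})
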