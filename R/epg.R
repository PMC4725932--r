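#' @include AllClasses.R
NULL

#' Per-recording waveform time ratios
#'
#' For each recording, the total time spent in each waveform divided by the
#' nominal recording length (the 5 h denominator), plus the unannotated
#' fraction. Absent codes score 0; unannotated time is reported separately,
#' never redistributed across codes.
#'
#' @param x an [EPGExperiment-class].
#' @return data.frame with columns recording_id, group, one column per
#'   waveform code, and unannotated. Ratios within a recording sum to 1
#'   together with the unannotated fraction.
#' @export
timeRatios <- function(x) {
  stopifnot(is(x, "EPGExperiment"))
  validObject(x)
  iv <- x@intervals
  recs <- x@recordings
  codes <- x@codes
  out <- data.frame(recording_id = recs$recording_id, group = recs$group,
                    stringsAsFactors = FALSE)
  for (cd in codes) out[[cd]] <- 0
  if (nrow(iv)) {
    dur <- (iv$end_s - iv$start_s) / x@duration
    agg <- tapply(dur, list(iv$recording_id, iv$code), sum)
    rowIdx <- match(out$recording_id, rownames(agg))
    for (cd in intersect(colnames(agg), codes)) {
      v <- agg[rowIdx, cd]
      out[[cd]] <- ifelse(is.na(v), 0, v)
    }
  }
  out$unannotated <- 1 - rowSums(out[, codes, drop = FALSE])
  rownames(out) <- NULL
  out
}

## ratios long: one row per recording x code
.ratiosLong <- function(x) {
  wide <- timeRatios(x)
  codes <- setdiff(names(wide), c("recording_id", "group", "unannotated"))
  do.call(rbind, lapply(codes, function(cd)
    data.frame(recording_id = wide$recording_id, group = wide$group,
               code = cd, ratio = wide[[cd]], stringsAsFactors = FALSE)))
}

#' Group means and SEMs of waveform time ratios
#'
#' Mean time ratio and its standard error of the mean (sd/sqrt(n)) for every
#' (group, waveform) cell. Groups with a single recording get an NA SEM and
#' are flagged.
#'
#' @param x an [EPGExperiment-class].
#' @return data.frame with columns group, code, mean, sem, n, semDefined.
#' @export
groupSummary <- function(x) {
  long <- .ratiosLong(x)
  agg <- aggregate(ratio ~ group + code, long, function(v)
    c(mean = mean(v), sem = if (length(v) > 1) sd(v) / sqrt(length(v))
                            else NA_real_, n = length(v)))
  out <- data.frame(group = agg$group, code = agg$code,
                    mean = agg$ratio[, "mean"], sem = agg$ratio[, "sem"],
                    n = as.integer(agg$ratio[, "n"]))
  out$semDefined <- !is.na(out$sem)
  if (any(!out$semDefined))
    warning("SEM undefined for group(s) with a single recording: ",
            paste(unique(out$group[!out$semDefined]), collapse = ", "))
  out[order(match(out$code, EPG_CODES), out$group), ]
}

## Compact letter display from a Tukey all-pairs comparison of a one-way fit.
.tukeyLetters <- function(ratio, group, alpha) {
  fit <- aov(ratio ~ group, data = data.frame(ratio = ratio,
                                              group = factor(group)))
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  multcomp::cld(glht, level = alpha)$mcletters$Letters
}

#' Compare waveform time ratios between groups
#'
#' Per waveform: two-sample t test (Welch by default) in \code{pairwise}
#' mode, or one-way ANOVA with a Tukey-HSD compact letter display in
#' \code{multigroup} mode. Cells where every value is identical across all
#' groups are reported as degenerate rather than tested.
#'
#' @param x an [EPGExperiment-class] with >= 2 groups.
#' @param mode \code{"auto"} (pairwise when exactly two groups),
#'   \code{"pairwise"} or \code{"multigroup"}.
#' @param welch use the unequal-variance (Welch) t test (default TRUE);
#'   FALSE gives Student's pooled-variance variant.
#' @param posthocAlpha significance level of the letter display (default 0.05).
#' @return data.frame: one row per waveform with statistic, df, p, stars and
#'   a note; in multigroup mode a \code{letters} column carries the compact
#'   letter display as "group=letter" pairs.
#' @export
compareGroups <- function(x, mode = c("auto", "pairwise", "multigroup"),
                          welch = TRUE, posthocAlpha = 0.05) {
  mode <- match.arg(mode)
  long <- .ratiosLong(x)
  groups <- unique(long$group)
  if (length(groups) < 2L) stop("need at least 2 groups to compare")
  if (mode == "auto") mode <- if (length(groups) == 2L) "pairwise"
                              else "multigroup"
  if (mode == "pairwise" && length(groups) != 2L)
    stop("pairwise mode requires exactly 2 groups")
  codes <- unique(long$code)
  rows <- lapply(codes, function(cd) {
    sub <- long[long$code == cd, ]
    vals <- split(sub$ratio, sub$group)
    if (var(sub$ratio) == 0)
      return(data.frame(code = cd, statistic = NA_real_, df = NA_real_,
                        df2 = NA_real_, p = NA_real_, stars = "",
                        letters = paste(paste0(groups, "=a"), collapse = ","),
                        note = "zero variance in all groups; test undefined"))
    if (mode == "pairwise") {
      tt <- t.test(vals[[1]], vals[[2]], var.equal = !welch)
      data.frame(code = cd, statistic = unname(tt$statistic),
                 df = unname(tt$parameter), df2 = NA_real_,
                 p = tt$p.value, stars = .stars(tt$p.value),
                 letters = NA_character_, note = "")
    } else {
      fit <- aov(ratio ~ group, data = transform(sub, group = factor(group)))
      an <- anova(fit)
      lets <- tryCatch(.tukeyLetters(sub$ratio, sub$group, posthocAlpha),
                       error = function(e) setNames(rep(NA_character_,
                                                        length(groups)),
                                                    groups))
      data.frame(code = cd, statistic = an[["F value"]][1],
                 df = an$Df[1], df2 = an$Df[2],
                 p = an[["Pr(>F)"]][1], stars = .stars(an[["Pr(>F)"]][1]),
                 letters = paste(paste0(names(lets), "=", lets),
                                 collapse = ","),
                 note = "")
    }
  })
  out <- do.call(rbind, rows)
  out[order(match(out$code, EPG_CODES)), ]
}

#' Feeding-step attainment matrix
#'
#' Fraction of recordings in each group that contain at least one interval of
#' each waveform: the "ratio of individuals entering a given feeding step".
#' Columns follow the feeding sequence np, C, E1, E2, then F and G.
#'
#' @param x an [EPGExperiment-class].
#' @return numeric matrix, groups x waveform codes, entries in [0, 1].
#' @export
attainmentMatrix <- function(x) {
  stopifnot(is(x, "EPGExperiment"))
  iv <- x@intervals
  recs <- x@recordings
  groups <- unique(recs$group)
  out <- matrix(0, length(groups), length(EPG_CODES),
                dimnames = list(groups, EPG_CODES))
  for (g in groups) {
    ids <- recs$recording_id[recs$group == g]
    sub <- iv[iv$recording_id %in% ids, ]
    for (cd in EPG_CODES)
      out[g, cd] <- length(unique(sub$recording_id[sub$code == cd])) /
        length(ids)
  }
  out
}

#' Combine EPG experiments
#'
#' Row-binds the intervals of several experiments sharing one nominal
#' duration (e.g. simulated groups) into a single [EPGExperiment-class].
#'
#' @param ... [EPGExperiment-class] objects.
#' @return An [EPGExperiment-class].
#' @export
combineEPG <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L,
            all(vapply(xs, is, logical(1), "EPGExperiment")))
  dur <- unique(vapply(xs, function(x) x@duration, numeric(1)))
  if (length(dur) != 1L) stop("experiments differ in nominal duration")
  ids <- unlist(lapply(xs, function(x) x@recordings$recording_id))
  if (anyDuplicated(ids))
    stop("recording ids collide across experiments")
  new("EPGExperiment",
      intervals = do.call(rbind, lapply(xs, function(x) x@intervals)),
      recordings = do.call(rbind, lapply(xs, function(x) x@recordings)),
      duration = dur,
      codes = Reduce(union, lapply(xs, function(x) x@codes)))
}
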