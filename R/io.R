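#' @include AllClasses.R
NULL

## Detect comma vs tab dialect from the header line.
.detectSep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read and validate a delimited table
#'
#' Reads a comma- or tab-delimited text file (dialect auto-detected from the
#' header), checks that all required columns are present, coerces them to
#' the declared types, and reports offending line numbers on type mismatch
#' or duplicate keys.
#'
#' @param path file path.
#' @param schema named character vector: column name -> one of
#'   \code{"character"}, \code{"integer"}, \code{"numeric"}.
#' @param key optional column name (or names) whose combination must be
#'   unique across rows.
#' @return data.frame with typed columns (extra columns are kept as read).
#' @export
readTableValidated <- function(path, schema, key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detectSep(path)
  df <- read.table(path, sep = sep, header = TRUE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   check.names = FALSE, quote = "\"", comment.char = "")
  missingCols <- setdiff(names(schema), names(df))
  if (length(missingCols))
    stop("missing column(s) in ", path, ": ",
         paste(missingCols, collapse = ", "))
  for (col in names(schema)) {
    raw <- df[[col]]
    conv <- switch(schema[[col]],
                   character = raw,
                   integer = suppressWarnings(as.integer(raw)),
                   numeric = suppressWarnings(as.numeric(raw)),
                   stop("unknown schema type: ", schema[[col]]))
    if (schema[[col]] != "character") {
      bad <- which(is.na(conv) & !is.na(raw) & nzchar(raw))
      if (length(bad))
        stop(sprintf("%s: column '%s' has a non-%s value at line %d",
                     path, col, schema[[col]], bad[1] + 1L))
    }
    df[[col]] <- conv
  }
  if (!is.null(key)) {
    kv <- do.call(paste, c(df[key], sep = "\r"))
    dup <- which(duplicated(kv))
    if (length(dup))
      stop(sprintf("%s: duplicate key (%s) at line %d", path,
                   paste(key, collapse = ","), dup[1] + 1L))
  }
  df
}

#' Read a cohort life-history table
#'
#' Long format, one row per individual per day: columns individual_id,
#' age_day, stage, offspring, alive (0/1). Per individual, days must run
#' contiguously from age 0 through the last day alive; the stage column
#' yields the first-entry ages.
#'
#' @param path delimited text file (comma or tab).
#' @param host host label for the cohort.
#' @return An [AphidCohort-class].
#' @export
readCohortTable <- function(path, host = "") {
  df <- readTableValidated(path, c(individual_id = "character",
                                   age_day = "integer",
                                   stage = "character",
                                   offspring = "integer",
                                   alive = "integer"),
                           key = c("individual_id", "age_day"))
  ids <- unique(df$individual_id)
  stageEntry <- vector("list", length(ids))
  deathAge <- integer(length(ids))
  offspring <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$individual_id == ids[i], ]
    sub <- sub[order(sub$age_day), ]
    aliveDays <- sub[sub$alive == 1L, ]
    if (!nrow(aliveDays))
      stop("individual '", ids[i], "': no alive day recorded")
    da <- max(aliveDays$age_day)
    if (!identical(aliveDays$age_day, 0:da))
      stop("individual '", ids[i],
           "': alive days must run contiguously from age 0")
    st <- aliveDays$stage
    bad <- setdiff(unique(st), STAGES)
    if (length(bad))
      stop("individual '", ids[i], "': unknown stage(s) ",
           paste(bad, collapse = ", "))
    ent <- vapply(STAGES, function(s)
      if (s %in% st) min(aliveDays$age_day[st == s]) else NA_integer_,
      integer(1))
    ent <- ent[!is.na(ent)]
    stageEntry[[i]] <- ent
    deathAge[i] <- da
    offspring[[i]] <- aliveDays$offspring
  }
  AphidCohort(ids, stageEntry, deathAge, offspring, host)
}

#' @rdname readCohortTable
#' @param cohort an [AphidCohort-class].
#' @export
writeCohortTable <- function(cohort, path) {
  rows <- lapply(seq_along(cohort@ids), function(i) {
    da <- cohort@deathAge[i]
    se <- cohort@stageEntry[[i]]
    stage <- character(da + 1L)
    for (x in 0:da) stage[x + 1L] <- names(se)[max(which(se <= x))]
    data.frame(individual_id = cohort@ids[i], age_day = 0:da,
               stage = stage, offspring = cohort@offspring[[i]],
               alive = 1L, stringsAsFactors = FALSE)
  })
  .writeTSV(do.call(rbind, rows), path)
}

#' Read an EPG waveform interval table
#'
#' Columns recording_id, group, waveform, start_s, end_s (seconds).
#'
#' @param path delimited text file (comma or tab).
#' @param duration nominal recording length in seconds (default 18000).
#' @param allowExtraCodes accept codes outside the six-code vocabulary.
#' @return An [EPGExperiment-class].
#' @export
readEPGTable <- function(path, duration = 18000, allowExtraCodes = FALSE) {
  df <- readTableValidated(path, c(recording_id = "character",
                                   group = "character",
                                   waveform = "character",
                                   start_s = "numeric",
                                   end_s = "numeric"))
  EPGExperiment(df, duration = duration, allowExtraCodes = allowExtraCodes)
}

#' @rdname readEPGTable
#' @param x an [EPGExperiment-class].
#' @export
writeEPGTable <- function(x, path) {
  iv <- x@intervals
  names(iv)[names(iv) == "code"] <- "waveform"
  .writeTSV(iv[order(iv$recording_id, iv$start_s), ], path)
}

#' Read a gene count table
#'
#' Columns gene_id, length_bp, then one integer column per sample. An
#' optional annotation sidecar (gene_id, secretory 0/1, go_terms
#' pipe-separated) attaches the secretory flag and GO annotations.
#'
#' @param path delimited text file (comma or tab).
#' @param annotationPath optional sidecar path.
#' @return A \code{SummarizedExperiment} from [countExperiment()]; GO
#'   annotations, when present, are in \code{metadata(se)$annotations}
#'   (data.frame gene_id, term_id).
#' @export
readCountTable <- function(path, annotationPath = NULL) {
  df <- readTableValidated(path, c(gene_id = "character",
                                   length_bp = "numeric"),
                           key = "gene_id")
  sampleCols <- setdiff(names(df), c("gene_id", "length_bp"))
  if (!length(sampleCols)) stop("no sample columns found in ", path)
  counts <- as.matrix(vapply(df[sampleCols], as.numeric,
                             numeric(nrow(df))))
  if (nrow(df) == 1L) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, sampleCols))
  rownames(counts) <- df$gene_id
  secretory <- NULL
  annDf <- NULL
  if (!is.null(annotationPath)) {
    ann <- readTableValidated(annotationPath,
                              c(gene_id = "character",
                                secretory = "integer",
                                go_terms = "character"),
                              key = "gene_id")
    idx <- match(df$gene_id, ann$gene_id)
    secretory <- ann$secretory[idx] == 1L
    lst <- strsplit(ann$go_terms[idx], "|", fixed = TRUE)
    keep <- which(!is.na(idx) & lengths(lst) > 0)
    annDf <- data.frame(
      gene_id = rep(df$gene_id[keep], lengths(lst[keep])),
      term_id = unlist(lst[keep]), stringsAsFactors = FALSE)
    annDf <- annDf[nzchar(annDf$term_id), ]
  }
  se <- countExperiment(counts, df$length_bp, secretory)
  if (!is.null(annDf)) S4Vectors::metadata(se)$annotations <- annDf
  se
}

#' @rdname readCountTable
#' @param se a \code{SummarizedExperiment} from [countExperiment()].
#' @export
writeCountTable <- function(se, path) {
  counts <- .countsOf(se)
  df <- data.frame(gene_id = rownames(counts),
                   length_bp = .lengthsOf(se),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

## ---- pipeline ------------------------------------------------------------

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run a multi-stage analysis pipeline
#'
#' Executes the selected stages on seeded synthetic inputs and/or supplied
#' files, writing every output as delimited text or JSON plus a manifest
#' with input/output checksums, parameters and the seed; identical
#' config + seed reproduces every output byte for byte.
#'
#' Config is a list (or YAML file path) with elements:
#' \describe{
#'   \item{stages}{character subset of "simulate", "lifetable", "epg", "de",
#'     "enrich".}
#'   \item{lifetable}{list(input = cohort file; bootstrap B).}
#'   \item{epg}{list(input = interval file; mode).}
#'   \item{de}{list(counts = count file, annotations = sidecar, contrasts =
#'     list of c(A, B), ratio, alpha).}
#'   \item{enrich}{list(minCount, level).}
#'   \item{simulate}{list(cohort/counts/epg = TRUE or spec-building
#'     arguments) — simulated inputs feed the later stages and truth
#'     sidecars are written next to them.}
#' }
#'
#' @param config list or path to a YAML file.
#' @param outDir output directory (created if needed).
#' @param seed integer seed recorded in the manifest and used for every
#'   stochastic stage.
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% character()
  known <- c("simulate", "lifetable", "epg", "de", "enrich")
  if (!length(stages)) {
    warning("empty stage list; nothing to do")
    return(invisible(list(stages = character())))
  }
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  inputs <- character()   # paths read
  outputs <- character()  # paths written
  sim <- list()

  if ("simulate" %in% stages) .stageTry("simulate", {
    sc <- config$simulate %||% list()
    if (!is.null(sc$cohort)) {
      spec <- do.call(cohortSimSpec,
                      if (is.list(sc$cohort)) sc$cohort else list())
      sim$cohort <- simulateCohort(spec, seed = seed)
      p <- file.path(outDir, "simulated_cohort.tsv")
      writeCohortTable(sim$cohort$cohort, p)
      tp <- file.path(outDir, "truth.cohort.json")
      jsonlite::write_json(sim$cohort$truth, tp, auto_unbox = TRUE,
                           digits = NA)
      outputs <- c(outputs, p, tp)
    }
    if (!is.null(sc$counts)) {
      spec <- do.call(countSimSpec,
                      if (is.list(sc$counts)) sc$counts else list())
      sim$counts <- simulateCounts(spec, seed = seed)
      p <- file.path(outDir, "simulated_counts.tsv")
      writeCountTable(sim$counts$se, p)
      tp <- file.path(outDir, "truth.counts.tsv")
      .writeTSV(sim$counts$truth, tp)
      outputs <- c(outputs, p, tp)
    }
    if (!is.null(sc$epg)) {
      spec <- do.call(epgSimSpec,
                      if (is.list(sc$epg)) sc$epg else list())
      sim$epg <- combineEPG(
        simulateEPG(spec, seed = seed, group = "groupA"),
        simulateEPG(spec, seed = if (is.null(seed)) NULL else seed + 1L,
                    group = "groupB"))
      p <- file.path(outDir, "simulated_epg.tsv")
      writeEPGTable(sim$epg, p)
      outputs <- c(outputs, p)
    }
    sim
  })

  if ("lifetable" %in% stages) .stageTry("lifetable", {
    lc <- config$lifetable %||% list()
    cohort <- if (!is.null(lc$input)) {
      inputs <- c(inputs, lc$input)
      readCohortTable(lc$input, host = lc$host %||% "")
    } else if (!is.null(sim$cohort)) sim$cohort$cohort
    else stop("no cohort input available")
    pp <- bootstrapPopulationParameters(cohort, B = lc$bootstrap %||% 2000,
                                        seed = seed)
    rp <- file.path(outDir, "lifetable_report.tsv")
    writeLifeTableReport(lifeTableReport(pp), rp)
    jp <- file.path(outDir, "lifetable_parameters.json")
    jsonlite::write_json(list(estimates = as.list(estimates(pp)),
                              se = as.list(standardErrors(pp)),
                              n = pp@n, B = pp@B,
                              nDegenerate = pp@nDegenerate,
                              seed = seed),
                         jp, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, rp, jp)
  })

  if ("epg" %in% stages) .stageTry("epg", {
    ec <- config$epg %||% list()
    epg <- if (!is.null(ec$input)) {
      inputs <- c(inputs, ec$input)
      readEPGTable(ec$input, duration = ec$duration %||% 18000)
    } else if (!is.null(sim$epg)) sim$epg
    else stop("no EPG input available")
    sp <- file.path(outDir, "epg_summary.tsv")
    .writeTSV(groupSummary(epg), sp)
    cp <- file.path(outDir, "epg_comparison.tsv")
    .writeTSV(compareGroups(epg, mode = ec$mode %||% "auto"), cp)
    ap <- file.path(outDir, "epg_attainment.tsv")
    am <- attainmentMatrix(epg)
    .writeTSV(data.frame(group = rownames(am), am, check.names = FALSE),
              ap)
    outputs <- c(outputs, sp, cp, ap)
  })

  deResults <- list()
  if ("de" %in% stages) .stageTry("de", {
    dc <- config$de %||% list()
    se <- if (!is.null(dc$counts)) {
      inputs <- c(inputs, dc$counts,
                  if (!is.null(dc$annotations)) dc$annotations)
      readCountTable(dc$counts, dc$annotations)
    } else if (!is.null(sim$counts)) sim$counts$se
    else stop("no count input available")
    contrasts <- dc$contrasts %||%
      list(colnames(.countsOf(se))[1:2])
    for (ct in contrasts) {
      res <- deContrast(se, ct[1], ct[2],
                        ratioThreshold = dc$ratio %||% 2,
                        alpha = dc$alpha %||% 0.001)
      nm <- paste0(ct[1], "_vs_", ct[2])
      deResults[[nm]] <- res
      p <- file.path(outDir, paste0("de_", nm, ".tsv"))
      .writeTSV(res, p)
      outputs <- c(outputs, p)
    }
    if (length(deResults) >= 2) {
      vp <- file.path(outDir, "de_venn.json")
      venn <- vennPartition(deResults)
      jsonlite::write_json(
        list(partition = as.list(venn$partition),
             unionSize = venn$unionSize,
             commonUp = venn$commonUp, commonDown = venn$commonDown,
             commonVaried = venn$commonVaried),
        vp, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, vp)
    }
    if (!is.null(sim$counts)) {
      ## truth sidecar present: evaluate calls against it
      truth <- sim$counts$truth
      res <- deResults[[1]]
      called <- !is.na(res$call) & res$call != "ns"
      tp <- file.path(outDir, "de_truth_evaluation.json")
      jsonlite::write_json(
        list(nCalled = sum(called),
             recall = if (any(truth$isDE))
               sum(called & truth$isDE) / sum(truth$isDE) else NA,
             falseCalls = sum(called & !truth$isDE)),
        tp, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, tp)
    }
    deResults
  })

  if ("enrich" %in% stages) .stageTry("enrich", {
    en <- config$enrich %||% list()
    if (!length(deResults)) stop("enrich stage needs a preceding de stage")
    res <- deResults[[1]]
    ann <- en$annotations %||% NULL
    if (is.character(ann)) {
      inputs <- c(inputs, ann)
      ann <- readTableValidated(ann, c(gene_id = "character",
                                       term_id = "character"))
    }
    if (is.null(ann)) stop("no annotation input available")
    lst <- res$gene_id[!is.na(res$call) & res$call != "ns"]
    if (!length(lst)) {
      message("no DE genes called; skipping enrichment test")
    } else {
      tab <- enrichTerms(lst, res$gene_id, ann,
                         minCount = en$minCount %||% 3)
      p <- file.path(outDir, "enrichment.tsv")
      .writeTSV(tab, p)
      outputs <- c(outputs, p)
    }
  })

  manifest <- list(
    stages = stages,
    seed = seed,
    parameters = config[setdiff(names(config), "stages")],
    inputs = lapply(unique(inputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(unique(outputs), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
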