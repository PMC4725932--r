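## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL runs code as-is.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

.assertCount <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop(what, " must be nonnegative integers", call. = FALSE)
}

.assertProb <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
}

## Significance stars at the conventional 0.05/0.01/0.001 cut-offs.
.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

## Fixed-dialect TSV writers/readers so pipeline outputs are byte-stable.
.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

.readTSV <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE, ...)
}
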