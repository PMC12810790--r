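## Internal helpers: deterministic seed splitting and stamped TSV output.

## Deterministic seed derivation. All simulator randomness flows from one
## master seed; sub-streams (per proteome, per sample, per fraction) get
## seeds via a fixed affine map modulo the Mersenne prime 2^31 - 1, so every
## derived seed is a valid 32-bit R integer and runs are reproducible
## sample-by-sample.
.splitSeed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  as.integer((abs(as.double(seed)) * 48271 + as.double(k) * 104729) %% m)
}

.isCount <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

.isProb <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

## Header comment stamped on every TSV the pipeline writes: version, seed,
## and a digest of the generating configuration.
.outputHeader <- function(seed = NA, config = NULL) {
  hash <- "none"
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE, digits = NA), tf)
    hash <- unname(tools::md5sum(tf))
  }
  sprintf("# monomix %s seed=%s config_md5=%s",
          as.character(utils::packageVersion("monomix")), as.character(seed), hash)
}

.writeTsv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(.outputHeader(seed = seed, config = config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
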