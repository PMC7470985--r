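# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed fan-out from one top-level seed; stays
# within 32-bit integer range.
fanOutSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(profiles = 11L, growth = 23L, scenarios = 37L,
               recovery = 53L, pipeline = 71L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 97L
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

# Shortest-round-trip decimal formatting: numbers re-read from text are
# bit-identical to the originals.
formatNumber <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
  out
}

# Deterministic TSV writer (fixed column order, no quoting surprises).
writeTsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) df2[[j]] <- formatNumber(df2[[j]])
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

# md5 of a character scalar (used for run manifests); base tools only.
md5String <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(x, f)
  unname(tools::md5sum(f))
}

sampleSd <- function(x) stats::sd(x)

extdata <- function(file) {
  path <- system.file("extdata", file, package = "secflux", mustWork = FALSE)
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}
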