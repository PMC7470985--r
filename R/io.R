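#' Read and write replicate concentration tables
#'
#' `loadProfiles()` reads a CSV/TSV table with one row per replicate sample:
#' a `sample` id column, the treatment columns `acetate_mM` and
#' `formate_mM`, and one column per registered metabolite. Concentration
#' columns may carry a unit suffix (`_mM` or `_uM`); micromolar values are
#' converted to the internal canonical unit, mM, at the boundary (the
#' organic acids are reported in mM and the amino acids in uM, so both occur
#' in practice). Unknown metabolite columns and unknown unit suffixes are
#' rejected; negative concentrations are rejected naming the offending
#' sample; a table without a 0 mM / 0 mM control treatment is rejected.
#'
#' `writeProfiles()` writes the experiment back as a TSV in mM with
#' shortest-round-trip number formatting, so `loadProfiles(writeProfiles(x))`
#' reproduces every value bit-exactly.
#'
#' @param path file path. `loadProfiles` sniffs the separator (TSV or CSV).
#' @param registry metabolite registry, see [defaultRegistry()].
#' @param x a [SecretionExperiment].
#' @return `loadProfiles`: a [SecretionExperiment]; `writeProfiles`: `path`,
#'   invisibly.
#' @export
loadProfiles <- function(path, registry = defaultRegistry()) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  for (col in c("sample", "acetate_mM", "formate_mM"))
    if (!col %in% names(tab)) stop("input table lacks column '", col, "'")
  metcols <- setdiff(names(tab), c("sample", "acetate_mM", "formate_mM"))
  parsed <- lapply(metcols, parseMetaboliteColumn, registry = registry)
  names(parsed) <- metcols
  conc <- matrix(NA_real_, nrow = length(metcols), ncol = nrow(tab),
                 dimnames = list(vapply(parsed, `[[`, character(1), "metabolite"),
                                 tab$sample))
  for (j in seq_along(metcols)) {
    v <- as.numeric(tab[[metcols[j]]]) * parsed[[j]]$scale
    neg <- which(v < 0)
    if (length(neg))
      stop(sprintf("negative concentration for %s in sample %s",
                   parsed[[j]]$metabolite, tab$sample[neg[1]]))
    conc[j, ] <- v
  }
  if (!any(tab$acetate_mM == 0 & tab$formate_mM == 0))
    stop("input table has no control treatment (0 mM acetate, 0 mM formate)")
  SecretionExperiment(conc, acetate_mM = tab$acetate_mM,
                      formate_mM = tab$formate_mM, registry = registry)
}

parseMetaboliteColumn <- function(col, registry) {
  name <- col
  scale <- 1
  if (grepl("_[^_]+$", col)) {
    suffix <- sub(".*_", "", col)
    stem <- sub("_[^_]+$", "", col)
    if (stem %in% registry$metabolite) {
      scale <- switch(suffix,
                      mM = 1,
                      uM = 1e-3,
                      stop("unknown unit suffix '", suffix, "' on column ", col))
      name <- stem
    }
  }
  if (!name %in% registry$metabolite)
    stop("unknown metabolite column: ", col)
  list(metabolite = name, scale = scale)
}

#' @rdname loadProfiles
#' @export
writeProfiles <- function(x, path) {
  stopifnot(is(x, "SecretionExperiment"))
  cd <- as.data.frame(colData(x))
  conc <- t(assay(x, "concentration"))
  df <- data.frame(sample = rownames(conc),
                   acetate_mM = cd$acetate_mM,
                   formate_mM = cd$formate_mM,
                   check.names = FALSE)
  for (m in colnames(conc)) df[[m]] <- conc[, m]
  writeTsv(df, path)
  invisible(path)
}
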