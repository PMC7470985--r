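#' Construct a SecretionExperiment
#'
#' @param concentrations numeric matrix, metabolites x samples, in mM. NA
#'   marks a metabolite that was not measured in a sample (never imputed as
#'   zero).
#' @param acetate_mM,formate_mM per-sample supplement concentrations (mM).
#' @param treatment optional per-sample treatment labels; derived from the
#'   supplement concentrations when omitted.
#' @param registry metabolite registry (see [defaultRegistry()]); rows of
#'   `concentrations` must all be registered.
#' @return a [SecretionExperiment-class] object.
#' @examples
#' m <- matrix(c(6.6, 0.12), nrow = 2, dimnames = list(c("acetate", "lactate"), "s1"))
#' se <- SecretionExperiment(m, acetate_mM = 0, formate_mM = 0)
#' treatments(se)
#' @export
SecretionExperiment <- function(concentrations, acetate_mM, formate_mM,
                                treatment = NULL,
                                registry = defaultRegistry()) {
  concentrations <- as.matrix(concentrations)
  mets <- rownames(concentrations)
  if (is.null(mets)) stop("concentration matrix must have metabolite rownames")
  idx <- match(mets, registry$metabolite)
  if (anyNA(idx))
    stop("unknown metabolite column(s): ",
         paste(mets[is.na(idx)], collapse = ", "))
  if (is.null(treatment))
    treatment <- treatmentLabel(acetate_mM, formate_mM)
  cd <- S4Vectors::DataFrame(
    acetate_mM = as.numeric(acetate_mM),
    formate_mM = as.numeric(formate_mM),
    treatment = as.character(treatment))
  rd <- S4Vectors::DataFrame(
    carbon_count = registry$carbon_count[idx],
    network_node = registry$network_node[idx],
    secreted = registry$secreted[idx],
    row.names = mets)
  se <- SummarizedExperiment(
    assays = list(concentration = concentrations),
    rowData = rd, colData = cd)
  new("SecretionExperiment", se)
}

# Human-readable treatment labels, e.g. "0 mM", "10 mM Ac", "10 mM Ac + 10 mM Fo".
treatmentLabel <- function(acetate_mM, formate_mM) {
  mapply(function(a, f) {
    if (a == 0 && f == 0) return("0 mM")
    parts <- character()
    if (a > 0) parts <- c(parts, sprintf("%g mM Ac", a))
    if (f > 0) parts <- c(parts, sprintf("%g mM Fo", f))
    paste(parts, collapse = " + ")
  }, acetate_mM, formate_mM, USE.NAMES = FALSE)
}

#' @rdname treatments
#' @export
setMethod("treatments", "SecretionExperiment", function(x) {
  cd <- as.data.frame(colData(x))
  agg <- unique(cd[c("treatment", "acetate_mM", "formate_mM")])
  agg$n_samples <- vapply(agg$treatment,
                          function(tr) sum(cd$treatment == tr), integer(1))
  rownames(agg) <- NULL
  agg[order(agg$formate_mM, agg$acetate_mM), c("treatment", "acetate_mM",
                                               "formate_mM", "n_samples")]
})

#' @rdname treatments
#' @export
setMethod("controlTreatment", "SecretionExperiment", function(x) {
  cd <- colData(x)
  unique(cd$treatment[cd$acetate_mM == 0 & cd$formate_mM == 0])
})

#' @rdname profileMeans
#' @export
setMethod("profileMeans", "SecretionExperiment",
  function(x, treatment, na.rm = TRUE) {
    sel <- colData(x)$treatment == treatment
    if (!any(sel)) stop("unknown treatment: ", treatment)
    m <- rowMeans(assay(x, "concentration")[, sel, drop = FALSE])
    if (na.rm) m <- m[!is.na(m)]
    m
  })

setMethod("show", "SecretionExperiment", function(object) {
  tr <- treatments(object)
  cat(sprintf("SecretionExperiment: %d metabolites x %d samples, %d treatments\n",
              nrow(object), ncol(object), nrow(tr)))
  cat("  control:", controlTreatment(object), "\n")
  cat("  treatments:", paste(tr$treatment, collapse = ", "), "\n")
})

#' Summary statistics per treatment and metabolite
#'
#' Pooled mean and sample standard deviation (n - 1 denominator) over all
#' replicates of each treatment. Biological and technical replicates are
#' pooled flat, matching how the study design reports means +/- SD.
#'
#' @param x a [SecretionExperiment].
#' @return a `data.frame` with columns `treatment`, `metabolite`, `mean`,
#'   `sd`, `n`. `sd` is NA (flagged, not guessed) when n < 2.
#' @export
summarizeProfiles <- function(x) {
  stopifnot(is(x, "SecretionExperiment"))
  cd <- as.data.frame(colData(x))
  conc <- assay(x, "concentration")
  out <- list()
  for (tr in unique(cd$treatment)) {
    sub <- conc[, cd$treatment == tr, drop = FALSE]
    for (m in rownames(sub)) {
      v <- sub[m, ]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, metabolite = m,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2L) sampleSd(v) else NA_real_,
        n = length(v))
    }
  }
  do.call(rbind, out)
}

#' @rdname summarizeProfiles
#' @param treatment,metabolite select a single cell of the design.
#' @export
summarizeMetabolite <- function(x, treatment, metabolite) {
  s <- summarizeProfiles(x)
  row <- s[s$treatment == treatment & s$metabolite == metabolite, ]
  if (!nrow(row)) stop("no such treatment/metabolite combination")
  as.list(row[1, c("mean", "sd", "n")])
}
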