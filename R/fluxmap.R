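#' Carbon-normalized secretion flux map
#'
#' Expresses each secreted metabolite's contribution as a percent mole-carbon
#' fraction of the total carbon secreted:
#' \deqn{F(x) = 100 \cdot \frac{x \, C(x)}{\sum_i x_i \, C(x_i)}}
#' with concentrations \eqn{x} in mM and \eqn{C(x)} the metabolite's carbon
#' count. The result is scale-invariant (multiplying all concentrations by a
#' positive constant changes nothing) and sums to 100 exactly.
#'
#' @param profile_means named numeric vector of per-metabolite mean
#'   concentrations (mM); NA entries (not measured) are dropped.
#' @param registry metabolite registry, see [defaultRegistry()].
#' @return a [FluxMap-class] with `basis = "secreted_only"`.
#' @examples
#' fm <- carbonFlux(c(acetate = 1, formate = 1))
#' fluxes(fm)  # acetate 66.67 (C2), formate 33.33 (C1)
#' @export
carbonFlux <- function(profile_means, registry = defaultRegistry()) {
  x <- profile_means[!is.na(profile_means)]
  if (!length(x)) stop("no measured concentrations")
  cc <- carbonCounts(names(x), registry)
  cmol <- x * cc
  total <- sum(cmol)
  if (total <= 0) stop("all concentrations are zero; flux map undefined")
  new("FluxMap", fluxes = 100 * cmol / total,
      co2_percent = NA_real_, biomass_percent = NA_real_,
      basis = "secreted_only", clamped = FALSE)
}

#' Glucose-balance flux map with inferred CO2
#'
#' Closes the carbon balance over consumed glucose: the CO2 carbon is
#' inferred as 6 x glucose consumed minus the secreted carbon minus the
#' biomass carbon, and all terms are expressed as percent of the input
#' carbon. Biomass carbon is computed from dry weight (g/L, e.g. via
#' [biomassFromOD()]) times the biomass carbon fraction, using 12.011 g/mol
#' for carbon. A small negative remainder (within the 10% mass-balance
#' tolerance) is clamped to zero with the `clamped` flag set; a secreted +
#' biomass carbon total exceeding the input by more than 10% is an error.
#'
#' @param glucose_consumed glucose consumed (mM), > 0.
#' @param profile_means named numeric per-metabolite mM means.
#' @param biomass_g_per_L biomass dry weight (g/L), default 0.
#' @param carbon_fraction_biomass carbon fraction of dry biomass, in (0, 1);
#'   default 0.5 g C per g dry weight.
#' @param registry metabolite registry.
#' @return a [FluxMap-class] with `basis = "glucose_balance"`.
#' @examples
#' fm <- inferCO2(1, c(acetate = 2, formate = 1))
#' co2Percent(fm)  # (6 - 5)/6 carbon -> 16.67%
#' @export
inferCO2 <- function(glucose_consumed, profile_means, biomass_g_per_L = 0,
                     carbon_fraction_biomass = 0.5,
                     registry = defaultRegistry()) {
  if (!is.finite(glucose_consumed) || glucose_consumed <= 0)
    stop("glucose_consumed must be > 0")
  if (carbon_fraction_biomass <= 0 || carbon_fraction_biomass >= 1)
    stop("carbon_fraction_biomass must be in (0, 1)")
  x <- profile_means[!is.na(profile_means)]
  cc <- carbonCounts(names(x), registry)
  secreted_c <- sum(x * cc)                      # C-mmol/L
  input_c <- 6 * glucose_consumed                # C-mmol/L
  biomass_c <- biomass_g_per_L * carbon_fraction_biomass / 12.011 * 1000
  if (secreted_c + biomass_c > input_c * 1.1)
    stop(sprintf(
      "mass-balance violation: secreted + biomass carbon (%.4g) exceeds input carbon (%.4g) by >10%%",
      secreted_c + biomass_c, input_c))
  co2_c <- input_c - secreted_c - biomass_c
  clamped <- FALSE
  if (co2_c < 0) {
    co2_c <- 0
    clamped <- TRUE
    warning("negative CO2 remainder clamped to 0 (secreted + biomass carbon ",
            "slightly exceeds input carbon)")
    input_c <- secreted_c + biomass_c
  }
  new("FluxMap",
      fluxes = 100 * (x * cc) / input_c,
      co2_percent = 100 * co2_c / input_c,
      biomass_percent = 100 * biomass_c / input_c,
      basis = "glucose_balance", clamped = clamped)
}

#' @rdname fluxes
#' @export
setMethod("fluxes", "FluxMap", function(x) x@fluxes)

#' @rdname fluxes
#' @export
setMethod("co2Percent", "FluxMap", function(x) x@co2_percent)

#' @rdname fluxes
#' @export
setMethod("biomassPercent", "FluxMap", function(x) x@biomass_percent)

#' @rdname fluxes
#' @export
setMethod("fluxBasis", "FluxMap", function(x) x@basis)

setMethod("show", "FluxMap", function(object) {
  cat(sprintf("FluxMap (%s): %d metabolites\n", object@basis,
              length(object@fluxes)))
  f <- sort(object@fluxes, decreasing = TRUE)
  for (m in names(f)) cat(sprintf("  %-12s %7.3f %%\n", m, f[m]))
  if (object@basis == "glucose_balance")
    cat(sprintf("  %-12s %7.3f %%  (inferred)\n  %-12s %7.3f %%\n",
                "CO2", object@co2_percent, "biomass", object@biomass_percent))
})

#' Flux table export
#'
#' @param map a [FluxMap-class].
#' @param profile_means the concentrations (mM) the map was computed from.
#' @param registry metabolite registry.
#' @param path optional TSV output path.
#' @return `data.frame` with columns `metabolite`, `mM`, `C_mmol`, `percent`.
#' @export
fluxTable <- function(map, profile_means, registry = defaultRegistry(),
                      path = NULL) {
  mets <- names(fluxes(map))
  cc <- carbonCounts(mets, registry)
  df <- data.frame(metabolite = mets,
                   mM = as.numeric(profile_means[mets]),
                   C_mmol = as.numeric(profile_means[mets] * cc),
                   percent = as.numeric(fluxes(map)))
  df <- df[order(-df$percent), ]
  rownames(df) <- NULL
  if (!is.null(path)) writeTsv(df, path)
  df
}

#' Classify per-metabolite secretion changes versus a reference treatment
#'
#' Two-sample comparison per metabolite between a treatment and a reference
#' (default the control), labelling each metabolite `increase`, `decrease`
#' or `no_change` at the given significance level (used for edge colouring
#' in network exports: increase = green, decrease = red, no change = gray).
#'
#' @param x a [SecretionExperiment].
#' @param treatment treatment label to test.
#' @param reference reference label; defaults to the control.
#' @param alpha significance level, default 0.05.
#' @param kind `"student_pooled"` (default) or `"welch"`.
#' @return named character vector over metabolites.
#' @export
secretionChanges <- function(x, treatment, reference = controlTreatment(x),
                             alpha = 0.05, kind = "student_pooled") {
  conc <- assay(x, "concentration")
  cd <- colData(x)
  a_idx <- cd$treatment == reference
  b_idx <- cd$treatment == treatment
  out <- character(0)
  for (m in rownames(conc)) {
    a <- conc[m, a_idx]; a <- a[!is.na(a)]
    b <- conc[m, b_idx]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) { out[m] <- "no_change"; next }
    tt <- metaboliteTTest(a, b, kind = kind)
    out[m] <- if (tt$p_value >= alpha) "no_change"
              else if (mean(b) > mean(a)) "increase" else "decrease"
  }
  out
}
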