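#' @include utils.R
NULL

#' Treatments of a secretion experiment
#'
#' @param x a [SecretionExperiment] object.
#' @return `treatments()` returns a `data.frame` with one row per distinct
#'   treatment (columns `label`, `acetate_mM`, `formate_mM`, `n_samples`);
#'   `controlTreatment()` returns the label of the unsupplemented (0 mM
#'   acetate, 0 mM formate) control.
#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))

#' @rdname treatments
#' @export
setGeneric("controlTreatment", function(x) standardGeneric("controlTreatment"))

#' Per-treatment mean concentrations
#'
#' @param x a [SecretionExperiment] object.
#' @param treatment a treatment label, as listed by [treatments()].
#' @param na.rm drop metabolites that were not measured in this treatment.
#' @return named numeric vector of mean concentrations (mM) per metabolite.
#' @export
setGeneric("profileMeans", function(x, treatment, na.rm = TRUE)
  standardGeneric("profileMeans"))

#' Accessors for flux maps
#'
#' @param x a [FluxMap] object.
#' @return `fluxes()`: named numeric vector of percent mole-carbon fluxes;
#'   `co2Percent()`, `biomassPercent()`: scalar percent (NA for a
#'   secreted-only map); `fluxBasis()`: `"secreted_only"` or
#'   `"glucose_balance"`.
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname fluxes
#' @export
setGeneric("co2Percent", function(x) standardGeneric("co2Percent"))

#' @rdname fluxes
#' @export
setGeneric("biomassPercent", function(x) standardGeneric("biomassPercent"))

#' @rdname fluxes
#' @export
setGeneric("fluxBasis", function(x) standardGeneric("fluxBasis"))

#' Accessors for stoichiometric models and FBA results
#'
#' @param x a [StoichiometricModel] or [FBAResult] object.
#' @return `reactionIds()`: character vector; `objectiveValue()`: optimal
#'   biomass flux; `reactionFluxes()` / `exchangeFluxes()`: named numeric
#'   vectors; `fbaStatus()`: `"optimal"` or `"infeasible"`.
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname reactionIds
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname reactionIds
#' @export
setGeneric("reactionFluxes", function(x) standardGeneric("reactionFluxes"))

#' @rdname reactionIds
#' @export
setGeneric("exchangeFluxes", function(x) standardGeneric("exchangeFluxes"))

#' @rdname reactionIds
#' @export
setGeneric("fbaStatus", function(x) standardGeneric("fbaStatus"))

#' Reaction knockouts
#'
#' Fixes the bounds of the given reactions to zero, mimicking a gene/enzyme
#' deletion.
#'
#' @param model a [StoichiometricModel].
#' @param ids character vector of reaction ids to delete.
#' @return the modified model.
#' @export
setGeneric("knockout", function(model, ids) standardGeneric("knockout"))

#' Accessors for scenario classification fits
#'
#' @param x a [ScenarioFit] object.
#' @return `bestScenario()`: the winning scenario name; `scenarioScores()`:
#'   named numeric residual sum of squares per candidate scenario;
#'   `scenarioCoefficients()`: named vector `c(a, b)` of the fitted response
#'   coefficients.
#' @export
setGeneric("bestScenario", function(x) standardGeneric("bestScenario"))

#' @rdname bestScenario
#' @export
setGeneric("scenarioScores", function(x) standardGeneric("scenarioScores"))

#' @rdname bestScenario
#' @export
setGeneric("scenarioCoefficients", function(x)
  standardGeneric("scenarioCoefficients"))
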