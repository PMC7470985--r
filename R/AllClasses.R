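#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' SecretionExperiment: replicate metabolite concentrations with treatments
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one `concentration` assay (rows = metabolites, columns = replicate
#' samples, units mM), the metabolite registry in `rowData()`
#' (`carbon_count`, `network_node`, `secreted`) and the treatment design in
#' `colData()` (`acetate_mM`, `formate_mM`, `treatment` label). A valid
#' object has non-negative (or NA = not measured) concentrations and exactly
#' one control treatment with 0 mM acetate and 0 mM formate.
#'
#' @slot int_elementMetadata,int_colData,assays inherited from
#'   `SummarizedExperiment`.
#' @seealso [SecretionExperiment()], [loadProfiles()], [treatments()],
#'   [profileMeans()]
#' @export
setClass("SecretionExperiment", contains = "SummarizedExperiment")

setValidity("SecretionExperiment", function(object) {
  msg <- character()
  if (!"concentration" %in% assayNames(object))
    msg <- c(msg, "assay 'concentration' is required")
  rd <- rowData(object)
  for (col in c("carbon_count", "network_node", "secreted"))
    if (!col %in% names(rd))
      msg <- c(msg, sprintf("rowData column '%s' is required", col))
  cd <- colData(object)
  for (col in c("acetate_mM", "formate_mM", "treatment"))
    if (!col %in% names(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if (!length(msg)) {
    conc <- assay(object, "concentration")
    if (any(conc < 0, na.rm = TRUE))
      msg <- c(msg, "concentrations must be >= 0")
    ctrl <- unique(cd$treatment[cd$acetate_mM == 0 & cd$formate_mM == 0])
    if (length(ctrl) != 1L)
      msg <- c(msg, "exactly one control treatment (0 mM acetate, 0 mM formate) is required")
    if (any(cd$acetate_mM < 0) || any(cd$formate_mM < 0))
      msg <- c(msg, "supplement concentrations must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' FluxMap: percent-mole-carbon secretion fluxes
#'
#' Percent mole-carbon flux per secreted metabolite, F(x) =
#' 100 * x * C(x) / denominator. On the `secreted_only` basis the
#' denominator is the total secreted carbon, so the fluxes sum to 100 and
#' there is no CO2 term. On the `glucose_balance` basis the denominator is
#' the carbon input from consumed glucose (6 C per molecule) and the map
#' additionally carries an inferred CO2 share and a biomass-carbon share, so
#' that fluxes + CO2 + biomass sum to 100.
#'
#' @slot fluxes named numeric, percent mole-carbon per metabolite.
#' @slot co2_percent numeric, inferred CO2 share (NA on `secreted_only`).
#' @slot biomass_percent numeric, biomass carbon share (NA on `secreted_only`).
#' @slot basis `"secreted_only"` or `"glucose_balance"`.
#' @slot clamped logical, TRUE if a slightly negative CO2 remainder was
#'   clamped to zero.
#' @seealso [carbonFlux()], [inferCO2()]
#' @export
setClass("FluxMap", representation(
  fluxes = "numeric",
  co2_percent = "numeric",
  biomass_percent = "numeric",
  basis = "character",
  clamped = "logical"
))

setValidity("FluxMap", function(object) {
  msg <- character()
  if (is.null(names(object@fluxes)) || anyDuplicated(names(object@fluxes)))
    msg <- c(msg, "fluxes must be uniquely named")
  if (any(object@fluxes < 0))
    msg <- c(msg, "fluxes must be >= 0")
  if (!object@basis %in% c("secreted_only", "glucose_balance"))
    msg <- c(msg, "basis must be 'secreted_only' or 'glucose_balance'")
  tot <- sum(object@fluxes)
  if (object@basis == "secreted_only" && abs(tot - 100) > 1e-9)
    msg <- c(msg, sprintf("secreted_only fluxes must sum to 100 (got %.12g)", tot))
  if (object@basis == "glucose_balance") {
    tot <- tot + object@co2_percent + object@biomass_percent
    if (abs(tot - 100) > 1e-9)
      msg <- c(msg, sprintf(
        "glucose_balance fluxes + CO2 + biomass must sum to 100 (got %.12g)", tot))
  }
  if (length(msg)) msg else TRUE
})

#' StoichiometricModel: curated constraint-based metabolic network
#'
#' A small flux-balance model: metabolites with a compartment tag and C/N
#' atom counts, reactions with sparse stoichiometry maps, reversibility and
#' flux bounds, and a biomass objective reaction. Exchange and biomass
#' reactions are exempt from elemental balancing; every other reaction must
#' balance carbon and nitrogen.
#'
#' @slot id model identifier.
#' @slot metabolites `data.frame` with columns `id`, `name`, `compartment`
#'   (`internal`/`external`), `carbon`, `nitrogen`.
#' @slot reactions named list; each element has `id`, `name`,
#'   `stoichiometry` (named numeric), `reversible`, `lb`, `ub`,
#'   `balance_exempt`.
#' @slot objective id of the biomass reaction.
#' @seealso [bthetaCoreModel()], [solveFBA()], [validateModel()]
#' @export
setClass("StoichiometricModel", representation(
  id = "character",
  metabolites = "data.frame",
  reactions = "list",
  objective = "character"
))

setValidity("StoichiometricModel", function(object) {
  msg <- character()
  rids <- vapply(object@reactions, `[[`, character(1), "id",
                 USE.NAMES = FALSE)
  if (anyDuplicated(rids)) msg <- c(msg, "duplicate reaction ids")
  if (!identical(names(object@reactions), rids))
    msg <- c(msg, "reactions list must be named by reaction id")
  if (anyDuplicated(object@metabolites$id)) msg <- c(msg, "duplicate metabolite ids")
  if (!object@objective %in% rids)
    msg <- c(msg, sprintf("objective reaction '%s' not in model", object@objective))
  for (r in object@reactions) {
    unknown <- setdiff(names(r$stoichiometry), object@metabolites$id)
    if (length(unknown))
      msg <- c(msg, sprintf("reaction %s references unknown metabolite(s): %s",
                            r$id, paste(unknown, collapse = ", ")))
    if (r$lb > r$ub)
      msg <- c(msg, sprintf("reaction %s has lb > ub", r$id))
  }
  if (length(msg)) msg else TRUE
})

#' FBAResult: solution of a flux-balance linear program
#'
#' @slot objective_value optimal biomass flux (0 when infeasible).
#' @slot reaction_fluxes named numeric flux per reaction (empty when
#'   infeasible).
#' @slot exchange_fluxes named numeric flux per exchange reaction (negative
#'   = uptake, positive = secretion).
#' @slot status `"optimal"` or `"infeasible"`.
#' @seealso [solveFBA()], [mediaGrid()]
#' @export
setClass("FBAResult", representation(
  objective_value = "numeric",
  reaction_fluxes = "numeric",
  exchange_fluxes = "numeric",
  status = "character"
))

setValidity("FBAResult", function(object) {
  if (!object@status %in% c("optimal", "infeasible"))
    return("status must be 'optimal' or 'infeasible'")
  TRUE
})

#' ScenarioFit: classification of a titration dataset
#'
#' Result of fitting the five theoretical secretion-response scenarios to
#' endpoint titration data and selecting the best-matching one.
#'
#' @slot best winning scenario (`additive`, `balanced`, `feedback_only`,
#'   `synergistic`, `upregulation`).
#' @slot coefficients named numeric `c(a, b)` from the selected family.
#' @slot scores named numeric residual sum of squares per candidate.
#' @slot null_effect TRUE when no dose effect is detectable (reported as
#'   `additive` with a = 0).
#' @seealso [classifyScenario()]
#' @export
setClass("ScenarioFit", representation(
  best = "character",
  coefficients = "numeric",
  scores = "numeric",
  null_effect = "logical"
))
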