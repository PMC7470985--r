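#' Read and write stoichiometric models (flat JSON)
#'
#' The model format is a flat JSON object with `id`, `metabolites` (id,
#' name, compartment `internal`/`external`, `carbon`, `nitrogen` atom
#' counts), `reactions` (id, name, explicit `stoichiometry` map, `reversible`,
#' bounds `lb`/`ub`, `balance_exempt` for exchange/biomass reactions) and
#' the `objective` reaction id.
#'
#' @param path JSON file path.
#' @return a [StoichiometricModel-class].
#' @export
readStoichiometricModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(j$metabolites, function(m) data.frame(
    id = m$id, name = m$name %||% m$id, compartment = m$compartment,
    carbon = as.numeric(m$carbon), nitrogen = as.numeric(m$nitrogen),
    stringsAsFactors = FALSE)))
  rxns <- lapply(j$reactions, function(r) list(
    id = r$id, name = r$name %||% r$id,
    stoichiometry = unlist(r$stoichiometry),
    reversible = isTRUE(r$reversible),
    lb = as.numeric(r$lb), ub = as.numeric(r$ub),
    balance_exempt = isTRUE(r$balance_exempt)))
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  new("StoichiometricModel", id = j$id %||% "model",
      metabolites = mets, reactions = rxns, objective = j$objective)
}

#' @rdname readStoichiometricModel
#' @param model a [StoichiometricModel-class].
#' @export
writeStoichiometricModel <- function(model, path) {
  j <- list(
    id = model@id,
    objective = model@objective,
    metabolites = lapply(seq_len(nrow(model@metabolites)), function(i)
      as.list(model@metabolites[i, ])),
    reactions = lapply(unname(model@reactions), function(r) list(
      id = r$id, name = r$name,
      stoichiometry = as.list(r$stoichiometry),
      reversible = r$reversible, lb = r$lb, ub = r$ub,
      balance_exempt = r$balance_exempt)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Curated central-carbon model of *B. thetaiotaomicron*
#'
#' A self-contained ~45-reaction model of anaerobic glucose fermentation:
#' Embden-Meyerhof-Parnas glycolysis, the pyruvate node (pyruvate kinase,
#' pyruvate phosphate dikinase, pyruvate carboxylase, pyruvate
#' dehydrogenase, pyruvate synthase, pyruvate formate-lyase, lactate
#' dehydrogenase), the Ack/Pta and acetyl-CoA synthetase acetate routes,
#' the reductive TCA branch to succinate (malate dehydrogenase, fumarase,
#' fumarate reductase) with the methylmalonyl route to propionate, a lumped
#' oxidative branch to 2-oxoglutarate, amino-acid metabolism around
#' aspartate (aspartate aminotransferase, aspartate oxidase, and the two
#' interchangeable asparagine routes: asparagine synthetase and aspartate
#' ammonia ligase), serine synthesis and serine ammonia-lyase, formate-THF
#' ligase, hydrogenase, currency-metabolite closure (adenylate kinase,
#' pyrophosphatase, ATP maintenance) and a lumped biomass reaction. This is
#' a curated teaching-scale network, not a genome-scale reconstruction:
#' exchange-flux comparisons are qualitative.
#'
#' @return a [StoichiometricModel-class].
#' @export
bthetaCoreModel <- function() {
  readStoichiometricModel(extdata("btheta_core_model.json"))
}

#' Media specifications
#'
#' A media specification is a named vector of maximum uptake rates
#' (mmol per g cell dry weight per hour) for external metabolites; an
#' absent metabolite means zero uptake. `baseMedia()` returns the
#' unbounded mineral base (ammonia, CO2); `mediaSpec()` adds carbon
#' sources. The conventional condition values: high glucose 2.78, low
#' glucose 0.1, supplemented acetate/formate 10.
#'
#' @param glucose,acetate,formate maximum uptakes (mmol/gCDW/h).
#' @param base named numeric base-media uptakes.
#' @return named numeric vector of maximum uptakes.
#' @export
mediaSpec <- function(glucose = 0, acetate = 0, formate = 0,
                      base = baseMedia()) {
  m <- c(base, glc_e = glucose, ac_e = acetate, for_e = formate)
  if (any(m < 0)) stop("uptake maxima must be >= 0")
  m
}

#' @rdname mediaSpec
#' @export
baseMedia <- function() {
  unlist(jsonlite::read_json(extdata("media_base.json")))
}

# Apply a media spec: exchange reactions get lb = -max_uptake.
applyMedia <- function(model, media) {
  if (any(media < 0)) stop("uptake maxima must be >= 0")
  for (rid in names(model@reactions)) {
    r <- model@reactions[[rid]]
    ext <- exchangeMetabolite(r)
    if (is.null(ext)) next
    up <- if (ext %in% names(media)) media[[ext]] else 0
    model@reactions[[rid]]$lb <- -up
  }
  model
}

# An exchange reaction has a single (external) metabolite in its
# stoichiometry; returns its id or NULL.
exchangeMetabolite <- function(r) {
  s <- r$stoichiometry
  if (length(s) == 1L) names(s) else NULL
}

isExchange <- function(model) {
  vapply(model@reactions,
         function(r) !is.null(exchangeMetabolite(r)), logical(1))
}

#' Stoichiometric matrix
#'
#' @param model a [StoichiometricModel-class].
#' @return dense numeric matrix S (metabolites x reactions).
#' @export
stoichiometryMatrix <- function(model) {
  mets <- model@metabolites$id
  rids <- names(model@reactions)
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (rid in rids) {
    s <- model@reactions[[rid]]$stoichiometry
    S[names(s), rid] <- s
  }
  S
}

#' @rdname reactionIds
#' @export
setMethod("reactionIds", "StoichiometricModel",
          function(x) names(x@reactions))

#' @rdname knockout
#' @export
setMethod("knockout", "StoichiometricModel", function(model, ids) {
  unknown <- setdiff(ids, names(model@reactions))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  for (rid in ids) {
    model@reactions[[rid]]$lb <- 0
    model@reactions[[rid]]$ub <- 0
  }
  model
})

setMethod("show", "StoichiometricModel", function(object) {
  cat(sprintf("StoichiometricModel '%s': %d metabolites, %d reactions\n",
              object@id, nrow(object@metabolites), length(object@reactions)))
  cat(sprintf("  objective: %s; %d exchange reactions\n", object@objective,
              sum(isExchange(object))))
})

#' Validate a stoichiometric model
#'
#' Checks (i) carbon and nitrogen balance of every reaction not marked
#' `balance_exempt` (exchanges and biomass), (ii) dead-end metabolites
#' (metabolites that cannot be both produced and consumed given
#' reversibilities), and (iii) bound sanity (lb <= ub, reversibility
#' consistent with a negative lower bound). Returns a machine-readable
#' report; an empty report means a clean model.
#'
#' @param model a [StoichiometricModel-class].
#' @return `data.frame` with columns `check`, `item`, `message`; zero rows
#'   when no violations are found.
#' @export
validateModel <- function(model) {
  rep_ <- list()
  add <- function(check, item, message)
    rep_[[length(rep_) + 1L]] <<- data.frame(check = check, item = item,
                                             message = message)
  carbon <- stats::setNames(model@metabolites$carbon, model@metabolites$id)
  nitro <- stats::setNames(model@metabolites$nitrogen, model@metabolites$id)
  for (r in model@reactions) {
    if (r$lb > r$ub) add("bounds", r$id, "lb > ub")
    if (!r$reversible && r$lb < 0 && is.null(exchangeMetabolite(r)))
      add("bounds", r$id, "irreversible reaction with negative lower bound")
    if (isTRUE(r$balance_exempt)) next
    s <- r$stoichiometry
    cbal <- sum(s * carbon[names(s)])
    nbal <- sum(s * nitro[names(s)])
    if (abs(cbal) > 1e-9)
      add("elemental_balance", r$id, sprintf("carbon imbalance: %+g", cbal))
    if (abs(nbal) > 1e-9)
      add("elemental_balance", r$id, sprintf("nitrogen imbalance: %+g", nbal))
  }
  # dead ends: can the metabolite be produced AND consumed by some reaction?
  S <- stoichiometryMatrix(model)
  rev_ <- vapply(model@reactions, function(r) r$lb < 0 || r$reversible,
                 logical(1))
  for (m in rownames(S)) {
    row <- S[m, ]
    produced <- any(row > 0 & !is.na(row)) || any(row < 0 & rev_)
    consumed <- any(row < 0) || any(row > 0 & rev_)
    if (all(row == 0))
      add("dead_end", m, "isolated metabolite (no reactions)")
    else if (!produced || !consumed)
      add("dead_end", m, "metabolite cannot be both produced and consumed")
  }
  if (!length(rep_))
    return(data.frame(check = character(), item = character(),
                      message = character()))
  out <- do.call(rbind, rep_)
  rownames(out) <- NULL
  out
}
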