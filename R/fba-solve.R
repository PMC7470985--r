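#' Flux balance analysis by linear programming
#'
#' Maximizes the biomass objective subject to steady state (S v = 0) and
#' flux bounds, with the media specification setting exchange lower bounds
#' (uptake is negative flux). The LP is solved with the simplex method
#' (`boot::simplex`) on the standard positive/negative flux split. Because
#' the optimum of an FBA problem is typically degenerate, a second
#' lexicographic stage minimizes the total absolute flux at the fixed
#' optimal objective, which resolves alternate optima deterministically
#' (and removes futile cycles), so exchange-flux comparisons between
#' conditions are well defined.
#'
#' @param model a [StoichiometricModel-class].
#' @param media named uptake maxima (see [mediaSpec()]); NULL leaves the
#'   model's bounds untouched.
#' @param lexicographic run the minimum-total-flux second stage (default
#'   TRUE).
#' @return an [FBAResult-class].
#' @examples
#' m <- bthetaCoreModel()
#' res <- solveFBA(m, mediaSpec(glucose = 2.78))
#' objectiveValue(res)
#' @export
solveFBA <- function(model, media = NULL, lexicographic = TRUE) {
  if (!is.null(media)) model <- applyMedia(model, media)
  S <- stoichiometryMatrix(model)
  rids <- colnames(S)
  lb <- vapply(model@reactions, `[[`, numeric(1), "lb")[rids]
  ub <- vapply(model@reactions, `[[`, numeric(1), "ub")[rids]
  nr <- length(rids)

  # split v = p - n, creating a variable only where the corresponding
  # bound is positive (zero-bound variables would introduce degenerate
  # pivots in the simplex)
  p_rxn <- which(ub > 0)
  n_rxn <- which(lb < 0)
  nv <- length(p_rxn) + length(n_rxn)
  if (nv == 0L) {
    v <- stats::setNames(rep(0, nr), rids)
    exch <- isExchange(model)
    return(new("FBAResult", objective_value = 0, reaction_fluxes = v,
               exchange_fluxes = v[names(v)[exch]], status = "optimal"))
  }
  vsign <- c(rep(1, length(p_rxn)), rep(-1, length(n_rxn)))
  vrxn <- c(p_rxn, n_rxn)
  A3 <- S[, vrxn, drop = FALSE] * rep(vsign, each = nrow(S))
  b3 <- rep(0, nrow(S))
  A1 <- diag(nv)
  b1 <- c(ub[p_rxn], -lb[n_rxn])
  obj <- numeric(nv)
  k <- match(model@objective, rids)
  obj[vrxn == k] <- vsign[vrxn == k]
  # forced-flux rows: v >= lb (lb > 0) or -v >= -ub (ub < 0)
  forced_pos <- which(lb > 0)
  forced_neg <- which(ub < 0)
  A2 <- NULL; b2 <- NULL
  if (length(forced_pos) || length(forced_neg)) {
    A2 <- matrix(0, length(forced_pos) + length(forced_neg), nv)
    i <- 0L
    for (j in forced_pos) {
      i <- i + 1L; A2[i, vrxn == j] <- vsign[vrxn == j]
    }
    for (j in forced_neg) {
      i <- i + 1L; A2[i, vrxn == j] <- -vsign[vrxn == j]
    }
    b2 <- c(lb[forced_pos], -ub[forced_neg])
  }

  s1 <- runSimplex(obj, A1, b1, A2, b2, A3, b3, maxi = TRUE)
  if (is.null(s1))
    return(new("FBAResult", objective_value = 0,
               reaction_fluxes = numeric(0), exchange_fluxes = numeric(0),
               status = "infeasible"))
  z <- s1$value
  soln <- s1$soln

  if (lexicographic) {
    # fix the objective at its optimum, minimize total |v| = sum(p + n)
    A3b <- rbind(A3, obj)
    b3b <- c(b3, z)
    neg <- b3b < 0
    A3b[neg, ] <- -A3b[neg, ]
    b3b[neg] <- -b3b[neg]
    s2 <- runSimplex(rep(1, nv), A1, b1, A2, b2, A3b, b3b, maxi = FALSE)
    if (!is.null(s2)) soln <- s2$soln
  }

  v <- stats::setNames(rep(0, nr), rids)
  for (i in seq_len(nv)) v[vrxn[i]] <- v[vrxn[i]] + vsign[i] * soln[i]
  v[abs(v) < 1e-10] <- 0
  exch <- isExchange(model)
  new("FBAResult", objective_value = unname(v[model@objective]),
      reaction_fluxes = v, exchange_fluxes = v[names(v)[exch]],
      status = "optimal")
}

# simplexLP wrapper (<=, >=, = blocks) returning NULL unless solved.
runSimplex <- function(a, A1, b1, A2, b2, A3, b3, maxi) {
  A <- rbind(A1, A2, A3)
  b <- c(b1, b2, b3)
  ctype <- c(rep("<=", length(b1)), rep(">=", length(b2)),
             rep("=", length(b3)))
  out <- simplexLP(a, A, b, ctype, maximize = maxi)
  if (out$status != "optimal") return(NULL)
  out
}

#' @rdname reactionIds
#' @export
setMethod("objectiveValue", "FBAResult", function(x) x@objective_value)

#' @rdname reactionIds
#' @export
setMethod("reactionFluxes", "FBAResult", function(x) x@reaction_fluxes)

#' @rdname reactionIds
#' @export
setMethod("exchangeFluxes", "FBAResult", function(x) x@exchange_fluxes)

#' @rdname reactionIds
#' @export
setMethod("fbaStatus", "FBAResult", function(x) x@status)

setMethod("show", "FBAResult", function(object) {
  cat(sprintf("FBAResult: status %s, objective %.6g\n", object@status,
              object@objective_value))
  ex <- object@exchange_fluxes
  ex <- ex[ex != 0]
  if (length(ex)) {
    cat("  nonzero exchange fluxes:\n")
    for (r in names(sort(ex)))
      cat(sprintf("    %-12s %+10.4g\n", r, ex[r]))
  }
})

#' The eight-condition in-silico experiment grid
#'
#' Runs FBA under high glucose (2.78) and low glucose (0.1) crossed with
#' presence/absence of 10 mmol/gCDW/h acetate and formate: eight conditions
#' in total. Alongside the per-condition results, a flux-delta table
#' compares each supplemented condition with the supplement-free condition
#' at the same glucose level.
#'
#' @param model a [StoichiometricModel-class].
#' @param glucose_levels named numeric, default `c(high = 2.78, low = 0.1)`.
#' @param supplement_uptake uptake bound for supplemented acetate/formate,
#'   default 10.
#' @return list with `conditions` (data.frame of the grid),
#'   `results` (named list of [FBAResult-class]), `objectives` (named
#'   numeric) and `deltas` (data.frame from [fluxDeltas()] per supplemented
#'   condition).
#' @export
mediaGrid <- function(model, glucose_levels = c(high = 2.78, low = 0.1),
                      supplement_uptake = 10) {
  grid <- expand.grid(formate = c(0, supplement_uptake),
                      acetate = c(0, supplement_uptake),
                      glucose = names(glucose_levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("glucose", "acetate", "formate")]
  grid$condition <- sprintf("%s_glucose%s%s", grid$glucose,
                            ifelse(grid$acetate > 0, "_ac", ""),
                            ifelse(grid$formate > 0, "_fo", ""))
  results <- list()
  for (i in seq_len(nrow(grid))) {
    media <- mediaSpec(glucose = glucose_levels[[grid$glucose[i]]],
                       acetate = grid$acetate[i], formate = grid$formate[i])
    results[[grid$condition[i]]] <- solveFBA(model, media)
  }
  objectives <- vapply(results, objectiveValue, numeric(1))
  deltas <- list()
  for (i in seq_len(nrow(grid))) {
    if (grid$acetate[i] == 0 && grid$formate[i] == 0) next
    ref <- sprintf("%s_glucose", grid$glucose[i])
    d <- fluxDeltas(results[[ref]], results[[grid$condition[i]]])
    d$condition <- grid$condition[i]
    d$reference <- ref
    deltas[[length(deltas) + 1L]] <- d
  }
  list(conditions = grid, results = results, objectives = objectives,
       deltas = do.call(rbind, deltas))
}

#' Classify flux changes between two FBA solutions
#'
#' Labels every reaction's flux change from a reference solution to a
#' perturbed one: `zero_net` (zero in both), `direction_change` (sign
#' flip), `increased` / `decreased` (magnitude change, same direction),
#' `no_change`.
#'
#' @param reference,perturbed [FBAResult-class] objects on the same model.
#' @param tol absolute tolerance below which a flux counts as zero.
#' @return `data.frame` with columns `reaction`, `flux_ref`, `flux_new`,
#'   `change`.
#' @export
fluxDeltas <- function(reference, perturbed, tol = 1e-9) {
  va <- reactionFluxes(reference)
  vb <- reactionFluxes(perturbed)[names(va)]
  classify <- function(a, b) {
    az <- abs(a) < tol; bz <- abs(b) < tol
    if (az && bz) return("zero_net")
    if (!az && !bz && sign(a) != sign(b)) return("direction_change")
    if (abs(b) > abs(a) + tol) return("increased")
    if (abs(b) < abs(a) - tol) return("decreased")
    "no_change"
  }
  data.frame(reaction = names(va), flux_ref = unname(va),
             flux_new = unname(vb),
             change = mapply(classify, va, vb, USE.NAMES = FALSE))
}
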