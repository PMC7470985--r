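#' Theoretical secretion-response scenarios
#'
#' Five hypotheses describe how a secreted metabolite's accumulated
#' concentration responds to supplementing the medium with its (or a
#' related) fermentation product at concentration `A` (mM):
#' \describe{
#'   \item{additive}{secretion with no destruction and no regulation:
#'     direct coefficient a > 0, regulatory coefficient b = 0.}
#'   \item{balanced}{secretion and absorption balance so the endpoint
#'     change equals -x_init at every supplement level (curves overlap).}
#'   \item{feedback_only}{feedback inhibition with no gene regulation:
#'     a < 0, b = 0.}
#'   \item{synergistic}{negative feedback with compensatory gene
#'     regulation: a < 0, b < 0.}
#'   \item{upregulation}{positive upregulation with increasing supplement:
#'     a > 0, b > 0.}
#' }
#' The direct (enzyme-level) term responds linearly to the supplement while
#' the regulatory term builds up with the culture itself, so along an
#' accumulation ramp g(t) (0 to 1 over the time grid) the concentration
#' change is \eqn{\Delta x_{sec}(t, A) = g(t)(aA + bA\,g(t))}; at the
#' endpoint (g = 1) this is \eqn{aA + bA^2}, which makes a and b separately
#' identifiable from a titration. Time is in arbitrary units; the ramp is
#' linear by default and configurable.
#'
#' @param scenario one of the five scenario names.
#' @param a direct response coefficient (per mM).
#' @param b regulatory response coefficient (per mM).
#' @param x_init control endpoint concentration (mM).
#' @param time_grid ordered time grid (arbitrary units).
#' @return object of class `ScenarioParams`.
#' @export
scenarioParams <- function(scenario = c("additive", "balanced",
                                        "feedback_only", "synergistic",
                                        "upregulation"),
                           a = 0, b = 0, x_init = 0,
                           time_grid = seq(0, 1, length.out = 11)) {
  scenario <- match.arg(scenario)
  if (is.unsorted(time_grid, strictly = TRUE))
    stop("time_grid must be strictly increasing")
  ok <- switch(scenario,
    additive = a > 0 && b == 0,
    balanced = TRUE,           # endpoint contract (a+b)A = -x_init applies
    feedback_only = a < 0 && b == 0,
    synergistic = a < 0 && b < 0,
    upregulation = a > 0 && b > 0)
  if (!ok)
    stop(sprintf("coefficients (a=%g, b=%g) violate the %s sign contract",
                 a, b, scenario))
  structure(list(scenario = scenario, a = a, b = b, x_init = x_init,
                 time_grid = time_grid),
            class = "ScenarioParams")
}

#' Simulate a titration dataset under a scenario
#'
#' @param params a `ScenarioParams` object.
#' @param a_sup_levels supplement levels (mM), at least 2.
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   noise applied to each value (>= 0).
#' @param n_replicates replicates per level and time point.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return `data.frame` with columns `time`, `g` (accumulation fraction),
#'   `a_sup`, `replicate`, `delta` (change in concentration vs control,
#'   mM), with the generating parameters attached as attribute
#'   `ground_truth`.
#' @examples
#' p <- scenarioParams("feedback_only", a = -0.1)
#' d <- simulateScenario(p, c(0, 5, 10))
#' subset(d, time == 1)$delta  # endpoints 0, -0.5, -1
#' @export
simulateScenario <- function(params, a_sup_levels, noise_cv = 0,
                             n_replicates = 1, seed = 1L) {
  stopifnot(inherits(params, "ScenarioParams"))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (length(a_sup_levels) < 2L) stop("need at least 2 supplement levels")
  tg <- params$time_grid
  g <- (tg - tg[1]) / (tg[length(tg)] - tg[1])
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      a_sup = a_sup_levels, time = tg,
                      KEEP.OUT.ATTRS = FALSE)
  grid$g <- g[match(grid$time, tg)]
  mean_delta <- if (params$scenario == "balanced") {
    ifelse(grid$a_sup > 0, -params$x_init * grid$g, 0)
  } else {
    # direct term responds to the supplement; the regulatory term builds
    # up with the culture (A^2 basis at the endpoint, g = 1)
    grid$g * (params$a * grid$a_sup + params$b * grid$a_sup^2 * grid$g)
  }
  noisy <- withSeed(seed, {
    mean_delta * (1 + noise_cv * stats::rnorm(length(mean_delta)))
  })
  out <- data.frame(time = grid$time, g = grid$g, a_sup = grid$a_sup,
                    replicate = grid$replicate, delta = noisy)
  attr(out, "ground_truth") <- params
  out
}

# Sign-constrained least squares for delta ~ a*A + b*A^2 through the origin.
# With only two coefficients the constrained optimum is the best of the
# unconstrained fit (if it satisfies the signs) and the boundary fits.
constrainedQuadFit <- function(A, d, a_sign, b_sign) {
  X <- cbind(A, A^2)
  cand <- list()
  fit2 <- stats::lm.fit(X, d)
  cand[[1]] <- c(fit2$coefficients[1], fit2$coefficients[2])
  cand[[2]] <- c(sum(A * d) / sum(A^2), 0)           # b = 0
  cand[[3]] <- c(0, sum(A^2 * d) / sum(A^4))          # a = 0
  cand[[4]] <- c(0, 0)
  okSign <- function(v, s)
    if (s == 0) v == 0 else if (s > 0) v >= 0 else v <= 0
  best <- NULL; best_rss <- Inf
  for (cf in cand) {
    cf[is.na(cf)] <- 0
    if (!okSign(cf[1], a_sign) || !okSign(cf[2], b_sign)) next
    rss <- sum((d - X %*% cf)^2)
    if (rss < best_rss - 1e-15) { best <- cf; best_rss <- rss }
  }
  list(a = best[1], b = best[2], rss = best_rss)
}

#' Classify a titration dataset by best-matching scenario
#'
#' Uses the endpoint values per supplement level (the last time point when
#' a time course is supplied). Linear (b = 0) and quadratic (b != 0)
#' response families are fitted through the origin by least squares; the
#' regulatory b term is admitted only when an F test at level `alpha` finds
#' it significant *and* its endpoint contribution exceeds twice the
#' residual noise (a parsimony guard: the simpler b = 0 families win
#' ties). The balanced scenario is detected by its own zero-parameter
#' profile (endpoint change = -x_init at every level). Among admitted
#' candidates the lowest residual sum of squares wins; remaining ties go to
#' the simpler family.
#'
#' @param dataset `data.frame` with columns `a_sup` and `delta` (and
#'   optionally `time`, in which case only the final time point is used);
#'   >= 3 supplement levels including 0.
#' @param x_init control endpoint concentration for the balanced check;
#'   taken from the dataset's `ground_truth` attribute when present.
#' @param alpha significance level of the F test for the b term.
#' @return a [ScenarioFit-class].
#' @export
classifyScenario <- function(dataset, x_init = NULL, alpha = 0.05) {
  gt <- attr(dataset, "ground_truth")
  if (is.null(x_init) && !is.null(gt)) x_init <- gt$x_init
  if ("time" %in% names(dataset))
    dataset <- dataset[dataset$time == max(dataset$time), ]
  A <- dataset$a_sup
  d <- dataset$delta
  levels_ <- sort(unique(A))
  if (length(levels_) < 3L || !0 %in% levels_)
    stop("need >= 3 supplement levels including 0")
  n <- length(d)
  A_max <- max(A)
  scale_eps <- 1e-9 * max(1, max(abs(d)), abs(x_init %||% 0))

  # family fits through the origin
  a_free <- sum(A * d) / sum(A^2)
  rss_lin <- sum((d - a_free * A)^2)
  quad <- stats::lm.fit(cbind(A, A^2), d)
  rss_quad <- sum(quad$residuals^2)
  b_free <- unname(quad$coefficients[2]); b_free[is.na(b_free)] <- 0

  # F test for the quadratic (regulatory) term + practical-magnitude guard
  sigma2 <- rss_quad / max(n - 2, 1)
  b_signif <- if (rss_quad < scale_eps^2) {
    abs(b_free) * A_max^2 > scale_eps
  } else {
    f_stat <- (rss_lin - rss_quad) / sigma2
    p_b <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
    (p_b < alpha) && (abs(b_free) * A_max^2 > 2 * sqrt(sigma2))
  }

  # does the dose have any detectable effect at all?
  sigma2_lin <- rss_lin / max(n - 1, 1)
  se_a <- sqrt(sigma2_lin / sum(A^2))
  null_effect <- if (se_a < scale_eps) abs(a_free) * A_max < scale_eps else
    2 * stats::pt(-abs(a_free) / se_a, n - 1) >= alpha
  null_effect <- null_effect && !b_signif

  fit_add <- constrainedQuadFit(A, d, a_sign = 1, b_sign = 0)
  fit_fb  <- constrainedQuadFit(A, d, a_sign = -1, b_sign = 0)
  fit_syn <- constrainedQuadFit(A, d, a_sign = -1, b_sign = -1)
  fit_up  <- constrainedQuadFit(A, d, a_sign = 1, b_sign = 1)
  bal_const <- if (!is.null(x_init)) -x_init else {
    cb <- mean(d[A > 0]); if (cb < 0) cb else NA_real_
  }
  rss_bal <- if (is.na(bal_const)) Inf else
    sum((d - ifelse(A > 0, bal_const, 0))^2)

  scores <- c(additive = fit_add$rss, feedback_only = fit_fb$rss,
              balanced = rss_bal, synergistic = fit_syn$rss,
              upregulation = fit_up$rss)
  candidates <- c("additive", "feedback_only", "balanced")
  if (b_signif) candidates <- c(candidates, "synergistic", "upregulation")
  # stable parsimony order; which.min takes the first minimum
  order_pref <- c("additive", "feedback_only", "balanced",
                  "synergistic", "upregulation")
  candidates <- order_pref[order_pref %in% candidates]
  cand_scores <- scores[candidates]
  best <- candidates[which.min(cand_scores)]
  if (null_effect) best <- "additive"

  coefs <- switch(best,
    additive = if (null_effect) c(a = 0, b = 0) else
      c(a = fit_add$a, b = 0),
    feedback_only = c(a = fit_fb$a, b = 0),
    balanced = c(a = unname(bal_const) / A_max, b = 0),
    synergistic = c(a = fit_syn$a, b = fit_syn$b),
    upregulation = c(a = fit_up$a, b = fit_up$b))
  names(coefs) <- c("a", "b")
  new("ScenarioFit", best = best, coefficients = coefs, scores = scores,
      null_effect = null_effect)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname bestScenario
#' @export
setMethod("bestScenario", "ScenarioFit", function(x) x@best)

#' @rdname bestScenario
#' @export
setMethod("scenarioScores", "ScenarioFit", function(x) x@scores)

#' @rdname bestScenario
#' @export
setMethod("scenarioCoefficients", "ScenarioFit", function(x) x@coefficients)

setMethod("show", "ScenarioFit", function(object) {
  cat(sprintf("ScenarioFit: best = %s%s (a = %.4g, b = %.4g)\n",
              object@best, if (object@null_effect) " [null/no-effect]" else "",
              object@coefficients["a"], object@coefficients["b"]))
  cat("  RSS per scenario:\n")
  for (s in names(object@scores))
    cat(sprintf("    %-13s %.6g\n", s, object@scores[s]))
})
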