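#' Secretion delta versus the unsupplemented control
#'
#' The effect of a supplement on secretion is unmasked by subtracting the
#' control concentration: \eqn{x_{sec} = x_{obs} - x_{init}}. Negative
#' values mean less of the metabolite in the medium than the control
#' secreted.
#'
#' @param x_obs observed concentration (mM), finite and >= 0.
#' @param x_init control (0 mM treatment) concentration (mM), finite, >= 0.
#' @return `x_obs - x_init` (mM), vectorized.
#' @examples
#' secretionDelta(10.81, 6.6)  # 4.21 mM: far below the 10 mM added
#' @export
secretionDelta <- function(x_obs, x_init) {
  if (any(!is.finite(x_obs)) || any(!is.finite(x_init)))
    stop("x_obs and x_init must be finite")
  if (any(x_obs < 0) || any(x_init < 0))
    stop("concentrations must be >= 0")
  x_obs - x_init
}

#' Additive null model for a supplemented metabolite
#'
#' Under the null hypothesis the supplement has no effect on metabolism:
#' the expected concentration of the supplemented species itself is the
#' control secretion plus the amount added (e.g. 6.6 mM secreted + 10 mM
#' supplemented = 16.60 mM expected acetate), and every other metabolite is
#' expected at its control level.
#'
#' @param metabolite metabolite name.
#' @param x_init control mean concentration (mM).
#' @param additive_supplement TRUE only for the supplemented species itself.
#' @return an object of class `NullModel`.
#' @export
nullModel <- function(metabolite, x_init, additive_supplement = FALSE) {
  stopifnot(is.finite(x_init), x_init >= 0)
  structure(list(metabolite = metabolite, x_init = x_init,
                 additive_supplement = isTRUE(additive_supplement)),
            class = "NullModel")
}

#' @rdname nullModel
#' @param model a `NullModel`.
#' @param a_sup supplement concentration (mM), >= 0.
#' @return `nullExpectation`: expected concentration (mM) under the null.
#' @examples
#' nullExpectation(nullModel("acetate", 6.6, additive_supplement = TRUE), 10)
#' @export
nullExpectation <- function(model, a_sup) {
  stopifnot(inherits(model, "NullModel"))
  if (any(a_sup < 0)) stop("a_sup must be >= 0")
  if (model$additive_supplement) model$x_init + a_sup else
    rep_len(model$x_init, length(a_sup))
}

#' Fold variance from the additive null model
#'
#' Relative deviation of the observed concentration from its null-model
#' expectation: \eqn{x_{var} = x_{obs} / x_{null} - 1}. Zero means the
#' observation matches the null; negative values quantify "missing"
#' metabolite (down to -1 at complete suppression); positive values mean
#' extra secretion.
#'
#' @param x_obs observed concentration (mM).
#' @param model a `NullModel` (see [nullModel()]).
#' @param a_sup supplement concentration (mM).
#' @return dimensionless fold variance; NA with a warning when the null
#'   expectation is zero (undefined).
#' @examples
#' m <- nullModel("acetate", 6.6, additive_supplement = TRUE)
#' foldVariance(10.81, m, 10)  # -0.3488: a third of expected acetate missing
#' @export
foldVariance <- function(x_obs, model, a_sup) {
  x_null <- nullExpectation(model, a_sup)
  n <- max(length(x_obs), length(x_null))
  x_obs <- rep_len(x_obs, n)
  x_null <- rep_len(x_null, n)
  if (any(x_null == 0))
    warning("null expectation is zero; fold variance undefined (NA)")
  ifelse(x_null == 0, NA_real_, x_obs / x_null - 1)
}

#' Suppression coefficient: slope of fold variance versus supplement
#'
#' Ordinary least-squares regression of the fold variance on the supplement
#' concentration over the titration. The slope is the relative molar
#' suppression coefficient (fold variance per mM supplement); the squared
#' Pearson correlation of the regression is reported with it.
#'
#' @param a_sup supplement concentrations (mM); at least 3 distinct values
#'   including 0.
#' @param x_var fold variances at those concentrations.
#' @return list with `slope`, `r_squared`, `n_points`.
#' @examples
#' suppressionCoefficient(c(0, 5, 10), c(0, -0.5, -1))  # slope -0.1, R2 1
#' @export
suppressionCoefficient <- function(a_sup, x_var) {
  ok <- is.finite(a_sup) & is.finite(x_var)
  a_sup <- a_sup[ok]; x_var <- x_var[ok]
  if (length(unique(a_sup)) < 2L)
    stop("all supplement concentrations identical; slope undefined")
  if (length(unique(a_sup)) < 3L || !any(a_sup == 0))
    stop("need >= 3 distinct supplement levels including 0")
  fit <- stats::lm(x_var ~ a_sup)
  r2 <- if (stats::var(x_var) == 0) {
    # flat response: the fit is exact, define R2 = 1 (slope 0)
    1
  } else stats::cor(a_sup, x_var)^2
  list(slope = unname(stats::coef(fit)["a_sup"]),
       r_squared = r2,
       n_points = length(a_sup))
}

#' Two-sample t test for metabolite replicates
#'
#' Pooled-variance Student's t test by default (the convention of the
#' study's supplementary tables), Welch's test selectable. Two-sided
#' p values. The degenerate zero-variance case is resolved explicitly:
#' equal constant samples give t = 0, p = 1.
#'
#' @param a,b numeric replicate vectors, each n >= 2.
#' @param kind `"student_pooled"` (default) or `"welch"`.
#' @return list with `t_statistic`, `p_value`, `df`, `test_kind`.
#' @export
metaboliteTTest <- function(a, b, kind = c("student_pooled", "welch")) {
  kind <- match.arg(kind)
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t_statistic = 0, p_value = 1,
                  df = length(a) + length(b) - 2, test_kind = kind))
    return(list(t_statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = length(a) + length(b) - 2, test_kind = kind))
  }
  tt <- stats::t.test(a, b, var.equal = (kind == "student_pooled"))
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), test_kind = kind)
}

#' Pooled t test from summary statistics
#'
#' For published tables reporting mean, SD and n per group (e.g.
#' doubling-time or pH tables) rather than raw replicates.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @param kind `"student_pooled"` or `"welch"`.
#' @return list with `t_statistic`, `p_value`, `df`, `test_kind`.
#' @export
tTestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2,
                             kind = c("student_pooled", "welch")) {
  kind <- match.arg(kind)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (kind == "student_pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  if (se == 0)
    return(list(t_statistic = if (mean1 == mean2) 0 else
                  sign(mean1 - mean2) * Inf,
                p_value = as.numeric(mean1 != mean2) * 0 + (mean1 == mean2),
                df = df, test_kind = kind))
  t <- (mean1 - mean2) / se
  list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df,
       test_kind = kind)
}

#' Suppression-coefficient table over an acetate titration
#'
#' For each metabolite: the control mean defines the null model (additive
#' for acetate itself, constant for everything else), per-treatment means
#' give one fold-variance point per acetate level (per-treatment means, not
#' per replicate), and the OLS slope over the titration is the suppression
#' coefficient. Metabolites missing from any treatment are excluded with a
#' warning. Rows are sorted by slope magnitude (largest suppression first).
#'
#' @param x a [SecretionExperiment] with an acetate titration (>= 3 acetate
#'   levels including the control; formate-containing treatments are
#'   ignored).
#' @param supplemented name of the supplemented metabolite (additive null),
#'   default `"acetate"`.
#' @return `data.frame` with columns `metabolite`, `slope`, `r_squared`,
#'   `n_points`.
#' @export
suppressionTable <- function(x, supplemented = "acetate") {
  stopifnot(is(x, "SecretionExperiment"))
  tr <- treatments(x)
  tr <- tr[tr$formate_mM == 0, ]
  levels_ <- sort(unique(tr$acetate_mM))
  if (length(levels_) < 3L)
    stop("need an acetate titration with >= 3 levels including the control")
  ctrl <- controlTreatment(x)
  means <- lapply(tr$treatment, function(t) profileMeans(x, t, na.rm = FALSE))
  names(means) <- tr$treatment
  x_init <- means[[ctrl]]

  out <- list()
  for (m in rownames(x)) {
    obs <- vapply(tr$treatment, function(t) means[[t]][m], numeric(1))
    if (anyNA(obs) || is.na(x_init[m])) {
      warning("metabolite '", m, "' missing from a treatment; excluded")
      next
    }
    nm <- nullModel(m, x_init[m], additive_supplement = (m == supplemented))
    xv <- foldVariance(obs, nm, tr$acetate_mM)
    sc <- suppressionCoefficient(tr$acetate_mM, xv)
    out[[m]] <- data.frame(metabolite = m, slope = sc$slope,
                           r_squared = sc$r_squared, n_points = sc$n_points)
  }
  if (!length(out)) stop("no metabolite present in every treatment")
  tab <- do.call(rbind, out)
  tab <- tab[order(-abs(tab$slope)), ]
  rownames(tab) <- NULL
  tab
}

#' Per-metabolite significance tests against a reference treatment
#'
#' @param x a [SecretionExperiment].
#' @param reference reference treatment label (default the control).
#' @param kind t-test variant, see [metaboliteTTest()].
#' @param adjust p-value adjustment method (`"none"` by default, matching
#'   the study's tables; `"BH"` enables Benjamini-Hochberg).
#' @return `data.frame` with columns `metabolite`, `treatment`, `reference`,
#'   `t_statistic`, `p_value`, `test_kind` (plus `p_adjusted` when
#'   `adjust != "none"`).
#' @export
testTable <- function(x, reference = controlTreatment(x),
                      kind = "student_pooled", adjust = "none") {
  conc <- assay(x, "concentration")
  cd <- colData(x)
  others <- setdiff(unique(cd$treatment), reference)
  out <- list()
  for (tr in others) {
    for (m in rownames(conc)) {
      a <- conc[m, cd$treatment == reference]; a <- a[!is.na(a)]
      b <- conc[m, cd$treatment == tr]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) next
      tt <- metaboliteTTest(a, b, kind = kind)
      out[[length(out) + 1L]] <- data.frame(
        metabolite = m, treatment = tr, reference = reference,
        t_statistic = tt$t_statistic, p_value = tt$p_value,
        test_kind = tt$test_kind)
    }
  }
  tab <- do.call(rbind, out)
  if (adjust != "none") tab$p_adjusted <- stats::p.adjust(tab$p_value, adjust)
  tab
}
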