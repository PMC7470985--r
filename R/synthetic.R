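#' Configuration of the synthetic-data generator
#'
#' The generator emulates the acetate-titration study design: acetate
#' levels \{0, 0.5, 1, 5, 10\} mM, 5 biological x 5 technical replicates
#' (25 pooled replicates per treatment), multiplicative Gaussian
#' concentration noise, and baseline (control) secretion means anchored to
#' the measured control concentrations: acetate 6.6 mM, lactate 0.120 mM,
#' histidine 0.101 mM, cysteine 0.242 mM, cystine 0.209 mM, glutathione
#' 0.121 mM. Baselines for succinate (2.0), formate (0.3), propionate
#' (0.2), asparagine (0.10) and alanine (0.15 mM) are order-of-magnitude
#' placeholders consistent with the reported abundance ordering, NOT
#' measured values.
#'
#' Default suppression slopes (fold variance per mM acetate) follow the
#' relative magnitude ladder of the measured suppression coefficients,
#' rescaled by 0.095 so that the strongest response (alanine) approaches
#' but does not cross complete suppression (fold variance -1) at the top
#' 10 mM dose; without this rescaling the linear fold-variance model would
#' predict physically impossible negative concentrations mid-titration.
#'
#' @param baseline_means named numeric control means (mM).
#' @param suppression_slopes named numeric fold-variance slopes (per mM).
#' @param scenario_b named numeric regulatory (quadratic) coefficients in
#'   mM per mM^2; default all zero (pure feedback, no regulation).
#' @param noise_cv coefficient of variation of replicate noise.
#' @param n_biological,n_technical replicate structure (pooled flat).
#' @param acetate_levels acetate titration levels (mM).
#' @param formate_flag also generate the 10 mM formate and 10 mM acetate +
#'   10 mM formate treatments.
#' @param glucose_consumed_mM,od_final consumed glucose and final OD of the
#'   control culture; defaults calibrated so the control glucose-balance
#'   flux map leaves a CO2 remainder of about 4.6%.
#' @param od_noise_cv OD measurement noise for growth curves.
#' @param doubling_times named numeric true doubling times (h) per
#'   treatment label; defaults to [referenceDoublingTimes()].
#' @param seed integer seed.
#' @return a list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(
    baseline_means = c(acetate = 6.6, succinate = 2.0, formate = 0.3,
                       propionate = 0.2, lactate = 0.120,
                       histidine = 0.101, cysteine = 0.242,
                       cystine = 0.209, glutathione = 0.121,
                       asparagine = 0.10, alanine = 0.15),
    suppression_slopes = 0.095 * c(
      acetate = -0.00535, formate = -0.05783, succinate = -0.01478,
      propionate = -0.07022, cysteine = -0.28908, cystine = -0.33741,
      glutathione = -0.57522, lactate = -0.57985, histidine = -0.68781,
      asparagine = -0.78083, alanine = -1.00662),
    scenario_b = NULL,
    noise_cv = 0.08,
    n_biological = 5L, n_technical = 5L,
    acetate_levels = c(0, 0.5, 1, 5, 10),
    formate_flag = FALSE,
    glucose_consumed_mM = 6.70, od_final = 0.5,
    od_noise_cv = 0.02,
    doubling_times = NULL,
    seed = 1L) {
  if (noise_cv < 0 || od_noise_cv < 0) stop("noise cv must be >= 0")
  if (n_biological < 1L || n_technical < 1L)
    stop("replicate counts must be >= 1")
  if (!0 %in% acetate_levels)
    stop("acetate_levels must include the 0 mM control")
  if (is.null(scenario_b))
    scenario_b <- stats::setNames(numeric(length(baseline_means)),
                                  names(baseline_means))
  if (is.null(doubling_times)) {
    ref <- referenceDoublingTimes()
    doubling_times <- stats::setNames(ref$doubling_time_h, ref$treatment)
  }
  structure(list(baseline_means = baseline_means,
                 suppression_slopes = suppression_slopes,
                 scenario_b = scenario_b,
                 noise_cv = noise_cv,
                 n_biological = as.integer(n_biological),
                 n_technical = as.integer(n_technical),
                 acetate_levels = acetate_levels,
                 formate_flag = isTRUE(formate_flag),
                 glucose_consumed_mM = glucose_consumed_mM,
                 od_final = od_final, od_noise_cv = od_noise_cv,
                 doubling_times = doubling_times,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Generate a synthetic secretion experiment with known ground truth
#'
#' Per metabolite m and acetate level A the expected concentration is the
#' null expectation (control baseline; baseline + A for acetate itself)
#' scaled by the configured feedback response:
#' mean(m, A) = max(0, x_null * (1 + s_m A + b_m A^2)), i.e. the true fold
#' variance is linear (plus an optional quadratic regulatory term) in the
#' supplement. Replicates receive multiplicative Gaussian noise with the
#' configured cv; negative draws are clamped to 0 and counted.
#'
#' @param config a `GeneratorConfig` (see [generatorConfig()]).
#' @return a [SecretionExperiment] whose `metadata()` carries
#'   `ground_truth` (the config) and `clamp_count` / `clamp_fraction`.
#' @export
generateProfiles <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  mets <- names(config$baseline_means)
  registry <- defaultRegistry()
  unknown <- setdiff(mets, registry$metabolite)
  if (length(unknown))
    stop("config names unregistered metabolite(s): ",
         paste(unknown, collapse = ", "))
  design <- data.frame(acetate_mM = config$acetate_levels, formate_mM = 0)
  if (config$formate_flag)
    design <- rbind(design, data.frame(acetate_mM = c(0, 10),
                                       formate_mM = c(10, 10)))
  n_rep <- config$n_biological * config$n_technical
  n_samples <- nrow(design) * n_rep
  conc <- matrix(NA_real_, length(mets), n_samples,
                 dimnames = list(mets, NULL))
  acetate_mM <- numeric(n_samples)
  formate_mM <- numeric(n_samples)
  sample_ids <- character(n_samples)
  clamp_count <- 0L

  withSeed(fanOutSeed(config$seed, "profiles"), {
    col <- 0L
    for (i in seq_len(nrow(design))) {
      A <- design$acetate_mM[i]
      Fo <- design$formate_mM[i]
      means <- vapply(mets, function(m) {
        x_init <- config$baseline_means[[m]]
        x_null <- x_init + (m == "acetate") * A + (m == "formate") * Fo
        resp <- 1 + config$suppression_slopes[[m]] * A +
          config$scenario_b[[m]] * A^2
        max(0, x_null * resp)
      }, numeric(1))
      for (r in seq_len(n_rep)) {
        col <- col + 1L
        draws <- means * (1 + config$noise_cv * stats::rnorm(length(means)))
        clamp_count <- clamp_count + sum(draws < 0)
        conc[, col] <- pmax(draws, 0)
        acetate_mM[col] <- A
        formate_mM[col] <- Fo
        sample_ids[col] <- sprintf("s%03d", col)
      }
    }
  })
  colnames(conc) <- sample_ids
  se <- SecretionExperiment(conc, acetate_mM = acetate_mM,
                            formate_mM = formate_mM, registry = registry)
  S4Vectors::metadata(se) <- list(
    ground_truth = config,
    clamp_count = clamp_count,
    clamp_fraction = clamp_count / length(conc))
  se
}

#' Generate synthetic OD600 growth curves with known doubling times
#'
#' Exponential curves OD(t) = OD0 * 2^(t / Td) capped at the configured
#' final OD (stationary plateau), with multiplicative observation noise on
#' OD. On the default 0-6 h grid the curves stay in exponential phase;
#' extending `times` runs them into the plateau (useful for exercising the
#' exponential-window auto-selection). True doubling times per treatment
#' come from the config (by default the reference supplementation series,
#' whose acetate response is parabolic in dose with a mid-titration
#' maximum).
#'
#' @param config a `GeneratorConfig`.
#' @param times sampling times (hours).
#' @param od0 inoculation OD.
#' @param n_replicates biological replicates per treatment.
#' @return `data.frame` with columns `treatment`, `replicate`, `time`,
#'   `od600`, with the true doubling times attached as attribute
#'   `ground_truth`.
#' @export
generateGrowth <- function(config = generatorConfig(),
                           times = seq(0, 6, by = 0.5), od0 = 0.02,
                           n_replicates = 6L) {
  stopifnot(inherits(config, "GeneratorConfig"))
  td <- config$doubling_times
  out <- withSeed(fanOutSeed(config$seed, "growth"), {
    rows <- list()
    for (tr in names(td)) {
      for (r in seq_len(n_replicates)) {
        od <- pmin(od0 * 2^(times / td[[tr]]), config$od_final)
        od <- od * (1 + config$od_noise_cv * stats::rnorm(length(od)))
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr, replicate = r, time = times, od600 = od)
      }
    }
    do.call(rbind, rows)
  })
  attr(out, "ground_truth") <- td
  out
}
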