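#' Doubling time from an OD600 growth curve
#'
#' Ordinary least squares of ln(OD) on time over the exponential window;
#' the population doubling time is Td = ln(2) / slope. With
#' `window = "auto"` the exponential window is chosen as the maximal
#' contiguous span of points (all OD > 0, >= 3 points) whose log-linear fit
#' reaches R^2 >= 0.99; ties go to the earlier window with more points.
#' The estimate is invariant to rescaling all OD values by a positive
#' constant.
#'
#' @param times time points (hours), strictly increasing.
#' @param od600 optical densities at 600 nm.
#' @param window `"auto"` or a numeric `c(t_min, t_max)` interval.
#' @param min_r_squared R^2 threshold for the auto window, default 0.99.
#' @return list with `doubling_time_h`, `growth_rate` (1/h), `r_squared`,
#'   `window` (time interval used), `n_points`.
#' @examples
#' doublingTime(0:3, c(1, 2, 4, 8))$doubling_time_h  # exactly 1
#' @export
doublingTime <- function(times, od600, window = "auto",
                         min_r_squared = 0.99) {
  stopifnot(length(times) == length(od600))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (is.numeric(window)) {
    sel <- which(times >= window[1] & times <= window[2] & od600 > 0)
    if (length(sel) < 3L) stop("fewer than 3 positive-OD points in window")
    win <- range(times[sel])
  } else {
    sel <- autoWindow(times, od600, min_r_squared)
    if (is.null(sel))
      stop("no contiguous window of >= 3 points reaches R^2 >= ",
           min_r_squared, " (no exponential phase found)")
    win <- range(times[sel])
  }
  t_w <- times[sel]
  y <- log(od600[sel])
  fit <- stats::lm(y ~ t_w)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("non-positive growth rate in window: no growth")
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(t_w, y)^2
  list(doubling_time_h = log(2) / slope, growth_rate = slope,
       r_squared = r2, window = win, n_points = length(sel))
}

autoWindow <- function(times, od600, min_r_squared) {
  n <- length(times)
  best <- NULL
  best_span <- -Inf
  best_np <- 0L
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      sel <- i:j
      if (any(od600[sel] <= 0)) next
      y <- log(od600[sel])
      if (stats::var(y) == 0) next
      r2 <- stats::cor(times[sel], y)^2
      if (r2 < min_r_squared) next
      span <- times[j] - times[i]
      np <- j - i + 1L
      if (span > best_span + 1e-12 ||
          (abs(span - best_span) <= 1e-12 && np > best_np)) {
        best <- sel; best_span <- span; best_np <- np
      }
    }
  }
  best
}

#' Biomass dry weight from optical density
#'
#' Biomass and OD600 correlate linearly in defined medium; the default
#' conversion coefficient is 0.54 g dry weight per OD unit per liter.
#'
#' @param od600 optical density (>= 0).
#' @param coefficient g dry weight per OD per liter.
#' @return biomass dry weight (g/L).
#' @examples
#' biomassFromOD(1)    # 0.54 g/L
#' biomassFromOD(2)    # 1.08 g/L
#' @export
biomassFromOD <- function(od600, coefficient = 0.54) {
  if (any(od600 < 0)) stop("od600 must be >= 0")
  od600 * coefficient
}

#' Dose-response fit of doubling time versus supplement concentration
#'
#' Least-squares fit of a response (typically doubling time, hours) against
#' supplement dose (mM): `"linear"` (degree-1) or `"parabolic"` (degree-2
#' polynomial; the non-monotone doubling-time response to acetate peaks at
#' an intermediate dose, which a line cannot represent).
#'
#' @param doses supplement concentrations (mM); >= 3 distinct values
#'   (parabolic: >= 4).
#' @param responses response values (same length).
#' @param model `"parabolic"` (default) or `"linear"`.
#' @return list with `model`, `coefficients` (intercept-first), `r_squared`,
#'   `fitted`, and for parabolic fits `peak_dose` (vertex location).
#' @export
doseResponse <- function(doses, responses, model = c("parabolic", "linear")) {
  model <- match.arg(model)
  stopifnot(length(doses) == length(responses))
  ndist <- length(unique(doses))
  need <- if (model == "parabolic") 4L else 3L
  if (ndist < need)
    stop(sprintf("%s fit needs >= %d distinct doses (got %d)",
                 model, need, ndist))
  fit <- if (model == "parabolic")
    stats::lm(responses ~ doses + I(doses^2))
  else stats::lm(responses ~ doses)
  cf <- unname(stats::coef(fit))
  # R^2 computed directly (summary() warns on numerically perfect fits)
  tss <- sum((responses - mean(responses))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  out <- list(model = model, coefficients = cf, r_squared = r2,
              fitted = unname(stats::fitted(fit)))
  if (model == "parabolic" && cf[3] != 0)
    out$peak_dose <- -cf[2] / (2 * cf[3])
  out
}

#' Doubling times for a set of growth curves
#'
#' @param curves `data.frame` with columns `time`, `od600`, `treatment`
#'   and optionally `replicate`.
#' @param ... passed to [doublingTime()].
#' @return `data.frame` with columns `treatment`, `replicate`,
#'   `doubling_time_h`, `r_squared`.
#' @export
doublingTimeTable <- function(curves, ...) {
  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  out <- list()
  for (tr in unique(curves$treatment)) {
    for (rep_ in unique(curves$replicate[curves$treatment == tr])) {
      sub <- curves[curves$treatment == tr & curves$replicate == rep_, ]
      sub <- sub[order(sub$time), ]
      dt <- doublingTime(sub$time, sub$od600, ...)
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, replicate = rep_,
        doubling_time_h = dt$doubling_time_h, r_squared = dt$r_squared)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Reference doubling-time table
#'
#' Doubling times (mean, SD, n = 6) of the acetate/formate supplementation
#' series used to parameterize the growth-curve generator, shipped as plain
#' TSV.
#'
#' @return `data.frame` with columns `treatment`, `acetate_mM`,
#'   `formate_mM`, `doubling_time_h`, `sd`, `n`.
#' @export
referenceDoublingTimes <- function() {
  readTsv(extdata("reference_doubling_times.tsv"))
}
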