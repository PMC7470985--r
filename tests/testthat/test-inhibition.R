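test_that("secretion delta subtracts the control concentration", {
  expect_equal(secretionDelta(10.81, 6.6), 4.21)
  expect_equal(secretionDelta(5, 5), 0)
  expect_equal(secretionDelta(0, 0.12), -0.12)
  expect_error(secretionDelta(-1, 0), ">= 0")
  expect_error(secretionDelta(Inf, 0), "finite")
  # control identity over a grid
  x <- seq(0, 20, by = 0.5)
  expect_equal(secretionDelta(x, x), rep(0, length(x)))
})

test_that("additive null model reproduces the expected supplemented concentration", {
  ac <- nullModel("acetate", 6.6, additive_supplement = TRUE)
  expect_equal(nullExpectation(ac, 10), 16.60)
  expect_equal(nullExpectation(ac, 0), 6.6)
  fo <- nullModel("formate", 0.5, additive_supplement = FALSE)
  expect_equal(nullExpectation(fo, 10), 0.5)
  expect_error(nullExpectation(ac, -1), ">= 0")
})

test_that("fold variance measures relative deviation from the null", {
  ac <- nullModel("acetate", 6.6, additive_supplement = TRUE)
  expect_equal(foldVariance(16.60, ac, 10), 0)
  expect_equal(foldVariance(10.81, ac, 10), 10.81 / 16.60 - 1)
  expect_equal(round(foldVariance(10.81, ac, 10), 4), -0.3488)
  expect_equal(foldVariance(0, ac, 10), -1)
  zero <- nullModel("lactate", 0)
  expect_warning(xv <- foldVariance(1, zero, 5), "undefined")
  expect_true(is.na(xv))
  # monotone increasing in x_obs at fixed null
  xs <- seq(0, 30, by = 0.5)
  xv <- foldVariance(xs, ac, 10)
  expect_true(all(diff(xv) > 0))
})

test_that("suppression coefficient is the OLS slope of fold variance on dose", {
  r <- suppressionCoefficient(c(0, 5, 10), c(0, -0.5, -1))
  expect_equal(r$slope, -0.1)
  expect_equal(r$r_squared, 1)
  r0 <- suppressionCoefficient(c(0, 5, 10), c(0, 0, 0))
  expect_equal(r0$slope, 0)
  expect_error(suppressionCoefficient(c(5, 5, 5), c(0, 1, 2)), "identical")
  expect_error(suppressionCoefficient(c(1, 2), c(0, 1)), "3 distinct")
})

test_that("OLS slope and R2 agree with a brute-force normal-equations oracle", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    a <- c(0, sort(runif(n - 1, 0.1, 10)))
    y <- -0.3 * a + rnorm(n, sd = 0.2)
    r <- suppressionCoefficient(a, y)
    # brute force: solve X'X beta = X'y
    X <- cbind(1, a)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(r$slope, unname(beta[2, 1]), tolerance = 1e-10)
    ybar <- mean(y)
    r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - ybar)^2)
    expect_equal(r$r_squared, r2, tolerance = 1e-10)
  }
})

test_that("pooled t test matches its closed form and handles degenerate input", {
  same <- metaboliteTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  r <- metaboliteTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t_statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$p_value, 0.2878641, tolerance = 1e-6)

  # far-separated samples
  a <- rnorm(10)
  r2 <- metaboliteTTest(a, a + 10 * sd(a))
  expect_lt(r2$p_value, 1e-6)

  # zero variance in both with equal means
  z <- metaboliteTTest(c(2, 2), c(2, 2))
  expect_equal(z$p_value, 1)
  # zero variance, different means
  z2 <- metaboliteTTest(c(2, 2), c(3, 3))
  expect_equal(z2$p_value, 0)

  expect_error(metaboliteTTest(1, c(1, 2)), "n >= 2")
})

test_that("summary-statistic t test equals the raw-data pooled test", {
  set.seed(99)
  a <- rnorm(8, 5, 1); b <- rnorm(6, 6, 1.5)
  raw <- metaboliteTTest(a, b)
  smry <- tTestFromSummary(mean(a), sd(a), length(a),
                           mean(b), sd(b), length(b))
  expect_equal(smry$t_statistic, raw$t_statistic, tolerance = 1e-12)
  expect_equal(smry$p_value, raw$p_value, tolerance = 1e-12)
  raww <- metaboliteTTest(a, b, kind = "welch")
  smryw <- tTestFromSummary(mean(a), sd(a), length(a),
                            mean(b), sd(b), length(b), kind = "welch")
  expect_equal(smryw$p_value, raww$p_value, tolerance = 1e-12)
})

test_that("suppression table recovers the generating slope ordering", {
  cfg <- generatorConfig(seed = 21L)
  se <- generateProfiles(cfg)
  tab <- suppressionTable(se)
  expect_named(tab, c("metabolite", "slope", "r_squared", "n_points"))
  # sorted by slope magnitude
  expect_true(all(diff(abs(tab$slope)) <= 1e-12))
  true_order <- names(sort(abs(cfg$suppression_slopes), decreasing = TRUE))
  expect_identical(tab$metabolite[1:3], true_order[1:3])
  expect_true(all(tab$r_squared >= 0 & tab$r_squared <= 1))
})

test_that("suppression table requires a titration", {
  m <- matrix(runif(10, 1, 2), nrow = 1, dimnames = list("acetate", NULL))
  se <- SecretionExperiment(m, acetate_mM = rep(0, 10),
                            formate_mM = rep(0, 10))
  expect_error(suppressionTable(se), "titration")
})

test_that("a strong suppression slope is recovered within 3 SE on a sub-mM titration", {
  # |slope| = 0.68/mM exceeds complete suppression beyond ~1.5 mM, so the
  # titration must stay in the identifiable range
  levels <- seq(0, 1, by = 0.2)
  cfg <- generatorConfig(baseline_means = c(histidine = 0.101),
                         suppression_slopes = c(histidine = -0.68),
                         noise_cv = 0.1, acetate_levels = levels,
                         seed = 77L)
  se <- generateProfiles(cfg)
  tab <- suppressionTable(se)
  # recompute the regression to get a standard error for the slope
  x_init <- mean(SummarizedExperiment::assay(se)["histidine",
    SummarizedExperiment::colData(se)$treatment == "0 mM"])
  xv <- vapply(treatments(se)$treatment, function(t)
    mean(profileMeans(se, t)["histidine"]) / x_init - 1, numeric(1))
  fit <- stats::lm(xv ~ treatments(se)$acetate_mM)
  se_slope <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(tab$slope - (-0.68)), 3 * se_slope)
})

test_that("test table reports per-metabolite comparisons with optional BH adjustment", {
  se <- makeTinyExperiment(n_rep = 5)
  tt <- testTable(se)
  expect_true(all(tt$p_value >= 0 & tt$p_value <= 1))
  expect_equal(sort(unique(tt$metabolite)),
               c("acetate", "histidine", "lactate"))
  tt_bh <- testTable(se, adjust = "BH")
  expect_true(all(tt_bh$p_adjusted >= tt_bh$p_value - 1e-12))
})
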