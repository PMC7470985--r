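test_that("scenario parameters enforce the sign contracts", {
  expect_s3_class(scenarioParams("additive", a = 0.2), "ScenarioParams")
  expect_error(scenarioParams("additive", a = -0.2), "sign contract")
  expect_error(scenarioParams("feedback_only", a = 0.1), "sign contract")
  expect_error(scenarioParams("synergistic", a = -0.1, b = 0.01),
               "sign contract")
  expect_error(scenarioParams("upregulation", a = 0.1, b = -0.01),
               "sign contract")
  expect_error(scenarioParams("additive", a = 1,
                              time_grid = c(1, 1, 2)), "increasing")
})

test_that("noise-free simulation endpoints follow the response family", {
  fb <- scenarioParams("feedback_only", a = -0.1)
  d <- simulateScenario(fb, c(0, 5, 10))
  ends <- d[d$time == 1, ]
  expect_equal(ends$delta[order(ends$a_sup)], c(0, -0.5, -1))

  add <- scenarioParams("additive", a = 0.2)
  d2 <- simulateScenario(add, c(0, 5, 10))
  e2 <- d2[d2$time == 1, ]
  expect_equal(e2$delta[order(e2$a_sup)], c(0, 1, 2))
  expect_true(all(diff(e2$delta[order(e2$a_sup)]) > 0))

  # balanced: endpoint change is -x_init at every nonzero level (overlap)
  bal <- scenarioParams("balanced", x_init = 0.5)
  d3 <- simulateScenario(bal, c(0, 1, 5, 10))
  e3 <- d3[d3$time == 1 & d3$a_sup > 0, ]
  expect_equal(e3$delta, rep(-0.5, 3))

  expect_error(simulateScenario(fb, c(0, 5), noise_cv = -0.1), ">= 0")
  expect_error(simulateScenario(fb, 5), "2 supplement levels")
})

test_that("endpoint response is exactly linear in dose when b = 0", {
  p <- scenarioParams("feedback_only", a = -0.07)
  d <- simulateScenario(p, c(0, 0.5, 1, 5, 10))
  e <- d[d$time == 1, ]
  expect_equal(stats::cor(e$a_sup, e$delta)^2, 1, tolerance = 1e-12)
})

test_that("identical seeds give identical datasets", {
  p <- scenarioParams("synergistic", a = -0.1, b = -0.01)
  d1 <- simulateScenario(p, c(0, 1, 10), noise_cv = 0.2,
                         n_replicates = 5, seed = 31)
  d2 <- simulateScenario(p, c(0, 1, 10), noise_cv = 0.2,
                         n_replicates = 5, seed = 31)
  expect_identical(d1, d2)
  d3 <- simulateScenario(p, c(0, 1, 10), noise_cv = 0.2,
                         n_replicates = 5, seed = 32)
  expect_false(identical(d1$delta, d3$delta))
})

test_that("classification recovers the generating scenario on simulated data", {
  p <- scenarioParams("feedback_only", a = -0.1)
  d <- simulateScenario(p, c(0, 0.5, 1, 5, 10), noise_cv = 0.05,
                        n_replicates = 25, seed = 4)
  fit <- classifyScenario(d)
  expect_identical(bestScenario(fit), "feedback_only")
  expect_lt(abs(scenarioCoefficients(fit)["a"] + 0.1), 0.02)
  expect_identical(bestScenario(fit),
                   names(which.min(scenarioScores(fit)[
                     c("additive", "feedback_only", "balanced")])))
})

test_that("all-zero deltas classify as additive with a null-effect flag", {
  d <- data.frame(a_sup = rep(c(0, 1, 5, 10), each = 3), delta = 0)
  fit <- classifyScenario(d, x_init = 1)
  expect_identical(bestScenario(fit), "additive")
  expect_true(fit@null_effect)
  expect_equal(unname(scenarioCoefficients(fit)), c(0, 0))
})

test_that("classification needs at least three levels including zero", {
  expect_error(classifyScenario(data.frame(a_sup = c(0, 1), delta = c(0, 1))),
               "3 supplement levels")
  expect_error(classifyScenario(data.frame(a_sup = c(1, 5, 10),
                                           delta = c(1, 2, 3))),
               "including 0")
})

test_that("simulate-classify round trip is reliable across all five scenarios", {
  # scaled-down nightly version of the full discrimination study
  study <- scenarioDiscriminationStudy(n_per_scenario = 20, seed = 8L)
  expect_true(all(study$accuracy >= 0.9))
  expect_identical(sum(study$confusion), 100L)
})
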