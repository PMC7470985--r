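test_that("carbon flux normalizes to percent mole carbon", {
  expect_equal(unname(fluxes(carbonFlux(c(acetate = 1)))), 100)
  fm <- carbonFlux(c(acetate = 1, formate = 1))
  expect_equal(unname(fluxes(fm)["acetate"]), 200 / 3)
  expect_equal(unname(fluxes(fm)["formate"]), 100 / 3)
  # full synthetic control profile sums to exactly 100
  se <- generateProfiles(generatorConfig(seed = 5L))
  fm2 <- carbonFlux(profileMeans(se, "0 mM"))
  expect_lt(abs(sum(fluxes(fm2)) - 100), 1e-9)
  expect_true(all(fluxes(fm2) >= 0))
})

test_that("carbon flux rejects degenerate or unregistered input", {
  expect_error(carbonFlux(c(acetate = 0, formate = 0)), "zero")
  expect_error(carbonFlux(c(unobtainium = 1)), "unregistered")
  expect_error(carbonFlux(c(acetate = NA_real_)), "no measured")
})

test_that("carbon flux is scale- and permutation-invariant and matches a hand oracle", {
  reg <- defaultRegistry()
  set.seed(7)
  for (i in 1:20) {
    mets <- sample(reg$metabolite, sample(2:5, 1))
    x <- stats::setNames(runif(length(mets), 0.01, 10), mets)
    fm <- fluxes(carbonFlux(x, reg))
    # direct hand computation
    cc <- stats::setNames(reg$carbon_count[match(mets, reg$metabolite)], mets)
    oracle <- 100 * x * cc / sum(x * cc)
    expect_equal(fm[mets], oracle[mets], tolerance = 1e-12)
    # scale invariance
    k <- runif(1, 0.1, 50)
    expect_equal(fluxes(carbonFlux(k * x, reg))[mets], fm[mets],
                 tolerance = 1e-12)
    # permutation invariance
    perm <- sample(mets)
    expect_equal(fluxes(carbonFlux(x[perm], reg))[mets], fm[mets],
                 tolerance = 1e-12)
  }
})

test_that("glucose-balance map infers the CO2 remainder", {
  # 1 mM glucose = 6 C; acetate 2 mM (4 C) + formate 1 mM (1 C) leaves 1 C
  fm <- inferCO2(1, c(acetate = 2, formate = 1))
  expect_equal(co2Percent(fm), 100 / 6, tolerance = 1e-12)
  expect_identical(fluxBasis(fm), "glucose_balance")
  expect_lt(abs(sum(fluxes(fm)) + co2Percent(fm) + biomassPercent(fm) - 100),
            1e-9)

  # secreted carbon equal to input carbon: zero CO2
  fm0 <- inferCO2(1, c(acetate = 3))
  expect_equal(co2Percent(fm0), 0)

  # slight overshoot within 10% is clamped with a warning
  expect_warning(fmc <- inferCO2(1, c(acetate = 3.1)), "clamped")
  expect_equal(co2Percent(fmc), 0)
  expect_true(fmc@clamped)

  # >10% overshoot is a mass-balance violation
  expect_error(inferCO2(1, c(acetate = 4)), "mass-balance")
})

test_that("calibrated synthetic control profile leaves a CO2 share near 4.6%", {
  # noise-free profile: checks the calibration itself, not replicate noise
  cfg <- generatorConfig(noise_cv = 0, seed = 3L)
  se <- generateProfiles(cfg)
  gb <- inferCO2(cfg$glucose_consumed_mM, profileMeans(se, "0 mM"),
                 biomass_g_per_L = biomassFromOD(cfg$od_final))
  expect_lt(abs(co2Percent(gb) - 4.6), 0.1)
})

test_that("network export is deterministic and colours changes by direction", {
  se <- generateProfiles(generatorConfig(seed = 9L))
  fm <- carbonFlux(profileMeans(se, "0 mM"))
  changes <- secretionChanges(se, "10 mM Ac")
  g <- networkMap(fm, changes = changes)
  f1 <- tempfile(); f2 <- tempfile()
  exportNetwork(g, f1, "dot")
  exportNetwork(g, f2, "dot")
  expect_identical(readLines(f1), readLines(f2))
  gml <- tempfile()
  exportNetwork(g, gml, "graphml")
  expect_true(any(grepl("graphml", readLines(gml))))
  expect_error(exportNetwork(g, tempfile(), "svg"), "unknown")

  # shading is in [0, 1]
  sh <- igraph::vertex_attr(g, "shading")
  expect_true(all(sh >= 0 & sh <= 1))

  # direction -> colour convention: increase green, decrease red
  ec <- igraph::edge_attr(g, "color")
  chg <- igraph::edge_attr(g, "change")
  expect_true(all(ec[chg == "increase"] == "green"))
  expect_true(all(ec[chg == "decrease"] == "red"))
  expect_true(all(ec[chg == "no_change"] == "gray"))
  # this synthetic dataset suppresses histidine strongly at 10 mM
  expect_identical(unname(changes["histidine"]), "decrease")

  # empty flux annotation: all edges gray
  g0 <- networkMap(NULL)
  expect_true(all(igraph::edge_attr(g0, "color") == "gray"))
})

test_that("per-frame network export writes one deterministic file per time point", {
  fm <- carbonFlux(c(acetate = 2, formate = 1))
  dir1 <- file.path(tempfile(), "frames")
  paths <- exportNetworkFrames(fm, dir1, frames = 3, format = "dot")
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
})
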