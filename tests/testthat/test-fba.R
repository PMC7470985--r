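test_that("shipped curated model validates cleanly and names the key enzymes", {
  m <- bthetaCoreModel()
  expect_identical(nrow(validateModel(m)), 0L)
  required <- c("PYK", "PYC", "POR", "PDH", "ACK", "PTA", "PPDK", "MDH",
                "SDA", "FTHFL", "LDH", "SCS", "AST", "ASPOX", "PFL",
                "ASNS", "ASNA")
  expect_true(all(required %in% reactionIds(m)))
})

test_that("validator flags elemental imbalance and dead ends", {
  m <- makeToyChainModel()
  expect_identical(nrow(validateModel(m)), 0L)
  # unbalance the conversion: 1 C in, 2 C out
  m2 <- m
  m2@reactions$CONV$stoichiometry <- c(A = -1, B = 2)
  rep2 <- validateModel(m2)
  expect_true(any(rep2$check == "elemental_balance" & rep2$item == "CONV"))
  # isolated metabolite
  m3 <- m
  m3@metabolites <- rbind(m3@metabolites, data.frame(
    id = "orphan", name = "orphan", compartment = "internal",
    carbon = 1, nitrogen = 0))
  rep3 <- validateModel(m3)
  expect_true(any(rep3$check == "dead_end" & rep3$item == "orphan"))
})

test_that("FBA solves bound-limited toy problems exactly", {
  m <- makeToyChainModel(uptake_bound = 2)
  res <- solveFBA(m)
  expect_identical(fbaStatus(res), "optimal")
  expect_equal(objectiveValue(res), 2)
  # empty media: nothing in, nothing grows
  res0 <- solveFBA(bthetaCoreModel(), mediaSpec())
  expect_equal(objectiveValue(res0), 0)
})

test_that("steady state holds at every reported optimum", {
  m <- bthetaCoreModel()
  S <- stoichiometryMatrix(m)
  for (media in list(mediaSpec(glucose = 2.78),
                     mediaSpec(glucose = 0.1, acetate = 10),
                     mediaSpec(glucose = 2.78, acetate = 10, formate = 10))) {
    res <- solveFBA(m, media)
    expect_identical(fbaStatus(res), "optimal")
    expect_lt(max(abs(S %*% reactionFluxes(res))), 1e-9)
    # bounds respected under the applied media
    m_med <- secflux:::applyMedia(m, media)
    lb <- vapply(m_med@reactions, `[[`, numeric(1), "lb")
    ub <- vapply(m_med@reactions, `[[`, numeric(1), "ub")
    v <- reactionFluxes(res)[names(lb)]
    expect_true(all(v >= lb - 1e-9))
    expect_true(all(v <= ub + 1e-9))
  }
})

test_that("objective is monotone under bound relaxation", {
  m <- bthetaCoreModel()
  base <- objectiveValue(solveFBA(m, mediaSpec(glucose = 1)))
  half <- objectiveValue(solveFBA(m, mediaSpec(glucose = 0.5)))
  expect_lte(half, base + 1e-9)
  more <- objectiveValue(solveFBA(m, mediaSpec(glucose = 2)))
  expect_gte(more, base - 1e-9)
})

test_that("knockouts fix bounds to zero and propagate to the objective", {
  m <- bthetaCoreModel()
  expect_error(knockout(m, "NOT_A_REACTION"), "unknown reaction")
  expect_equal(objectiveValue(solveFBA(knockout(m, "BIOMASS"),
                                       mediaSpec(glucose = 2.78))), 0)
  # deleting both asparagine routes abolishes growth (asparagine is a
  # biomass component with no third route)
  both <- solveFBA(knockout(m, c("ASNS", "ASNA")), mediaSpec(glucose = 2.78))
  expect_equal(objectiveValue(both), 0)
})

test_that("either asparagine route alone sustains identical exchange fluxes", {
  m <- bthetaCoreModel()
  for (media in list(mediaSpec(glucose = 2.78),
                     mediaSpec(glucose = 2.78, acetate = 10),
                     mediaSpec(glucose = 2.78, formate = 10))) {
    base <- solveFBA(m, media)
    for (ko in c("ASNS", "ASNA")) {
      alt <- solveFBA(knockout(m, ko), media)
      expect_equal(objectiveValue(alt), objectiveValue(base),
                   tolerance = 1e-9)
      expect_lt(max(abs(exchangeFluxes(alt) - exchangeFluxes(base))), 1e-9)
    }
  }
})

test_that("high-glucose grid is biomass-invariant and reproducible", {
  m <- bthetaCoreModel()
  g1 <- mediaGrid(m)
  hg <- g1$objectives[grep("^high", names(g1$objectives))]
  expect_length(hg, 4)
  expect_lt(max(hg) - min(hg), 1e-9)
  # low glucose grows strictly slower
  expect_lt(g1$objectives[["low_glucose"]], min(hg))
  # two grid runs are bit-identical
  g2 <- mediaGrid(m)
  expect_identical(g1$objectives, g2$objectives)
  expect_identical(lapply(g1$results, reactionFluxes),
                   lapply(g2$results, reactionFluxes))
  # all-zero media: every objective zero
  z <- vapply(g1$conditions$condition, function(cond) 0, numeric(1))
  g0 <- mediaGrid(m, glucose_levels = c(high = 0, low = 0),
                  supplement_uptake = 0)
  expect_true(all(g0$objectives == 0))
})

test_that("flux-delta table labels direction and magnitude changes", {
  m <- bthetaCoreModel()
  a <- solveFBA(m, mediaSpec(glucose = 2.78))
  b <- solveFBA(m, mediaSpec(glucose = 1.0))
  d <- fluxDeltas(a, b)
  expect_setequal(setdiff(unique(d$change), ""),
                  intersect(unique(d$change),
                            c("zero_net", "direction_change", "increased",
                              "decreased", "no_change")))
  expect_identical(d$change[d$reaction == "EX_biomass"], "decreased")
  # self-comparison: nothing changes
  dd <- fluxDeltas(a, a)
  expect_true(all(dd$change %in% c("zero_net", "no_change")))
})

test_that("model JSON round trips through the writer and reader", {
  m <- bthetaCoreModel()
  path <- tempfile(fileext = ".json")
  writeStoichiometricModel(m, path)
  m2 <- readStoichiometricModel(path)
  expect_identical(reactionIds(m2), reactionIds(m))
  expect_identical(stoichiometryMatrix(m2), stoichiometryMatrix(m))
  expect_equal(objectiveValue(solveFBA(m2, mediaSpec(glucose = 2.78))),
               objectiveValue(solveFBA(m, mediaSpec(glucose = 2.78))))
})

test_that("infeasible forced uptake is reported, not mis-solved", {
  m <- makeToyChainModel()
  # force flux through CONV above the uptake bound
  m@reactions$CONV$lb <- 5
  res <- solveFBA(m)
  expect_identical(fbaStatus(res), "infeasible")
  expect_length(reactionFluxes(res), 0)
})
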