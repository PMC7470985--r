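test_that("default registry holds the detected secreted set with standard carbon counts", {
  reg <- defaultRegistry()
  expected <- c(acetate = 2, succinate = 4, formate = 1, propionate = 3,
                lactate = 3, histidine = 6, cysteine = 3, cystine = 6,
                glutathione = 10, asparagine = 4, alanine = 3)
  expect_setequal(reg$metabolite, names(expected))
  expect_equal(carbonCounts(names(expected)),
               stats::setNames(as.integer(expected), names(expected)))
  expect_true(all(reg$carbon_count >= 1))
  expect_true(all(reg$secreted))
})

test_that("loadProfiles parses treatments, units, and flags the control", {
  path <- writeProfileFixture(c(
    "sample\tacetate_mM\tformate_mM\tacetate\tglutathione_uM",
    "s1\t0\t0\t6.6\t121",
    "s2\t10\t0\t10.81\t80"))
  se <- loadProfiles(path)
  expect_s4_class(se, "SecretionExperiment")
  expect_identical(controlTreatment(se), "0 mM")
  # micromolar column converted to mM at the boundary
  expect_equal(unname(SummarizedExperiment::assay(se)["glutathione", "s1"]),
               0.121)
  tr <- treatments(se)
  expect_equal(nrow(tr), 2)
  expect_equal(sort(tr$acetate_mM), c(0, 10))
})

test_that("loadProfiles rejects malformed input with informative errors", {
  no_control <- writeProfileFixture(c(
    "sample\tacetate_mM\tformate_mM\tacetate",
    "s1\t10\t0\t10.8"))
  expect_error(loadProfiles(no_control), "control")

  negative <- writeProfileFixture(c(
    "sample\tacetate_mM\tformate_mM\tacetate",
    "s1\t0\t0\t6.6",
    "s2\t10\t0\t-1"))
  expect_error(loadProfiles(negative), "s2")

  unknown_met <- writeProfileFixture(c(
    "sample\tacetate_mM\tformate_mM\tcaffeine",
    "s1\t0\t0\t1"))
  expect_error(loadProfiles(unknown_met), "unknown metabolite")

  bad_unit <- writeProfileFixture(c(
    "sample\tacetate_mM\tformate_mM\tacetate_nM",
    "s1\t0\t0\t1"))
  expect_error(loadProfiles(bad_unit), "unit|unknown")
})

test_that("write/load round trip reproduces every value bit-exactly", {
  se <- makeTinyExperiment()
  path <- tempfile(fileext = ".tsv")
  writeProfiles(se, path)
  se2 <- loadProfiles(path)
  expect_identical(SummarizedExperiment::assay(se, "concentration"),
                   SummarizedExperiment::assay(se2, "concentration"))
  expect_equal(as.data.frame(SummarizedExperiment::colData(se)),
               as.data.frame(SummarizedExperiment::colData(se2)))
})

test_that("summary statistics use the pooled mean and n-1 standard deviation", {
  m <- matrix(c(1, 1, 1, 1), nrow = 1, dimnames = list("acetate", NULL))
  se <- SecretionExperiment(m, acetate_mM = rep(0, 4), formate_mM = rep(0, 4))
  s <- summarizeMetabolite(se, "0 mM", "acetate")
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)

  m2 <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("acetate", NULL))
  se2 <- SecretionExperiment(m2, acetate_mM = rep(0, 3), formate_mM = rep(0, 3))
  s2 <- summarizeMetabolite(se2, "0 mM", "acetate")
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, 1)
  expect_equal(s2$n, 3)
})

test_that("generator control mean lands within Monte-Carlo bounds of its target", {
  # 25 draws at mean 6.6, cv 0.08: mean within 3 * 0.528 / sqrt(25)
  se <- generateProfiles(generatorConfig(seed = 2024L))
  m <- summarizeMetabolite(se, "0 mM", "acetate")
  expect_equal(m$n, 25)
  expect_lt(abs(m$mean - 6.6), 3 * (6.6 * 0.08) / sqrt(25))
})

test_that("validity rejects negative concentrations and duplicated controls", {
  m <- matrix(6.6, 1, 1, dimnames = list("acetate", "s1"))
  expect_error(SecretionExperiment(m, acetate_mM = 10, formate_mM = 0),
               "control")
  m2 <- matrix(-1, 1, 1, dimnames = list("acetate", "s1"))
  expect_error(SecretionExperiment(m2, acetate_mM = 0, formate_mM = 0),
               ">= 0")
})
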