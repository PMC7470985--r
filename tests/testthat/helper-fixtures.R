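# Shared fixtures, all built in code at test time.

# minimal secretion experiment: two treatments x n replicates
makeTinyExperiment <- function(n_rep = 3) {
  set.seed(42)
  mets <- c("acetate", "lactate", "histidine")
  treat <- data.frame(acetate_mM = c(0, 10), formate_mM = c(0, 0))
  conc <- NULL
  acet <- form <- numeric(0)
  for (i in seq_len(nrow(treat))) {
    base <- c(acetate = 6.6, lactate = 0.12, histidine = 0.101)
    if (treat$acetate_mM[i] > 0) base <- base * 0.7 + c(10, 0, 0) * 0.4
    block <- sapply(seq_len(n_rep), function(r)
      base * (1 + 0.05 * rnorm(3)))
    conc <- cbind(conc, block)
    acet <- c(acet, rep(treat$acetate_mM[i], n_rep))
    form <- c(form, rep(treat$formate_mM[i], n_rep))
  }
  rownames(conc) <- mets
  colnames(conc) <- sprintf("s%02d", seq_len(ncol(conc)))
  SecretionExperiment(conc, acetate_mM = acet, formate_mM = form)
}

# write a small profile table to a temp file, returning the path
writeProfileFixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# three-reaction toy chain: uptake (bound 2) -> convert -> biomass
makeToyChainModel <- function(uptake_bound = 2) {
  mets <- data.frame(
    id = c("A_e", "A", "B", "biomass_e"),
    name = c("A external", "A", "B", "biomass"),
    compartment = c("external", "internal", "internal", "external"),
    carbon = c(1, 1, 1, 0), nitrogen = c(0, 0, 0, 0))
  rxns <- list(
    EX_A = list(id = "EX_A", name = "A exchange",
                stoichiometry = c(A_e = -1), reversible = TRUE,
                lb = -uptake_bound, ub = 1000, balance_exempt = TRUE),
    T_A = list(id = "T_A", name = "A uptake",
               stoichiometry = c(A_e = -1, A = 1), reversible = FALSE,
               lb = 0, ub = 1000, balance_exempt = FALSE),
    CONV = list(id = "CONV", name = "convert",
                stoichiometry = c(A = -1, B = 1), reversible = FALSE,
                lb = 0, ub = 1000, balance_exempt = FALSE),
    BIO = list(id = "BIO", name = "biomass",
               stoichiometry = c(B = -1, biomass_e = 1),
               reversible = FALSE, lb = 0, ub = 1000,
               balance_exempt = TRUE),
    EX_BIO = list(id = "EX_BIO", name = "biomass sink",
                  stoichiometry = c(biomass_e = -1), reversible = FALSE,
                  lb = 0, ub = 1000, balance_exempt = TRUE))
  new("StoichiometricModel", id = "toy_chain", metabolites = mets,
      reactions = rxns, objective = "BIO")
}
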