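---
title: "Methods: secretion flux maps, feedback inhibition, and the curated FBA model"
author: "secflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secretion flux maps, feedback inhibition, and the curated FBA model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secflux)
```

This vignette documents the models, statistical procedures and numerical
choices behind `secflux`, in the spirit of a methods section: what each
stage assumes, which parameters matter, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open.

# Data model

A `SecretionExperiment` (a thin `SummarizedExperiment`) holds one
`concentration` assay in mM with metabolites as rows and replicate
samples as columns; `colData` carries the treatment design (`acetate_mM`,
`formate_mM`, a label) and `rowData` the metabolite registry (carbon
count, precursor network node, secreted flag). Three conventions are
worth stating explicitly:

* **Units.** The internal canonical unit is mM. Micromolar values are
  accepted only at the file boundary (column suffix `_uM`) because
  organic acids are conventionally reported in mM and amino acids in µM;
  conversion is a single exact division by 1000.
* **Replicates are pooled flat.** The study design is 5 biological × 5
  technical replicates per treatment (n = 25). Only pooled means ± SD are
  scientifically meaningful downstream, so no nested variance components
  are modelled; the biological/technical split survives only as metadata.
  A consequence: the generator uses one pooled coefficient of variation,
  and nothing in the package can (or claims to) separate the two variance
  sources.
* **Missingness.** A metabolite absent from a treatment table is "not
  measured": it is excluded from flux maps and suppression tables with a
  warning, never imputed as zero. Zero is a measurement (complete
  suppression); absence is not.

# Secretion flux maps

`carbonFlux()` expresses each secreted metabolite as a percent
mole-carbon fraction of total secreted carbon,
$F(x) = 100\,x\,C(x)/\sum_i x_i C(x_i)$. This normalization is exactly
scale-invariant (culture volume, dilution and OD normalization cancel)
and sums to 100 by construction, both enforced as validity invariants at
1e-9. Cystine is counted as one C6 species (the Cys-Cys disulfide), not
two cysteines: it is detected as a distinct species and its carbon should
not be double-assigned.

Because a secreted-only normalization cannot produce a CO₂ term,
the CO₂ share is inferred by a separate carbon balance over consumed
glucose (`inferCO2()`): CO₂ carbon = 6·glucose − secreted carbon −
biomass carbon, with biomass carbon from dry weight × carbon fraction
(default 0.5 g C per g dry weight, a standard bacterial composition
value) and dry weight from OD via 0.54 g·OD⁻¹·L⁻¹ (the measured linear
coefficient for this organism in defined medium; both are arguments).
Both bases are exposed — `secreted_only` and `glucose_balance` — and
every `FluxMap` records which one it used, because published secretion
maps do not always state their denominator. A negative CO₂ remainder
within 10% of input carbon is clamped to zero with a flag (measurement
noise); beyond 10% it is an error (a real mass-balance violation).

One honesty note on calibration: the measured control concentrations are
mutually inconsistent with the nominal 2.78 mM glucose in the medium
(6.6 mM secreted acetate alone is 13.2 C-mmol against 16.7 C-mmol of
glucose carbon, before succinate, amino acids, biomass or CO₂). Real
cultures draw on additional carbon sources. The synthetic control profile
therefore treats the consumed-glucose pool as a free parameter,
calibrated once to 6.70 mM (with final OD 0.5) so that the glucose-balance
map leaves a CO₂ remainder of ≈4.6%, a realistic share for this
fermentation; the package then recomputes that share from the generated
data rather than asserting it.

# Feedback inhibition statistics

The null model for an acetate titration is *additivity*: supplementation
changes nothing, so every metabolite is expected at its control mean, and
the supplemented species itself at control mean + supplement (6.6 mM
secreted + 10 mM added = 16.60 mM). Deviation is quantified as the fold
variance
$$x_{var} = x_{obs}/x_{null} - 1,$$
chosen over alternatives (e.g. absolute deltas) because it is
dimensionless, bounded below by −1 ("all of it missing"), exactly 0 under
the null, and comparable across metabolites whose absolute
concentrations span two orders of magnitude. The observed 10.81 mM
acetate at the 10 mM treatment gives x_var = −0.349.

The **suppression coefficient** is the unweighted OLS slope of x_var on
supplement concentration over the titration, control point included; the
squared Pearson correlation is reported with it. Per-treatment means (not
per-replicate values) are the regression points: the replicate scatter is
measurement noise around a treatment mean, and weighting or multilevel
schemes would add machinery the design (5 points) cannot support.

Two identifiability facts shape defaults and validation:

* With x_var linear in dose and bounded below by −1, a slope s is only
  observable over doses A with |s|·A < 1. The generator's default slopes
  follow the relative magnitude ladder of the observed coefficients but
  are rescaled (factor 0.095) so the strongest responder (alanine) stays
  just short of complete suppression at 10 mM; literal per-mM use of the
  published-scale magnitudes (up to ≈1.0 per mM) would pin most of the
  titration at zero concentration, which no estimator can invert.
* The parameter-recovery study (`suppressionRecoveryStudy()`: 200
  datasets, levels 0/0.5/1/5/10 mM, n = 25, cv = 0.1) uses five true
  slopes spaced 0.02 apart (−0.01 … −0.09). At this noise level the
  slope standard error is ≈0.002, so this ladder is orderable while
  near-ties (real coefficient tables contain pairs differing by <1%) are
  not; exact rank recovery is only a meaningful criterion for separated
  ladders.

Significance testing uses pooled-variance Student's t by default (the
convention of the study's tables), Welch selectable; no multiple-testing
correction by default (again the tables' convention), Benjamini-Hochberg
available. Degenerate zero-variance cases are defined explicitly (equal
constant samples: t = 0, p = 1) rather than left to error.

# Secretion-response scenarios

Five phenomenological hypotheses describe the endpoint response of a
secreted metabolite to supplement dose A: additive (a>0, b=0), balanced
(endpoint change = −x_init at every dose), feedback inhibition without
regulation (a<0, b=0), synergistic feedback with compensatory regulation
(a<0, b<0), and upregulation (a>0, b>0). The direct coefficient a acts at
enzyme level and responds linearly to A; the regulatory coefficient b
represents an adaptation that builds up with the culture itself. Along a
normalized accumulation ramp g(t) (linear by default, configurable —
time is in arbitrary units) the simulated change is
$$\Delta x_{sec}(t, A) = g(t)\,(a A + b A^2 g(t)),$$
so the endpoint (g = 1) is $aA + bA^2$. The quadratic basis for b is a
deliberate design choice: with both terms linear in A the two
coefficients are unidentifiable from endpoint data, and the scenarios
with regulation could never be distinguished from pure feedback. The
sign semantics of the five scenarios are preserved exactly; only the
basis function is pinned down.

`classifyScenario()` works on endpoint values per dose (≥3 levels
including 0): it fits the b = 0 family (Δ = aA) and the b ≠ 0 family
(Δ = aA + bA²) through the origin by least squares with sign
constraints (a two-parameter constrained fit solved exactly by
enumerating the unconstrained optimum and the boundary fits), admits the
quadratic families only if an F test at α = 0.05 finds b significant
*and* its endpoint contribution |b|A²_max exceeds twice the residual
noise (a parsimony guard that keeps the ~5% of F-test false positives
from masquerading as regulation), detects the balanced scenario by its
own zero-parameter profile (endpoint ≈ −x_init at every dose), and
returns the lowest-RSS admitted candidate, ties resolved toward the
simpler family. All-zero data is reported as additive with a = 0 and an
explicit null-effect flag. The Monte-Carlo discrimination study
(`scenarioDiscriminationStudy()`: 200 datasets per scenario, cv = 0.1,
n = 25 per level) is the package's operating characteristic for this
procedure.

# Growth analysis

`doublingTime()` regresses ln(OD) on time and returns ln 2 / slope. The
automatic exponential window is the package's own rule: the maximal
contiguous span of ≥3 positive-OD points whose log-linear R² reaches
0.99, ties to the earlier, denser window. The rule is simple and
assumption-light but knowably imperfect: on a curve that hits stationary
phase abruptly, the maximal-span criterion can admit one plateau point
and bias the estimate by a few percent (the test suite pins this at
<12% for an extreme plateau); on clean exponentials it is exact to
machine precision. Callers who know their exponential phase can pass an
explicit window. Dose-response fits (`doseResponse()`) are plain
polynomial least squares — degree 2 ("parabolic") captures the
non-monotone doubling-time response to acetate that peaks mid-titration
(the fitted vertex of the reference series lies near 5.6 mM); the fit
also reports R² computed directly from residuals.

Growth statistics accept either raw replicates or published-style
summary statistics (mean, SD, n) via `tTestFromSummary()`. The printed
p-values of the reference doubling-time and pH tables are not exactly
reproducible from their printed summary statistics with a standard
pooled t test; the package reports what the standard test gives and does
not chase the discrepancy.

# The curated FBA model

`bthetaCoreModel()` is a ~45-reaction central-carbon fermentation network
— deliberately teaching-scale, not a genome-scale reconstruction.
Glycolysis is lumped to two steps (hexokinase; G6P → 2 PEP), the
pyruvate node is explicit (pyruvate kinase, pyruvate phosphate dikinase,
pyruvate carboxylase, pyruvate dehydrogenase, pyruvate synthase,
pyruvate formate-lyase, lactate dehydrogenase), acetate has both the
Ack/Pta and acetyl-CoA synthetase routes, the reductive TCA branch runs
to succinate with the methylmalonyl route to propionate, a lumped
oxidative branch supplies 2-oxoglutarate, and aspartate-family amino
acid metabolism includes the two asparagine routes. Cofactors (ATP/ADP/
AMP, NAD/NADH, Pi/PPi, THF) are carbon/nitrogen-free currency
metabolites; every non-exempt reaction balances C and N exactly
(`validateModel()` enforces this plus dead-end and bound checks, and the
shipped model passes with zero violations). Phosphate has an exchange
(the growth medium is phosphate-buffered), which matters because
sugar-phosphate carbon leaving in biomass would otherwise drain Pi
irrecoverably.

Three curation choices deserve justification:

* **Glutamine synthetase is lumped without its ATP cost.** Glutamine
  exists in the model purely as the amide-nitrogen donor for asparagine
  synthetase. With GS at zero ATP, the asparagine synthetase route
  (asp + gln + ATP → asn + glu + AMP + PPi, plus GS regenerating gln)
  and aspartate ammonia ligase (asp + NH₃ + ATP → asn + AMP + PPi) have
  *identical net stoichiometry*, making the observed interchangeability
  of the two routes (deleting either leaves objective and exchange
  fluxes unchanged) a structural property of the model rather than an
  accident of which resource happens to be limiting.
* **Aspartate oxidase is shipped as the lumped anaerobic deamination**
  asp + fum → oaa + NH₃ + succ (oxidase plus spontaneous iminoaspartate
  hydrolysis), avoiding a dead-end iminoaspartate node in a model with
  no NAD-biosynthesis sink.
* **High-glucose invariance is structural.** Acetate assimilation costs
  ATP (1 via Ack/Pta, 2 via ACS) while acetyl-CoA from pyruvate via PFL
  is free, and no acetate- or formate-consuming path in this network
  yields net ATP; with biomass ATP-limited under glucose, maximal
  biomass is therefore identical across the four high-glucose
  conditions. The model reproduces the *qualitative* in-silico findings
  (high-glucose invariance, lower growth at low glucose, asparagine
  route interchangeability); the published genome-scale biomass values
  and flux magnitudes are outside its scope, as are effects that require
  forcing supplement uptake rather than merely permitting it.

The LP itself is solved by an internal dense two-phase simplex with
Bland's anti-cycling rule (deterministic; exact steady state to ~1e-15
on the shipped model). FBA optima are routinely degenerate, so a second
lexicographic stage minimizes total absolute flux at the fixed optimal
objective; this removes futile cycles and makes exchange-flux
comparisons between conditions well defined and bit-reproducible. Media
are named maximum-uptake vectors (mmol·gCDW⁻¹·h⁻¹) applied as exchange
lower bounds: high glucose 2.78, low glucose 0.1, supplements 10, the
conventional condition values for this experiment grid.

# Synthetic data generator

`generateProfiles()` emulates the titration design: acetate levels
{0, 0.5, 1, 5, 10} mM (optionally the 10 mM formate and combination
arms), 25 replicates per treatment, and control means anchored to the
measured control concentrations (acetate 6.6 mM, lactate 0.120,
histidine 0.101, cysteine 0.242, cystine 0.209, glutathione 0.121 mM).
Baselines for succinate (2.0), formate (0.3), propionate (0.2),
asparagine (0.10) and alanine (0.15 mM) are order-of-magnitude
placeholders consistent with the reported abundance ordering — they are
**not** measured values. Noise is multiplicative Gaussian
(cv-parameterized, default 0.08 to match the control acetate mean ± SD;
the validation studies use 0.1) because reported SDs scale roughly with
means across the measured concentration range; a constant-SD model would
mis-scale the µM-level amino acids. Negative draws are clamped at zero
and counted; at defaults clamping is absent (<1% is the declared
invariant). Expected concentrations follow the scenario endpoint model
(per-metabolite slope, optional quadratic term), floored at zero.
`generateGrowth()` produces exponential OD curves from per-treatment
true doubling times (default: the reference supplementation series,
control 1.322 h) with multiplicative OD noise (default cv 0.02); the
default 0–6 h sampling grid stays within exponential phase so estimator
inversion is exact, and longer grids deliberately run into the
stationary plateau.

What the generator does **not** emulate: biological-vs-technical
variance structure (unknown, pooled), between-metabolite correlations,
NMR peak overlap or quantification bias, non-Gaussian outliers, and any
kinetic time dependence beyond the abstract accumulation ramp. Passing
tests on synthetic data therefore demonstrate estimator correctness
under the declared noise model, not robustness to every pathology of
real spectra.

# Determinism and problem sizes

All randomness flows from one integer seed, fanned out per stage with a
fixed affine map kept inside 32-bit range. Tables are written with
shortest-round-trip number formatting, so `runPipeline()` bundles are
byte-identical across reruns of the same configuration, and the manifest
(seed, config hash, output checksums — no timestamps) makes that
checkable. The validation studies run at 200 datasets for slope
recovery, 200 per scenario for discrimination, and 100 random bound
relaxations for LP monotonicity — sizes chosen so the full suite
finishes in about a minute while leaving Monte-Carlo margins (binomial
SE ≈ 1.5% at n = 200) well inside the claimed thresholds.

# Known limitations

* Suppression slopes are phenomenological; no enzyme-kinetic (Kᵢ)
  interpretation is attempted.
* The fold-variance regression assumes linearity in dose within the
  identifiable range; saturating titrations (|s|·A_max ≥ 1) violate it
  by construction and need a restricted dose range.
* The balanced scenario is only detectable when the control level
  x_init is known (or estimable from the data's nonzero-dose plateau).
* The exponential-window rule can admit a plateau point (see above).
* The FBA model's low-glucose predictions are qualitative; it contains
  no regulation, no kinetics, and no forced-uptake mechanism, so
  supplement-induced *decreases* in biomass are outside its
  expressiveness.
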