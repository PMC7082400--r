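---
title: "Stoichiometric mass balance of microbial sulfur oxidation"
author: "thiostoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric mass balance of microbial sulfur oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiostoich)
```

## The problem

Acidophilic sulfur oxidisers such as *Acidithiobacillus thiooxidans* grow on
elemental sulfur (S0) or thiosulfate (S2O3^2-) by driving a web of oxidation,
comproportionation and disproportionation reactions whose intermediates
(polythionates, sulfite, colloidal S0 — collectively "SOI", sulfur oxidation
intermediates) are hard to measure individually. Closing the sulfur budget of
a batch culture therefore needs two ingredients this package provides:

1. **A mass balance with an explicit unresolved pool.** Total dissolved
   sulfur (the < 0.45 µm fraction) minus the sum of all individually measured
   species leaves the *Other SOI* pool — sulfur that is demonstrably in
   solution but not speciated. All concentrations are handled in sulfur-atom
   millimolar (mM-S): 1 mM sulfate is 1 mM-S, 1 mM thiosulfate is 2 mM-S, so
   sulfur conservation is a plain sum.
2. **A stoichiometric reaction library in exact arithmetic.** The candidate
   reactions (S0 → sulfite → sulfate; comproportionation S0 + SO3^2- ↔
   S2O3^2-; thiosulfate → tetrathionate → hydrolysis/oxidation; polythionate
   disproportionation back to S0 and sulfite; sulfide oxidation) carry
   fractional coefficients (1/2, 7/2) that must round-trip exactly, so all
   stoichiometry is rational-number arithmetic; floating point enters only in
   the statistical fitting.

## Reaction representation and balancing

Species are represented exactly as the field writes the reactions
(`SO3^2-`, not `H2SO3`, although culture pH < 3): the printed equations are
the normative objects, and adding speciation corrections would change their
coefficients. Elemental sulfur is a single S atom — its ring structure is
irrelevant to atom counting. The unresolved pool enters reactions as the
placeholder `S_OtherSOI`, counted in single-sulfur units; whenever elemental
closure is needed the placeholder is expanded through a **polythionate
proxy**, by default tetrathionate (4 units = 1 molecule of S4O6^2-),
configurable to any SnO6^2- with n = 3..6. Tetrathionate is the natural
default because it is the entry product of thiosulfate oxidation and the
most commonly invoked constituent of the unresolved pool.

`check_balance()` reports exact residuals of S, O, H and charge (products
minus reactants). Species declared *free* (O2, H2O, H+ as reservoirs) are
granted arbitrary signed rational coefficients: the residual is reduced by
its exact rational least-squares projection onto the span of the free
species' element vectors. This zeroes exactly the residual components the
grants can reach and provably leaves the rest — e.g. the net observed
reaction `6 S0 -> 2 SO4^2- + 4 S_OtherSOI + 5 H+` keeps a charge residual of
−1 under free O2/H2O, which is the formal signature of it being a
measurement summary rather than elementary chemistry. The test suite checks
this decision procedure against a brute-force enumeration of rational grants
(denominators up to 2, magnitude up to 8).

`complete_reaction()` solves the 4-row conservation system for unknown
coefficients restricted to H+, O2 and H2O (a negative solution moves the
species to the other side); it reports inconsistent skeletons with their
unremovable residuals and underdetermined ones with the null-space
dimension. Every library reaction is regenerated from its skeleton this way
in the tests.

One library entry needs care: the biotic sulfite oxidation
`SO3^2- + H2O -> SO4^2- + 2 H+` is a **respiratory half-reaction** — as
written it carries a +2 charge residual because the two electrons leave
through the electron-transport chain. Rather than silently accepting a
charge error or rewriting a canonical equation, the registry contains a
charge-only electron species `e-` which that reaction declares as its free
species. This is bookkeeping for one half-reaction, not a model of the
quinone/cytochrome chain (which stays out of scope).

The reversible comproportionation `S0 + SO3^2- <-> S2O3^2-` is stored as two
directed reactions so that fitted extents remain nonnegative.

## From measured changes to reaction extents

For an interval of the time series, `deltas()` assembles the signed changes:
each measured species in mM-S, the proton change from pH (treated as
concentration, `10^-pH`, without activity correction — consistent with how
such data are plotted), and the Other-SOI change by difference. Small
negative Other-SOI values (within 5% of total S by default) are clamped to
zero with a warning; larger deficits are a hard mass-balance error, because
they mean the speciation measurements exceed the total and no inference
should proceed.

`fit_extents()` solves the nonnegative least-squares problem

> minimise ‖W (M x − d)‖² subject to x ≥ 0

where columns of M are library reactions in sulfur-atom units, rows are the
measured species, one aggregate Other-SOI row (all sulfur of species not
individually measured), and optionally the proton row; O2 and H2O are
excluded as reservoirs. Extents x are mM of reaction turnover, so sulfur
closure is the statement that every column sums to zero over the sulfur
rows — which the tests assert for the whole library. The Lawson–Hanson
algorithm (`pracma::lsqnonneg`) does the solving. Three design points:

* **Identifiability is reported, never hidden.** The full library is
  rank-deficient in observation space (cycles such as comproportionation
  followed by thiosulfate oxidation are invisible at the endpoints). The fit
  carries the null-space dimension and a per-reaction identifiability flag
  computed from the SVD null basis; downstream interpretation should use
  identifiable subsets or the L1 option.
* **Sparse representative.** An optional L1 penalty (λ = 10⁻³‖d‖ under
  `l1 = "auto"`) selects a minimum-turnover representative among exact
  fits, via projected coordinate descent started from the NNLS solution.
  Note that minimum total turnover is not the same thing as minimum support:
  for some signatures a longer pathway with smaller summed extent is the
  honest L1 optimum.
* **The proton row is optional and weightable.** Measured acid production
  systematically undershoots the oxidative model's prediction (see below),
  so fits that should reflect speciation only can exclude or down-weight the
  H+ row (`include_proton`, `weights = c("H+" = ...)`).

`normalize_net_reaction()` turns a delta vector into an integer net
reaction: produced pools are scaled so their sulfur totals a target (6 for
the S0 treatment), each pool's molecule coefficient is rounded to the
nearest integer with a largest-remainder repair so the rounded sulfur still
hits the target, and the proton change is scaled and rounded identically.
With the measured day-5 pools (13.7 mM-S sulfate, 25.3 mM-S Other-SOI) this
reproduces `6 S0 -> 2 SO4^2- + 4 S_OtherSOI + 5 H+` from 2.11 → 2 and
3.89 → 4. Auto mode picks the smallest target ≤ 12 whose worst rounding
residual is below 0.15 — tight enough to reject nonsense splits, loose
enough to accept the 2.11/3.89 case. The procedure is scale-invariant in the
input.

`compare_models()` fits candidate reaction subsets and ranks them by
objective with a parsimony tie-break; objectives within solver tolerance
(10⁻¹² × observation scale) count as ties, otherwise exact fits would never
tie in floating point. It also reports whether adding the polythionate
disproportionation reactions improves the best objective by more than a
configurable factor (default 10×) — the signature of the late-interval
thiosulfate chemistry.

## The proton discrepancy

Composing the oxidative S0 array (4× S0 oxidation, 2× sulfite oxidation,
2× comproportionation, 1× thiosulfate-to-tetrathionate) gives the net model
prediction `6 S0 + 11/2 O2 + 3 H2O -> 2 SO4^2- + S4O6^2- + 6 H+`: six
protons per six S0 converted. The measured pH trajectory, normalised over
the same interval, yields five. `build_model()` carries both numbers and
attaches a discrepancy note whenever |predicted − observed| exceeds 10% of
observed; the report's proton ledger makes the misfit explicit instead of
absorbing it into the fit.

## The synthetic-data generator

`simulate_batch()` exists so that every inference stage can be tested
against known ground truth. It applies an extent schedule through the
library stoichiometry interval by interval, tracks every species (including
polythionates the "instruments" do not resolve), computes total dissolved S
from the full dissolved pool — so Other-SOI is recoverable by difference by
construction — and only then applies measurement effects:

* **Noise**: multiplicative lognormal per measurement, mean-preserving,
  default CV 5%, independent across species and days — concentrations are
  positive and chromatographic/spectrometric errors scale with signal.
* **Censoring**: values below a configurable limit of detection are stored
  as zero and flagged (the total-S LOD of 1 mg/L corresponds to 0.0312
  mM-S).
* **Pools**: the particulate S0 substrate is tracked outside the dissolved
  pool, mirroring the < 0.45 µm filtration semantics; reactions consuming
  S0 draw on the particulate pool when one is present, produced S0 enters
  the colloidal pool.
* **pH**: derived from the initial pH plus the cumulative stoichiometric
  proton balance, unless the scenario supplies an observed pH trajectory.
  Measured pH is an independent observable, and this override is what lets
  a scenario carry a genuine model-versus-measurement proton misfit instead
  of baking the model's prediction into its own "data". Extents that would
  drive a species (or the proton pool) negative are scaled back with a
  warning, or raise in strict mode.

O2 and H2O are unlimited (aerobic shaken flasks). The generator does *not*
emulate cell growth, instrument drift, day-to-day pH electrode
recalibration, or speciation within the unresolved pool — so passing tests
demonstrate correctness of the mass-balance and inference machinery, not
that real cultures obey the library.

### Calibrated scenarios

`batch_scenarios()` ships two noiseless reference scenarios whose endpoints
are the study conditions the package models. Their extent schedules were
solved by hand from the endpoint constraints, once, as follows.

**S0, days 0–5.** Substrate 1% m/v S0 = 311.9 mM-S particulate. Writing e2,
e3, e4, e5 for the total extents of S0 oxidation, sulfite oxidation,
comproportionation and tetrathionate formation, the day-5 constraints
(sulfate 13.7 mM-S; Other-SOI 25.3 mM-S as tetrathionate; no residual
sulfite or thiosulfate) give e3 = 13.7, e5 = 25.3/4 = 6.325, e4 = 2·e5 =
12.65, e2 = e3 + e4 = 26.35, consuming exactly 39 mM-S of substrate. Daily
fractions (5/10/18/27/40%) shape a plausible accelerating trajectory;
because production and consumption scale together, intermediates stay at
zero every day. The observed pH falls 4.0 → 1.5 (2.5 on day 3); the initial
pH is a scenario parameter set to 4.0, a typical fresh sulfur-salts medium
value, chosen once. The resulting measured proton rise (31.5 mM) normalises
to 5 H+ per 6 S0, against the stoichiometric 40.1 mM (6 per 6) — the
discrepancy the model reports.

**Thiosulfate, days 0–4.** Substrate 0.2% m/v Na2S2O3 = 12.65 mM = 25.3
mM-S; sampling days 0/2/4; initial pH 2.8, day-2 pH 2.4, final pH 2.5.
Days 0–2 are oxidative (tetrathionate formation a = 5.965, its oxidation
b = 0.6375 and hydrolysis c = 5.25 mM), fixed by three constraints: sulfate
reaches 7.8 mM-S by day 2 (4b + c = 7.8), the proton rise matches the pH
drop (−2a + 6b + 2c = 2.40), and thiosulfate drawdown leaves what the day-4
budget needs. Days 2–4 disproportionate (trithionate disproportionation
f = 0.9, comproportionation h = 3.2, residual tetrathionate formation
g = 0.41), chosen so S0 rises to 4.0 mM-S, sulfite stays at 0.4 mM (< 0.5),
sulfate stays flat, Other-SOI falls from 16.1 to 6.9 mM-S, and protons
decline — the oxidative-then-disproportionating sign pattern. Sulfur
conservation makes the day-4 Other-SOI constraint automatic, which is a
useful consistency check on the algebra.

## Numerical choices

* Rational arithmetic stores numerator/denominator as doubles with gcd
  reduction at every step; magnitudes stay far below 2⁵³ for this problem
  class, and constructors reject non-integers.
* FPKM bins: below 200 none/low; 200–1,000 low; 1,000–4,000 medium;
  4,000–10,000 high; above 10,000 very high. A shared printed edge belongs
  to the lower bin (upper-edge inclusive, so 10,000 is "high"); real data
  never sit exactly on an edge, and the convention is documented and
  testable. Log2 comparisons use a pseudocount of 1 FPKM against zeros and
  a ±6 display clip, with unclipped values retained. Multi-copy genes
  aggregate by max by default — a pathway is available if any copy is
  expressed — with sum/mean for sensitivity analysis.
* Expression support threshold: a reaction needs one catalyst at ≥ 200 FPKM
  ("low" or better); below that it is dropped unless it can proceed
  abiotically, and unmapped reactions are retained as "abiotic/unknown".
* Feasibility clipping in the simulator uses a 10⁻⁹ mM slack on species and
  a 10⁻⁵ mM floor on protons; accumulation dust below 10⁻¹² mM is zeroed.
* Test problem sizes: property suites use 20–50 random cases per invariant
  and 200 replicates for the noisy-recovery statistic at CV 5%, sizes at
  which the whole suite runs in seconds while the medians are stable.

## Known limitations

* Endpoint deltas cannot separate reaction cycles: only identifiable
  subsets (or an explicit sparsity preference) give unique extents. Denser
  sampling in time is the real cure; the machinery supports per-interval
  fitting.
* The Other-SOI pool is a single lump with a single proxy composition;
  if the real pool mixes polythionates of different chain lengths the
  proxy's S:O ratio is wrong in a way no endpoint mass balance can detect.
* Proton accounting ignores activity coefficients and buffering by medium
  salts; at ionic strengths of these media the absolute H+ numbers carry
  that caveat, though interval comparisons mostly cancel it.
* Expression support is categorical evidence, not kinetics: an extent fit
  weighted by transcript abundance would need calibration data this package
  does not assume.
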