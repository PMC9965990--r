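---
title: "The ketopbpk model: structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ketopbpk model: structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ketopbpk)
```

`ketopbpk` is a whole-body physiologically based pharmacokinetic (PBPK)
model of oral ketoconazole and its sequential metabolites
*N*-deacetylketoconazole (M1, formed by arylacetamide deacetylase, AADAC)
and *N*-deacetyl-*N*-hydroxyketoconazole (M2, formed from M1 by
flavin-containing monooxygenase 3, FMO3).  Its purpose is twofold: to
simulate ketoconazole's oral pharmacokinetics under fasted and fed
conditions (the drug–food interaction, DFI), and to quantify how much of
ketoconazole's notorious CYP3A4/P-glycoprotein (P-gp) drug–drug interaction
(DDI) potential is carried by its liver-accumulating metabolites rather
than by the short-lived parent itself.

# Model structure

## Physiology

All simulations run on a reference European adult (30 y, 73 kg, 176 cm)
assembled from ICRP-style organ volumes, blood flows and tissue-composition
tables embedded in the package (`build_reference_individual()`).  Fourteen
compartments are distinguished: venous and arterial blood plus twelve
tissues (lung, liver, kidney, gut wall, adipose, muscle, skin, bone, brain,
heart, spleen, rest).  Organ volumes, flows and the glomerular filtration
rate scale linearly with body weight; the splanchnic organs (gut wall,
spleen) drain into the liver.  Enzyme localization follows the pathways the
model needs: AADAC, UGT1A4 and FMO3 in liver cells; CYP3A4 in liver and gut
wall; P-gp at the apical gut wall, the liver canalicular membrane and the
kidney.  Because expression databases report abundances on heterogeneous
scales, the pool concentrations are round literature-informed values
(CYP3A4 4.32 µmol/L liver, the others 1 µmol/L or below); the optimized
catalytic constants carried in the compound files were estimated against
abundances of this magnitude, and all rates enter only as the product
`k_cat × amount`.

Each tissue is split into a perfusion-limited extracellular space (plasma
plus interstitial) and a permeability-limited intracellular space.  The
cellular exchange flux acts on unbound aqueous concentrations,

$$J = P\,A\,\left(\frac{f_u}{B\!:\!P}\,C_{ec} - \frac{f_u}{K_p}\,C_{ic}\right),$$

with `P` the compound's cellular permeability, `A` an effective exchange
area (10^5 cm² per litre of organ, a single value for all organs), `fu` the
fraction unbound in plasma, `B:P` the blood-to-plasma concentration ratio
(0.62 for ketoconazole and its metabolites, which are albumin-bound with
little erythrocyte association), and `K_p` the cell-to-plasma partition
coefficient.  At equilibrium the intracellular unbound concentration equals
the extracellular unbound concentration; during active formation of a
metabolite inside cells the intracellular unbound level transiently exceeds
it, which is exactly the mechanism by which the trapped metabolites sustain
intracellular CYP3A4/P-gp inhibition after the parent has been cleared.

Partition coefficients are computed from tissue composition by the method
declared per compound: Berezhkovskiy (ketoconazole, M2), Rodgers–Rowland
(M1) or charge-dependent Schmitt.  The Rodgers–Rowland implementation is
the neutral/weak-base reduction (cytosolic-pH ion trapping, no acidic
phospholipid association term, which would require blood-cell binding data
that are not available here); the Schmitt variant weights the membrane
affinity of each ionization species (cations retain full affinity through
electrostatic attraction to acidic head groups, anions are repelled) and is
phospholipid-centric in its lipid weighting.  Cellular permeability uses a
lipophilicity/size relation `P = 1.2e-2 · 10^logP / sqrt(MW)` cm/min,
which, at the embedded exchange areas, gives unbound transmembrane
equilibration half-times of minutes for moderately lipophilic drugs (as
transcellular absorption requires); the charge-dependent variant used for
M1 and M2 multiplies by the neutral fraction at plasma pH, which is what
makes the strongly basic M1 (pKa 8.90) slow to leave cells.

## Absorption and the food effect

The gastrointestinal tract is an eight-segment transit chain (stomach,
duodenum, upper/lower jejunum, upper/lower ileum, caecum, colon) with
luminal volumes, pH values, effective absorptive surface areas and mean
transit times embedded as package defaults.  Transit is first order; the
stomach rate is `ln 2 / GET` with a gastric emptying time (GET) of 15 min
fasted and 45 min fed.  Absorption from each segment is
`P_int × area × C_dissolved` into the gut-wall cells, with the transcellular
intestinal permeability taken from the compound file per prandial state
(ketoconazole: 1.56·10⁻⁵ cm/min fasted, 9.95·10⁻⁶ cm/min fed).

Solid doses dissolve by a Noyes–Whitney flux proportional to the remaining
solid surface (taken as the specific surface of particles at each bin's
nominal radius) and to the local solubility gap `S(pH) − C`; supersaturated
lumen contents never precipitate (the gap is clipped at zero), consistent
with the supersaturation assumed for this compound class over the full
dosing range.  Solubility is interpolated log-linearly between the
tabulated points and extrapolated as a constant — chosen for positivity and
stability.  Tablets and capsules default to a log-normal particle-radius
distribution with median 300 µm and geometric SD 2 in ten bins.  The large
*effective* (granule-scale) radius was chosen from dissolution arithmetic:
at gastric pH the tabulated solubility (2–4·10⁴ mg/L) would dissolve
micron-scale particles in seconds, leaving no dissolution dynamics at all,
whereas a 300 µm effective radius reproduces tablet dissolution half-times
of tens of minutes in acidic media.  This matters because the gastric
residence time is the food-effect lever: ketoconazole dissolves essentially
only in the stomach (intestinal solubility is four orders of magnitude
lower), so tripling the GET in the fed state increases the fraction
dissolved before emptying — this is what raises the fed AUC at 400–600 mg
despite the lower fed intestinal permeability.  The fed stomach pH is set
to 3.0 (meal buffering raises gastric pH transiently; pH 3 is both a
realistic time-average over the 45-min fed emptying phase and the pH of
maximal ketoconazole solubility in its own solubility table); the fasted
stomach is pH 2.0.  The food effect is carried *only* by these gastric
parameters and the fed intestinal permeability — no bile-solubilization or
meal-composition model.

When a study does not declare its prandial state,
`resolve_prandial_state()` applies three rules: fed is assumed if the
observed T_max exceeds two hours, if multiple doses are given within a day,
or if single oral tablet doses of 800 mg or more are administered;
otherwise fasted.

## Metabolism, inhibition and excretion

Ketoconazole is metabolized by AADAC (to M1), CYP3A4 and UGT1A4, and
effluxed by P-gp; M1 is oxidized by FMO3 to M2; M2 is eliminated by an
FMO3-normalized first-order clearance (`CL_spec × [FMO3] × C_u × V`), the
parametrization used when no saturable in vitro data exist.  All saturable
processes are Michaelis–Menten with competitive reversible inhibition:

$$v = \frac{k_{cat}\,E\,C_u}{K_M\,(1 + \sum_j I_j / K_{i,j}) + C_u},$$

where the inhibitor concentrations `I_j` are the unbound intracellular
concentrations in the organ hosting the enzyme.  The interaction scenario
(`"P"`, `"P_M1"`, `"P_M1_M2"`) selects which of ketoconazole, M1 and M2
contribute to the sum; the compounds are always simulated, only their
inhibition entries are switched.  For ketoconazole the CYP3A4 and P-gp
`K_M` values are surrogates equal to the corresponding autoinhibition
`K_i` values — this coupling is asserted when the parameter files load.
M2's inhibition constants are surrogated from M1's.

P-gp efflux routes by organ: gut wall to lumen (redistributed over the
small-intestinal segments by surface area), liver to a bile pool released
continuously into the duodenum (rate constant 0.03/min, fraction
`EHC_continuous_fraction = 1`), kidney to urine.  Renal elimination is
glomerular filtration `GFR_fraction × GFR × fu/BP × C`.  M2 is
plasma-restricted: it has no cell/plasma exchange terms anywhere, so it
exists only where it is formed (liver cells) until metabolized — the
encoding of a metabolite that has never been detected in plasma.

# Numerical choices

The state vector (amounts in µmol, time in minutes) couples, per compound:
venous/arterial blood, twelve extracellular and twelve intracellular organ
spaces, a bile pool, eight dissolved luminal states, and eight solid states
per particle bin, plus cumulative ledgers (urine, feces, per-pathway
metabolism).  A 200 mg tablet simulation of the three-compound model has
162 states.  Integration uses `deSolve::lsoda` with `rtol = 1e-8`,
`atol = 1e-10` µmol; dosing is applied through solver events, and states
are clipped at zero inside the right-hand side.  Molar mass balance
(remaining amounts + urine + feces + sink-metabolism ledgers versus the
administered dose) closes to machine precision on the shipped scenarios,
and halving the tolerances changes AUC_last by well under 0.1%.  Output
rows that coincide with a dosing instant report the pre-dose state.

Parameter fitting (`fit_parameters()`) minimizes pooled squared residuals
of log10 concentrations over all studies simultaneously — concentrations
span three orders of magnitude, and the log scale matches the evaluation
metrics.  Bounded Levenberg–Marquardt (via `minpack.lm`) uses a relative
finite-difference step of ~10⁻³ (`epsfcn = 1e-6`): the default
machine-precision step would sit below the ODE solver's noise floor and
yield a meaningless Jacobian.  The Monte-Carlo option draws uniformly
within bounds (seeded, best-of-N with `n_mc = 100` by default, a
desk-scale choice) and polishes with Levenberg–Marquardt.  Below-LOQ
observations are dropped before any log-based metric.  Local sensitivities
are central differences of AUC, `S = (ΔAUC/AUC)/(Δp/p)`.

Evaluation statistics follow the standard definitions: MRD is 10 to the
root-mean-square log10 concentration deviation; GMFE is 10 to the mean
absolute log10 fold error of AUC_last or C_max over studies; predicted
interaction ratios are judged against the ratio-dependent Guest band with
1.25-fold variability, `L = (1.25 + 2(R−1))/R`, which equals (0.8, 1.25)
at a ratio of 1 and approaches the two-fold criterion for large ratios.

# The synthetic-data generator

No clinical profiles ship with the package.  `generate_observed_profiles()`
emulates digitized mean plasma concentration–time profiles: the truth model
is simulated under a study design (dose, formulation, prandial state,
sampling schedule), multiplicative log-normal noise with log-scale SD
`cv/sqrt(n_subjects)` is applied (default cv = 0.2, typical of
between-study variability in digitized means), and values below the limit
of quantification are censored (defaults 1 ng/mL for ketoconazole,
0.25 ng/mL for the thousand-fold less abundant M1).  `dose_grid_studies()`
spans the modeled design space (100–1200 mg, solutions/tablets,
fasted/fed, single and multiple doses); `generate_study_table()` emits
study metadata with a configurable fraction of prandial states masked, for
testing the resolution rules; `generate_ddi_dataset()` produces paired
reference/effect victim profiles whose noise-free version reproduces the
truth interaction ratio exactly.

What passing tests on these data do and do not show: they demonstrate that
the pipeline (simulation → sampling → noise → censoring → metrics →
fitting) is self-consistent and that the identifiable catalytic constants
are recoverable at realistic noise; they do not validate the model against
real clinical data, do not emulate within-study subject variability or
covariate structure, and cannot detect structural misspecification shared
by generator and fitter.  One structural fact the generator makes explicit:
M2's clearance is not identifiable from plasma data (M2 never appears in
plasma), so recovery tests target the AADAC and CYP3A4 catalytic constants.

# Design decisions on open points

* **Fig-style liver readouts.**  The single-dose liver-cell simulation is
  anchored to 400 mg fasted — the dose of the study that anchors the
  metabolite plasma data — because the source text does not state the dose.
* **Liver M2 peak time.**  With first-order formation from a precursor
  whose liver half-life is ~12 h and first-order elimination with half-life
  ~46 h, a linear cascade peaks near
  `ln(k_f/k_e)/(k_f − k_e) ≈ 32 h`.  Our simulation peaks near 37 h; a
  ~13 h peak cannot arise from this cascade, so the corresponding
  acceptance expectation is left failing rather than forced.
* **Victim drugs.**  The five victim models are *synthetic simplified
  surrogates* (single CYP3A4 elimination, or P-gp efflux plus filtration
  for digoxin) whose clearances and half-lives sit in literature ranges.
  They exercise the interaction machinery; victim-specific quantitative
  DDI ratios are out of scope.
* **Monte-Carlo default.**  `n_mc = 100` rather than thousands: the search
  space shipped here is low-dimensional and bounded, and the
  Levenberg–Marquardt polish does the local work.
* **Problem sizes in the shipped tests.**  Property suites use 12–24 h
  windows, 0.25–0.5 h output grids and relative tolerance 10⁻⁶ (comparisons
  of smooth functionals need far less accuracy than the 10⁻⁸ production
  default); recovery tests use oral-solution designs with eight sampling
  times, which carry the same information per study at a fraction of the
  stiffness.  These are the package's own desk-scale choices.

# Known limitations

* One virtual individual: no population variability, pediatrics, disease
  states or ethnicity-specific physiology.
* Blood is carried at a single compound-wide B:P ratio; erythrocyte
  kinetics are not modeled.
* The food effect is two parameters (GET, fed permeability) plus the fed
  gastric pH; meal timing and composition are collapsed into them.
* Reversible inhibition only — no mechanism-based inactivation or
  induction, consistent with the reversible-inhibition reading of the
  recent in vitro literature.
* The Rodgers–Rowland strong-base phospholipid-association term is
  omitted (see above); M1's tissue partitioning is therefore conservative.
* M2 stands in for "further metabolites" generally; its parameters are
  surrogates, and its disposition (liver confinement, FMO3 clearance) is
  an assumption, not an observation.

# Worked example

```{r example}
# single 400 mg fasted tablet: parent + metabolites
res <- simulate_ketoconazole(400, prandial = "fasted", t_end = 48)
print(res)
pk_parameters(res$times, res$plasma[, "ketoconazole"])

# paired fed/fasted study
run_dfi_study(400, t_end = 48)

# midazolam DDI across perpetrator scenarios
perp <- regimen("ketoconazole", 400, 1, formulation = formulation("tablet"))
vic <- regimen("midazolam", 7.5, 1, start = 1)
scen <- ddi_scenario("midazolam", "P_M1_M2", perp, vic)
run_ddi_study(scen, scenarios = c("P", "P_M1", "P_M1_M2"), window = 24)
```
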