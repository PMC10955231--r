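---
title: "A jointed PBPK model of dabigatran etexilate and its metabolite cascade: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A jointed PBPK model of dabigatran etexilate and its metabolite cascade: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dabepbpk)
```

## The problem

Dabigatran etexilate (DABE) is the double-ester prodrug of the anticoagulant
dabigatran (DAB) and the standard clinical probe for intestinal
P-glycoprotein (P-gp). Clinically, dual CYP3A/P-gp inhibitors raise DAB
exposure far more after a microdose of DABE (hundreds of micrograms) than
after a therapeutic dose (150-300 mg). If DABE reported only on P-gp, the
interaction magnitude should not depend on dose this strongly. This package
implements a mechanistic explanation: the ethyl-ester intermediate BIBR0951,
formed from DABE inside the enterocyte, is cleared there almost exclusively
by CYP3A with a Michaelis constant of a few micromolar. At a microdose the
pathway operates far below saturation and gut CYP3A inhibition multiplies
the intermediate's gut availability severalfold; at a therapeutic dose the
pathway is already saturated by the drug itself and the same inhibitor
exposure moves it much less.

## Model structure

Four compounds are chained: DABE is dosed orally; intestinal CES2 hydrolyses
it in the enterocyte to BIBR0951 (major) and BIBR1087 (minor), in parallel
with a smaller oxidative CYP3A route; plasma esterases convert circulating
DABE to BIBR1087 (half-life 364 min) and BIBR0951 to DAB (55 min);
BIBR1087 is stable in plasma. In the liver, BIBR0951 partitions between
CES1 hydrolysis to DAB, CYP3A oxidation to an inert sink, and biliary
excretion (intrinsic clearance 273 uL/min/10^6 hepatocytes, a terminal sink
with no enterohepatic recirculation); BIBR1087 is hydrolysed by CES1/CES2 to
DAB. DAB itself distributes two-compartmentally and is cleared
renal-dominantly on its unbound blood concentration.

The gut is nine luminal segments (stomach, duodenum, two jejunal, four
ileal, colon) in the style of segmented absorption-transit models: serial
first-order transit, diffusion-layer dissolution of solid drug
(shrinking-sphere kinetics, flux $k_d A^{2/3} (C_s - C)$),
supersaturation-triggered precipitation, passive uptake across the apical
membrane ($k_a = 2 P_{eff}/r$), saturable apical P-gp efflux
(Km fixed at 2.6 uM), and saturable enterocyte metabolism distributed over
segments by CYP3A/CES2 abundance fractions. Precipitation uses the
critical-supersaturation-ratio / precipitation-rate-constant mechanism: a
per-segment latch fires once the dissolved concentration reaches CSR times
the local solubility (CSR 17.9), after which the excess above solubility
precipitates at 2.88 per hour. Precipitated material is treated as lost
from the absorbable pool; re-dissolution is not modeled, which is the
simplest reading of the latched trigger mechanism.

Hepatic elimination is well-stirred: each pathway's whole-organ capacity is
scaled from its source basis (per mg microsomal protein via MPPGL 40 mg/g
and 1650 g liver; per pmol recombinant enzyme via abundance and an
intersystem extrapolation factor), and the unbound liver outflow
concentration drives all saturable rates, so the tracer-limit clearance
reproduces $CL_h = Q_h f_{u,b} CL_{int,u}/(Q_h + f_{u,b} CL_{int,u})$
exactly. First-pass fractions are computed by cumulative flux accounting:
$F_a$ as net apical transfer over dose, $F_g$ as basolateral transfer over
total enterocyte input, $F_h$ as hepatic outflow over hepatic input; with
recirculation these equal one minus the average extraction over all passes.

### Basolateral transfer

The enterocyte-to-portal step is villous-perfusion-limited: the transfer
rate constant is the segmental mucosal blood flow over the enterocyte
volume, scaled by a basolateral global scalar of 0.1 for BIBR0951 (1 for
the others). A permeability-based basolateral step was considered and
rejected: the intermediate's predicted jejunal permeability (from PSA 137
and HBD 3, about 0.13e-4 cm/s) is so low that a membrane-limited exit would
trap it in the enterocyte and drive its gut availability to zero, which is
incompatible with the observed interaction dissection. The 0.1 scalar on a
perfusion-limited step is what makes enterocyte residence long enough for
gut CYP3A to compete, which is the heart of the mechanism.

### Gastric versus intestinal solubility

The intestinal aqueous solubility is the published 0.003 mg/mL in every
intestinal segment, for both the dissolution cap and the precipitation
driving force. The stomach uses a separate, higher solubility (default
1 mg/mL): the marketed pellet formulation carries a tartaric-acid core
precisely so that the weak base dissolves in an acidic microenvironment and
arrives in the duodenum supersaturated. With a single flat solubility a
300 mg dose could never absorb more than a fraction of a percent, and no
supersaturation (hence no precipitation mechanism) could ever arise; the
two-level solubility is therefore a structural requirement of the
formulation being modeled, not a tuning convenience.

## Drug-drug interactions

Perpetrators are empirical one-compartment oral models (superposition over
the regimen) with four exposure surrogates: unbound systemic and hepatic
inlet concentrations, and two gut surrogates derived from the remaining
absorbable luminal amount (luminal concentration, and absorption flux over
villous blood flow for the enterocyte). Competitive inhibition multiplies
the target's Michaelis constant by $1 + \sum I_u/K_i$; mechanism-based
CYP3A inactivation runs an enzyme-turnover state per organ,
$de/dt = k_{deg}(1-e) - e\,k_{inact} I_u/(K_{I,u}+I_u)$, with gut and liver
turnover at 0.030 and 0.019 per hour. Esterases are never inhibited. The
shipped perpetrator set: clarithromycin (MBI on CYP3A plus competitive
P-gp), itraconazole with hydroxy-itraconazole as a proportional metabolite
perpetrator (competitive CYP3A; P-gp Ki 2 and 5 uM), verapamil (MBI on
CYP3A plus potent competitive P-gp), and single-dose rifampin (competitive
P-gp and CYP3A; no induction, single dose).

## Calibration: what is fixed and what is fitted

Measured or published values are fixed: the plasma half-lives, unbound
plasma fractions and blood partitioning of the intermediates, the P-gp Km,
the intestinal solubility, CSR, PRC, the biliary intrinsic clearance, the
PSA/HBD permeability correlation, and the physiological constants (MPPGL,
hepatocellularity, liver mass, hepatic and villous blood flows, CYP3A
abundances, turnover rates). Everything else - the CES/CYP3A capacities of
the three ester species, the P-gp Jmax, DAB's disposition constants, the
perpetrator PK and inhibition constants - is a calibrated stand-in (the
source platform's values are not public) and is flagged "calibrated" in
`default_compounds()` / `default_perpetrators()`. Calibration proceeded in
a fixed order: (1) DAB disposition to the microdose exposure anchor
(Cmax ~0.15-0.17 ng/mL, AUC 1.44 ng.h/mL); (2) the gut CES2/CYP3A split and
the intermediate's hepatic partition to the microdose clarithromycin and
itraconazole interaction ratios; (3) solubility/CSR/PRC held at their
published values; (4) Jmax and the remaining perpetrator constants to the
therapeutic-dose behavior (fraction absorbed ~0.4, therapeutic
clarithromycin and verapamil ratios). No parameter was moved after the
acceptance checks were frozen.

One tension in the published evaluation is worth recording: the printed
microdose and 300 mg exposures are nearly dose-proportional between
themselves, while the dose-nonlinearity analysis reports microdose exposure
more than twofold below the therapeutic-range proportionality line. These
cannot both hold in one model. This implementation follows the
nonlinearity analysis (the mechanistically meaningful statement): the
calibrated model places dose-normalized microdose exposure about 2.6-fold
below the 300 mg reference, at the cost of running the absolute 300 mg
exposure about twofold above the printed value. All therapeutic-dose
acceptance surfaces are ratios or fractions, which are unaffected.

## Numerics

Amounts are in micromoles, time in hours; plasma outputs convert to ng/mL
through molecular weight and the blood-to-plasma ratio. The ODE system
(135 states for the four-compound cascade: luminal pools and latches,
enterocyte amounts, systemic compartments, two enzyme-activity states, and
a per-compound cumulative flux ledger) is integrated with a sparse-Jacobian
stiff solver (`deSolve::lsodes`); default tolerances rtol 1e-7 / atol
1e-10. Doses are instantaneous additions to the gastric dissolved
(solution) or solid (immediate-release) pool; doses at time zero go into
the initial state, later ones are solver events. The precipitation latch
is a smooth auxiliary state (steep logistic trigger, engagement rate 30 per hour)
rather than a discrete event, keeping the right-hand side continuous and
runs bit-reproducible. Negative excursions at the solver tolerance are
clamped inside the right-hand side before rates are formed. Every
simulation closes a whole-system molar mass balance (amounts plus terminal
sinks against dose) to well below 1e-6 of the dose; tightening rtol by two
decades moves the active metabolite's AUC by less than 0.1%.

## Estimation and sensitivity screening

Top-down estimation minimizes weighted least squares (default weights
$1/obs^2$, appropriate when concentrations span orders of magnitude across
dose levels) by Nelder-Mead on logistic-transformed parameters, so bounds
hold by construction and the optimization is deterministic. One-dimensional
problems use golden-section search directly. An optional coordinate-wise
refinement stage follows the simplex: with the 200 mg supersaturation data
the precipitation pair (CSR, PRC) lies in a strongly correlated, shallow
valley - the trigger fires essentially instantly at that dose, so CSR acts
only through late, distal segments - and the simplex collapses along the
valley before reaching its floor. Where that correlation bites, the
recommended estimator is nested: profile out the well-identified parameter
(PRC) with an inner line search while the outer search runs on CSR. The
parameter-recovery tests exercise exactly this protocol.

Morris elementary-effects screening uses standard trajectory sampling on a
p-level grid (default 4 levels; trajectories seeded and reproducible);
effects are reported per unit of the normalized parameter, so an additive
linear model yields mu-star equal to |coefficient times range| exactly, and
a parameter with no influence yields exactly zero.

## Synthetic data

The generators mirror the three data classes the estimation pipeline
consumes: first-order plasma-decay incubations (0-120 min design),
Michaelis-Menten rate-versus-concentration designs, and sparse plasma
concentration samples drawn from a known-truth simulation. Noise is
multiplicative log-normal (assay-like); the lower limit of quantification
defaults to 0.01 ng/mL, plausible against the ~0.15 ng/mL microdose peak.
Every generator is bit-reproducible from its seed, and zero-noise
generation composed with the corresponding fitter recovers the truth - the
module's core guarantee. What the generators deliberately do not emulate:
between-study design heterogeneity, covariate structure, or assay drift;
passing the seeded round-trip tests therefore demonstrates estimator
correctness, not robustness to real clinical data pathologies.

## Population variability

`simulate_population()` draws per-subject multiplicative log-normal factors
(defaults: 30% CV on clearance-side capacities, 20% on distribution
volumes, shared across compounds within a subject) and returns pooled
5th-95th percentile bands in the trial-structured shape (subjects x
trials). This is a convenience approximation for predictive-check coverage,
not a covariate-based virtual population; its bands should not be read as
demographic predictions.

## Problem sizes used in the shipped analyses

The analysis scripts and tests run the mean individual: single simulations
over 24-36 h grids at 0.25-0.5 h output spacing, interaction runs over
132 h (five days of perpetrator loading before the substrate dose),
dose-response sweeps over ten doses, Morris screens with 4-8 trajectories
over 3-5 parameters, and parameter-recovery fits with about one to two
hundred model evaluations. These sizes keep any single script or test file
in the minutes range on one CPU while leaving the estimators' behavior
clearly visible.

## Known limitations

The intermediates' absolute plasma concentrations are structurally
overpredicted - their true distribution volumes and systemic clearances are
unknown, and BIBR1087 carries a calibrated unassigned clearance precisely
because its disposition beyond CES hydrolysis is uncharacterized; no
conclusion should be drawn from their simulated plasma levels. DAB
glucuronidation is not modeled (free DAB only). Precipitated drug never
re-dissolves. Bile-micelle solubilization, regional pH-dependent
ionization, fed-state physiology, transporter-mediated hepatic uptake,
enterohepatic recirculation, induction, and intravenous administration are
out of scope. CSR is weakly identified from high-dose supersaturation data
in this model (and plausibly in any model of this mechanism at such doses):
its recovery depends on the nested estimation protocol described above,
and confidence in its value should come from the low-dose boundary of the
precipitation regime rather than from 200 mg data alone.
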