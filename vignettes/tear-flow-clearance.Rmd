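---
title: "Modelling precorneal clearance in a dynamic ex vivo permeation assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling precorneal clearance in a dynamic ex vivo permeation assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacriflow)
```

## The problem

Topically applied ophthalmic formulations are washed off the cornea by tear
turnover long before a static permeation assay would suggest.  A Franz-type
diffusion cell keeps the formulation in contact with the excised cornea for
the whole run; on the eye, basal tear turnover removes roughly 11--16 % of
the precorneal volume per minute, and a reflex-tearing response after
instillation clears it even faster.  A dynamic ex vivo assay mounts a glass
donor compartment on a whole porcine eye globe and pumps simulated tear
fluid through it, so the formulation is progressively diluted and drained
while penetration proceeds.  `lacriflow` implements the quantitative
skeleton of that assay: the washout mathematics, the donor-compartment
design table, the inverse HPLC calibration used to quantify penetrated
drug, a synthetic stand-in for the animal experiments, and the
formulation-comparison statistics.

## The clearance model

A donor compartment holding volume $V_0$ and cleared at a constant fraction
$c$ of its current volume per minute empties exponentially,

$$V(t) = V_0\, e^{-\beta t}, \qquad \beta = -\ln(1 - c),$$

with $\beta$ in min$^{-1}$.  The per-minute fraction and the continuous
coefficient are linked through discrete compounding: after $k$ whole
minutes, $V_0 (1-c)^k$ remains, and the continuous curve passes through
exactly those points.  (Published accounts of this model sometimes attach
"s$^{-1}$" to $\beta$; every reported value is only dimensionally
consistent per minute, and the package uses minutes throughout.)

Two conventions matter for reproducing reported figures, and both are
explicit options:

* **Canonical (rounded) coefficients.** `beta_from_rate()` rounds $\beta$
  half-up to 3 decimals by default (0.11 → 0.117, 0.16 → 0.174) *before*
  any trajectory evaluation.  This is the convention under which the
  familiar summary percentages arise: 17.29 % of the volume remains after
  15 min at 11 %/min, 7.35 % at 16 %/min.  `rounded = FALSE` /
  `round_beta = FALSE` keeps full precision.
* **Reporting rounding.** `percent_remaining()` reports half-up at two
  decimals; raw volumes are always available from `volume_at()`.

Multi-regime operation is handled by `clearance_schedule()`: an ordered
sequence of constant-clearance regimes on half-open intervals
$[t_k, t_{k+1})$, each re-based on the end volume of the previous regime,
so the trajectory is continuous.  The operating condition of the dynamic
assay is the two-stage schedule — 300 µL cleared at 16 %/min for 2 min
(reflex response, pump flow 48 µL/min) then 11 %/min for 13 min (basal
turnover, 33 µL/min):

```{r}
two <- clearance_schedule(c(0.16, 0.11), c(2, 13), v0 = 300)
summary(two)
```

About 211.83 µL survives the reflex stage and 15.43 % of the load survives
the full 15-minute run.  `auc_volume()` gives the exposure integral
$\int_0^T V(t)\,dt$ in closed form (with the $\beta = 0$ rectangle limit),
`simulate_trajectory()` evaluates the curve on a grid (default
`dt = 0.01` min, fine enough that the grid end point is within 0.1 % of
the closed form) with exact mass balance between remaining and drained
volume, and `fit_beta()` recovers the coefficient from sampled volumes by
least squares on $-\ln V$ versus $t$ — exact on clean single-regime data,
and unbiased enough under replicate noise that 1 % multiplicative error on
100 samples recovers $\beta$ to a few percent.

Degenerate inputs are rejected rather than coerced: clearance fractions
must lie in $[0, 1)$ (a rate of 1 would empty the compartment in the first
minute and has no continuous coefficient), durations must be positive with
only the final regime unbounded, and evaluation outside the schedule
horizon is an error.

## Donor-compartment geometry

Five glass prototypes of the donor compartment are shipped as a plain-CSV
table (`donor_geometry_table()`), each described by inlet/outlet channel
diameters and heights, the flow angle (stored categorically as
`right_angle`/`acute`, since no numeric acute angle is recorded), the
compartment and base diameters, and the global height.  Absent base
dimensions are `NA`, not zero.

`derived_ratios()` recomputes the two engineering ratios,
$d_{out}/d_{in}$ and $H_{in}/H_{out}$, **truncated** (not rounded) at two
decimals.  Truncation is the convention that reproduces every tabulated
value — 10.8/11.5 = 0.9391 is tabulated as 0.93, and 5.00/2.43 = 2.0576 as
2.05 — and a $10^{-9}$ epsilon guards against binary representation
pushing an exact two-decimal value below itself.

`rank_versions()` codifies the narrative selection of the final prototype
as a deterministic rule: candidates must have an acute flow angle (so the
outflow does not oppose the inflow) and a widened base (so the eyeball
seats); among those, a larger inlet/outlet height gap $H_{in}/H_{out}$
drains dammed fluid better and ranks first, with ties broken by the larger
base-widening height $H_b$ and then the lower version number.  The rule is
order-invariant and selects version 5 on the shipped table.  The relative
weighting of these criteria is a design choice of this package — the
source narrative motivates each criterion but never states weights.

## HPLC inverse prediction

Penetrated drug is quantified by inverting a linear detector calibration,
$c = (\text{area} - b)/m$, against the fluconazole UV assay line
($y = 30676\,x + 2843.9$, linear over 0.5--10 µg/mL, LOD 0.007 µg/mL,
LOQ 0.021 µg/mL; `calibration_curve()` defaults, also shipped as JSON).
Flags partition the concentration axis with boundaries closed on the
informative side: below the LOD the value is reported as 0 and flagged
`not_detected` (zero, not `NA`, so downstream means and ANOVAs stay
defined); at or above the LOD but below the LOQ it is
`detected_not_quantifiable`; from the LOQ up to the top of the linear
range it is `quantifiable`.  Above the linear range the inversion is an
extrapolation and errors unless explicitly allowed, in which case the
value carries an `out_of_range` flag.  A $10^{-9}$ relative guard keeps
values that sit exactly on a limit from being reclassified by float
cancellation in the inversion.  `tissue_amount()` converts extract
concentration to total drug (default 5 mL extraction volume) and to
amount per cm² of diffusional area (1.0 cm² in the Franz-cell mounts).

The re-derivation of LOD/LOQ from calibration residuals is out of scope —
the underlying assay sigma is not recoverable — as is any chromatogram
processing.  (The source protocol states the dynamic-arm dosing solution
as 60 µg/mL while the formulation definitions imply 0.2 % w/v; nothing in
this package computes from either number, so the inconsistency is noted
here and left alone.)

## The synthetic permeation generator

No public dataset of the animal experiments exists, so
`generate_permeation_dataset()` emulates their design: 7 formulations
(aqueous solution SOL; poloxamer 407 gels PLX14/16/20; 16 % poloxamer gels
with 0.5/1.0/1.25 % chitosan), 5 static replicates and 4 dynamic
replicates per formulation, drawn from a lognormal within each
formulation × arm cell.  Lognormal noise keeps amounts strictly positive
and matches the right-skewed, multiplicative variability typical of tissue
assays; the default coefficient of variation is 25 %, a realistic
between-cornea spread for ex vivo permeation work (no variances are
published for these experiments, and error bars were deliberately not
digitized from figures).

The default cell means (µg/cm²) are: static 3.0 for every formulation;
dynamic 0.5 for SOL and the poloxamer-only gels; dynamic 1.5 for the
chitosan gels.  They were fixed once, before any testing, to encode the
three qualitative findings the generator must reproduce: (i) the static
assay cannot distinguish the formulations, (ii) under simulated tear flow
the mucoadhesive chitosan gels deliver severalfold more drug than
poloxamer alone, and (iii) the static assay overestimates penetration
about 6-fold for poloxamer-only formulations and about 2-fold for chitosan
gels.  All means, CVs, replicate counts and the seed are overridable in
code or via a YAML config (`design_from_yaml()`).

What the generator does **not** emulate: any mechanistic link from the
clearance trajectory to the penetrated amount (none is established for
this assay), eye-to-eye covariance across formulations, the temperature
difference between arms (static runs at 32 ± 2 °C, dynamic at room
temperature), or real detection-limit censoring.  Tests that pass on
generated data therefore validate the *pipeline* — its statistics, its
determinism, its sensitivity at the published design size — not any claim
about real corneas.

## The comparison pipeline

`run_pipeline()` analyses the two arms separately (different apparatus and
temperature make a pooled two-way model unattractive): a classical one-way
ANOVA of amount on formulation per arm, all-pairs post hoc comparisons,
and per-formulation static/dynamic overestimation ratios, with
significance starred at two tiers (* p < 0.05, ** p < 0.01) and
$\alpha = 0.05$ throughout.  The post hoc procedure is Tukey's HSD on the
pooled within-group variance — the conventional default when a report
names only "ANOVA with multiple comparisons" — with Games–Howell
(Welch-studentized, no equal-variance assumption) available via
`method = "games_howell"` for heteroscedastic cells; under the default
generator the chitosan cells do have three times the SD of the poloxamer
cells, and the tests confirm both procedures agree on the detected
pattern.  Degenerate inputs (a single group, identical values, zero
within-group variance) are explicit errors rather than NaN statistics.

In the test suite the "mucoadhesion detected" event is operationalised as
the Tukey pair PLX16 vs PLX16C100 — the minimal contrast that isolates
chitosan at matched poloxamer content — and "viscosity not distinguished"
as no rejection among the three PLX14/16/20 pairs.  At the published
design size (4 dynamic replicates) the mucoadhesion contrast is detected
in well over 80 % of generator seeds while the poloxamer pairs stay below
a 10 % rejection rate, reproducing the reported comparison pattern as a
power property.

## Numerical choices and problem sizes

* Half-up rounding (`round_half_up()`) for reported percents (2 dp) and
  coefficients (3 dp); base `round()` half-to-even would misreport
  boundary cases such as 70.4969 → 70.50.
* Regime intervals are half-open; the end point of a bounded schedule
  evaluates in the final regime.
* The trajectory grid default `dt = 0.01` min keeps exports small while
  staying within fractions of a percent of the closed form; the
  discrete-compounding (Euler) oracle in the tests converges monotonically
  through steps 1, 0.1, 0.01 min.
* Simulation-based tests use sizes chosen to make their Monte-Carlo error
  small relative to the asserted bands: 2000 null datasets for the ANOVA
  type-I error (binomial SE ≈ 0.5 pp around 5 %), 500 generator seeds for
  the comparison-pattern power check, 50 seeds × 100 points for noisy
  coefficient recovery.

## Limitations

The washout model assumes a well-stirred compartment — exponential, not
plug-flow, drainage — which the glassware cannot itself verify; no
hydrodynamics, evaporation or tear-film optics are modelled; and neither
the clearance trajectory nor the synthetic comparison claims to predict in
vivo bioavailability.  The package reproduces the arithmetic and the
statistical logic of the assay so that formulation comparisons made with
it are explicit, seeded and repeatable.
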