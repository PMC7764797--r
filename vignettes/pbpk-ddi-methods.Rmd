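---
title: "Mechanistic basis and design of the pbpkddi CYP1A2/CYP2C19 DDI network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic basis and design of the pbpkddi CYP1A2/CYP2C19 DDI network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(pbpkddi)
```

## Scope and intended use

pbpkddi predicts how CYP1A2- and CYP2C19-mediated inhibition — competitive
and time-dependent — changes victim drug exposure, including the interplay
with CYP2C19/CYP2D6 genotype (extensive vs poor metabolizers). It is an
inhibition network: enzyme induction, transporters, enterohepatic
recirculation, metabolite kinetics and permeability-limited distribution are
out of scope by design.

## The structural model

**Circulation.** A reduced whole-body topology: 12 perfused organs plus
arterial and venous blood. Gut wall and spleen drain via the portal vein into
the liver, so the liver blood flow is the hepatic artery plus the portal
inflow; systemic arterial flows are constrained to sum exactly to cardiac
output (validated to 1e-9 relative). The reference adult (70 kg, cardiac
output 6.5 L/min) uses literature-standard resting organ volumes and flows;
no population database is reproduced — model behavior, not database parity,
is the target.

**Distribution** is flow-limited (perfusion-limited) for every organ:
`dA/dt = Q (C_art − C B:P/Kp)`. Tissue-to-plasma partition coefficients Kp
are inputs, never predicted; a `default` Kp applies to organs without a
specific entry.

**Metabolism and inhibition.** Liver and gut wall metabolize at the local
unbound concentration `Cu = fu·C/Kp` (well-stirred: intracellular unbound
equals plasma unbound). Three kinetic laws are supported per drug-enzyme
pathway: linear intrinsic clearance, Michaelis–Menten, and an
inhibitor-insensitive unspecific hepatic clearance scaled from an apparent
in vivo clearance (used where classical in-vitro-to-in-vivo extrapolation is
impossible, e.g. for a victim with no intravenous reference data).
Competitive inhibition multiplies the linear denominator (or Km) by
`1 + Σ I_u/K_i`, with I_u summed over *co-dosed* drugs only — a drug's
saturation of its own enzyme is already carried by its Michaelis–Menten
term, so counting it again as self-competition would double-count.

The inhibitor concentration driving both competitive and time-dependent
terms is always the unbound local concentration of the perpetrator
(`I_u = fu·C_organ/Kp`). This is a deliberate fixed choice rather than an
option: the interaction constants shipped with the package are
protein-binding-corrected values, and mixing bound-drug exposures with
unbound constants is a classic source of order-of-magnitude DDI error.

**Time-dependent inhibition (TDI).** When any co-dosed drug carries a TDI
entry against an enzyme, that enzyme becomes a dynamic state in every organ
expressing it: `dE/dt = kdeg(E0 − E) − E·Σ k_inact I_u/(K_I + I_u)`. The
pool is shared across drugs, which is what makes racemate autoinhibition
(the two omeprazole enantiomers inactivating the same CYP2C19 pool) and
cross-inhibition interact without special cases. Degradation rate defaults
(per enzyme, 1/min) correspond to reported hepatic enzyme half-lives of
roughly 26–104 h and are overridable per assembly — kdeg is a genuine
uncertainty and deserves sensitivity analysis in any serious application.

**Phenotypes** multiply an enzyme's expression in every organ
(EM = 1, PM = 0, intermediate alleles in between); application is
multiplicative-composable and never mutates the input individual. Gut-wall
expression can additionally be scaled alone (`scale_gut_expression`), the
mechanism used to emulate the higher-than-expected oral bioavailability of
R-omeprazole; the appropriate factor is formulation-dependent, so the
package deliberately ships no default.

**Racemates** are represented as two co-dosed enantiomer drugs at half the
racemate dose each, with mutual inhibition entries; victim metrics are
computed on the summed enantiomer plasma profile.

## Dosing, absorption and solver

Dosing supports IV bolus, constant-rate infusion and oral administration.
Oral doses enter the gut lumen — optionally through a Weibull-release solid
state whose release uses the Weibull hazard measured from the most recent
dose, so shape 1 reduces exactly to first-order release at rate 1/scale —
and are absorbed with first-order ka into the gut wall, where they are
exposed to gut-wall metabolism before draining into the portal vein. A
fraction `1 − f_abs` is routed to an unabsorbed sink. With multiple doses the
Weibull hazard restarts at each dose, approximating overlap of release from
an earlier dose by the latest dose's hazard; for the first-order limit this
is exact.

Integration uses a stiff-capable solver (lsoda) with hard restarts at every
dose event (zero-amount events are injected at infusion start/stop so rate
discontinuities also restart the integrator). Defaults are rtol 1e-8 /
atol 1e-10; the test-suite and network runs use rtol 1e-6 / atol 1e-9, which
changes interval AUCs by far less than the two-fold qualification margin.
States are floored at zero on output with a warning if the floor exceeds
100×atol. Every simulation carries a mass-balance diagnostic (compartment
amounts + cumulative metabolized + unabsorbed vs administered); at an exact
dose instant the recorded state may be pre- or post-event, so the diagnostic
takes the smaller of the two conventions.

## PK endpoints and DDI ratios

AUC uses the linear-up/log-down trapezoid (the log trapezoid is exact on
mono-exponential decay segments); the method had to be fixed by choice since
no single convention is universal. Optional extrapolation to infinity fits
lambda_z by log-linear regression of the last 3–6 positive descending points
after Cmax. Tmax takes the first occurrence of the maximum. DDI trials
compare victim-with vs victim-without-perpetrator on a *declared* endpoint
interval: steady-state dosing-interval AUC for multiple-dose designs,
AUC(0→∞) for single-dose designs — the trial specification makes this
explicit because clinical DDI studies themselves differ. Predicted/observed
ratios carry two-fold acceptance flags (0.5 ≤ r ≤ 2), the conventional
qualification criterion.

## Sensitivity analysis

Relative sensitivity coefficients `S = ((ΔPK/PK)/(Δp/p))` are averaged over
perturbation sizes Δ ∈ {−10%, −5%, +5%, +10%} (configurable); averaging over
symmetric ± pairs cancels the leading curvature bias, and for power-law
responses S converges to the exponent. Parameters with a zero baseline are
skipped with a sentinel (relative change is undefined at zero). The ranked
report returns the minimal |S|-ordered prefix of parameters whose summed
share *strictly exceeds* the 90% threshold — a prefix landing exactly on the
threshold is extended by one, so the selected set always contributes more
than the stated share; ties are broken by parameter name for determinism.
Ranking is per endpoint (AUC and Cmax ranked separately, with a combined
report available), which we consider the defensible reading of "most impact
on either endpoint". The default parameter whitelist covers the tunable,
non-structural inputs: fu, blood:plasma ratio, Kp entries, pathway rate
constants, absorption parameters, inhibition constants, dose, and liver
volume/flow; perturbing an organ flow re-balances cardiac output so the
circulatory topology is preserved rather than silently violated.

## The synthetic-data generator

No clinical concentration data ship with the package; trials are emulated.
The generator reproduces the statistical structure that digitized
mean(±SD) clinical DDI data exhibit: sparse sampling schedules (6–16 points),
multiplicative (log-normal) residual error with configurable CV (default
20%), log-normal inter-individual variability applied as a per-subject
profile scale factor (default CV 30%, a stand-in for clearance/volume
variability), and LLOQ censoring with flagged BLQ rows. Datasets are
byte-reproducible given the seed. A non-compliance variant adds a constant
background intake for dietary compounds (caffeine), producing the elevated
pre-dose troughs that motivate hypothesis testing with the model.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: correlated residuals within a subject, parameter-level
(rather than profile-level) inter-individual variability with its nonlinear
propagation, covariate structure, dropout, assay heteroscedasticity beyond
the proportional model, and real digitization error. Parameter recovery
results on synthetic data are therefore a check of the estimation machinery,
not evidence about clinical identifiability.

Parameter fitting is bounded Levenberg–Marquardt least squares on log
concentrations (BLQ excluded) with three documented starts (the start value
and its geometric means with each bound); standard errors and correlations
come from the Jacobian at the optimum, and a singular or near-singular
Jacobian (|r| > 0.999) flags non-identifiability. Least squares on the log
scale is a declared stand-in for the (unpublished) objective of the
reference platform.

## Problem sizes and bundled parameterization

The qualification panel runs all 11 network pairs with one shared design —
perpetrator to near steady state over three days, victim dose on day 3,
24 h endpoint interval, 481-point output grid — chosen so the full panel
(22 simulations) completes in about a minute while interval AUCs are
grid-converged to well below 0.1%. Analytic-oracle checks use a fast-mixing
reduction of the same whole-body topology (organ flows of hundreds of L/min)
so the full engine, not a special code path, is compared against
one-compartment closed forms.

The bundled drug files reproduce the published *structures* (pathways,
inhibition mechanisms, interaction constants) but not the fitted PK
parameter sets, which are not in the main text; their PK values are
literature-plausible placeholders labeled illustrative. Quantitative DDI
ratios from the bundled files are therefore structurally sound
illustrations, not reproductions of reported predictions — with one
exception that is forced by structure alone: a CYP2C19 poor metabolizer
co-dosed with a pure competitive CYP2C19 inhibitor shows exactly 0% AUC
change regardless of parameterization.

## Known limitations

Flow-limited distribution only; adults only (no ontogeny); inhibition
network only (no induction); enzyme expression is organ-lumped (no zonation);
the Weibull multiple-dose overlap approximation above; TDI k_inact values
for the omeprazole/moclobemide autoinhibition are illustrative defaults, so
autoinhibition magnitudes (not mechanisms) are placeholders; and the
engine's competitive self-inhibition exclusion means a drug inhibiting an
enzyme it is also metabolized by contributes no *competitive* term to its
own pathways.
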