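---
title: "Modelling light-limited phototrophic growth with photofba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light-limited phototrophic growth with photofba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photofba)
```

## The problem

Flux balance analysis (FBA) predicts growth by maximizing a biomass
objective over the steady-state flux cone of a stoichiometric network. For
heterotrophs, capping a substrate uptake flux is usually enough to obtain
realistic optima. For phototrophs it is not: if photons are treated as an
ordinary substrate, the predicted growth rate is a linear function of the
photon supply, whereas measured growth-irradiance curves of cyanobacteria
saturate and then decline at high light (photoinhibition). `photofba`
closes this gap with two additions to the linear program, both with clear
photophysiological interpretations, and with the estimation machinery
needed to parameterize them from a measured growth-irradiance curve.

## Light absorption, quantum yield, photodamage

A culture illuminated with red light of intensity $I_0$ and a constant
blue background $I_b$ (both in µmol photons m$^{-2}$ s$^{-1}$) absorbs
photons at the specific rate

$$J_I = 3.6\,\alpha\,(I_0 + \alpha_b I_b)
\quad[\text{mmol photons gCDM}^{-1}\,\text{h}^{-1}],$$

where $\alpha$ (m$^2$ gCDM$^{-1}$) lumps the per-cell absorption
cross-section, culture density and vessel geometry into one effective
constant, and $\alpha_b$ weights blue photons relative to red ones (blue
light is predominantly absorbed at photosystem I and contributes less to
growth). The single unit conversion 3.6 (µmol s$^{-1}$ to mmol h$^{-1}$)
is applied here and nowhere else.

Absorbed photons are used productively with a quantum yield that decreases
with the absorption rate,

$$\eta(J_I) = \frac{K_L}{K_L + J_I}, \qquad
J_I^* = \eta(J_I)\, J_I = \frac{K_L J_I}{K_L + J_I},$$

so the utilizable photon flux $J_I^*$ saturates at the capacity $K_L$
(mmol photons gCDM$^{-1}$ h$^{-1}$). This form is not ad hoc: a two-state
model of a photosynthetic unit — activation $P^0 \to P^*$ at rate
$\sigma I_0 P^0$, relaxation $P^* \to P^0$ at rate $k_2 P^*$ feeding the
electron transport chain — yields exactly the same expression at steady
state under $K_L = k_2 P^T$ and $J_I = \sigma I_0 P^T$
(`two_state_activated()` and the identity tests in the suite), and with
$K_L = \alpha K_A$ the product $Y^{max}\,\eta(J_I)\,J_I$ is algebraically
a Monod curve (`monod_equivalence()`). Photodamage — dominated by D1
repair, observed at *all* intensities and proportional to light — is not
modelled as protein turnover but as its energetic shadow: an ATP demand

$$v_D = k_d\, J_I$$

driven by the *absorbed* (not the utilized) flux, with the dimensionless
$k_d$ in mmol ATP per mmol photons.

In the linear program, $J_I^*$ caps the summed photon flux through the
photon-consuming reactions (one shared cap over both photosystems — the
quantum yield describes the whole electron transport chain, so no
per-photosystem split is attempted), and $v_D$ is a dedicated
ATP-hydrolysis pseudo-reaction with both bounds fixed, so maintenance
(NGAM) and photodamage remain separately reportable.

## Physiological couplings

Biologically plausible optima additionally require ratio couplings that do
not emerge from stoichiometry alone. `physiological_constraints()` holds
them, with defaults matching the *Synechocystis* sp. PCC 6803 simulations
the package is built around:

| constraint | default | basis | mode |
|---|---|---|---|
| RuBisCO oxygenase, fraction of total RuBisCO flux | 0.03 | fraction of total flux | equality |
| Mehler-like | 0.10 | of PSII O2 production | equality |
| Mehler at PSI / PSII | 0.005 / 0.005 | of PSII O2 production | equality |
| terminal oxidase | 0.091 | of PSII O2 production | lower bound |
| NGAM | 1.5 mmol ATP gCDM$^{-1}$ h$^{-1}$ | — | lower bound |

The oxidase is a lower bound because it is conventionally stated as a
minimum electron overflow; the Mehler-type and RuBisCO couplings are
enforced as equalities since single values (not ranges) are prescribed for
them. Both modes are switchable per constraint. "PSII O2 production"
means the PSII reaction flux scaled by its O2 stoichiometric coefficient.
These couplings are constant across light intensities; they are inputs,
not predictions — the model cannot dissect their regulatory origin.

## Light-dependent biomass objective

Measured protein and glycogen mass fractions vary with light intensity.
`build_biomass_composition()` sets those two classes to measured values
and rescales the remaining classes proportionally so mass fractions sum
to 1; the growth-associated polymerization ATP scales with the protein
fraction by default (protein synthesis dominates polymerization costs),
with a switch to keep it constant. `set_biomass_objective()` maps a
composition back onto the biomass reaction through a metabolite-to-class
table, preserving the total drawn mass per unit flux of the reference
reaction (1 gCDM for a normalized reconstruction; the toy network's
biomass drain is a nominal gCDM unit, so its photon cost of 360 mmol/gCDM
stays exact).

## Parameter estimation

`fit_light_parameters()` estimates $\alpha$, $\alpha_b$, $K_L$, $k_d$ and
optionally the NGAM and oxidase minima by bounded Levenberg-Marquardt
least squares over the residual vector
$[\,10^3(\mu_{model}-\mu_{obs});\; (O_2^{dark,model}-O_2^{dark,obs})\,]$,
each model evaluation being one constrained LP solve. Net O2 evolution is
deliberately *not* fitted: it serves as an out-of-sample consistency check.
Standard errors come from the Jacobian at the optimum. Two robustness
choices matter:

* **Multistart.** The residual surface has a flat spurious basin at zero
  growth (e.g. $\alpha \to 0$); a single local search started far from
  the optimum can collapse into it. The fit therefore also starts from
  the package default and a capacity-shifted variant and keeps the best
  weighted RSS. With this, different sensible initializations reach the
  identical optimum.
* **What is identifiable.** On the toy network the non-light O2
  consumption is exactly proportional to growth, so NGAM and the oxidase
  fraction cannot be separated from the four light parameters by these
  data (the full 6-parameter problem has a one-dimensional ridge of
  zero-residual solutions). The recovery studies therefore fix the two
  maintenance parameters, as a practitioner would source them from
  literature, and estimate the four light constants — which are then
  exactly identified (zero-noise recovery to machine precision). At
  realistic noise ($\sigma_\mu = 0.003$ h$^{-1}$ on $\mu \approx 0.1$)
  the blue-light weight $\alpha_b$ remains the weakest parameter: it only
  enters through the constant offset $\alpha_b I_b \approx 14$ µE against
  red intensities of 25–1100 µE, and its sampling error is of order 20%
  — an identifiability limit of the experimental design, not of the
  optimizer. $\alpha$, $K_L$ and $k_d$ recover to within 15% under the
  same conditions. The same sloppiness appears in the phenomenological
  Haldane/Aiba fit (`fit_haldane()`): at a few percent noise its three
  parameters are strongly correlated, and the identifiable object is the
  fitted curve, which the tests assert instead of the parameter triple.

## The LP engine

No linear-programming backend is assumed: the package includes a dense
bounded-variable two-phase primal simplex (`solve_lp()`), refactorizing
the basis every iteration. This is deliberate for the problem sizes at
hand (tens to ~10^3 variables) — numerically transparent and easily
validated; it is not intended for models orders of magnitude larger.
Anti-cycling falls back to Bland's rule after $3(n+m)$ iterations;
entering-variable tolerance is $10^{-9}$; feasibility of phase 1 is
accepted below $10^{-7}$. The test suite validates the solver against a
brute-force vertex-enumeration oracle on random LPs and against the toy
network's closed forms; during development it was additionally
cross-checked against an external GLPK-based implementation on the same
SBML file. Degeneracy of the optimal flux distribution is resolved by a
parsimonious step (`parsimonious_solution()`): growth is fixed at the
optimum within a relative $10^{-6}$ (widened once to $10^{-4}$ if the
fixed problem is numerically infeasible) and total absolute flux is
minimized over split variables; all reported per-reaction quantities come
from this representative, while objective values are always taken from
the maximization step. Flux variability analysis fixes growth the same
way. Infeasible and unbounded statuses are surfaced, never silently
returned as zero — except inside scans and fits, where an infeasible
condition is recorded as zero growth with a flag, which is the correct
biological reading (the maintenance demand cannot be met at that light).

## The toy phototroph

`toy_phototroph_model()` is a first-class, tested fixture: the smallest
elementally balanced network that exercises every constraint type. Lumped
photosynthetic electron transport (PSET: 8 photons, 2 H2O, 4 ferredoxin
→ 1 O2, 9 lumen protons), FNR, an ATPase making 3 ATP per full cycle of
9 lumen protons, cyclic electron transport (2 photons → 3 pumped
protons, i.e. 1 ATP per 2 photons), a CBB carboxylase (1 CO2 + 3 ATP +
2 NADPH → CH2O), an oxygenase, Mehler-type sinks, a terminal oxidase,
NGAM and a biomass drain of $n_C$ CH2O and $n_A$ ATP per nominal gCDM.
Linear electron transport hence supplies exactly 3 ATP + 2 NADPH per 8
photons, and the optimum has the closed form used as the oracle across
the suite: the photon cost is $8 n_C + 2 n_A$ (360 mmol/gCDM at the
defaults $n_C = 40$, $n_A = 20$), and every extra mmol of ATP (NGAM or
photodamage) costs 2 photons through the cyclic route.

One consequence worth stating explicitly: at the default biomass
composition the optimal ATP/NADPH synthesis ratio, measured as
$3 J_{ATPase}/J_{FNR}$, is $(3 n_C + n_A)/(2 n_C) = 1.75$, *not* the 1.5
of the linear chain alone — the biomass ATP demand is met by cyclic
transport through the same ATPase. The pure 3:2 ratio is recovered
exactly (with zero variability width) in the configuration the derivation
describes, $n_A = 0$ with zero maintenance; both values are asserted in
the tests. Adding NGAM or photodamage raises the ratio, which is also the
qualitative behaviour of the genome-scale model at high light.

The synthetic dataset generator (`synthetic_growth_dataset()`) emulates a
turbidostat growth-irradiance experiment: 10 log-spaced red intensities
over 25–1100 µE with a constant 27.5 µE blue background, growth rates from
the full toy-FBA forward pipeline (or a Haldane closed form), dark O2
consumption from the O2 accounting, and zero-mean Gaussian noise clipped
at zero. Log spacing is the standard dose-response design and balances
information between the light-limited and photoinhibited regimes. What
the generator does *not* emulate: heteroscedastic or correlated
measurement error, optical-density dynamics, pigment acclimation
(α changing with light), or light-dependent biomass composition — so
passing recovery tests demonstrate the estimator's correctness and
conditioning, not that real cultures satisfy the model.

## Sensitivities and scans

`light_scan()` solves one LP per grid point (default grids: 1000 points
over 0–1210 µE for growth scans, 200 for variability scans; the tests and
the acceptance script use 25–122 points to keep runtimes in seconds) and
refines the optimal intensity by golden-section search to 0.5 µE inside
the bracketing grid interval. `normalized_sensitivity()` uses symmetric
finite differences with a fixed ±1% step (a 2% total change) on one
parameter at a time; the red intensity is perturbed with the blue
background held constant, mirroring the experimental design. The
coefficients are dimensionless and reproduce the expected regime
structure: absorption parameters dominate at low light; the sensitivity
to $I_0$ and $\alpha$ crosses zero exactly at the optimal intensity;
$k_d$ is negative wherever light is positive; and in a strictly linear
configuration (no saturation, damage or maintenance) the coefficient for
$\alpha$ is exactly +1 because growth is then proportional to absorption.
Coefficients are undefined (flagged `NA`) where growth is zero.

## Reading reconstructions

`read_sbml_model()`/`write_sbml_model()` handle the SBML Level 3
Version 1 subset relevant to constraint-based models, with the fbc
extension for formulas, charges, parameter-backed flux bounds, gene
products and the active objective; infinite bounds round-trip as
`INF`/`-INF`. Summary statistics count unique metabolites by stripping a
trailing `_<compartment>` suffix matching a declared compartment id — the
convention behind "unique metabolites" counts in published
reconstructions. Elemental balance checking skips exchange and biomass
reactions and reactions carrying photon species (massless by convention,
recognized by name among the formula-less species); reactions with other
formula-less metabolites are reported as uncheckable rather than failed.
The genome-scale *Synechocystis* reconstruction itself is consumed as an
input (see `reference_model_path()`), not curated or bundled here.

## Known limitations

* Single effective wavelength per band; no action spectra, scattering or
  fluorescence corrections.
* The ~12% headspace O2 loss discussed for net-O2 measurements is not
  modelled; predicted net O2 is the dissolved-phase optimum.
* Overflow reactions enter as fixed couplings, so their regulatory
  role at high light cannot be dissected.
* The simplex is dense and unsuited to networks far beyond $10^3$
  reactions.
* Haldane/Aiba and 6-parameter pipeline fits are locally identifiable at
  best; see the estimation section for what is asserted instead.
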