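---
title: "Calibration methods: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration methods: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcalib)
```

## The calibration problem

A daily soil–crop model predicts volumetric soil water content
$\theta$ (cm^3^/cm^3^) through a growing season as a function of a
45-dimensional parameter vector: for each of 8 soil layers the saturated
conductivity $K_s$ (cm/d), saturated water content $SAT$, field capacity
$FC$ and wilting point $PWP$ (cm^3^/cm^3^); five nitrogen transformation
constants ($V_n$, $K_n$, $K_d$, $A_d$, $K_v$); and eight crop parameters
($K_{ini}$, $K_{mid}$, $K_{end}$, $T_{sum}$, $SLA_{max}$, $SLA_{min}$,
$AMAX$, $R_{max}$). Observations are TDR soil water content readings at
16 depths (20–170 cm every 10 cm) on 17 fixed days after sowing, with
measurement error assumed Gaussian, sd 0.005 cm^3^/cm^3^. Priors are
independent uniforms over published calibration intervals; `param_space()`
is the canonical ordered table, and its row order defines the coordinate
semantics of every parameter vector in the package.

This vignette records the modelling choices behind each module, what the
synthetic-data generator does and does not emulate, and the numerical
conventions the samplers rely on.

## The surrogate forward model

The forward operator is a deliberately simple daily water-balance
surrogate rather than a full Richards-equation soil–crop simulator. The
design goal was threefold: consume all 45 parameters with physically
sensible roles, expose an exactly closing water ledger, and run one season
in well under a millisecond so that $10^4$–$10^5$ forward runs remain a
desk-scale exercise (the compiled daily loop runs a season in roughly
0.3 ms).

**Profile geometry.** The 180 cm profile is divided into 8 equal layers of
22.5 cm; measurement depth $d$ maps to layer $\lceil d / 22.5 \rceil$.
Layer thicknesses are a convention — the source tables define per-layer
parameter bounds but no layer geometry — and equal thickness is the
simplest consistent choice.

**Within-day order.** (1) precipitation plus irrigation infiltrate
top-down, filling layers to saturation (flood irrigation is given one day
to soak in); water left over once the profile is saturated ponds and runs
off. (2) each layer drains its storage above field capacity downward at
the conductivity-scaled rate

$$\mathrm{drain}_i \;=\; e_i \cdot \frac{K_{s,i}}{K_{s,i} + \Delta z_i}
  \cdot \min\!\Big(1, \frac{\theta_i - FC_i}{SAT_i - FC_i}\Big),$$

where $e_i$ is the drainable excess in cm, additionally capped by $K_s$
(one day's percolation) and by the receiving layer's remaining pore space;
the bottom layer drains freely out of the profile. (3) evapotranspiration
is removed last. A plain tipping rule (`drain = min(excess, Ks)`) was
rejected: with the published ranges ($K_s$ 29–89 cm/d against daily
excesses of a few cm) the cap never binds and $K_s$ would have no
influence at all. The rate form keeps every hydraulic parameter
influential — $FC$ sets storage levels, $SAT$ sets pore space, infiltration
depth and the drainage-rate denominator, $K_s$ the drainage tempo, $PWP$
the uptake floor — which is what a calibration testbed needs.

**Evapotranspiration.** Potential crop ET is $K_c(\mathrm{gdd}) \cdot
ET_0$ with the FAO-56-style piecewise-linear coefficient curve
(`crop_coefficient()`): $K_{ini}$ up to $0.2\,T_{sum}$, linear rise to
$K_{mid}$ by $0.45\,T_{sum}$, plateau to $0.75\,T_{sum}$, linear fall to
$K_{end}$ at $T_{sum}$. It is split 30% soil evaporation (layer 1, down
to an air-dry floor of $0.5\,PWP_1$) and 70% transpiration, distributed
over the root zone proportional to plant-available water
$(\theta - PWP)^+$ per layer. Root depth grows linearly with
$\mathrm{gdd}/T_{sum}$ to $R_{max}$. Transpiration demand carries a
bounded leaf-area proxy $\max(0.5,\; AMAX \cdot SLA_{max}/(54 \cdot 36))$,
so $AMAX$ and $SLA_{max}$ have a weak, smooth influence; $SLA_{min}$ is
accepted and validated but does not move the water balance — one of
several deliberately weakly- or un-constrained directions (see below).
Growing degree days use base 8 °C on the generated temperature series.

**Nitrogen.** Ammonium and nitrate pools are stepped daily
(`nitrogen_step()`): Michaelis–Menten nitrification
$V_n \cdot \mathrm{NH_4}/(K_n + \mathrm{NH_4})$, first-order
volatilization $K_v \cdot \mathrm{NH_4}$, and denitrification
$K_d A_d \cdot \mathrm{NO_3} \cdot s(\theta)$ with $s$ rising linearly
from 0 at $FC$ to 1 at $SAT$; fluxes are capped so pools stay
non-negative. Nitrogen has **no feedback on water**, so the soil water
observation vector is bit-identical under any nitrogen parameter change.
This is intentional: with water content as the only observed state the
five nitrogen parameters are unidentifiable, and a faithful testbed should
present the samplers with exactly that pathology (flat/multimodal nitrogen
marginals) rather than hide it.

**Initial conditions and time step.** Moisture starts at field capacity on
the sowing day; nitrogen pools at 5 and 20 g/m^3^ with fertilizer entering
the ammonium pool on its scheduled day. The step is one day, explicit, no
sub-daily iteration. Initial conditions are conventions shared between
truth generation and calibration, so they cancel out of the inference.

**Invariants.** $\theta \in [0, SAT]$ by construction, and the daily
ledger (inputs, ET, drainage, runoff, storage change) closes to machine
precision; the tests assert closure to 1e-9 cm and monotone storage
response to added irrigation.

## Synthetic data generation

`generate_weather()` emulates an extremely arid irrigated oasis: about
116 mm annual precipitation against roughly 20-fold potential
evaporation. Per 189-day season (sowing April 12, harvest October 18) it
places 16 wet days uniformly at random with Gamma(4, 1) event depths
(expected total ≈ 64 mm, the warm-season share of the annual total), a
sinusoidal $ET_0$ cycle with mean ≈ 6 mm/d calibrated so cumulative
$ET_0 \approx 20\times$ cumulative precipitation, and a continental
temperature sinusoid (≈ 10 °C at sowing, 26 °C midsummer) with mild
noise. Management follows the four published treatments: standard
irrigation (5 × 150 mm = 750 mm) or water-saving (105, 105, 120, 120,
120 = 570 mm), crossed with 138 or 92 kg urea-N/ha applied at the first
scheduled date.

What the generator does **not** emulate: real TDR error structure
(correlated, possibly depth-dependent — here homoscedastic diagonal
noise, deliberately unclipped so the stated covariance stays exact),
weather measurement error, inter-annual variability, and any structural
discrepancy between model and reality. Passing tests therefore
demonstrate that the samplers invert the surrogate correctly under their
own assumptions — the "perfect model" experiment — not that the surrogate
matches field soils.

The practical-style design reuses the field experiment's split:
8 depths (20–160 cm by 20 cm; 136 points) for calibration and 7
interleaved depths (plus 170 cm, 150 cm unused; 119 points) held out for
validation.

## Ensemble smoothers

`es_update()` implements the stochastic-perturbation analysis step: each
member assimilates its own perturbed observation copy, gains are computed
with 1/(Ne−1) covariances, and the linear system is solved (never
inverted) after a trace-scaled ridge of 1e-10 is added to the innovation
covariance.

**ES-MDA** (`esmda()`): default schedule is the constant
$\alpha_i = N$ satisfying $\sum_i 1/\alpha_i = 1$, the condition that
makes the multi-step scheme consistent with a single Bayes update in the
linear-Gaussian limit (the test suite verifies a `[2, 2]` schedule against
the closed-form posterior). A second convention requiring
$\sum_i 1/\alpha_i^2 = 1$ circulates in the literature; it is available as
`inflation_variant = "sum_inv_sq"` but is not the default because it
breaks the linear-Gaussian consistency property.

**ILUES** (`ilues()`): the combined objective uses equal weights
$a = b = 1$ (no published guidance; exposed in the interface) and a local
fraction of 0.1, i.e. $N_L = 50$ at $N_e = 500$. The normalising maxima
$J_1^{max}, J_2^{max}$ are taken over the candidate set being ranked — an
interpretation, since the defining equation does not say; per-candidate-set
maxima keep the two terms on comparable scales for every member. Each
member's local update uses local covariances and fresh perturbed
observations per local member per iteration, and the member is replaced by
a uniform draw from its updated local ensemble. Optional per-iteration
error inflation (`mda_inflation = TRUE`) combines the multiple-data-
assimilation idea with the local scheme; it is off by default since the
plain iteration is the canonical form.

**Bound handling.** Updated vectors falling outside the prior box are
reflected back inside (folding, an involution that preserves jump
magnitude almost everywhere). Reflection was chosen over clipping because
clipping piles probability mass onto the bounds and collapses ensemble
spread there.

**MAP convention.** Ensemble methods carry no posterior density, so the
MAP member is defined as the minimum-$J_1$ (equivalently maximum Gaussian
likelihood) member; `rmse_map()` is recomputable bit-exactly from the
stored ensemble and observations.

**Calibrated spread.** A local-updating scheme buys multimodality at a
price: resampling from small local ensembles tends to underestimate
marginal posterior spread relative to the global scheme, whose
linear-Gaussian limit is exact. The parameter-recovery coverage check in
the test suite therefore uses the ES-MDA posterior; the bimodal-recovery
check uses ILUES. Each method is asserted on the property it is designed
to deliver.

**Mode-occupancy conventions.** For the bimodal benchmark ($f(m) = m^2$,
observation 4, prior $U[-5,5]$; a dense-grid oracle confirms two equal
modes at $\pm 2$ holding >99% of the mass) a mode counts as *populated*
when it holds at least half of its true 50% share (occupancy ≥ 0.25), and
an ensemble as *collapsed* when the minority mode retains under 0.15.
The toy uses a small ensemble (50), sharp noise (0.02) and 20 iterations:
small-ensemble sampling noise is exactly what seeds mode extinction under
a global update, while the local update resists it; with a local fraction
of 0.2 the local sets keep ≥ 10 members so local covariances stay stable.

## DREAM samplers

`dream()` runs multiple chains whose proposals are generated from an
archive of thinned past states, in bound-normalised coordinates (each
parameter scaled to [0, 1]), which makes a common jump scale meaningful
across parameters whose natural units differ by four orders of magnitude.

Decisions the sampler needed that no published setting fixes:

* **Likelihood**: independent Gaussian with $R = \sigma^2 I$,
  $\sigma$ = the observation noise sd; a uniform-prior box indicator
  contributes $-\infty$ outside the bounds.
* **Archive**: initialised with $10d$ prior draws (and their
  predictions, needed by the Kalman proposal); every 10th generation all
  chains' current states are appended. The archive never contains the
  proposing generation's states.
* **Moves**: parallel-direction jumps use $\delta \in \{1,2,3\}$
  difference pairs, crossover probability drawn from $\{1/3, 2/3, 1\}$
  (the full adaptive crossover machinery is out of scope),
  $\gamma = 2.38/\sqrt{2\delta d'}$ with unit-jump generations every 5th
  step for mode hopping; snooker moves use
  $\gamma_s \sim U(1.2, 2.2)$ and carry the
  $(\|\theta_p - z\|/\|\theta - z\|)^{d-1}$ Metropolis correction.
* **Kalman proposal** (kzs only): $\theta_p = \theta + K r + K\epsilon$
  with $r = d - f(\theta)$ — the data residual of the current state, the
  only dimensionally consistent reading of the defining equation — and
  $K$ estimated from the archive's parameter/prediction pairs (cached
  until the archive grows). The move is asymmetric and is used without a
  proposal-ratio correction, so it is restricted to the first
  $T_k = 0.2\,T$ generations and **all** generations $t \le T_k$ are
  discarded as burn-in for both variants, keeping summaries comparable.
* **Bounds**: proposals are reflected into the box, as for the smoothers.
* **Reproducibility**: a single seeded RNG stream drives the whole run;
  chains advance sequentially within a generation and share the archive,
  so one root seed reproduces a run bit-for-bit.
* **Outlier-chain correction**: none — at 3 chains × 1000 generations the
  usual IQR test has no power; long-run users should raise the chain
  count instead.

Convergence reporting uses the multi-chain Gelman–Rubin statistic on
post-burn-in samples (for identical chains it attains its floor
$\sqrt{(n-1)/n}$). Note that at the published run length (3 × 1000) R-hat
on the 45-dimensional problem remains well above 1; the fit-oriented
diagnostics (RMSE evolution, first-passage generation, ME/IA
distributions) are the operative comparison there, as they were in the
original study design.

## Evaluation conventions

`fit_stats()` implements ME, RMSE and Willmott's IA exactly; IA is
undefined (NA) only when both series equal the observed mean.
`uncertainty_bands()` reports pointwise central 95% quantiles of the
posterior predictions (parameter uncertainty) and of predictions plus a
fresh noise draw (total uncertainty) — pointwise central quantiles are a
choice, documented here, since band semantics are not otherwise pinned
down. `summarize_marginals()` bins with a fixed Freedman–Diaconis rule so
histograms are reproducible. `first_passage()` censors chains that never
reach the threshold at $T + 1$.

## Problem sizes

The experiment functions default to the study's stated conditions —
ensemble size 500 with 3 iterations, 3 chains × 1000 generations, noise
sd 0.005 — because the compiled forward model makes them cheap (seconds).
The test suite itself runs reduced configurations chosen for coverage per
unit time: toy problems with closed-form posteriors for correctness,
ensembles of 100–500 on the full 45-parameter problem, MCMC runs of
300–4000 generations, and 5–20 seeded repetitions for the
frequency-of-success properties.

## Known limitations

* The surrogate is a bucket model: no Richards flow, heat transport, crop
  growth feedback or yield; conclusions about sampler behaviour transfer
  to heavier simulators, conclusions about soil physics do not.
* The nitrogen block is observationally inert by design; with additional
  observed states (nitrate, N uptake, yield) those parameters would
  become identifiable, and the samplers accept any forward function with
  richer outputs.
* ILUES marginal intervals are not calibrated frequentist intervals (see
  above); treat them as mode-structure summaries.
* The DREAM implementation omits adaptive crossover learning, multi-try
  variants and parallel tempering.
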