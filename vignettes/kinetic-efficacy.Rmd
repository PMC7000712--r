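---
title: "Measuring kinetic efficacy (k-tau) and biased agonism from biosensor time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring kinetic efficacy (k-tau) and biased agonism from biosensor time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktau)
```

## The model

GPCR signaling assays based on genetically encoded fluorescent biosensors
read the same wells repeatedly, producing dense time courses of the signal.
This package quantifies such time courses with a single kinetic efficacy
parameter: the **initial rate of response generation by the agonist-occupied
receptor**, written $k_\tau$ and expressed in normalized fluorescence units
(NFU) per minute. Like the initial rate of an enzyme reaction, $k_\tau$ is
the rate before regulation mechanisms (receptor desensitization, signal
degradation, precursor depletion, arrestin dissociation) bend the curve, so
it does not depend on the time point at which the assay is read.

**Arrestin recruitment.** Agonist-bound receptor ($RA$) binds arrestin ($N$)
with rate constant $k_N$ (in practice dominated by receptor phosphorylation)
and the complex dissociates with $k_{-N}$. Under either stoichiometric excess
(receptor over arrestin or the converse) the ternary complex follows

$$[NRA]_t = \frac{\rho_A\, k_\tau}{k_{obs}}\left(1 - e^{-k_{obs} t}\right),
\qquad k_{obs} = \rho_A C + k_{-N},
\qquad \rho_A = \frac{[A]^n}{K_A^n + [A]^n},$$

where $k_\tau = [N]_{TOT}[R]_{TOT} k_N$ and $C$ is $[R]_{TOT} k_N$ or
$[N]_{TOT} k_N$ depending on which side is in excess. The two scenarios are
indistinguishable from time-course data, and the individual factors
$[R]_{TOT}$, $[N]_{TOT}$, $k_N$ are not separately identifiable: the package
is deliberately parameterised by the products (`k_tau`, `c_scale`) and keeps
the scenario as metadata only (`arrestin_params()`).

The key identity is that the asymptote (Plateau) times the observed rate
constant equals $\rho_A k_\tau$ exactly, so at a maximally effective
concentration ($\rho_A \to 1$)

$$[\mathrm{Plateau} \times k_{obs}]_{[A] \gg K_A} = k_\tau .$$

**Downstream signaling.** Second-messenger responses (diacylglycerol,
calcium) rise and then fall as two regulation mechanisms engage. They are
described by the biexponential

$$y = \frac{C}{k_1 - k_2}\left(e^{-k_2 t} - e^{-k_1 t}\right),$$

whose initial slope is exactly $C$ regardless of $k_1, k_2$ — so the fitted
$C$ **is** $k_\tau$ for that pathway, in the same units. This common currency
across curve shapes is what makes kinetic bias comparisons possible.

**Biased agonism.** Each ligand's $k_\tau$ is normalized to a reference full
agonist within each pathway (percent of reference), and kinetic bias is the
ratio of those normalized values between two pathways. Because the
normalization divides out pathway-specific sensor gain and amplification,
the ratio is invariant to rescaling either pathway's signal — the property
that justifies comparing different sensors.

## Fitting workflows

All fitters are unweighted nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`) with asymptotic, Jacobian-based standard errors, matching
standard curve-fitting practice for plate-reader data. Time courses include
a flat pre-stimulus baseline and a **free onset time** `x0`, which absorbs
well-to-well differences in the moment of agonist addition:

* `fit_association()` / `fit_decay()` — plateau-then-exponential for upward
  and downward responses, with parameters `y0`, `plateau`, `k`, `x0`;
* `fit_risefall()` — baseline, `c`, `k1`, `k2`, `x0`, optionally a linear
  baseline `drift` (for calcium sensors whose late plateau sits slightly
  below the pre-stimulus signal);
* `fit_sigmoid()` — the variable-slope log-concentration sigmoid (bottom
  fixed at zero in the $k_\tau$ analysis);
* `fit_operational()` — the operational model
  $y = E_m \rho_A \tau / (1 + \rho_A \tau)$ with $E_m$ fixed externally to
  the reference agonist's fitted maximum.

Technical replicates are always fitted as **separate points**, never
averaged, which propagates the true replicate scatter into the standard
errors.

Two estimation routes give $k_\tau$ for exponential responses:

1. **Concentration-response** (`ktau_dose_response()`): fit each
   concentration, multiply Plateau by $k_{obs}$, fit the sigmoid against
   log concentration. $k_\tau$ is the top of the curve and the midpoint
   L50 estimates the ligand equilibrium dissociation constant $K_A$
   (reported also as $pK_A$).
2. **Single saturating concentration** (`ktau_single_conc()`):
   Plateau $\times$ $k_{obs}$ directly, with first-order error propagation
   using the fit covariance. The saturation criterion is
   $[A] \ge 100 \times K_A$ when $K_A$ is known; below it a warning marks
   the estimate as occupancy-attenuated.

`ktau_global()` fits all concentrations simultaneously to the mechanistic
model (shared $k_\tau$, $C$, $k_{-N}$, $K_A$, slope $n$). The split between
$C$ and $k_{-N}$ is only weakly identified when $k_{-N}$ is small; the
function warns when their estimates are nearly perfectly anti-correlated.
`ktau_risefall()` reads $k_\tau$ off the fitted `c`. `half_life()` converts
rate constants to seconds ($60 \ln 2 / k$).

### Numerical choices

* Convergence: relative parameter tolerance $10^{-10}$, at most 10,000
  residual evaluations; non-convergence raises an error, never a silent
  return.
* Bounds: rate constants positive; `x0` within the observed time range and,
  for the rise-and-fall model, not later than the (smoothed) peak; other
  parameters unbounded.
* Starting values are data-driven: onset at the largest first difference of
  a running-mean smoothed copy of the trace, baseline from the earliest
  reads, plateau from the last 10% of points, rate from time-to-half-change.
  The smoothing enters only the heuristics — fits always use the raw points.
* The biexponential objective has competing ridges in (`c`, `k1`, `x0`) on
  weak-amplitude traces, so `fit_risefall()` tries a small fixed grid of
  rate-constant starting pairs and keeps the lowest residual sum of squares.
  Its two rates are exchangeable; the `k1 >= k2` convention is applied after
  convergence, and within a relative gap of $10^{-6}$ the analytic
  degenerate limit $C t e^{-kt}$ is evaluated instead of the cancelling
  difference of exponentials.
* An unidentifiable parameter (for example the rate constant of a flat
  trace) is reported with an infinite standard error and flagged, rather
  than failing.

## The synthetic data generator

`plate_scenario()` plus `generate_arrestin_plate()` /
`generate_risefall_plate()` emulate a plate-reader experiment with known
ground truth: a 9-second read interval over 20 minutes, at least five
baseline reads before agonist addition at 0.75 min, per-well onset jitter
(sd 3 s) reflecting manual pipetting, and a downward (or upward) sensor
whose fluorescence is a linear map of the model signal,
$F = F_0 (1 \mp \mathrm{gain}\cdot y(t))$ with gain 1 by default so that a
saturating arrestin plateau of ~0.44 NFU appears as $\Delta F/F \approx
0.56$. Noise is **multiplicative Gaussian** with constant CV (default 3%),
chosen because plate-reader robustness is conventionally summarised as
percent CV; an additive read-noise floor is deliberately not modelled.
Preprocessing mirrors the experimental convention: `delta_f_over_f()`
divides by the mean pre-addition fluorescence of the same well and
`invert_downward()` maps downward sensors to $1 - \Delta F/F$.

`builtin_fixtures()` ships ready scenarios whose ground truth mirrors the
AT1 angiotensin receptor system: an AngII-like full agonist
($k_\tau = 0.41$ NFU/min, $K_A = 120$ nM, saturating half-time 45 s), an
SII-like slow partial agonist (half the rate, ~9-fold weaker affinity,
84-s half-time), a TRV055-like near-full agonist, DAG-like
($C = 1.7$ NFU/min) and calcium-like ($C = 2.2$ NFU/min, negative drift)
rise-and-fall pathways, and a two-pathway pair with a built-in
arrestin/calcium kinetic bias factor of exactly 3.

What the generator does **not** emulate: photobleaching, channel
bleed-through, well-edge effects, receptor internalization, and any
nonlinearity between complex formation and fluorescence quench (the linear
map is a generator assumption, not a claim about the sensor). Passing
recovery tests on this generator therefore demonstrates correctness of the
analysis chain under the stated noise model, not robustness to optics
artifacts.

Two resolution-driven design choices deserve emphasis:

* **Rise-and-fall kinetics in the fixtures are set so the 9-s grid resolves
  the rise** ($k_1 = 2$–$3\ \mathrm{min}^{-1}$, peak around 1–1.5 min).
  Real calcium transients can rise within seconds; at that speed only ~3
  reads cover the rise and the initial-rate constant $C$ becomes practically
  unidentifiable with a free onset time (we measured ~25% estimator error at
  $k_1 = 6\ \mathrm{min}^{-1}$, shrinking to ~5–10% at $k_1 \le 3$). Users
  simulating faster pathways should shorten the read interval accordingly.
* **Replicate %CV of duplicates is a half-normal, not a point mass.** With
  i.i.d. multiplicative Gaussian noise of CV $\sigma$ and $n = 2$
  replicates, the per-timepoint sample CV is distributed as
  $\sigma\lvert Z\rvert$, $Z \sim N(0,1)$: its median is $0.67\sigma$ and
  the probability of any single point exceeding $\tfrac{7}{3}\sigma$ is
  ~2%. Across the ~1000 points of a full plate, an empirical envelope such
  as "every duplicate CV below 7% and 98% below 5%" is therefore only
  attainable with Gaussian duplicates if the underlying noise CV is about
  2% or lower (or with many more replicates). A dataset reporting such an
  envelope is evidence of sub-3% instrument noise; the generator run at 3%
  CV intentionally does not reproduce it, and the corresponding acceptance
  check documents this gap rather than papering over it.

## Plate quality control and endpoint comparison

`percent_cv()` summarises replicate agreement per time point (sample sd over
mean, in percent). `z_prime()` computes the screening-window statistic
$Z' = 1 - 3(\sigma_+ + \sigma_-)/\lvert\mu_+ - \mu_-\rvert$ per time point
from positive and negative control wells, using sample standard deviations;
it is highest and stable on the plateau phase, which is where a single-point
screen should read. `endpoint_dose_response()` evaluates each well's fitted
curve at a fixed time after its own onset (using the fit rather than raw
wells removes addition-time offsets) and fits the sigmoid to give the
endpoint EC50 and Emax. On simulated recruitment data this reproduces the
characteristic endpoint pathologies: EC50 shrinks as the read time grows,
and a half-rate partial agonist looks partial on the rise phase but
near-full at the plateau — the phenomena the rate-based $k_\tau$ analysis
avoids.

## A worked run

```{r worked, eval = FALSE}
fx <- builtin_fixtures(seed = 1)
plate <- generate_arrestin_plate(fx$angii_single_conc)
fit <- fit_association(preprocess_plate(plate))
ktau_single_conc(fit)
half_life(coef(fit)[["k"]])
```

Problem sizes used throughout the test suite and the acceptance script are
the study's own: 0–20 min at 9-s spacing (134 reads/well), half-log
concentration series from 10 nM to 32 µM, duplicate or triplicate wells,
3% noise. A full synthetic concentration-response (8 concentrations × 3
replicates) fits in well under a second.

## Known limitations

* $k_\tau$ for downstream pathways inherits receptor-reserve effects; no
  reserve correction is attempted.
* No statistical test of "biased vs. unbiased" is provided — the package
  reports ratios with propagated uncertainties and leaves inference to the
  user.
* The global fit assumes a single shared onset across wells; per-well
  jitter (3 s) is well below the read interval (9 s), making this a
  second-order approximation.
* Percent columns recomputed from rounded published means can differ by a
  couple of percentage points from values computed on unrounded means;
  comparisons against printed tables should allow for that.
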