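---
title: "Modeling detection of electrocutaneous pulse trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling detection of electrocutaneous pulse trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocidetect)
```

## The problem

Low-amplitude intra-epidermal electrical stimulation preferentially
recruits thinly myelinated Aδ nociceptive fibers while bypassing
mechanoreceptors, which makes a yes–no detection task with such stimuli a
window onto the nociceptive pathway. The stimulus is a cathodic square-wave
pulse train with four parameters: amplitude $A$ (mA; the package works with
the magnitude of the cathodic current throughout), number of pulses NoP,
onset-to-onset inter-pulse interval IPI (ms) and pulse width PW (ms). The
detection threshold $A_{50}$ is the amplitude at which the detection
probability $\Psi(A)$ equals one half.

`nocidetect` implements two lumped six-parameter models of this detection
process and the machinery to compare them:

* a **drift-diffusion model (DDM)** — a stochastic leaky integrator for the
  lumped postsynaptic potential (PSP) of dorsal-horn neurons, spiking on a
  first threshold crossing;
* a **hazard model (HM)** — the same deterministic PSP, with spikes
  generated by an inhomogeneous Poisson process whose rate is a sigmoidal
  function of the PSP (escape noise).

## Model structure

### Peripheral layer

A pulse of width PW activates afferent fibers by the strength–duration law
$f_A = A\,(1 - e^{-\mathrm{PW}/\tau_1})$, which saturates to the rheobase
level $A$ for long pulses. The recruited synaptic drive is threshold-linear
in the activation, $[f_A - \alpha_1]_+ = \pi\,(f_A-\alpha_1)\,H(f_A-\alpha_1)$.
The factor $\pi$ is not cosmetic: it is inherited from the area of the
recruited disc of nerve endings in the underlying physical geometry
(point-source potential, inverse-square input to vertically terminating
nerve endings, a minimal ending depth $h$ and homogeneous areal density
$\rho$). The physical layer is implemented in full
(`critical_radius()`, `recruited_count()`, `membrane_peak()`) but sits off
the simulation hot path; it serves as a consistency oracle for the lumped
layer, and the tests verify the algebraic identity
$N_r = \kappa\,[f_A-\alpha_1]_+$ to $10^{-10}$ relative error over random
parameter sweeps. No numeric values are published for the physical
quantities, so the oracle uses arbitrary positive values and the identity
only. The recruited count is kept continuous deliberately; no integer
rounding is applied.

### Central layer

Each presynaptic volley injects an exponential synaptic current with decay
constant $\tau_s = 1.5$ ms; the PSP follows a leaky integrator with
membrane constant $\tau_2$. The noise-free PSP is therefore a sum of
double-exponential transients, one per pulse (`hm_psp()`), with the
degenerate case $\tau_2 = \tau_s$ handled by its analytic limit whenever
the relative gap is below $10^{-9}$.

The DDM adds white noise: $\tau_2\,dx = (-x + I_p(t))\,dt + \sigma\,dW$,
simulated by Euler–Maruyama with fixed step $dt$, and a spike is a crossing
of the scaled firing threshold $\alpha_2$ anywhere on the discrete grid
(no interpolation between steps; the $O(\sqrt{dt})$ crossing bias is shared
with the reference results). The noise increment is taken literally from
the stochastic differential equation, i.e. $(\sigma/\tau_2)\sqrt{dt}\,\eta$
with time in ms — the printed equation never resolves the
$\sqrt{\mathrm{ms}}$ dimension of $dW$, and the package treats
$\sigma$ as a plain numeric value in the package unit convention. The
single-channel detection probability is the spike fraction of $N$
realizations; $l$ channels with identical input and independent noise
combine analytically as $\Psi_D = 1-(1-\Psi_{D,s})^l$, which is exact under
the independence assumption, so the $l$ channels are never simulated
separately.

The HM replaces path noise by escape noise: an inhomogeneous Poisson
process with rate
$\lambda(t) = \lambda_L\,/\,(1+e^{-(x^0(t)-\alpha_L)/\sigma_L})$ and
$\Psi_H = 1 - e^{-\int_0^T \lambda\,dt}$. The population size is absorbed
into $\lambda_L$, so the HM parameter vector is
$(\alpha_1, \tau_1, \tau_2, \alpha_L, \sigma_L, \lambda_L)$ against the
DDM's $(\alpha_1, \tau_1, \tau_2, \alpha_2, \sigma, l)$, sharing the first
three.

## Units and defaults

All times are in ms, currents in mA, the lumped PSP and
$(\alpha_2, \sigma, \alpha_L, \sigma_L)$ in A/s (= mA/ms), and rates
($\lambda_L$) in kHz (= 1/ms). With this convention no unit conversion
factor appears anywhere in the dynamics. Defaults: trial interval
$T = 500$ ms, timestep $dt = 0.01$ ms, ensemble size $N = 200$, amplitude
grid 0 to 2 mA in steps of 0.01 (201 points), $\tau_s = 1.5$ ms. These are
the study conditions; every default can be overridden through
`trial_config()` or the config files.

## Numerical choices

**RNG.** Drift-diffusion ensembles use a counter-seeded xoshiro256++
generator with Box–Muller normals inside the compiled core. Each
(combination, amplitude) cell gets its own substream derived from the root
seed, so curves are bit-reproducible, order-independent and embarrassingly
parallel in structure. Independent draws are used across amplitudes (no
common random numbers): independence is the conservative reading for
Monte-Carlo curves. Below the recruitment kink
$A < \alpha_1/(1-e^{-\mathrm{PW}/\tau_1})$ the drive is identically zero
and all such cells estimate the same spontaneous-detection probability;
`ddm_curve(share_subthreshold = TRUE)` can reuse one zero-drive ensemble
for all of them, but the default keeps every cell independent. The
distinction matters for fitting: the population rate $\lambda_L$ is
identified largely by the spontaneous level, and averaging many
independent tail estimates pins it far better than one shared draw
(empirically, the spread of fitted $\lambda_L$ across seeds roughly
triples under sharing).

**Early termination.** When only the spike flag is needed, a realization
stops at its first crossing. The max-based response is unaffected, and the
saving is what makes full 201-point curves with $N = 200$ affordable.

**Hazard integral.** The public `expected_spikes()` and
`hm_detect_prob()` use adaptive quadrature (`stats::integrate`,
rel. tol. $10^{-10}$) split at the pulse onsets where the integrand has
kinks. Curve evaluation and fitting use a fixed graded Gauss–Legendre
panel rule (panels clustered behind each onset on the $\tau_s$ scale,
widening into the $\tau_2$ decay): its nodes depend only on the temporal
parameters, so a whole amplitude grid is evaluated as one matrix sweep.
The two routes agree to $10^{-6}$ in the fitted regime (tested). Using the
same fixed rule on both sides of a fit keeps self-fits exact; in extreme
corners of the parameter space (hazard slope $\sigma_L$ orders of
magnitude below $\alpha_L$) the fixed rule can misplace a few $10^{-3}$ of
probability, but there the psychometric function is a grid-scale step and
the fitting error is insensitive.

**Optimisation.** The fit of $(\alpha_L, \sigma_L, \lambda_L)$ minimises
the relative fitting error
$E=\sum_j \sum_i (\Psi_{D,j}(A_i)-\Psi_{H,j}(A_i))^2 / \sum_i \Psi_{D,j}(A_i)^2$
jointly across all combinations (one parameter triple for all panels).
The denominator uses the reference curve only; a combination whose
reference curve is identically zero on the grid is dropped with a warning
to avoid 0/0. Optimisation runs Nelder–Mead over the log-transformed
parameters — positivity by construction, and $\sigma_L$ spans orders of
magnitude so log-space avoids boundary pathologies — from one data-driven
start (hazard threshold at the PSP peak of the reference half-detection
amplitude) plus stratified log-uniform starts, refining the two best to a
$10^{-13}$ relative tolerance with a fresh-simplex restart. Self-fits
recover known parameters to well under 1% with $E \le 10^{-6}$ (tested).

**Thresholds.** The HM threshold solves $\Psi_H(A) = 0.5$ by `uniroot`
(tolerance $10^{-9}$ mA) on $[0, 10]$ mA, expanding the bracket
geometrically if needed; existence requires
$T\lambda_L < \ln 2\,(1+e^{\alpha_L/\sigma_L})$, which is checked first —
otherwise spontaneous activity alone reaches the half-detection level and
an error is raised. The DDM threshold interpolates the simulated curve
linearly at its first upward half-crossing (deterministic and simple);
isotonic-regression pre-smoothing is available for noisy curves.

## Probability summation and observation windows

For widely separated pulses each pulse is perceived independently and the
expected spike count doubles, giving
$\Psi_H(\mathrm{NoP}=2) = 1-(1-\Psi_H(\mathrm{NoP}=1))^2$ and the two-pulse
threshold asymptote defined by
$\Psi_H(A_{2,50}, \mathrm{NoP}=1) = 1-\sqrt2/2$. One bookkeeping subtlety
matters at the package's tolerances: the hazard rate has a spontaneous
floor $\lambda_L/(1+e^{\alpha_L/\sigma_L})$ that accrues over the whole
trial, so at a *fixed common* window $T$ the identity is violated by
exactly one baseline term ($\lambda_T^{(2)} = 2\lambda_T^{(1)} -
\lambda_0 T$), which for the threshold-study parameters amounts to roughly
$10^{-2}$ relative — far above the $10^{-3}$ the identity should hold to.
The package therefore matches observation windows: a two-pulse trial of
length $2T_1$ is compared against single-pulse quantities on $T_1$, under
which the identity is exact up to transient tails ($e^{-\mathrm{IPI}/\tau_2}$,
negligible for IPI $\ge 10\tau_2$). The relative spike-count check is
additionally evaluated on suprathreshold amplitudes, where stimulus-driven
firing dominates the floor; at $A = 0$ the "doubling" statement is about
nothing but baseline and carries no information.

## What the study pipeline does

```{r, eval = FALSE}
params_d <- preset_params("comparison_ddm")
crv <- ddm_curve(stim_table2(), params_d, trial_config(seed = 1))
fit <- fit_hm(crv, n_starts = 8, seed = 1)
glance(fit)
autoplot(fit)
```

`ddm_curve()` simulates the eight-combination psychometric family
(201 amplitudes, $N = 200$); `fit_hm()` then finds the single
$(\alpha_L, \sigma_L, \lambda_L)$ triple that reproduces all eight curves.
The Monte Carlo study (`mc_fit_study()`) repeats this for parameter
vectors drawn uniformly from the study box (`table3_bounds()`; `l` uniform
over the integers 1–20), keeping only *admissible* draws with
$\Psi_D(0) < 0.35$ and $\Psi_D(2) > 0.65$ — the endpoint restriction is
enforced for every fitted combination, so each accepted sample contributes
informative curves, and the endpoint probabilities are estimated with the
study's own $N$ and $dt$. Accepted samples are counted exclusive of
rejections, and the rejection count is reported. The result is the
empirical fitting-error distribution $F_E$; its median is the headline
summary.

Problem sizes: the packaged acceptance script runs the joint fit at full
study scale (three seed replicates) and the Monte Carlo study at a reduced
scale chosen for a desk-class machine — 50 accepted samples, amplitude
step 0.05, $N = 100$ — which the test suite bounds at twice the
full-scale median error target. A full-scale 500-sample study is a
several-hour run of the same function with different arguments.

## What the synthetic conditions do and do not show

All inputs are synthetic by construction: the models *are* the object of
study, and the "data" are model-generated psychometric curves. The
generator therefore emulates the study conditions exactly (stimulus
combinations, grids, ensemble sizes, parameter boxes) and nothing else.
Passing tests show internal consistency (scheme versus closed form,
simulation versus analytic probability theory, optimizer recovery) and
reproduction of the published comparison numbers; they do not validate
either model against human psychophysics beyond the qualitative threshold
orderings (wider pulses and more pulses lower thresholds) that the matched
parameter sets reproduce. Reaction times, short-term synaptic plasticity,
threshold noise, NMDA-receptor signalling and descending modulation are
deliberately outside the models.

## Known limitations

* The DDM detection probability inherits an $O(\sqrt{dt})$ bias from
  discrete-grid crossing detection; it is part of the model definition
  here, not corrected for.
* The fixed hazard quadrature trades worst-case accuracy in pathological
  ($\sigma_L \to 0$) corners for vectorised speed, as discussed above.
* `l` enters the DDM only through an analytic power; correlated channel
  noise would need a different combination rule.
* The Monte Carlo acceptance region depends on the stochastic endpoint
  estimates; at $N = 100$ a borderline draw can flip its admissibility
  decision between re-evaluations, which slightly blurs the region's
  boundary but not the error distribution of clearly admissible samples.
* At the reduced study scale the fitting error of high-channel-count
  samples is dominated by an irreducible noise floor: the population
  transform $1-(1-k/N)^l$ amplifies baseline binomial noise by roughly a
  factor $l$, so for $l \gtrsim 10$ the per-sample error is
  $\sim 0.1$–$0.2$ at $N = 100$ regardless of how well the hazard model
  fits the underlying curve (halving at the full-scale $N = 200$).
  Re-optimising such samples with twice the starts changes none of their
  errors, confirming the floor is statistical, not numerical. As a
  consequence the 50-sample median is itself noisy at the working bound
  used in the tests; the full-scale 500-sample study is the quantity with
  a stable median.
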