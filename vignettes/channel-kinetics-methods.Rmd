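---
title: "Methods: gating kinetics under diffusion-limited solution exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating kinetics under diffusion-limited solution exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chankin)
```

## Scope and model

`chankin` analyzes macroscopic activation of ligand-gated channels
(CNG-type channels gated by cyclic nucleotides, P2X receptors gated by ATP,
and similar) recorded from excised patches under rapid solution switching.
Three layers make up the framework.

### 1. The concentration step at the patch

A patch excised into the pipette interior sits a distance $L$ (order of
micrometres) behind the tip. When the bath solution switches, the ligand
reaches the membrane by diffusion through this dead volume. Treating the
tip-to-patch space as a one-dimensional cylinder, with a mirror cylinder
accounting for molecules reflected at the membrane, the concentration at
the membrane is

$$c(L,t) = c_2 + (c_1 - c_2)\,\frac{4}{\pi}\sum_{n=1}^{\infty}
  \frac{-(-1)^n}{2n-1}
  \exp\!\left[-D\,(2n-1)^2\frac{\pi^2}{4L^2}\,t\right],$$

with initial level $c_1$, final level $c_2$ and diffusion coefficient $D$.
After an initial sigmoid phase the first term dominates, giving a delayed
exponential with

$$\tau = \frac{4L^2}{D\pi^2}, \qquad t_0 = \tau\,\ln\frac{4}{\pi}
  \approx 0.24\,\tau .$$

`series_concentration()` evaluates the full series, adding terms until the
next term falls below `tol` (default $10^{-10}$) of the step amplitude —
the series alternates with decreasing terms, so this truncation bound is
rigorous; a hard cap of $10^4$ terms guards the $t \to 0$ edge, where the
exact value $c_1$ is returned directly. `approx_concentration()` is the
delayed exponential. For $t \ge \tau/2$ the two agree within 2% of the step
amplitude, so the delayed exponential is used everywhere downstream.

Two conventions exist for $t < t_0$. The general form holds the pre-switch
concentration $c_1$ (continuous at $t_0$); the convenient special case when
stepping up from zero ligand returns 0. Both are available
(`strict_zero`); the $c_1$ branch is the default because it chains
arbitrary protocols continuously.

**Calibration.** $\tau$ is measured per patch by switching the permeant K⁺
concentration from 150 to 120 mM at maximally open channels and fitting
the delayed exponential to the current relaxation (`fit_exchange_tau()`).
The delay is *constrained* to $t_0 = \tau\ln(4/\pi)$, since the diffusion
model fixes that ratio — a free-delay variant exists behind
`constrain_delay = FALSE` as a robustness check. A fitted amplitude smaller
than three residual standard deviations flags the result low-confidence
(e.g. on a flat trace). The ligand's time constant follows from the
geometry being fixed: $\tau_\text{ligand} = \tau_\text{K}\,
D_\text{K}/D_\text{ligand}$ (`rescale_tau()`), with
$D_\text{K} = 1.96\times10^{-5}$ and
$D_\text{cAMP} = 4.4\times10^{-6}\ \mathrm{cm^2\,s^{-1}}$ shipped in an
editable table; cGMP is assigned the cAMP value (closest structural
analogue with a published coefficient). Convection outside the pipette is
ignored — its lumped effect is absorbed into the fitted $\tau$.

`correct_protocol()` turns a nominal rectangular protocol into the
effective concentration trace: each segment relaxes from the *current*
effective concentration toward the new level, so incomplete relaxations
chain correctly; the output is discretized piecewise-constant at 0.5 ms
(the default sampling of the concentration command), each interval carrying
its midpoint value, which halves the discretization bias relative to a
left-edge rule.

### 2. Gating schemes and exact propagation

Sequential schemes $C_0 \rightleftharpoons \cdots \rightleftharpoons C_m
\rightleftharpoons O$ have $m$ ligand-binding steps and one conformational
opening step with fixed rates $e_+$ (opening) and $e_-$ (closing); the
defaults 990 and 10 s⁻¹ are single-channel estimates for CNG-type channels
and give $P_{o,\max} = 0.99$. *Cooperative* schemes carry free microscopic
rates $k_j, k_{-j}$ per step (models 3s2p, 4s4p, 5s6p, 6s8p for
$m = 1\ldots4$; the label counts states and free parameters).
*Independent* schemes assume identical sites, leaving only $k_\text{on}$,
$k_\text{off}$ with statistical factors $(m-j+1)$ forward and $j$ backward
— the exact aggregation of the $2^m$ site-occupancy microstates by
occupancy count, verified in the tests against a brute-force microstate
model. The two-state C–O scheme with a ligand-proportional opening rate is
the minimal case used for the robustness studies. All association rates
are linear in concentration; rates are stored in s⁻¹ and M⁻¹ s⁻¹,
concentrations in molar internally (µM at config boundaries).

State probabilities obey $\mathrm{d}\mathbf p/\mathrm{d}t =
\mathbf p\,\mathbf Q(c,\theta)$. On each constant-concentration interval
the exact solution is $\mathbf p \leftarrow \mathbf p\,e^{\mathbf Q
\Delta t}$, so no sub-stepping or ODE error control is needed — the
propagator is exact at the sampling grid, which the tests confirm against
dense `deSolve` integration to $10^{-6}$ in $P_o$. The single-step
`propagate()` uses eigendecomposition with a condition guard (eigenvector
condition number $>10^{12}$, as can occur for near-defective generators at
extreme parameters, triggers a scaling-and-squaring fallback). The batch
propagator behind `simulate_deterministic()` is compiled code using
scaling-and-squaring throughout, with propagators cached per concentration
value — within a pulse the corrected concentration converges onto its
target, so the cache collapses thousands of intervals onto a few dozen
distinct matrices. Probability conservation is enforced to $10^{-10}$.

The state is carried continuously across all segment boundaries (complex
protocols probe exactly this memory); the first segment starts at the
stationary distribution of its concentration, computed as the null vector
of $\mathbf Q^\top$ (least-squares solve, SVD fallback at numerically
rank-deficient extremes). At zero ligand the chain is reducible — all mass
collects in $C_0$ — and the returned distribution carries a `degenerate`
flag. Whether experimental traces start at equilibrium is unknowable in
general; initializing at the stationary distribution of the first
concentration (usually zero ligand, hence $C_0$) is the package's
convention.

**Stochastic traces.** `simulate_stochastic()` evolves per-state channel
counts by multinomial draws from $e^{\mathbf Q \Delta t}$ each interval.
Because that matrix is the true conditional law at the sampling grid, this
is exact at the sample times without event-by-event (Gillespie)
simulation, which would be far slower at $N = 1000$ channels and 0.5 ms
resolution. `to_current()` scales $P_o$ to current
($I = N i P_o + \text{leak} + \text{Gaussian noise}$). Seeds are mandatory
for reproducibility and are embedded in trace metadata.

### 3. Fitting, uncertainty, ranking

`global_fit()` minimizes $S = \sum_i [P_{o,m}(t_i) - P_{o,c}(t_i,
\theta)]^2$ with the Levenberg–Marquardt algorithm (minpack.lm) acting on
$\log\theta$, which enforces positivity and equalizes scales across rates
spanning many orders of magnitude. All point variances are treated as
equal (per-point weights are accepted optionally), so minimizing $S$
minimizes the weighted $\chi^2 = S/\bar\sigma^2$ with $\bar\sigma^2 =
S/(n-k-1)$. At the optimum a central finite-difference Jacobian (relative
step $10^{-6}$, in the rate scale) gives $\mathrm{cov} = \bar\sigma^2
(J^\top J)^{-1}$, SD$(\theta_j) = \sqrt{\mathrm{cov}_{jj}}$ and the
correlation matrix $\rho_{ij} = \mathrm{cov}_{ij}/(\sigma_i\sigma_j)$.
A singular-value ratio of $J$ below $10^{-10}$, non-convergence within
`max_iter` (default 100), or too few degrees of freedom mark the fit
*underdetermined*. `underdetermination_report()` lists parameter pairs with
$|\rho|$ above a threshold (default 0.999): such pairs are constrained only
in combination, typically their ratio. Trial steps at extreme rates that
overflow the matrix exponential return a constant penalty residual, so the
line search backs off instead of aborting.

**Reduced SSR.** Successive samples of a relaxation are strongly
correlated, so counting data points as degrees of freedom would grossly
overstate the information content. Model ranking therefore uses
$S/(n_\text{jumps} - k)$, with $n_\text{jumps}$ the number of
concentration jumps in the protocol (level changes of ligand segments,
K⁺-calibration segments excluded, the pre-protocol level counting as
baseline) and $k$ the number of free parameters. `rank_models()` orders
determined fits by this statistic and lists underdetermined fits
separately, refusing to rank across different data.

**Hill fits.** Steady-state concentration–activation data are fitted with
$I/I_{\max} = 1/(1 + (\mathrm{EC}_{50}/c)^n)$. The zero-concentration
response supplies the offset and the saturating (highest) concentration
the normalization — tie-broken to the latest occurrence, since later
saturating pulses best reflect accumulated run-down — and both are
excluded from the fitted set, which must retain at least 3 points.

## Tunable parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| sampling interval `dt` | s | 5e-4 | concentration-command step width; 1000 samples per 500 ms pulse |
| `e_plus`, `e_minus` | s⁻¹ | 990, 10 | single-channel gating estimates for CNG-type channels; $P_{o,\max}=0.99$ |
| series `tol` | – | 1e-10 | rigorous alternating-series truncation, machine-level accuracy |
| `max_iter` | – | 100 | exhausting it defines an underdetermined fit |
| FD Jacobian step | relative | 1e-6 | balances truncation vs. rounding for rates known to ≫1e-6 |
| correlation `threshold` | – | 0.999 | flags pairs determined only as ratios |
| `n_channels` | – | 1000 | typical macropatch population; sets binomial noise $P_o(1-P_o)/N$ |

## What the synthetic generator emulates — and what it does not

The generator reproduces: diffusion-limited concentration steps chained
across arbitrary protocols; exact Markov gating on those profiles;
binomial gating noise of a finite channel population; current scaling with
leak and Gaussian recording noise. It does **not** emulate amplifier/Bessel
filtering, capacitive or piezo-vibration artefacts, desensitization,
run-down, or voltage-dependent rates. Passing recovery tests therefore
demonstrate correctness and statistical power of the *analysis* under the
stated noise model, not robustness to every nuisance of real recordings.

Study conditions fixed in the test suite:

* **Robustness of the C–O analysis.** Opening $10^6\ \mathrm{M^{-1}s^{-1}}
  \times 100\ \mathrm{\mu M}$, closing 100 s⁻¹ ($\tau_a = 5$ ms). Noiseless
  recovery stays below 1% error up to exchange 50-fold *slower* than
  activation; with 1000-channel noise, median errors over 10 seeded
  replicates stay below 20% at 10- and 50-fold.
* **τ misestimation.** The claim that a 10–20% error in the exchange time
  constant still permits useful rate estimates can only hold when gating is
  slower than the exchange (when the exchange dominates the response, the
  rate estimates inherit its error severalfold — the package's tests
  demonstrate both regimes' sensitivities). The robustness study therefore
  runs with activation 10-fold slower than exchange, where ±10%/±20%
  perturbations of τ keep rate errors within 10%/25%.
* **Model discrimination fixture.** Ground truth 4s4p with strong first /
  weak second binding ($k_1 = 2\times10^7$, $k_{-1} = 100$,
  $k_2 = 2\times10^6$, $k_{-2} = 1000$; EC₅₀ ≈ 8 µM). In this regime
  tied-rate (independent-site) expansions misfit as badly as a one-step
  scheme — their occupancy curve rises quadratically at the foot where the
  data rise linearly — while freeing the second binding step improves the
  reduced SSR severalfold and further steps add nothing and become
  underdetermined. Richer cooperative schemes are initialized by
  continuation from the fitted simpler one ("continuous model expansion");
  cold starts can strand the larger models in poor local optima.
* **Identifiability contrast.** The loss of identifiability from assuming
  rectangular pulses requires pulses short relative to the exchange: with
  100 ms staircase pulses at τ = 18.7 ms, the rectangular-protocol fit
  shows a correlation of ~1 between $k_{-1}$ and $k_2$ that disappears
  (and the truth is recovered exactly) once the corrected concentration is
  used. With 500 ms pulses both fits resolve the parameters, because most
  of each pulse reaches quasi-equilibrium regardless.
* **Hysteresis.** 12-level up/down staircases (0.2–100 µM) of a
  cooperative scheme with slow deactivation show a positive hysteresis
  index (signed area between normalized down- and up-branches on the
  log-concentration axis) that decreases strictly as pulse duration grows
  from 100 ms to 1 s.

The 23-pulse reference protocol (`pulse_train_protocol()`: 500 ms pulses,
zero to 100 µM, one zero-ligand segment at 6.5–7.0 s, 11.5 s total,
23 concentration jumps) uses deterministic log-spanning levels constructed
by this package as a stand-in; the levels of published complex protocols
are not tabulated anywhere reproducible.

## Numerical choices and degenerate inputs

* Matrix exponentials: scaling-and-squaring (batch) / guarded
  eigendecomposition (single step); both exact to machine precision for
  these small (≤6-state) generators.
* Stationary distributions: least-squares null vector; SVD fallback;
  degenerate (reducible, zero-ligand) chains flagged, not errored.
* Zero-concentration protocol segments are represented explicitly (they
  cannot be log-spaced) and are excluded from Hill fitting.
* Traces must be on uniform grids; non-uniformity errors name the first
  offending index. Header-only trace files load as zero-length traces
  flagged `empty`.
* `hill_fit` requires ≥3 usable points; `reduced_ssr` refuses
  $n_\text{jumps} \le k$.
* Problem sizes in the test suite (trace lengths of $10^3$–$2.3\times10^4$
  samples, 10 stochastic replicates per condition, ≤5 multistarts per
  2-parameter model) are chosen so the whole suite documents the claimed
  properties at desk scale.

## Known limitations

Single-channel (hidden-Markov dwell-time) likelihoods, Bayesian posterior
sampling, desensitized or flip/priming states, voltage-dependent rates,
2-D/3-D diffusion geometries and vendor electrophysiology file formats are
out of scope. The correlation-based identifiability diagnosis is local
(Jacobian at the optimum); globally flat directions far from the optimum
are only surfaced through multistart disagreement.
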