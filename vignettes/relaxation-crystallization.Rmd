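---
title: "Methods: enthalpy relaxation, crystallization times, and their correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enthalpy relaxation, crystallization times, and their correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxcryst)
```

## The model and its assumptions

An amorphous glass stored at temperature $T$ below its glass transition
$T_g$ relaxes structurally; the fraction of relaxation enthalpy not yet
released follows the modified stretched exponential (MSE)

$$\Phi(t) = \exp\!\left[-\frac{t}{\tau_0}\Bigl(1+\frac{t}{\tau_1}\Bigr)^{\beta-1}\right],$$

a variant of the Kohlrausch–Williams–Watts (KWW) function
$\exp[-(t/\tau)^\beta]$ that is better behaved at short times: for
$t \ll \tau_1$ it decays simply with $\tau_0$, and for $t \gg \tau_1$ it
converges to the KWW form with $\tau^\beta = \tau_0\,\tau_1^{\beta-1}$.
The calorimeter does not observe $\Phi$ but its derivative — the
exothermic, mass-normalized heat flow

$$P(t) = 277.8\,\frac{\Delta H_r^\infty}{\tau_0}
         \Bigl(1+\beta\frac{t}{\tau_1}\Bigr)
         \Bigl(1+\frac{t}{\tau_1}\Bigr)^{\beta-2}\,\Phi(t)
         \quad[\mu W/g],$$

with time in hours and $277.8 = 10^6/3600$ converting J/(g·h) to µW/g.
$P = -277.8\,\Delta H_r^\infty\,\mathrm{d}\Phi/\mathrm{d}t$ holds exactly
(the identity is asserted against a finite-difference oracle in the test
suite), so the integral of $P$ over all time returns the amplitude
$\Delta H_r^\infty = (T_g - T)\,\Delta c_p$ — the maximum recoverable
relaxation enthalpy, computed from DSC quantities and positive below
$T_g$. A measurement at or above $T_g$ is rejected: there is no glassy
relaxation to model there.

Key assumptions: the 12 h IMC record contains only relaxation heat flow
(plus drift and noise); the amplitude is known from DSC rather than
fitted, so the three shape parameters carry all the information; and the
glass is physically stable over the 12 h measurement itself.

### The composite relaxation time

A fitted triple $(\tau_0, \tau_1, \beta)$ is summarized as a single
relaxation time. How that composite should be formed from the MSE
parameters is a genuinely open convention, and fits of stretched
exponentials correlate $\tau$ and $\beta$ strongly, so the choice matters.
The package default is

$$\tau^\beta := \tau_0\,\tau_1^{\beta-1},$$

the composite the MSE exponent converges to at long times (the
KWW-equivalent), which is comparatively robust to the $\tau$–$\beta$
trade-off; $\tau_0^\beta$ is selectable as an alternative
(`tau_beta(..., convention = "tau0_beta")`), and the convention in force
is recorded in every fit report. With $\tau_1 = 1$ h — the conventional
start value — both conventions reduce to functions of $\tau_0$ alone.

## Fitting: constraints, loss, numerical choices

The model constraints $\tau_0 > \tau_1 > 0$ and $0 < \beta \le 1$ are
enforced by reparameterization, not by post-hoc checking: the optimizer
works on $(\log\tau_1,\ \log(\tau_0-\tau_1),\ \mathrm{logit}\,\beta)$, so
every iterate is feasible and estimates cannot stick to the boundary.
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) minimizes the
unweighted residual sum of squares — uniform weights match the
spreadsheet-style fitting practice of the field — with convergence
tolerances `ftol = ptol = 1e-10` and at most 5000 function evaluations.
Starts default to $\tau_0 = 2$ h, $\tau_1 = 1$ h, $\beta = 0.1$, the
conventional values for this model; a start pinned exactly at the
$\beta = 1$ boundary is nudged to 0.995 because the logit gradient
vanishes at the boundary. Degenerate inputs (constant power, i.e. no
relaxation signal) return a flagged non-converged result instead of an
exception, so one dead sample does not abort a study.

Two further choices the measurement itself does not dictate: the time
origin is the first recorded point (no re-zeroing, configurable trim),
and by default no initial equilibration segment is excluded
(`preprocess_imc(trim_start = 0)`), preserving the nominal 12 h procedure
while allowing 0–1 h of cleanup where a record needs it. The amplitude can
be freed (`free_amplitude = TRUE`) for sensitivity analysis; it is fixed
by default because treating a known multiplier as a free parameter feeds
the $\tau$–$\beta$ degeneracy.

## DSC feature extraction

The glass transition is read from the reversing curve of a
modulated-DSC measurement, the crystallization peak from the total curve;
the instrument's modulation deconvolution is taken as given. Conventions,
since single reported $T_g$ values rarely name them: the midpoint is the
half-height temperature between linear baselines fitted on 15 K windows
offset 5 K from the transition region, $\Delta c_p$ is the extrapolated
step height at the midpoint divided by the heating rate, and the onset is
the intersection of the pre-transition baseline with the steepest-slope
tangent — standard thermal-analysis practice. A step smaller than five
times the noise scale is "no glass transition found". The crystallization
exotherm is integrated against a local linear baseline fitted on flanks
just outside the peak extent (extent taken as ±4σ estimated from
half-prominence crossings), and its onset uses the same
tangent-intersection construction; enthalpy is area divided by heating
rate, making it invariant to the rate and to linear baseline tilt (both
properties are tested). Overlapping exotherms yield the
lowest-temperature peak plus a warning.

## Crystallization times

**Fast path (IMC).** Long records are screened after subtracting a
relaxation baseline refitted on the early segment (MSE shape with free
amplitude plus a drift line, fitted jointly). Peaks are detected on the
smoothed residual — interpolated onto a uniform grid first, because the
native acquisition grid mixes 2 s, 10 s and 60 s intervals — with a
prominence threshold of 5 times a median-absolute-deviation noise scale.
Detected maxima are then refined by a joint split-Gaussian + linear
baseline fit, which locates each maximum well below the sampling interval
even for asymmetric peaks; the time of the maximum is the crystallization
time. Pooled-vial records can crystallize vial by vial and show double
maxima a few days apart; the default policy reports the first maximum
(the first vial to crystallize), with largest-area and mean-of-maxima
policies selectable and the policy echoed in the output.

**Slow path (storage DSC).** For samples that would occupy the
calorimeter for months, weekly DSC of stored aliquots tracks the above-Tg
crystallization peak. The enthalpy of that peak is proportional to the
remaining amorphous fraction, so the default rule takes the
crystallization time as the first (linearly interpolated) crossing of
$\theta = 0.5$ of the week-0 enthalpy — half the material crystallized.
An onset-drop rule (first drop of the onset temperature by a configurable
$\Delta T$, default 5 K) is provided as the alternative, since a falling
onset also signals ongoing crystallization; the enthalpy rule is the
default because it tracks the amorphous fraction directly rather than a
kinetic signature. A week-0 enthalpy of zero means already crystalline
(time 0); a never-crossed trajectory means still amorphous (`NA`).

## Correlation and prediction

Crystallization time (hours) is regressed on $\tau^\beta$ (hours) by OLS
— this direction matches the prediction use case. The report carries
$r^2$, the slope (hours of crystallization delay per hour of relaxation
time), Kendall's $\tau_b$ as the quantitative form of "the order of
crystallization was predicted", and OLS new-observation prediction
intervals (an extension; the underlying methodology reports none).
Pooling pairs across formulations or storage temperatures is an error by
design: only different processes of the same formulation at the same
temperature are comparable. A fit through fewer than four points warns
that it is not statistically robust rather than refusing.

## What the synthetic data emulate — and what they do not

`generate_study()` reproduces the study design with known truth: five
processes (CN, AN1.5, AN3.0, RN, QN) of one formulation, per-process true
MSE parameters chosen so $\tau^\beta$ spans 1.2–4.8 h with controlled
nucleation shortest and quench cooling longest; true crystallization
times drawn from the linear law $t_c = a + b\,\tau^\beta + \varepsilon$
with defaults $a = 24$ h, $b = 601.35$ h/h and
$\sigma_c = 60$ h — the slope is the literature-scale value for a
sucrose-based formulation at 40 °C, and the scatter reflects the reported
2–5 day vial-to-vial spread (2.5 d ≈ 60 h). IMC records use the real
acquisition scheme (2 s for the first hour, 10 s to 12 h) with white
noise of 0.2 µW/g and 0.01 µW/g/h drift; records extended past 12 h for
the fast path are sampled every 60 s, the package's own choice for
long-term logging. Exotherms are split Gaussians (rise 6 h, fall 12 h by
default) — real IMC crystallization peak shapes are not well
characterized, and this asymmetric shape is a deliberate stand-in.
Thermograms use per-process $T_g$ values of a real sucrose formulation
family (48.3–64.1 °C), $\Delta c_p = 0.5$ J/(g·K), a 3 K transition
width, SNR 50, and a crystallization onset at 85 °C drifting −0.05 K/day
during storage; the stored fraction crystallized follows a logistic ramp
of 3.5 d time scale centred at the true crystallization time, so the
$\theta = 0.5$ rule should recover that time up to weekly-interpolation
error. An optional early exothermic transient at 0.58 h with a shallow
endothermic valley reproduces the controlled-nucleation anomaly purely as
a robustness challenge for the fitter, not as physics. All randomness
descends from one seed via a fixed splitting order (per-process noise
draw, then sub-seeds), so studies are bit-reproducible.

What passing tests on these data do **not** show: real records have
non-white (1/f-like) noise, imperfect mass normalization, equilibration
artefacts in the first minutes, exotherm shapes that are not split
Gaussians, and crystallization laws that need not be linear in
$\tau^\beta$ — at higher temperature the real correlation can be much
weaker. Recovery results here bound what the pipeline can do under its
own generative assumptions, nothing more.

## Problem sizes and tolerances used in the checks

The test suite runs recovery at the standard 5760-point record; the
Monte-Carlo checks use 12–25 seeds per condition and the end-to-end
acceptance check 20 five-process studies (a few minutes in total). The
noise-free end-to-end study is required to reach $r^2 = 1$ within
$10^{-3}$: the residual is the weekly linear interpolation of the
logistic enthalpy ramp, which is part of the method, not noise. Energy
conservation is checked to 0.1% by adaptive quadrature in log-time (small
$\beta$ spreads the decay over many decades); the derivative identity to
$10^{-6}$ relative at random points; noiseless parameter recovery to
$10^{-3}$ relative from 1.5× perturbed starts; exotherm maxima to one
sampling interval; Tg midpoints to 0.2 K and $\Delta c_p$ to 3% at
SNR 50.

## Known limitations

- The pipeline is scoped to one formulation at one temperature; it
  deliberately refuses cross-formulation pooling and offers no Arrhenius
  temperature extrapolation.
- $\tau^\beta$ is convention-dependent; comparisons across software
  require knowing which composite was used (it is echoed in all outputs).
- The storage rule needs a trackable above-Tg exotherm; formulations
  whose crystallization signature is onset-only should use the
  onset-drop rule, whose $\Delta T$ threshold is a tuning choice.
- Peak refinement assumes locally split-Gaussian exotherms; grossly
  different shapes fall back to grid-resolution maxima.
- Residual moisture, specific surface area and surfactant content all
  modulate both relaxation and crystallization; they appear here only as
  an optional proportional covariate in the generator, never as model
  regressors.
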