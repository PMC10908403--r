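---
title: "Assessing pulse-wave indices of vascular aging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing pulse-wave indices of vascular aging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwva)
```

`pwva` evaluates nineteen noninvasive pulse-wave indices of vascular aging
against an exact reference aortic stiffness. This vignette documents the
models behind the package, the tunable parameters and their defaults, the
synthetic virtual-subject generator and what it does and does not emulate,
and the numerical choices made where the design was genuinely open.

## 1. Reference stiffness

The stiffness of every arterial segment follows the Olufsen wall law,
$Eh/r = k_1 e^{k_2 r} + k_3$, where $E$ is the effective Young's modulus of
the wall, $h$ the wall thickness and $r$ the luminal radius, with a fixed
thickness-to-radius ratio $h/r = 0.15$ (`eh_product()`,
`segment_young_modulus()`). $k_1$ (Pa) describes the stiffness of small
arteries, $k_2$ (1/m, negative) the radius of transition, and $k_3$ (Pa) the
stiffness of large arteries. The reference aortic stiffness is the
length-weighted mean over the aortic path,
$E_{Ao} = \sum_j (L_j/L_{Ao}) E_j$ with each $E_j$ evaluated at the mean of
the segment's inlet and outlet radii (`aortic_young_modulus()`). The
theoretical aortic-root wave speed is the thin-wall elastic form
$\mathrm{aoPWV}_t = \sqrt{2Eh/(3\rho r)}$ with blood density
$\rho = 1060\ \mathrm{kg/m^3}$ (`theoretical_ao_pwv()`); with $h/r$ fixed it
reduces to $\sqrt{0.1\,E/\rho}$.

All internal units are SI — Pa, m, s, kg/m³ — because CAVI and the
distensibility coefficient are dimensionally consistent only in coherent
units; mmHg appears solely at I/O boundaries (`convert_pressure()`, 1 mmHg
= 133.322 Pa). Augmentation ratios (AIx, RM, AIx$_{ppg}$) are stored as
dimensionless ratios, not percents.

## 2. The nineteen indices

One `compute_panel()` call produces, per subject:

* **Transit-time PWVs** (`transit_time_pwv()`): aoPWV (ascending vs
  descending aorta **flow** waves), cfPWV, baPWV, cbPWV, crPWV (pressure),
  ftPWV (digital vs ankle **PPG**; the ankle stands in for the toe), plus
  the heart–ankle PWV used inside CAVI. The transit time is the difference
  of intersecting-tangent feet, wrapped into $(0, T)$; path lengths come
  from the subject's arterial geometry, with opposing-direction paths
  (e.g. carotid–femoral) combined by subtraction of the common trunk.
  Transit times under two sample intervals are flagged unreliable.
* **Pressure morphology**: cPP and AP/AIx from the aortic-root pressure
  directly (no transfer function), bPP from the brachial beat.
* **Wave separation** (`wave_separation()`): characteristic speed
  $c = \frac{1}{\rho}\sqrt{\sum dP^2 / \sum dU^2}$ on simple first
  differences at the native sampling rate (no smoothing — smoothing would
  bias the backward amplitude), $P_f$ and $P_b$ as cumulative sums of
  $\tfrac12(dP \pm \rho c\, dU)$ anchored at zero, amplitudes as max − min,
  $RM = P_b^{amp}/P_f^{amp}$.
* **CAVI** with configurable empirical coefficients, default $c_1 = 1$,
  $c_2 = 0$: the coefficients' published values are vendor calibrations,
  and the default keeps the index a pure stiffness parameter; both are
  `config` keys of `compute_panel()`.
* **Carotid distensibility** $DC = (\Delta A / A_{dia})/\mathrm{bPP}$.
* **PPG panel**: RI, SI $= H/\Delta T$, AGI $=(b-c-d-e)/a$, AIx$_{ppg}$
  $= PT_2/PT_1$ and $d/a$, from `ppg_landmarks()` and
  `sdppg_landmarks()`. RI is implemented as s/dia — the orientation that
  rises with stiffness as the diastolic wave attenuates — with a
  `ri_orientation` flag exposing dia/s for the in vivo convention.

A missing or unusable signal degrades only the indices that need it; the
panel records an explicit reason per absent index and never silently
reports zero.

## 3. Fiducial detection

Derivatives of sampled beats amplify noise, so all derivatives are
local-polynomial (Savitzky–Golay) smoothing differentiators. Windows are
about 50 ms at order 3 for first-derivative features; the pulse-foot slope
uses order 2, whose derivative equals the local *linear* regression slope
and therefore never overshoots at piecewise-linear corners; the
second-derivative PPG uses a deliberately wide 150 ms window because the
a–e curvature waves live well below 10 Hz while the band-passed noise floor
extends to 35 Hz. Beats are treated as periodic: signals are padded
circularly before filtering, which makes every detector exactly equivariant
to circular shifts and amplitude-scale invariant (the PPG detectors
normalise to [0, 1] first).

The **foot** is the intersection of the horizontal line through the
pre-systolic minimum with the tangent at the point of maximum upslope, at
sub-sample resolution. The maximum-upslope search is global over the
(periodic) beat rather than windowed: the systolic upstroke dominates every
beat this package handles, and a global search preserves shift
equivariance. The pre-systolic minimum is found by walking backwards from
the maximum-slope point.

**P1/P2** are the systolic peak plus a shoulder found from the smoothed
first derivative — before the peak, a local maximum of the signal or a
pronounced local minimum of the slope (type A when the later landmark is
higher, type B otherwise); after the peak, a local maximum of the signal or
of the slope within the first 45% of the beat (type C; augmentation may be
negative). With no detectable shoulder the beat is flagged degenerate with
$P_1 = P_2$ at the peak.

The **diastolic PPG peak** is searched between 32% and 95% of the beat
after the foot — past end of systole, so late-systolic reflection features
cannot masquerade as the diastolic wave — and the *most prominent* local
maximum wins. On clean beats this coincides with the first local maximum
after the dicrotic region; under residual post-filter noise it is far more
stable. When the diastolic peak has vanished (as it does with age), the
fallback is the diastolic inflection, the local maximum of the first
derivative in the same window, flagged via `dia_found = FALSE`.

## 4. The synthetic virtual-subject generator

`make_subject()` builds, per subject: a 10-segment aortic path (51 cm,
radii tapering 13.5 → 6 mm) plus carotid, brachial–radial–digital and
iliac–leg branches with peripheral $k_3$ 30% above aortic; the wall-law
constants $k_1 = 2\times10^6$ Pa, $k_2 = -2253$ 1/m (the CGS literature
values in SI) and $k_3 = 10^5\,\mathrm{Pa} \times s(\mathrm{age})$ with the
linear aging law $s(a) = 0.6 + 0.025\,(a - 25)$, spanning
$E_{Ao} \approx 0.4$–$1.3$ MPa from 25 to 75 years.

The aortic-root beat is $P = \mathrm{DBP} + P_f + P_b$: the forward wave has
a raised-cosine upstroke (rise time 20% of systole, systole 35% of the
period) and an exponential decay (time constant 50% of the period,
continuous at the period wrap); the backward wave is the forward wave
scaled by the reflection gain and delayed by $2 \times 0.6\,\mathrm{m}/c$ —
the delay shortens as stiffness grows, reproducing the shift from type-C
(young, negative augmentation) to type-A (elderly, positive augmentation)
morphology. Flow velocity is the water-hammer conjugate
$U = (P_f - P_b)/(\rho c)$. These shape constants were chosen so that the
sum-of-squares wave-speed estimator is nearly unbiased on the generated
beats (increment cross-correlation under 1%), making wave separation
recover the constructed reflection ratio within 2% across the population —
with a slow decay and a short rise, the forward increments barely overlap
the delayed backward upstroke. The stored ground-truth onset is the
intersecting-tangent foot of the analytic upstroke,
$t_0 + (\tfrac12 - \tfrac1\pi)\,t_{rise}$.

Distal waveforms are the root components evaluated at the exact per-segment
transit delay $\sum_j L_j/c_j$ (local Eq.-3 speeds), with mild peripheral
pulse-pressure amplification (≤ 8%); the carotid area is linearly coupled
to carotid pressure so the true distensibility is $1/(\rho c_{car}^2)$;
digital and ankle PPG are the min–max-normalised local pressure plus a
diastolic Gaussian wave (width 5% of the period, centred a round-trip
$2 \times 1.3\,\mathrm{m}/c$ after the upstroke) whose amplitude — 0.45 at
age 25 — declines linearly to zero at 75, reproducing the disappearance of
the diastolic peak with age and exercising the inflection fallback.

`make_population()` jitters heart rate (log-SD 0.06), stroke volume (0.10),
stiffness (0.08), arterial diameter (0.05), peripheral resistance (0.10)
and height (SD 0.07 m) around the spec and samples ages uniformly;
everything is deterministic given the seed, with the caller's RNG state
restored. The reflection gain additionally grows mildly with age
($0.8 + 0.008\,(a-25)$, times the peripheral-resistance scale) so the
reflection magnitude carries a genuine, confounded stiffness association
rather than zero variance.

**What the generator does not emulate:** it solves no 1-D hemodynamic PDEs,
so waveforms carry no dicrotic notch, no nonlinear steepening, no
site-dependent shape dispersion beyond delay + amplification, and no
sex-specific physiology. Passing tests therefore demonstrate that the
*pipeline* — detection, index formulas, statistics — is correct and
well-conditioned, not that any index will reach the same correlation on
real or fully simulated data. Conversely the generator's exact ground truth
(stiffness, delays, wave components, distensibility) enables closed-loop
checks no real dataset allows.

## 5. Noise and filtering

`add_white_noise()` injects zero-mean Gaussian noise with variance
$\overline{x^2} / 10^{\mathrm{SNR_{dB}}/10}$ — the SNR definition is the
linear power ratio, reported in dB (`realized_snr()`). Noise is drawn
independently per signal (independent sensors), deterministically per seed.
`bandpass_filter()` removes content above 35 Hz and below 0.0665 Hz:
because 0.0665 Hz is unresolvable on one beat, the beat is tiled
periodically to at least 16 s, filtered forward–backward (zero phase — the
transit-time indices would otherwise inherit group delay) with cascaded
order-4 Butterworth high- and low-pass sections, and the central beat is
extracted. Cascading the two edges keeps the recursion numerically sound at
the extremely low normalised high-pass frequency, where a single band-pass
design is ill-conditioned. The beat mean is removed before filtering and
restored afterwards: the high-pass removes the pressure mean, but CAVI
needs absolute SBP/DBP, so mean restoration is the only way to keep
$\ln(\mathrm{SBP/DBP})$ meaningful; a constant beat passes through
unchanged. Clean (infinite-SNR) signals are never filtered, so the
noise-free pipeline stays untouched.

## 6. Statistical harness

`correlate()` reports Pearson and Spearman coefficients (average ranks for
ties) after dropping missing pairs; subgroup tables use exact ages 25 and
75 when present. `bland_altman()` uses the population (divide-by-$n$) SD by
default — at thousands of subjects the $n-1$ convention is
indistinguishable, but the choice is testable at toy sizes and switchable
(`sample_sd`). The relative sensitivity index
$I = \frac{1}{n}\sum \frac{V - \bar V}{\bar V}\,\frac{1}{v} \times 100$
(with $v = \pm 1$ for ±1 SD perturbations) is aggregated **per parameter**
over its 12 runs (6 age-decade baselines × 2 directions); a symmetric
response cancels to zero by design — the index is signed. The six
perturbed dials are heart rate, stroke volume and duration of systole
(cardiac) and large-artery diameter, input PWV (the stiffness scale) and
peripheral vascular resistance (vascular), at relative SDs of 10/15/8 and
10/15/20% — generator choices standing in for clinical variability.
`noise_robustness()` re-noises every waveform of every subject per SNR
level, filters, recomputes all panels and re-correlates; the infinite
level reproduces the clean table exactly.

`run_full_assessment()` orchestrates all of the above and writes CSV
tables. Analyses in this package use populations of 40–200 synthetic
subjects — large enough that rank correlations stabilise (sampling SD
$\lesssim 0.07$), small enough to iterate comfortably.

## 7. Degenerate inputs, tie-breaks, tolerances

* Beats need ≥ 3 finite samples and a positive upstroke; zero-range beats
  are rejected with explicit errors.
* Wave separation requires non-constant flow; identical clean/noisy pairs
  give an `Inf` SNR with a warning.
* SDPPG landmarks below 1% of the dominant curvature magnitude are treated
  as ripple, not waves; absent landmarks are `NA`-flagged through to AGI
  and $d/a$.
* Equal-value plateaus in extrema detection resolve to the plateau centre.
* Tangent feet, being analytic line intersections, carry sub-sample
  resolution; transit-delay recoveries in the test-suite are held to two
  sample intervals at 500 Hz.

## 8. Known limitations

The zenodo-style MATLAB population loader delegates to a Python
(`scipy.io`) helper behind a JSON field mapping
(`inst/extdata/zenodo_matlab_mapping.json`); the mapping must be finalised
against actual container files, which are not bundled. The synthetic
aging laws are linear by construction; real cohorts show nonlinear and
heteroscedastic stiffening. CAVI's default coefficients make its absolute
scale vendor-incomparable (its correlations are unaffected). PPG indices
on synthetic beats share the pressure waveform's shape up to the diastolic
wave, which likely overstates their clean-data correlations relative to
real PPG morphology.
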