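---
title: "Calculated PSIR LGE from joint T1/T2 mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calculated PSIR LGE from joint T1/T2 mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psirsynth)
```

## Overview

`psirsynth` implements the simulation side of the "all-in-one" cardiac MR
workflow in which a single free-breathing saturation-recovery acquisition
yields joint T1 and T2 maps, and bright-blood (BB) and dark-blood (DB)
phase-sensitive inversion-recovery (PSIR) late gadolinium enhancement (LGE)
images are then *calculated* from the maps instead of being acquired as
separate scans. This vignette documents the models, the tunable parameters,
the numerical choices, and the limits of what the synthetic test bed can
demonstrate.

## Signal models and their assumptions

All times are in milliseconds and all rates in Hz, so `R = 1000 / T`.

**Saturation-recovery (mSASHA) frames.** Every frame starts from saturated
(zeroed) longitudinal magnetization, which makes frames mutually independent
and order-insensitive:

- anchor: $A\,(1 - e^{-\tau/T_1})$ with recovery duration
  $\tau = 3\,RR + TS$ (three idle heartbeats plus the saturation delay) —
  an approximation to the equilibrium amplitude $A$;
- SR: $A\,(1 - e^{-TS/T_1})$;
- SR + T2 preparation: $A\,(1 - e^{-TS/T_1})\,e^{-TE/T_2}$.

Assumptions: perfect saturation efficiency and an idealized, readout-free
recovery. In practice a variable-flip-angle readout is what keeps this
approximation usable on a scanner; no readout-driven recovery correction is
modelled here, so the fitter is validated against its own forward model
(see *Limitations*). The T2-preparation decay is applied multiplicatively
immediately before readout; its exact placement inside the beat is not
otherwise resolved. For SR and SR+T2prep frames, idle recovery beats
precede the saturation pulse and therefore cannot influence the signal;
for anchors the idle beats follow saturation and extend the recovery.

**Inversion-recovery references.** For comparison with acquired LGE the
exponential signals are also provided: $1 - 2e^{-TI/T_1}$ for BB PSIR and
$1 - [1 - (1 - 2e^{-TD_1/T_1})e^{-TE/T_2}]\,e^{-TD_2/T_1}$ for the IR-T2 DB
sequence. They are reference formulas only; the calculated images below are
the package's primary output because they are linear in contrast
concentration, while the inversion-recovery signal is strongly nonlinear
in it.

**Relaxivity.** Under fast exchange, $R_1 = R_{1,0} + r_1[\mathrm{Gd}]$ and
$R_2 = R_{2,0} + r_2[\mathrm{Gd}]$. `gd_concentration_from_r2()` inverts
the R2 relation with a default $r_2 = 5.85\,\mathrm{s^{-1}mmol^{-1}L}$.

## The calculated PSIR formulation

With myocardial reference rates $(R_{1m}, R_{2m})$ and blood rates
$(R_{1b}, R_{2b})$:

$$\mathrm{BB} = R_1 - R_{1m}, \qquad
  \mathrm{DB} = R_1 - \frac{R_{1m}}{a_{DB}\,R_2/R_{2m} + (1 - a_{DB})},$$

$$a_{DB} = \frac{R_{1m}R_{2m}/(R_{1b} - \mathrm{LGEb}) - R_{2m}}
               {R_{2b} - R_{2m}}.$$

Three properties are enforced and tested exactly: the normal myocardium is
nulled in both images; DB coincides with BB wherever $R_2 = R_{2m}$; and the
blood operating point $(R_{1b}, R_{2b})$ maps to exactly LGEb. The
formulation degenerates when $R_{2b} = R_{2m}$ or $\mathrm{LGEb} = R_{1b}$
(zero denominators); both are rejected at construction. For extreme $R_2$
with $a_{DB}$ outside $[0, 1]$ the DB denominator can become non-positive;
such pixels are returned as `NaN` and counted.

**Tunable parameters.**

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `LGEb` | Hz | −0.5 | target blood level in DB; more negative = darker blood |
| `TS` | ms | 300 | saturation delay (post-contrast setting) |
| `TE_prep` | ms | 55 | T2-preparation echo time |
| `RR` | ms | 1000 | heartbeat interval (60 bpm); schedule bookkeeping only |
| `snr` | — | 40 | anchor-image SNR of the simulator |

The reference values $(R_{1m}, R_{2m}, R_{1b}, R_{2b})$ are estimated as
medians of the fitted T1/T2 over myocardial and blood-pool masks
(`tissue_reference_from_maps()`). The median tolerates a scar sector inside
the myocardial mask, and PSIR nulling is in any case insensitive to
moderate reference error, which window-leveling can absorb. Masks are
explicit inputs: automatic (CNN) segmentation is out of scope, and the
blood reference uses the same median rule as the myocardium for symmetry —
how a clinical pipeline derives it (median vs mean of a segmented pool) is
not specified anywhere we could follow, so the symmetric choice is
documented here.

**Edema attenuation.** Elevated myocardial T2 (edema) pulls the DB signal
below its BB counterpart. `db_attenuation_curve()` reports the ratio
$\mathrm{DB}(T_1, T_2)/\mathrm{BB}(T_1)$ per edematous $(T_1, T_2)$; the
ratio (rather than a difference) was chosen because it is dimensionless,
equals 1 exactly when $T_2$ is at the reference, and is undefined only
where BB itself vanishes ($T_1$ equal to remote), which is reported as
`NaN`. A difference-based ordinate would be an equally defensible
convention; this one is flagged as a package choice.

## Joint fitting

`fit_pixel()` minimizes the sum of squared differences between the measured
frame signals and the forward model over $(A, T_1, T_2)$ with
Levenberg–Marquardt (`minpack.lm::nls.lm`), bounds
$T_1 \in [50, 5000]$ ms, $T_2 \in [5, 1000]$ ms, $A > 0$, convergence
tolerance $10^{-10}$ on the cost, at most 200 iterations. Initialization
inverts single frames in closed form: $A_0$ = strongest anchor,
$T_{1,0} = -TS/\log(1 - S_{SR}/A_0)$ clipped to $[100, 3000]$ ms,
$T_{2,0} = -TE/\log(S_{T2p}/S_{SR})$ clipped to $[10, 500]$ ms. A fit that
ends on a bound, exceeds the iteration budget, or receives degenerate data
(all-zero pixels, non-finite values) is flagged `converged = FALSE` rather
than raising; a protocol lacking any of the three preparation kinds is
rejected up front as non-identifiable. Magnitude data are fitted as
real-valued: saturation-recovered signal is non-negative, so no polarity
restoration is needed. Joint estimation decouples the parameters — T1 does
not inherit T2 error and vice versa.

On noise-free data the fitter recovers all nine phantom-vial $(T_1, T_2)$
pairs to ~$10^{-13}$ relative error with residuals below $10^{-8}$,
so the accuracy bounds reported by `scripts/acceptance.R` (T1 within 1%,
gel-range T2 within 1.5%, liquid-range T2 within 3.2%) measure the
correctness of the estimation chain, not of the idealized physics.

## The synthetic test bed

`make_t1mes_phantom()` emulates a nine-vial quality-assurance plate whose
ground truth is the long-TR spin-echo reference values (T1 from 258 to
1527 ms, T2 from 40 to 234 ms). `make_cardiac_phantom()` builds an
idealized short-axis slice — circular blood pool (radius 28 px on a
128-px grid), annular myocardium (outer radius 40 px), and a 60° scar
sector, subendocardial for infarct scenarios and subepicardial for
myocarditis — with post-contrast group-mean tissue values: chronic MI
(441, 43.8) ms, remote (668, 42.4) ms, blood (466, 142.4) ms; the
elevated-T2 scenarios use MI (392, 58.3), remote (608, 41.7), blood
(396, 141.8) ms.

`simulate_series()` adds zero-mean Gaussian noise with
`sd = max amplitude / snr`, i.e. `snr` is the anchor-image SNR of a
full-amplitude region. Gaussian rather than Rician noise reflects the
high-SNR regime of motion-corrected averaged magnitude images; a Rician
option exists for low-SNR work. Default `snr = 40` is a realistic
averaged-image operating point for this kind of acquisition.

**Vial ROI size.** Vial radius defaults to 15 px (~700 px area). Under the
post-contrast protocol (TS = 300 ms, TE = 55 ms) the per-pixel T2 scatter
in the long-T2 liquid vials is large — both preparations are weakly
sensitive to T2 ≳ 150 ms — roughly 47% relative at SNR 40, so the
vial-median T2 needs several hundred pixels before its sampling error
(~2% at 700 px) is small against the few-percent recovery checks the
phantom exists to support. Smaller vials make those checks noise-dominated.

**What the phantom does not emulate:** respiratory motion and its
correction (frames are pre-registered by construction), coil sensitivities
and parallel-imaging noise amplification, partial-volume blur at borders,
off-resonance, imperfect saturation/inversion, and readout-driven recovery.
Passing tests therefore demonstrate that the estimation and synthesis chain
is correct for the stated signal model — not that the model captures every
effect in scanner data.

## Monte-Carlo SNR/CNR

The calculated images are nonlinear functions of the raw frames, so their
noise cannot be read off an SNR-scaled reconstruction. `mc_psir_stats()`
instead repeats, per region and trial: generate the noise-free signal
vector at the region's (T1, T2), add Gaussian noise at the region's
anchor-referenced SNR, jointly fit, and evaluate the BB and DB expressions
at the fitted rates. Means and SDs over trials give region signal and
noise; CNR is a mean difference divided by a reference region's SD (remote
for scar-vs-remote, blood for scar-vs-blood, configurable). Noise is
injected into the *raw signals* and carried through the full estimation
chain — the alternative of perturbing (T1, T2) directly is offered as the
`"linearized"` fast mode, which draws parameter perturbations from
$\mathcal{N}(\theta,\ \sigma^2 (J^\top J)^{-1})$ with the analytic model
Jacobian and agrees with the full chain at moderate-to-high SNR. Trials
whose fit fails are dropped and counted (warning above 5%).

The per-region anchor SNRs of the original patient study are not published,
so absolute CNR values cannot be regenerated; the package asserts the
structural properties instead — the remote region's mean BB signal is
statistically zero, noise shrinks as raw SNR grows, and the DB image's
scar-vs-blood CNR exceeds the BB image's under matched conditions (the
ordering that motivates dark-blood imaging).

## Problem sizes and determinism

The shipped tests fit full 128-px phantoms only where the check needs them
(vial-median recovery at SNR 40, ~6400 pixel fits, a few seconds at ~0.5 ms
per fit); structural checks use 32–64 px grids. Monte-Carlo tests use 300 to
1000 full-chain trials, or 4000 linearized trials, per configuration —
enough for 3-standard-error assertions on the means. Every stochastic path
takes an explicit integer seed and reproduces bit-for-bit; `fit_maps()`
deduplicates identical signal vectors, so noise-free phantom fits cost one
fit per region. Output bundles carry a hash of their configuration.

## Known limitations

- The forward model and the fitter share the same idealized physics;
  accuracy against scanner data rests on the acquisition-side mitigations
  (variable flip angle, adiabatic preparations) making that idealization
  valid, which this package cannot test.
- Post-contrast T2 is accurate but is not a substitute for native T2 in
  edema assessment; myocardial T2 is itself reduced by gadolinium.
- The DB image attenuates enhancing tissue whose T2 is elevated; the
  attenuation analysis quantifies this, and less aggressive suppression
  (larger LGEb) reduces it.
- Protocol event ordering is bookkeeping only under the full-recovery
  assumption; arrhythmia and trigger-delay effects are not modelled.
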