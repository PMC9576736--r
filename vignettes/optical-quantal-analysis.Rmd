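---
title: "Optical quantal analysis of single-synapse glutamate imaging"
author: "quantalglu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical quantal analysis of single-synapse glutamate imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalglu)
```

## The scientific problem

Classical quantal analysis describes the strength of a synapse as the
product of three parameters: the number of release-ready vesicles $N$,
the probability $p_{ves}$ that any one of them fuses in response to an
action potential, and the response to a single vesicle, the quantal
size $q$. At the small glutamatergic boutons of the hippocampus these
parameters cannot be read from somatic electrophysiology, because every
synapse sits at a different electrotonic distance and there is no
unitary response. A membrane-anchored fluorescent glutamate sensor
(iGluSnFR) expressed in the presynaptic neuron moves the measurement to
the synapse itself: the fluorescence transient of a single bouton,
sampled trial by trial, reports the glutamate released into the cleft
in units of $\Delta F/F_0$.

`quantalglu` implements the complete analysis chain for such
recordings, together with a synthetic-data generator with known ground
truth so that every stage is testable without any raw-data download:

1. **synth** — trial-resolved session synthesis (spiral-scan
   emulation, photon noise, bleaching, artifacts, strontium wash-in,
   frame-scan stacks);
2. **traces** — from raw trial matrices to a quality-controlled
   amplitude table (dynamic ROI, bleach correction, template fit,
   2$\sigma$ classification, $F_0$ and bouton QC);
3. **quantal** — the binomial release model with saturation-spaced,
   shot-noise-broadened Gaussian mixtures, fitted jointly over two
   calcium conditions by exhaustive grid search, plus two independent
   quantal-size estimators;
4. **cleft** — a reduced Brownian-dynamics simulation of vesicular
   glutamate in the synaptic cleft that validates the saturation model
   and its constants;
5. **localize** — sub-diffraction release-site localization by 2D
   Gaussian fitting and 95% confinement ellipses.

## The statistical model

A trial releases $k \sim \mathrm{Binomial}(N, p_{ves})$ vesicles. The
sensor does not report glutamate linearly: the peak bouton response to
$k$ simultaneous vesicles follows a hyperbolic saturation curve

$$A(k) = \frac{B_{max}\,k}{K_d + k}, \qquad K_d = \frac{B_{max}}{q} - 1,$$

so that $A(1) = q$ and quantal peaks are compressed, not equidistant.
The measured amplitude adds photon shot noise. Because shot-noise
variance is proportional to the detected photon count, i.e. to total
fluorescence $1 + \Delta F/F_0$, the width of the $k$-th quantal peak
is

$$\sigma_k = \sigma_0 \sqrt{1 + A(k)},$$

with $\sigma_0$ the baseline width measured on non-stimulated windows
of the same bouton. The predicted amplitude density is therefore a
Gaussian mixture with binomial weights, saturation-spaced means and
shot-noise-broadened widths. `fitQuantalModel()` scores this density
against the amplitude histogram (bin-integrated, scaled to the trial
count, root-mean-square error) for every grid cell, sharing $N$ and
$q$ between the low- and high-calcium condition while $p_{ves}$ is
free per condition; the combined error is the sum of the per-condition
RMS errors. Because adding vesicles carries no cost in this model,
near-identical fits exist for different $N$; the fitter returns the
most parsimonious fit — the smallest $N$ within 2% of the global
minimum combined error, with ties broken by smaller error, then
smaller $q$.

Default grid: $N$ 1–15, $p_{ves}$ 0.01–0.99 in steps of 0.01, $q$
0.5–2.0 $\Delta F/F_0$ in steps of 0.01. The published grid starts at
$p_{ves} = 0.1$, yet fitted values below 0.1 are routinely reported
for low calcium; the floor is therefore relaxed to 0.01 by default and
the literal grid is available as `quantalGrid(preset = "paper")`. The
parsimony window is implemented on the RMS scale; the source
literature alternates between RMS and mean-square wording, which only
affects the width of the window, not the selection logic.

## What the generator emulates — and what it does not

`synthesizeSession()` renders each trial as a lines-by-positions
matrix

$$F(t, x) = b(\mathrm{trial}) \,[1 + A\,\kappa(t - t_{stim})\,s(x)] + \varepsilon,$$

with a step-onset monoexponential kernel $\kappa$ (default decay 40
ms, 44 lines at 500 Hz), a contiguous release-site column block
$s(x)$ (12 of 64 positions), monoexponential bleaching $b$ across
trials (default time constant 1500 trials — mild, as appropriate for
drift-stabilized recordings), Gaussian photon noise whose per-pixel
variance is proportional to expected photons, and occasional artifact
trials with elevated $F_0$ (default rate 3%, matching the reported
2–5% incidence of fluorescent particles passing through the axon).
Spiral-scan geometry is not reproduced: the analysis consumes only the
time-space matrix, so a column block stands in for the sampled bouton
surface.

Quantal variability of vesicle content is off by default: the analysis
deliberately attributes all peak broadening to photon shot noise,
consistent with the observation that including content variability
produces unrealistically broad predictions; an optional `cvQ`
parameter exists for sensitivity studies only.

The noise convention deserves emphasis: the generator's `sigma0` is
defined as the standard deviation of the *null template-fit
amplitude* — exactly the statistic the trace analysis measures — and
the per-pixel noise scale is derived backwards from it through the
fit-window algebra. Generator and analysis therefore share one
calibration, and the 2$\sigma$ classifier can be validated against
the Gaussian tail (false-positive rate $1 - \Phi(2) \approx 2.3\%$)
with no free constants.

What passing tests on these data do *not* show about real recordings:
release sites that move across trials, correlated noise (detector
afterpulsing, tissue motion), non-exponential sensor kinetics,
multi-active-zone boutons, and true paired-pulse plasticity (the
two-pulse mode draws independent binomial outcomes; a paired-pulse
ratio of 100% is the design expectation, not a biological claim).

## Trace analysis: numerical choices

* **Window layout.** The stimulation line defaults to 30 of 44. The
  template fit uses $L = \min(6\tau/\Delta t,\ \mathrm{post
  \ length},\ (stim-1)/2)$ lines (14 at the defaults) with the
  preceding 15 lines as baseline. The null fit — the basis of the
  noise model — is laid out *inside* the pre-stimulus segment with an
  identically sized window and baseline, so null amplitudes are
  distributed exactly like failure amplitudes and the 2$\sigma$
  threshold is self-calibrating.
* **Preliminary classification** for ROI routing uses the 2$\sigma$
  criterion on whole-matrix averages; final labels come from the
  template fit. The ambiguous published "5%" failure-column routing
  rule is provided as `failureRule = "5pct"` (a trial routes to the
  carried ROI when no column exceeds baseline by more than 5% of the
  trial's maximum $\Delta F$); the default is the 2$\sigma$ route.
* **Consensus ROI.** Dynamic per-trial ROIs (columns above half the
  maximal column $\Delta F$, carried over from the last success on
  failures) locate the release site, but the final single-parameter
  fits use the session-consensus ROI (columns selected in at least
  half of the success ROIs). Selecting the ROI per trial on the same
  noise realization the fit sees inflates small amplitudes by several
  percent; with a spatially stable release site the consensus is the
  unbiased choice.
* **Template refinement.** The template decay constant is first fitted
  on the average of the five largest preliminary successes (automating
  the published manual selection; `kLargest` is configurable), then
  refined on *all* successes after the first classification pass. The
  few-trial template is otherwise the dominant noise source of the
  amplitude scale: a 15% error in $\tau$ biases every amplitude by
  about 5%.
* **Bleach correction** divides every trial by a monoexponential
  fitted to failure-trial $F_0$; disabling it (`bleachCorrect =
  FALSE`) normalizes by the session mean instead and demonstrably
  biases late-trial amplitudes downward. Non-convergent fits fall back
  to a linear detrend with a warning.
* **Trial-$F_0$ QC** detrends the $F_0$ sequence with a robust
  monoexponential before applying the 2 SD rule, and rejects
  one-sidedly (only elevated $F_0$): the targeted artifacts are bright
  particles, and a two-sided rule would discard ~5% of clean trials.
* **Baseline FWHM** is estimated robustly from the interquartile range
  of the null amplitudes ($\mathrm{FWHM} = 2.355\,\mathrm{IQR}/1.349$);
  boutons with FWHM $> 0.4\ \Delta F/F_0$ fail QC (strict inequality).
* **Desynchronized events** (strontium wash-in) are detected by a
  greedy matched filter whose onset choice is made on a
  noise-normalized score (truncated late windows would otherwise be
  preferred for their larger amplitude noise), followed by a joint
  least-squares refit of all amplitudes at fixed onsets; the evoked
  transient is always fitted and subtracted first. The quantal-size
  estimate is the median of the delayed-event amplitudes — coincident
  fusion events within one line period merge into a single detection
  and would inflate the mean.

## The cleft simulation

The simulation asks whether the hyperbolic saturation ansatz and its
constants are consistent with the physics of the measurement: a
vesicle injects ~3000 glutamate molecules into a 20 nm cleft; the
molecules diffuse ($D = 200\ \mu m^2/s$), bind membrane-anchored
sensors, and are captured by astrocytic glutamate transporters
(10,000 $\mu m^{-2}$). The sensor follows the linearized two-step
scheme — fast binding, then a slower bright-state isomerization at
$k_{+2} = 2481\ s^{-1}$, reverting at $k_{-2} = 111\ s^{-1}$ (the
cell-based rate constants); full bright occupancy corresponds to the
sensor-intrinsic ceiling of 4.4 $\Delta F/F_0$.

The engine is a bespoke Brownian-dynamics stepper (compiled code, all
randomness derived from R's RNG so runs are seed-reproducible). The
geometry is reduced: the extracellular space is a 20 nm slab over the
*flattened* axon/bouton membrane (axis coordinate $u$, circumference
coordinate $v$), with the cleft disc (150 nm radius) as the contact
facet, the spine contact reflective, the astrocytic sheath as the
far face beyond it, and open axon ends. Each membrane cell of the
sensor-density pitch carries one sensor; binding and transporter
capture use per-contact probabilities derived from the association
rates (Erban–Chapman). Every cell is mapped back to its position on
the 3D cylinder surface to receive a 3D-Gaussian PSF weight, and
$\Delta F/F_0(t)$ is the PSF-weighted bright fraction times the
contrast. Two mechanisms proved essential to reproduce the published
saturation behaviour:

* **Transporter capacity is finite** on sub-millisecond timescales
  (transporters do not recycle that fast). At high vesicle counts the
  sheath near the cleft saturates, glutamate travels farther, and
  progressively more extrasynaptic sensors are recruited. This
  weakly-saturating tail is what pushes the *fitted* hyperbolic
  asymptote above the sensor-intrinsic 4.4 ceiling while every
  simulated peak stays below it — the apparent paradox of
  bouton-level saturation.
* **Bulk clearance** (first-order, default time constant 0.6 ms)
  removes glutamate outside the cleft: the flattened slab has no
  three-dimensional dilution pathway, and without it molecules that
  outlive the local transporters would wander indefinitely.

Unprinted parameters — the sensor surface density (600 $\mu m^{-2}$),
the association rate of the rapid binding step ($1.45 \times 10^6\
M^{-1}s^{-1}$), the transporter association rate ($2 \times 10^7\
M^{-1}s^{-1}$), the PSF dimensions (lateral/axial FWHM 0.35/1.6
$\mu m$) and the clearance constant — were fixed once by calibrating
the simulated saturation curve to the published fit constants at
optimal orientation ($B_{max} = 5.9\ \Delta F/F_0$, $K_d = 6.5$
vesicles), which is also how the original analysis anchored its
saturation correction. Sensitivity to these choices is part of the
test suite as ordering properties (apparent $K_d$ grows with the
extrasynaptic PSF fraction; tilting the synapse raises $K_d$ and
lowers $q$). Orientation is modelled as rigid rotations: spine tilt
rotates the cleft normal toward the optical axis, axon tilt takes the
assembly out of the focal plane.

Known limitations: re-entry into the cleft is more frequent than in
open 3D geometry (the cleft-escape property is therefore stated as
first passage); glutamate re-released by bright-state reversion
(~9 ms) is treated as cleared, which is irrelevant for the ~1–2 ms
peak; the AMPA-receptor channel is a deliberately reduced two-state
occupancy proxy driven by the simulated cleft concentration, provided
for qualitative comparison only and excluded from any quantitative
claim.

## Localization

Frame-scan stacks are reduced to a stimulus-evoked difference image
(post-stimulus frames within one decay constant minus baseline
frames) and fitted with a 2D Gaussian plus offset (sub-pixel centroid,
initialized at the image maximum). The spatial confinement of success
centroids is summarized by the covariance ellipse scaled to the
empirical 95% Mahalanobis radius, which contains exactly
$\lceil 0.95\,n \rceil$ points by construction; a minimum-area
enclosing ellipse (Khachiyan) is available as the alternative
construction, and orientation is always free. Bead-based precision
calibration is replaced by synthetic point-source stacks at a
configurable photon budget.

## Problem sizes

The shipped tests and the acceptance script run at the following
scales, chosen to give stable statistics at interactive runtimes: 50
replicate boutons of 300 trials per condition for parameter recovery;
$10^4$ noise-only trials for classifier calibration; $10^5$ samples
per point for the mixture-density oracle; 20 Monte Carlo runs per
vesicle count (1–15, two orientations sharing the binding
realizations) for the saturation experiment; 40 stacks per jitter
level for the confinement ladder. Unit tests use smaller versions of
the same designs.

## A worked example

```{r example, eval = FALSE}
truth <- gluGroundTruth()                  # N = 3, q = 0.84, p 0.08/0.79
acq <- acquisitionParams(nTrials = 300, sigma0 = 0.08)
ses <- synthesizeSession(truth, acq, seed = 1)
amps <- processSession(ses)                # QC, bleach, template, labels
fit <- fitQuantalModel(amps)               # joint two-condition grid search
fit
synapticStrength(fit)
```

The README shows this example with the numbers it prints.
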