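---
title: "Measuring undulatory swimming kinematics: models, estimators, and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring undulatory swimming kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimkin)
```

## The measurement problem

An elongate fish swimming steadily propagates a wave of body bending from
head to tail. High-speed video of such trials is routinely reduced to a
small set of magnitude variables: swimming speed $U$ (body lengths per
second), tail-beat amplitude $A$ (BL), body wave frequency $f$ (Hz), body
wave speed $V$ (%BL s$^{-1}$, the transit speed of a curvature crest along
the posterior body), body wavelength $\lambda$ (BL), and — for fishes that
recruit their pectoral fins — fin beat frequency $f_{fin}$ (Hz) and a
binary fin-use state. These variables feed treatment comparisons, e.g.
between water viscosities or sensory conditions.

swimkin implements this reduction from the two artefacts such experiments
produce: landmark tracks (nose, tail tip, fin tips) in the three-header-row
pose-estimation CSV dialect, and binarized silhouette stacks. Because real
trials come with no ground truth, the package also ships a synthetic
swimmer whose parameters are known exactly, so that every estimator can be
validated by parameter recovery.

## The synthetic swimmer

The generator models steady anguilliform swimming as an
amplitude-enveloped sinusoidal traveling wave riding on uniform forward
translation. With $s \in [0, 1]$ the head-to-tail body fraction measured
*along the body*, lateral displacement is

$$ y(s, t) \;=\; A \, \mathrm{BL} \; s^{p} \,
   \sin\!\big(2\pi (f t - s / \lambda)\big), $$

so the bending wave travels tailward at $f \lambda$ BL s$^{-1}$ and the
tail tip reaches peak excursion $A\,\mathrm{BL}$. The longitudinal
coordinate is obtained by integrating
$dx = \sqrt{(\mathrm{BL}\,ds)^2 - dy^2}$, i.e. the body is inextensible.
This matters: if the lateral wave is simply superimposed on a straight
backbone, the midline's arc length exceeds BL by about 3.5% at the default
amplitude and wavelength ($A = 0.08$, $\lambda = 0.6$, $p = 2$), which
alone would bias every BL-normalized variable by that amount. With the
inextensible construction the generated arc length equals BL to numerical
precision.

Defaults emulate the study design the package targets: 500 frames
s$^{-1}$, 2 s trials (5 locomotor cycles at $f = 2.5$ Hz), BL = 300 px,
$U = 0.5$ BL s$^{-1}$, $A = 0.08$ BL, $\lambda = 0.6$ BL, $f_{fin} = 3.5$
Hz, 1 px landmark jitter, and a factorial design of 5 fish × 2 viscosities
× 2 light levels × 2 lateral-line states × 2 trials. The amplitude
envelope exponent $p$ defaults to 2; it is a free knob and is not claimed
to match any particular species. Condition labels (viscosity, light,
lateral line) carry no physics — their kinematic consequences are injected
as parameter shifts via `generate_study()`'s `effects` argument, plus a
per-fish normal random intercept (`fish_sd`) and a within-fish
trial-to-trial deviation (`trial_sd`). The trial-level term is an
extension beyond a pure fish-intercept model: without it a simulated study
has zero residual variance and no mixed model is estimable.

Silhouettes are rendered as unions of disks along the midline with a
half-width profile $w(s) = w_0 (1 - s^2)$ (default $w_0 = 0.04$ BL),
strictly positive except at the tail tip. Fin tips sit at a lateral offset
from the body at 15% BL; when fins are "On" the offset oscillates at
$f_{fin}$ (antiphase left/right). Everything is deterministic given the
trial seed.

### What the generator does not emulate

No hydrodynamics (viscosity effects must be injected, not derived), no
turning or acceleration, no self-occluding postures, no fin silhouettes in
the rendered frames, no pose-estimation failure modes beyond Gaussian
jitter. Passing recovery tests therefore demonstrates the correctness of
the measurement chain on clean steady swimming — not robustness to every
artefact of real video.

## Signal conditioning

Digitized points carry tracker jitter. Following standard practice the
package low-passes each coordinate series with a zero-phase (applied
forward and backward) 4th-order Butterworth filter at **5× the movement
frequency** — body points at $5f$, fin points at $5 f_{fin}$. Zero phase
is essential because every downstream variable is built from event timing
(peaks, adductions). Edges are padded by odd reflection over one cutoff
period; trials are short (3–10 cycles), so uncontrolled edge transients
would contaminate a material fraction of the series.

The pre-filter frequency estimate comes from the largest peak of the
Hann-windowed, detrended periodogram (4× zero-padded), refined by
parabolic interpolation of log-magnitude. A series is declared
non-oscillatory when the peak does not stand out from the broadband floor
(peak power < 20× mean power). The threshold sits well above the
max/mean ratio of pure white noise (≈ ln N ≈ 7 for these lengths) and far
below that of any genuine tone (hundreds to thousands even at SNR 10), so
it separates "fins never beat" from "fins beat" with a wide margin.

## Midline extraction

Each binary frame is reduced to an ordered head-to-tail midline:

1. keep the single large 8-connected component (two or more large
   components abort the frame as ambiguous; landmarks farther than 10 px
   from the foreground abort it too);
2. thin it to a 1-px skeleton (Zhang–Suen);
3. take the least-cost skeleton path between the pixels nearest the nose
   and tail landmarks (Dijkstra on the 8-connected skeleton graph with
   $\sqrt{2}$ diagonal costs) — side branches from fins or rendering
   artefacts are discarded automatically because they are not on the path;
4. re-anchor the path ends to the landmarks (thinning erodes the blunt
   head cap by about one half-width);
5. smooth $x(s), y(s)$ with a Savitzky–Golay filter (cubic, 33-point
   window) and resample to 100 equally spaced arc-length points.

Two smoothing choices deserve justification. A penalized smoothing spline
was rejected because its natural boundary conditions force curvature to
zero at the ends of the curve — and the tail end is exactly where the
curvature wave is measured; in round-trip tests the spline visibly
flattened $|\kappa|$ beyond 93% BL and roughly halved the apparent wave
speed. The Savitzky–Golay window (33 points ≈ 0.1 BL at the default
resampling) is well below half the shortest plausible bending wavelength,
and round-trip tests show mean distance to the true midline below 1.5 px
with arc length within 3%.

Signed curvature is the arc-length derivative of the unwrapped tangent
angle by central differences. On the body-fraction × frame grid
(`curvature_field()`), a 7-frame moving average along *time* removes
pixel-quantization noise: across frames the noise is independent while
the signal at fixed $s$ oscillates at $f \ll$ fps/2, so temporal averaging
denoises without displacing anything along the body (an earlier along-body
average measurably dragged extremum positions near the tail).

## The seven variables

**Tail lateral excursion.** The tail's deviation from its own one-cycle
moving-average path, projected on the normal of the local heading (the
nose-to-tail axis averaged over a one-cycle sliding window). Projecting
the deviation of the tail from a *line* is avoided deliberately: with the
tail ~BL/2 behind the window centre, a heading-angle error $\alpha$
displaces the perpendicular distance by $\sim \alpha \mathrm{BL}/2$ —
first order in $\alpha$ — whereas the deviation-vector projection is
second order. The moving-average reference is extended linearly across the
truncated first/last half window; letting the window shrink instead drags
the reference toward the instantaneous excursion and shifts edge peaks
(in tests this biased wave frequency by +3%).

**Peaks and cycles.** Per-side maxima of the filtered excursion with
prominence ≥ 10% of the series range and spacing ≥ 0.3 cycles; among
consecutive same-side peaks the larger survives, enforcing alternation. A
trial needs 3 same-side peaks to be measurable at all and 3 full cycles
(4 same-side peaks) to be accepted, mirroring the steady-cycle acceptance
rule for filmed trials.

**Swimming speed** is the net displacement of the nose–tail midpoint
between the first and last same-side peak (whole cycles, so within-cycle
oscillation cancels), divided by elapsed time and BL.

**Tail amplitude** is the classic chord construction: perpendicular
distance from the tail position at an intervening right-side maximum to
the line through the two flanking left-side maxima, halved and normalized
by BL, averaged over triples. The chord makes the measure exactly
invariant to straight-line drift between beats (verified against a
brute-force point-line oracle).

**Body wave frequency** is the mean of $1/\Delta t$ over consecutive
same-side peak pairs, both sides pooled.

**Pectoral fin frequency** detects adductions as minima of the fin tip's
perpendicular distance to the *local body axis* — the nose-to-tail
direction averaged over 0.5 s and anchored on the equally smoothed nose
path. The instantaneous nose–tail line is unusable here: it swings with
every tail beat, imprinting the body frequency on the fin distance of a
fish whose fins never move (this exact false positive occurred in
testing). Fewer than two adductions, or no detectable oscillation, yields
a missing value — by definition never zero — and fin state "Off".

**Body wave speed** tracks local extrema of $|\kappa|$ (within one bending
sign) across frames by nearest-position continuity over the posterior
body, and times each extremum's transit from 75% to 95% BL:
$V = 0.2 / (t_{95} - t_{75}) \times 100$, averaged over all complete
transits of both signs. A standing flexion produces no transit and a
missing value with a warning.

**Body wavelength** is the mean chord distance between consecutive
same-sign curvature extrema along the midline, normalized by BL; the
adjacent opposite-sign spacing × 2 is emitted alongside as
`wavelength_alt`, covering the half-wavelength reading of "distance
between minimum or maximum curvature". The extremum height threshold is
deliberately low (10% of the frame's $|\kappa|$ maximum): with a
tailward-growing envelope the anterior extrema are weak, and discarding
them selects the compressed posterior pairs, biasing the estimate further
down (see below).

### A known, quantified bias of the wavelength measure

For an enveloped wave $y = A\,e(s) \sin(2\pi(ft - s/\lambda))$ the
curvature extrema are not at the phase extrema: they are shifted by
$\delta(s) \approx \arctan\!\big(2 e'(s) / (e(s)\, 2\pi/\lambda)\big)$,
which **does not depend on the amplitude** $A$. With the default envelope
$e(s) = s^2$ and $\lambda = 0.6$, the spacing of same-sign extrema is
compressed by roughly 9%, and measuring chords rather than arcs removes
another ~4%. A dense analytic differentiation oracle confirms the true
extrema spacing of the default motion is 0.53–0.55 BL, and the package
estimator reproduces *that* value within a few percent — i.e. the
estimator is faithful to the definition; the definition itself under-reads
the wavelength parameter of enveloped waves. On envelope-free waves
($p = 0$) the estimator recovers $\lambda$ within tolerance across
amplitudes. Recovery expectations for the default swimmer should therefore
be set against roughly 0.52–0.53 BL, not 0.6 BL; the package reports the measure as
defined rather than applying an envelope-dependent correction. The wave
*speed* tracker inherits a milder version of the same shift (extrema move
a few percent faster than $f\lambda$ under the default envelope).

## Statistics stage

Each variable is fitted by REML to a linear mixed model with swimming
speed as a covariate (dropped when speed itself is the response), the
three treatment factors as fixed effects (all two-way interactions among
them by default; main-effects-only available), and a per-fish random
intercept, via `nlme::lme`. A `varIdent`-style variance structure
(distinct residual variance per level of a grouping factor, default
choice: viscosity) is available where residual spread differs between
groups. Rows with a missing response — absent fin frequencies — are
dropped from that variable's fit only. A constant response short-circuits
to a degenerate fit with zero effects and variances. Treatment contrasts
are estimated-marginal-means pairwise differences on the full factorial
reference grid (covariate at its mean, equal weights, containment degrees
of freedom via emmeans), Bonferroni-adjusted by the number of comparisons
made for that variable, significant at adjusted p < 0.05. Fin-state counts
are tested with a two-sided exact conditional test by full enumeration of
the (multivariate) hypergeometric support; `stats::fisher.test` serves as
an independent oracle in the test suite, never as the implementation.
Outlier screening flags trials whose absolute normalized residual exceeds
3 *and* whose removal improves Shapiro–Wilk normality of the remaining
residuals; it only flags — removal is left to the analyst.

Simulation checks run at the study's own scale (5 fish × 8 conditions × 2
trials): 200 replicate studies for 95% CI coverage of each fixed effect
(accepted range 90–98%) and 500 null replicates for the Bonferroni
familywise error (≤ 6% at nominal 5%). These sizes keep the default test
run to a few minutes while leaving Monte-Carlo error well inside the
accepted bands. In the coverage simulation the covariate's true slope is
zero by construction (the generator draws speed and wave frequency
independently), so its coverage is assessed against zero.

## Numerical choices and degenerate inputs

* Resampling density: 100 midline points; "75% BL" etc. refer to this
  grid's arc-length fraction.
* Landmark anchoring tolerance: 10 px; extraction must not abort from
  ordinary landmark jitter.
* Peak prominence 10% of range, spacing 0.3 cycles; wave-speed extremum
  threshold 20% of the field maximum (tracking needs strong crests),
  wavelength threshold 10% of the frame maximum (see bias discussion).
* Zero-amplitude or flat series: rejection errors, never silent zeros.
  Trials under 3 cycles: refused by the generator and rejected by
  `assemble_trial`. Standing waves: missing wave speed with a warning.
  Fins off: missing fin frequency, state "Off".
* Exact-test tables with a zero margin carry no information: p = 1 with a
  warning.

## Known limitations

* The wavelength measure's envelope bias, quantified above.
* Midlines of self-occluding (coiled) postures are rejected, not
  recovered.
* The skeleton path assumes nose and tail landmarks are roughly correct;
  systematically swapped landmarks would silently reverse the midline.
* The 2×K exact test enumerates the full conditional support; it is exact
  but combinatorial — fine for per-factor 2×2 and the 2×8 condition
  table at this study's size, slow for much larger tables.
* `wavelength_alt` aside, no attempt is made to disambiguate the two
  readings of "distance between consecutive instances of minimum or
  maximum curvature"; both are reported.
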