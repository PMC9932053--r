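---
title: "Multi-scale movement analysis: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale movement analysis: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitscale)
```

## The problem

Marker-free video tracking of a rodent in an open-field arena yields,
per animal, seven simultaneous position series at 30 frames per second:
snout, the four paws, the tail base and the body midpoint, each with X
and Y coordinates.  `gaitscale` asks two questions of such data: *how
does displacement variability grow with time scale* (and where does
that growth change regime), and *how are the body parts coupled to each
other* once the shared locomotor drive is accounted for — including who
leads whom, and by how much.

## The movement model

Displacement statistics of confined animal locomotion are not
scale-free.  At short time scales movement is smooth and strongly
persistent: the fluctuation function grows approximately as
$F(s) \propto s^2$, the signature of $1/f$ increments.  At long scales
the arena confines the animal; displacements become nearly random and
even anti-persistent, $F(s) \propto s^{1/2}$.  The two regimes are
separated by a single crossover scale $s_\times$ of the order of
seconds, and the position of that crossover is the headline discriminant
between cohorts with different gait dynamics.

## Estimators

**DFA / DCCA / DPCCA.**  For $m$ series $x^j$ the profiles
$X^j_i = \sum_{k \le i} x^j_k$ are formed.  For each scale $s$, every
sliding window of $s+1$ frames (step 1, so $N-s$ windows) receives a
least-squares polynomial fit of order 2 (configurable 1–3); the
residuals $Y^j_l$, $l = 1,\dots,(N-s)(s+1)$, give the detrended
covariance matrix

$$F^2_{j_1 j_2}(s) = \frac{1}{(N-s)(s+1)} \sum_l Y^{j_1}_l Y^{j_2}_l .$$

Its diagonal is the squared DFA fluctuation function; normalizing,
$R_{j_1 j_2}(s) = F^2_{j_1 j_2} / \sqrt{F^2_{j_1 j_1} F^2_{j_2 j_2}}$,
gives the DCCA coefficient matrix, and the partial (DPCCA) coefficients
follow from its inverse $C = R^{-1}$ as
$P_{j_1 j_2} = -C_{j_1 j_2} / \sqrt{C_{j_1 j_1} C_{j_2 j_2}}$.
Partial coefficients matter here because at large scales every body
part follows the walking animal, so pairwise $R$ converges to 1; $P$
removes the correlation mediated by the other series (in particular
the common locomotor drive) and exposes the intrinsic pairwise
coupling.

The sliding-window convention (overlapping windows, step one frame) is
used throughout; it is the convention implied by the
$(N-s)(s+1)$ normalizer, even though a disjoint-window reading of the
procedure is also in circulation.  Total displacement combines axes as
the elementwise sum of the X- and Y-axis $F^2(s)$ matrices.

**Delayed coupling.**  The covariance is extended with a relative shift
$k$, $|k| \le s/2$: the windows of one residual series are compared
against the windows of the other shifted by $k$ frames, using
overlapping windows only and renormalizing by the overlap count.  The
shift is applied at the window level — i.e. to a relatively shifted
copy of the data — rather than to the flattened residual index, because
only the window-aligned shift recovers an exactly delayed copy exactly:
if series 2 is series 1 delayed by $d$ frames, its window-$a$ residuals
equal series 1's window-$(a-d)$ residuals identically, so the
cross-covariance peaks exactly at $k = d$ at every scale $s \ge 2d$.
The flat-index shift mixes residuals across window boundaries and
drifts off the true delay at larger scales.  At $k = 0$ both readings
coincide with the undelayed covariance exactly.

Within the network pipeline the shifted entry is re-inserted into the
covariance matrix before normalization and inversion, so the reported
edge strength is the *shift-maximized partial correlation*.  Shifts
that make the modified matrix indefinite have no valid partial
correlation and are excluded from the maximization.  Ties in the
maximum are broken toward the smallest $|k|$, then toward negative $k$.

**Crossover localization.**  $F(s)$ is divided by $s^{5/4}$ — an
exponent strictly between the two asymptotic slopes, so both sides of
the crossover decay — and $s_\times$ is the maximum of the rotated
curve.  The grid argmax is refined by the vertex of the interpolating
parabola through the three surrounding points in log–log coordinates
(grid-free, but assuming no parametric crossover shape); an argmax at a
grid edge raises a boundary flag instead.  Asymptotic exponents are fit
by least squares on $s < s_\times/2$ and $s > 2 s_\times$; the factor-2
guard bands keep the fits away from the crossover region, which this
class of estimators smears toward larger scales.

## Numerical choices

* **Scale grid**: ~20 log-spaced scales from $\max(8,\ \mathrm{order}+3)$
  to $N/4$ frames (standard variance control); recorded in every output.
* **Two computational routes** for $F^2(s)$, agreeing to $10^{-10}$
  with naive triple loops: an explicit blocked residual computation
  (used at small scales, numerically benign even for very smooth
  $\alpha \approx 2$ series), and an $O(N)$ cumulative-moment identity
  per scale (used at large scales, where residuals are a sizable
  fraction of the windowed profile and its squared-difference
  cancellation is harmless).  A non-positive diagonal from the moment
  route triggers the explicit fallback.  Profiles are pre-reduced by a
  global polynomial fit of the detrending order, which leaves all
  residuals mathematically unchanged.
* **Near-singular $R(s)$**: ridge $\lambda = 10^{-8}\,\mathrm{tr}(R)/m$
  before inversion; still-singular scales are flagged, not dropped
  silently.  An inverse with non-positive diagonal (indefinite input)
  is likewise flagged rather than propagated.
* **Degenerate inputs**: constant series produce a named error at the
  DCCA normalization; empty series, even median windows, and scales
  incompatible with the detrending order are rejected with specific
  messages.

## Preprocessing defaults

* **Likelihood gate 0.6**: the tracking confidence below which a
  detection counts as a miss.  Common pose-estimation practice; the
  source procedure states only that undetected frames are gap-filled,
  so the value is a package decision and is CLI-configurable.
* **Gap filling**: previous observed value; a missing prefix takes the
  first observed value (nearest neighbour).  Idempotent; leaves no
  missing samples.
* **Median filter over 5 frames**, shrinking symmetric windows at the
  edges (widths 1, 3, 5) so no data are invented and length is
  preserved.
* Analysis is unit-agnostic — all reported coefficients are
  scale-free; an optional px→cm factor is configuration only.

## The synthetic generator: what it emulates, and what not

The generator exists so that every downstream stage is testable without
recordings.  Its stated world: 15-minute, 30-fps, 7-part trajectories
whose per-axis series have a two-regime fluctuation function with a
tunable crossover (defaults: $\alpha = 2$ below, $\alpha = 1/2$ above,
$s_\times = 8$ s; the default cohort contrast shifts the test-group
crossover to 4 s and changes nothing else, isolating the headline
discriminator).

Series are produced by random-phase spectral synthesis: Gaussian
Fourier coefficients shaped by $S(f) \propto f^{-(2\alpha - 1)}$, with
a piecewise spectrum (continuous at the break) for the two-regime case.
The amplitude scale of a two-regime series is anchored on its
high-frequency branch (normalized so a crossover-free
$\alpha_\mathrm{small}$ reference has unit population variance): the
small-scale statistics represent step-level motor dynamics and are
*invariant* across crossover settings, so two cohorts differing only in
$s_\times$ differ only at scales near and above the crossover.  A
per-series unit-variance standardization would instead rescale the
common small-scale branch by a group-dependent constant and leak the
contrast into every scale.
The spectral break is placed at $1/(c\, s_\times f_\mathrm{fps})$ with
$c = 1/1.27$: a one-time calibration study (N = 2^15, exponent pair
(2, 1/2), stable across designed crossovers of 4 s and 10 s) showed the
rotation estimator localizes the crossover a constant 1.27× above the
naive break scale, and the generator's contract is that the analysis
recovers the *designed* $s_\times$.  The constant is part of the
generator definition, not a tuning knob.

Inter-part structure: the midpoint follows an independent two-regime
series per axis; each other part responds to it with correlation $\rho$
(default 0.8) and delay $d$,
$\mathrm{part}(t) = \rho\,\mathrm{mid}(t-d) +
\sqrt{1-\rho^2}\,w(t-d) + \sigma_\eta \eta(t)$, where the relative
driver $w$ is shared by the parts of an axis (so part–part delays are
recoverable) and $\eta$ is white tracking jitter
($\sigma_\eta = 0.05$).  The delay shifts the part's whole response
while the midpoint itself stays unshifted, keeping it a common driver.
Delays use circular shifts to preserve length and stationarity.

What the generator does *not* emulate: arena geometry and wall
reflections, biomechanical gait cycles, intermittent rest/locomotion
bouts, heavy-tailed displacement bursts, or any superstatistical
two-level cascade.  A green test therefore establishes that the
estimators recover the statistical structure they assume — scaling
exponents, crossover position, coupling strength and delay — not that
real recordings satisfy that structure.  There is also no generative
model for the confined large-scale regime beyond its scaling signature;
the piecewise spectrum reproduces the exponent, not the mechanism.

## Group statistics

Quartiles for the Tukey fence use linear interpolation between order
statistics (quantile type 7; the convention is recorded in the output
because other conventions move the fence on small samples).  Fencing is
applied per metric, scale and group before testing.  The Mann–Whitney
U test is exact by enumeration of all group assignments when both
groups have ≤ 8 observations (exact under ties as well), and uses the
tie-corrected normal approximation with continuity correction
otherwise.  P-values are adjusted across scales by Bonferroni (default;
Benjamini–Hochberg optional) — the unnamed "multiple testing
correction" of the source analysis is taken as the most conservative
standard choice.  The gliding-window map uses 30-s windows with 50%
overlap (the overlap is a package decision; only the duration is
stated) and truncates scales above window/3.

## Network construction

Edges carry the shift-maximized partial correlation and the maximizing
delay.  Direction follows the sign of the delay — the leading part is
the source, on the principle that the cause can only precede the
response; zero-delay pairs stay undirected.  $T_{j_1 j_2} > 0$ means
$j_1$ leads; the convention is stored in the export metadata.  Only the
dominant (maximizing) coupling per pair is kept; secondary local maxima
of the cross-covariance are out of scope.  Default reporting scales are
5 s and 30 s.  Part–midpoint edges are flagged as the network backbone.

## Known limitations

* The delayed-coupling scan is $O((N-s)\,s)$ per pair and shift range,
  so network construction at 30 s scales on full 15-minute recordings
  is minutes-per-animal; restrict the scale list or window the
  recording if that matters.
* Partial correlations between parts that also share a delayed common
  driver can peak at a shift different from the pairwise injected
  delay (conditioning reshapes the shift profile); part–midpoint
  delays are recovered as designed.
* One crossover per fluctuation function; curves with two genuine
  crossovers report the dominant one.
* The exact Mann–Whitney enumeration grows combinatorially; above 8
  per group the normal approximation is used, which is what the
  cohort sizes here require anyway.
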