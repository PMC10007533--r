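---
title: "Quantifying infant motor overflow from wearable accelerometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infant motor overflow from wearable accelerometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinegc)
```

## The problem

Young infants produce *motor overflow*: involuntary movement of limbs that
are not involved in a goal-directed action. When a 4-month-old reaches for a
toy with one arm, the other arm and the legs co-activate. `kinegc`
quantifies this phenomenon from wearable accelerometer recordings of the
four limbs, asking a temporal question: does the non-acting limb's activity
*lead* or *follow* the acting arm's?

The pipeline has five stages, each exposed as ordinary functions and
orchestrated by `run_full()`:

1. **Preprocessing** of raw 3-axis streams (`preprocess_recordings()`),
2. **Clock synchronization** between video annotations and sensor data
   (`sync_clocks()`),
3. **Event-locked epoching** around reach onsets (`role_epoch_matrices()`,
   `average_epochs()`),
4. **Bilateral Granger causality** with supporting statistics
   (`analyze_pairs()`, `granger_bilateral()`),
5. **Reporting** (`render_tables()`, the run manifest).

Because real infant recordings of this kind are rarely shareable, the
package ships a first-class synthetic-data generator
(`simulate_recordings()`) that produces four-limb recordings with *known*
directional coupling, clock offset and artifacts, so every stage can be
validated against ground truth.

## The synthetic generator

Latent limb "activity magnitudes" follow a stationary lag-1 vector
autoregression across the four limbs,

$$ z_t = A\, z_{t-1} + \varepsilon_t, \qquad
   \varepsilon_t \sim \mathcal N(0, \sigma^2 I_4), $$

with the 4×4 coupling matrix $A$ (row = target limb, column = source limb)
required to have spectral radius below 1. Magnitudes must be nonnegative, so
a constant baseline is added and the result truncated at zero; the
truncation rate is recorded so tests can bound the distortion (at the
defaults it is far below 1%). We chose baseline-plus-truncation over a
log-transform because it keeps the series in m/s² and preserves the
magnitude-collapse algebra end to end.

Reaches and kicks are smooth Hann-envelope bursts added to the acting
limb's magnitude. Kicks are kept temporally isolated (no other event onset
within a 5 s guard) because the synchronization stage uses them as fiducial
events; the guard value quantifies the otherwise informal notion of a
"robust, isolated" kick. Each magnitude series is then embedded in three
axes whose per-sample Euclidean norm equals magnitude + gravity exactly
(the direction is a smoothed random walk on the unit sphere, mimicking slow
orientation drift of a worn sensor). Finally one-point outliers
(|value| ≫ 150 m/s², emulating tracker glitches), missing-data gaps, and a
constant annotation-minus-sensor clock offset are applied, and everything
injected is recorded in a `sim_truth` object.

Default values and why:

| parameter | default | rationale |
|---|---|---|
| `fs` | 60 Hz | the common tracker rate (one supported alternative: 40 Hz) |
| `duration` | 300 s | a typical ~5 min supine play session |
| `innovation_sd` | 0.5 m/s² | background limb-acceleration fluctuation of an awake infant |
| `baseline` | 2 m/s² | keeps magnitudes positive with negligible truncation |
| `burst_amplitude` | 5 m/s² | a clear reach/kick burst above background |
| `burst_duration` | 2 s | average duration of an infant reaching movement |
| `clock_offset` | 1.5 s | camera/sensor start-up delays are a few seconds at most |
| `outlier_count` | 6 | glitch counts observed in practice at this recording scale |
| `outlier_magnitude` | 5 × 10⁴ m/s² | typical tracker-glitch magnitude (10²–10⁵ above real movement) |
| `gravity` | 9.8 m/s² | added to the embedding, later subtracted by preprocessing |

All randomness flows from one integer seed through fixed per-stage
sub-streams; an identical configuration reproduces byte-identical files.

What the generator does **not** emulate: biomechanical realism (joint
kinematics, posture), orientation/gyroscope channels, burst-shape
variability across reaches (every reach burst has the same envelope), and
non-Gaussian innovation spectra. Passing tests therefore demonstrate the
pipeline's correctness under the stated statistical structure, not its
behavior on every feature of real infant data — see "Known limitations".

## Preprocessing

Stage order is fixed and logged: per-axis outlier nulling → missingness
accounting and the exclusion rule → cubic-spline gap interpolation →
magnitude collapse → low-pass filtering → resampling → gravity subtraction.

- **Outliers**: any raw-axis sample with |value| > 150 m/s² becomes missing.
  The rule runs on raw axes *before* the magnitude collapse, because glitch
  magnitudes (~10⁴ m/s²) would otherwise contaminate three derived values at
  once and be double-counted.
- **Exclusion**: a sensor with more than 25% missing samples in any axis is
  excluded wholesale (configurable). 25% is the stricter of the two
  conventions in circulation for this paradigm; the run manifest records
  the decision either way.
- **Interpolation**: interior gaps are filled with a *natural* cubic spline
  through the valid samples; leading/trailing gaps take the nearest valid
  value, because spline extrapolation is unsafe. Natural boundary conditions
  introduce error only near the series edges; in the interior the
  natural-spline solution reproduces smooth signals (including cubics) to
  machine precision, which the test suite exploits.
- **Magnitude**: $\sqrt{x^2 + y^2 + z^2}$ per sample, rotation-invariant by
  construction.
- **Filter**: a causal single-pass digital Butterworth low-pass (order 4,
  cutoff 25 Hz), i.e. the bilinear transform of the analog prototype
  $|H(f)|^2 = 1/(1 + (f/f_c)^{2n})$ with pre-warped cutoff: unit DC gain and
  gain $1/\sqrt 2$ at $f_c$. An optional zero-phase (forward–backward) mode
  exists; it squares the gain, so the cutoff gain becomes 1/2, which the
  documentation and tests state explicitly.
- **40 Hz recordings**: a 25 Hz cutoff is not below the 20 Hz Nyquist limit
  of a 40 Hz stream, so filtering at the native rate is impossible. For any
  `fs < 2 * cutoff` the series is resampled to 60 Hz *before* filtering and
  the reordering is logged.
- **Gravity**: 9.8 m/s² is subtracted globally after filtering; values are
  not clipped. Whether this happens before or after epoching is immaterial
  for the causal inference — constant shifts drop out of regressions with
  an intercept, which a dedicated test asserts to 1e-8 on the F statistic.

## Clock synchronization

Cameras and sensors start independently, so annotation timestamps run ahead
of (or behind) the sensor clock by an unknown offset. Alignment uses the
isolated leg kicks: within a window from 15 s before the first annotated
kick to 15 s after the last, the leg sensor with the highest variance is
binarized at `median + 3·MAD` (computed inside the window; the robust
threshold is insensitive to the very bursts it detects), the annotated kick
intervals are rendered on the same sample grid, and a diagonal
cross-recurrence search over integer lags $d \in [-L, L]$ (default
$L = 5\,\mathrm s \times f_s$) maximizes

$$ RR(d) = \frac{\#\{t : a_t = b_{t+d} = 1\}}{\text{overlap length at } d}. $$

Ties break toward the smallest |d|, then toward the negative lag. A
positive lag means the annotation timestamps run ahead of the sensor clock;
the correction subtracts `lag_seconds` from all annotation times, after
which re-estimation returns 0 (a fixed point the tests assert). The
recurrence rate at lag 0 after the shift is reported as an automated
residual check, replacing manual visual validation.

Numerical caveat, stated openly: the binarized sensor marks cover the
*central* suprathreshold portion of each kick burst, while the annotation
marks cover the full annotated interval. When one mark set is a strict
subset of the other, $RR(d)$ has a plateau, and the overlap normalization
tilts its argmax toward the plateau edge — a systematic sub-burst-width
bias (well under one burst duration; typically a few hundred ms here).
Because the bias is a *uniform* time shift of all events, downstream
epoch-averaged Granger statistics are unaffected. Exact recovery holds
whenever the two trains have matching mark shapes, which is what the
recovery tests (offset grid, jitter robustness) verify.

## Epoching

Unimanual reaches (left or right hand) are kept; bimanual reaches are
dropped, since overflow in an arm is only observable when that arm is not
acting. Participants with fewer than four unimanual reaches are excluded
(ledgered, not analyzed). For each reach the limbs are mapped to roles:
*acting arm* (the reach's hand), *non-acting arm* (contralateral), and
*legs mean* (per-sample average of both legs). A fixed window of 2 s before
to 2 s after the onset is cut per role — 240 samples at 60 Hz, onset at row
121 (1-based) — using `round(onset · fs)` for the onset sample and a
half-open window; the mapping and the skip-don't-pad rule for edge reaches
are our choices where the procedure is conventionally left unstated, and
every skipped reach is logged so counts reconcile. Epochs are collapsed
per reach type (`all`, `grasp`, `touch`, `unsuccessful`) and averaged
*across reaches per sample*, yielding one 240-sample series per role and
type. (The averaging axis is stated here precisely because the informal
phrase "averaged across rows" is ambiguous; only per-sample averaging
yields a 240-sample series.)

## Statistical core

**Stationarity screen.** Each role series passes through an augmented
Dickey–Fuller test: least squares of $\Delta y_t$ on
$\{1, y_{t-1}, \Delta y_{t-1..k}\}$, $k$ chosen by AIC (Schwert rule
ceiling), statistic = t-ratio of the $y_{t-1}$ coefficient, p-value from
the MacKinnon response-surface constants for the constant-only case. A
failed screen flags the affected rows and warns but never halts —
differencing would silently change the estimand.

**Lag selection.** For each pair, the bivariate VAR is fit by least squares
for orders $p = 1..120$ (reduced below $(T-1)/3$ with a warning when the
series is short; for $T = 240$ the ceiling is 78) and the order minimizing
a corrected Akaike criterion is kept:

$$ \mathrm{AICc}(p) = \ln\det\hat\Sigma_{ML}(p)
   + \frac{2k}{T_{\mathrm{eff}} - k_{\mathrm{eq}} - 3}, $$

with $k = 2(1+2p)$ total coefficients, $k_{\mathrm{eq}} = 1+2p$ per
equation and $T_{\mathrm{eff}} = T - p$ (per-order alignment). The
small-sample correction in the denominator matters: with the plain
$2k/T_{\mathrm{eff}}$ penalty, the residual determinant collapses
mechanically once per-equation parameters approach the sample size, and the
*maximal* feasible order always wins on short series — a degenerate
selection that reference implementations reproduce as well. Away from that
boundary the corrected and plain criteria are numerically indistinguishable,
and the corrected criterion recovers the true order of simulated VAR
processes (p\*=1 for a lag-1 coupled pair at T = 240 in ≥ 80% of
replicates).

**Granger F-test.** For a chosen lag $p$, the restricted model regresses
the target on an intercept and its own $p$ lags; the unrestricted model
adds the source's $p$ lags; both on the common sample of $T - p$
observations:

$$ F = \frac{(RSS_r - RSS_u)/p}{RSS_u / \big((T-p) - 2p - 1\big)}, $$

with numerator df $p$ and denominator df $(T-p)-2p-1$ — for the 240-sample
epoch-averaged series at lag 1, the familiar 236. Every pair is always
tested in *both* directions (`granger_bilateral()`), with one shared
effect size

$$ d = \frac{|M_y - M_x|}{\sqrt{(s_x^2 + s_y^2)/2}} $$

(sample standard deviations, reported as a magnitude) attached to both
directions. p-values are reported raw, starred at 0.05 and 0.001; a
configuration flag can apply a Holm correction but is off by default to
match the reporting convention of the source paradigm.

## What the end-to-end simulations show — and what they do not

The package's validation battery establishes, under the generator's
conditions:

- the F statistic agrees with a brute-force two-regression oracle to
  below 1e-8, holds its nominal 5% size on white noise (rate within
  [0.03, 0.07] over 1000 pairs), and detects $y_t = 0.8 x_{t-1} + \epsilon$
  with p < 0.001 in ≥ 95% of runs;
- clock offsets on a ±3 s grid are recovered exactly for clean event
  trains, and within ±1 sample under 20% mark jitter in ≥ 95% of runs;
- the full pipeline (simulate → preprocess → sync → epochs → analyze) flags
  both injected coupling directions (non-acting arm → acting arm, acting
  arm → legs) at p < 0.05 in well over 80% of 200 replicates at coupling
  0.4.

One result is deliberately reported as a *negative* finding rather than
engineered away: in those same end-to-end replicates the *reverse*
directions reject above the nominal rate (about 20% for the arm pair and
50% for the legs pair instead of ≤ 5–10%). Ablations isolate two causes,
both properties of the analysis design rather than of the implementation.
First, the epoch-averaged series are dominated by the deterministic,
time-locked reach burst (averaging shrinks the stochastic component by
$1/\sqrt{n_{\text{reaches}}}$ while the burst persists); an F-test between
nested regressions on a nearly deterministic target will reject for *any*
additional linearly independent regressor once the lag order grows, and the
legs series even carries a lag-delayed copy of the burst through the true
coupling. With ground-truth alignment, no filtering and lag fixed at 1, the
reverse rejection rate is a nominal ~2.5%; at data-driven lag orders it
inflates severely. Second, low-pass filtering colors the innovations, so a
finite-order VAR is misspecified and the partner limb's lags proxy the
target's unmodelled own history. These are textbook anticonservativeness
mechanisms for Granger causality applied to event-locked averages, and they
are worth knowing about when interpreting forward-direction findings from
this design on real data: significant "reverse" or secondary effects should
be treated with caution whenever the averaged waveform dwarfs its
trial-to-trial variability. The generator's burst and noise scales were
chosen on realism grounds (table above) and kept fixed; making the bursts
small relative to noise would "fix" the rate but would also break the
kick-detection premise of the synchronization stage and misrepresent real
recordings.

## Numerical choices and degenerate inputs

- Onset-to-sample mapping `round(onset · fs)`; half-open windows; 0-based
  sample indices in files, 1-based in R.
- DCRQA ties: smallest |lag| first, then the negative lag; a flat
  recurrence profile warns and returns lag 0; an all-zero train is an error.
- Interpolation needs ≥ 4 valid samples; constant series are rejected by
  the ADF screen and by `cohens_d()` (both-constant); a perfect unrestricted
  fit (zero residual) is a degenerate F and is an error.
- Filtering requires `cutoff < fs/2`; the error message tells the user to
  resample first, and `preprocess_sensor()` does so automatically.
- `sim_config()` rejects non-stationary coupling with the offending
  spectral radius in the message, and outlier magnitudes at or below the
  150 m/s² detection threshold.

## Problem sizes used by the validation suite

Test and acceptance runs use one ~200 s session with 20 right-hand reaches
and 5 kicks per replicate (200 replicates end-to-end), a 800 s session for
the 184-reach epoch-geometry check, 1000 white-noise pairs for null
calibration, 100–300 seeded runs for the Monte Carlo bounds, and n = 10⁴
samples for the generator's stationarity and cross-correlation checks.
These sizes are stated here so results are interpretable as
Monte Carlo estimates at those scales.

## Known limitations

- Identical burst envelopes across reaches overstate the determinism of
  real infant reaching; consequences for reverse-direction inference are
  discussed above.
- The DCRQA estimator's plateau bias (uniform shift, sub-burst-width) is
  harmless downstream but means the *absolute* alignment can be off by a
  few hundred milliseconds when sensor marks are much narrower than
  annotation marks.
- Only acceleration magnitude is analyzed; orientation information is
  discarded by design.
- Pooling reaches across participants (no random effects) matches the
  source paradigm but ignores between-infant heterogeneity.
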