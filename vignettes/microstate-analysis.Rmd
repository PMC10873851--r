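---
title: "Microstate analysis of resting-state EEG: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The analysis in one paragraph

Resting-state EEG alternates between brief (tens of milliseconds) periods
during which the scalp potential topography stays quasi-stable — microstates.
The pipeline implemented here identifies those topographies, quantifies how
long and how often each one dominates, compares the dynamics between two
within-subject conditions, and correlates them with a per-subject trait
score. Because real recordings come without ground truth, the package ships a
generator that produces multichannel signals from *known* templates, dwell
times and coverages; every stage of the pipeline is validated by recovering
those knowns.

## Global field power and the clustering substrate

The global field power (GFP) at sample $t$ is the *population* standard
deviation of the potentials across the $C$ electrodes. The population form
(divisor $C$) rather than the sample form is a documented constant choice:
the two differ by a global factor $\sqrt{C/(C-1)}$, which moves no peak and
changes no correlation. Topographies at strict interior local maxima of the
GFP carry the highest signal-to-noise ratio and form the clustering
substrate. Plateaus (exact ties) contribute their first sample only — a
deterministic, order-independent rule — and peaks falling on masked (artifact)
samples are discarded; a peak is valid whenever the peak sample itself is
unmasked, the simplest rule consistent with excluding marked noisy segments.

## Polarity-invariant modified k-means

Microstate topographies are defined up to sign: the field alternates polarity
with the oscillatory carrier while the spatial configuration stays fixed.
The clustering therefore assigns each zero-meaned peak map $x_t$ to the
template $a_k$ maximizing $|\mathrm{corr}(x_t, a_k)|$ and updates each
template as the dominant eigenvector of $\sum_{t \in k} x_t x_t^\top$,
renormalized to zero mean and unit norm. Sign-averaging centroids would
cancel; the eigenvector update is the standard polarity-invariant
formulation. Both steps are coordinate ascent on the global explained
variance
$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t\,
\mathrm{corr}(x_t, a_{L_t})\big)^2}{\sum_t \mathrm{GFP}_t^2},$$
so iteration converges monotonically; we stop when the GEV gain drops below
`tol = 1e-6` (default cap 300 iterations). Each of the `n_restarts = 50`
default restarts first fits a random 90% subsample of the peak maps and is
then consensus-refit on the full set — a resampling scheme that stabilizes
the solution against individual maps — and the restart with the best full-set
GEV wins. Assignment ties break toward the lowest class index,
deterministically. Empty clusters are re-seeded from the worst-fitting map.

Correctness is checked against an *exhaustive* oracle: for up to 8 maps and
$k = 2$ every 2-partition is enumerated with eigenvector centroids, and the
restarted fit must attain the enumeration optimum to $10^{-9}$. Because both
assignment and update steps monotonically increase GEV, the global optimum is
a fixed point; the oracle test confirms the restarts actually find it.

## Choosing the number of classes

`choose_k()` fits every $k$ in a candidate range (default 1–12) and selects
the minimizer of the predictive cross-validation criterion
$$\mathrm{CV}(k) = \hat\sigma^2 \left(\frac{C-1}{C-1-k}\right)^2,
\qquad \hat\sigma^2 = \frac{\sum_t \left(\lVert x_t\rVert^2 -
\langle x_t, a_{L_t}\rangle^2\right)}{T\,(C-1)},$$
a residual-variance measure penalized for the degrees of freedom absorbed by
$k$ templates. The GEV curve is reported alongside and a `force_k` override
exists, because no single criterion is authoritative for real data — cluster
counts in the literature are often fixed by convention at four. Each $k$ is
warm-started from the previous solution plus the worst-fitting map, keeping
the GEV curve nondecreasing up to restart noise. The criterion degenerates
as $k \to C-1$, so candidates above $C-2$ are dropped. One caveat worth
stating: spatially smooth noise is genuinely low-dimensional, so on data
containing *only* noise the criterion can prefer $k > 1$; with distinct
generative classes present it reliably recovers their number (validated at
$k = 4$ across simulated cohorts).

## Two-level clustering and condition pairing

Clustering runs first per subject and condition, then the pooled subject
templates — all zero-mean unit-norm, hence equally weighted — are clustered
again with the same algorithm to give group templates per condition. Classes
are paired across conditions by maximizing total $|$spatial correlation$|$
with an exact assignment solver (Hungarian algorithm); greedy matching can
mispair near-degenerate maps. A topographic permutation test (TANOVA) gates
the pairing: per subject and condition the best-matching subject template is
taken, each map is L2-normalized, the statistic is the GFP of the difference
between the two grand-average maps, and the null swaps condition labels
within subject. With $n \le 12$ subjects all $2^n$ swaps are enumerated
exactly (the p value then includes the identity permutation); otherwise the
Monte-Carlo estimator uses the add-one correction
$p = (\#\{S^* \ge S\} + 1)/(B + 1)$.

## Backfitting and temporal parameters

Group templates are fitted back to every unmasked sample by
winner-takes-all $|$spatial correlation$|$; all-zero samples (the carrier
crosses zero) get correlation 0 to every template and fall to the lowest
class index by the tie rule. No temporal smoothing and no minimum-duration
rejection are applied by default — fidelity to the per-sample rule — though
fragmentation-sensitive users can smooth externally.

A *run* is a maximal constant-label stretch of contiguous unmasked samples.
Runs truncated by a mask boundary or epoch edge censor the true dwell time:
they are excluded from **mean duration** (which would otherwise be biased
downward) but kept in **time coverage**, whose denominator is the labeled
(unmasked) sample count — so coverages always sum to exactly 1 over labeled
time. A class seen only in censored runs reports `NA` duration with a
censoring flag; the fully degenerate single-class epoch reports the labeled
length as its duration, flagged. These rules are validated sample-by-sample
against a brute-force scan oracle.

Split-half reliability computes both parameters on the first and second half
of every epoch and correlates them across subjects per class and parameter —
the standard internal-consistency check for microstate statistics.

## Statistics

* **Repeated-measures ANOVA** (class × condition, both within-subject): the
  sums-of-squares decomposition is implemented directly, each effect tested
  against its own subject-interaction stratum with conventional
  (uncorrected) degrees of freedom; Greenhouse–Geisser correction is not
  applied. The implementation matches an independent brute-force oracle and
  `stats::aov` Error-strata to $10^{-9}$.
* **Paired contrasts**: two-tailed paired t per class × parameter, with
  Cohen's d from pooled condition SDs, $d = \bar{x-y} /
  \sqrt{(s_x^2+s_y^2)/2}$ (the paired $d_z = \bar{x-y}/s_{x-y}$ is also
  reported — published effect sizes are often ambiguous between the two
  conventions, and the pooled form yields the smaller, more conservative
  values). The family threshold defaults to Bonferroni $\alpha/m$ over the
  declared class × parameter family and is configurable, since reported
  corrected alphas in the literature do not always equal $\alpha/m$.
  Zero-variance difference vectors are flagged degenerate, not tested.
* **Trait correlations**: Pearson r with t-based p ($df = n-2$),
  Benjamini–Hochberg step-up across the declared family (the independence
  variant; the FDR flavor is rarely stated in applied work). BH never
  rejects fewer tests than Bonferroni at the same level.
* **Instrument scoring**: the 8-item neuroticism scale sums 5-point items
  after reverse-keying ($x \mapsto 6-x$), giving scores in $[8, 40]$;
  odd–even split-half reliability is the Pearson correlation between
  odd-item and even-item sums.

## The synthetic-cohort generator

The generator is first-class, tested code, not a fixture. Its defaults *are*
the emulated study conditions: 36 subjects, two conditions (`neutral`,
`fear`) with 6 epochs of 45 s each at 200 Hz, 32-channel spherical-cap
montage (configurable up to 256), $K = 4$ orthogonal smooth templates, mean
dwell 75 ms, equal coverages, and a per-subject trait score drawn
uniform-integer in $[8, 40]$ — the instrument's range, asserting no
population distribution.

**State dynamics.** Dwell times are discrete gamma (shape 2) with the
class mean and a 1-sample floor — avoiding the geometric law's excess of
1-sample states, which the backfitter must nonetheless handle. Successive
states always differ; transition weights are solved by a short fixed-point
iteration so that the long-run occupancy matches the target coverages
*including* the no-self-transition correction.

**Rendering.** The signal is $A \sin(2\pi f t)\, a_{L_t}$: the topography is
stable within a state while its polarity alternates with the carrier
half-cycles, so GFP maxima sit at carrier amplitude maxima. The default
carrier is 10.7 Hz — upper alpha band, deliberately incommensurate with the
200 Hz grid so samples rarely land on exact carrier zeros. Noise is
zero-mean, spatially smooth (Gaussian kernel on the cap, correlation length
0.4 chord units) and shares the carrier envelope, emulating
amplitude-modulated broadband background; `snr` is the amplitude ratio of
signal to noise, default 2. Envelope-sharing keeps the instantaneous
assignment quality stationary in time, which is what makes per-sample
backfitting informative about the generative dwell times.

**Effects.** In the `fear` condition the parameters (dwell and coverage) of
class C are scaled by $1 + \texttt{effect\_c}$ (default $-15\%$) and class D
by $1 + \texttt{effect\_d}$ (default $+15\%$); trait slopes (default
$\pm 1\%$ per unit of centered trait, positive for C, negative for D) apply
in both conditions. After targeting C and D, the remaining classes'
coverages are rescaled proportionally, preserving the sum-to-one invariant
while keeping the targeted effect interpretable. Each subject additionally
carries a stable lognormal baseline factor per class
(`subject_sd = 0.15`): genuine between-subject variance is what makes
split-half reliabilities above 0.7 and trait correlations around 0.4–0.6
possible at realistic cohort sizes, and ~15% CV matches the spread of
microstate parameters across published cohorts.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: broadband $1/f$ spectra beyond a single carrier,
ocular/cardiac artifacts (artifact handling is via the supplied mask only),
volume-conduction-realistic template shapes (templates are orthogonalized;
real class maps correlate at 0.3–0.6), nonstationary dwell distributions,
and electrode-level noise heterogeneity.

**Re-filtering synthetic cohorts.** The rendered output represents
*already-preprocessed* data: DC-free, band-limited around the carrier, and
average-referenced. Temporal filtering of a rendered cohort smears noise
across the carrier's zero-crossings, where the signal vanishes — label
assignments there become arbitrary and apparent durations collapse. Analyses
of synthetic cohorts therefore run with `band = NULL`; the filter stage is
validated separately by frequency-response tests (DC rejection, passband
flatness within 5%, stopband attenuation of at least 20 dB, notch depth and
neighborhood preservation). For raw recordings `pipeline_config()` keeps the
1–40 Hz default.

## Numerical choices

* Filters: linear-phase FIR (Kaiser window, 60 dB stopband per pass) applied
  forward–backward via FFT convolution of the squared-magnitude kernel, with
  odd reflection padding — zero phase distortion, since phase shifts would
  corrupt topographic timing. The notch is a biquad (Q = 30) run through
  `signal::filtfilt`. Downsampling low-passes at 80% of the target Nyquist
  and decimates; the artifact mask is OR-reduced over each decimation
  window.
* All randomized routines take explicit seeds and restore the caller's RNG
  state; reruns with one configuration are bit-identical.
* Ties everywhere break toward the lowest index; plateau maxima take their
  first sample.
* `spatial_correlation` raises an error on zero-variance maps rather than
  returning `NaN`; backfitting treats all-zero *samples* (not maps) as
  correlation zero so that every unmasked sample receives a label.

## Validation problem sizes

The test-suite checks run at desk scale, chosen once: recovery uses 20
cohorts of 6 subjects (2 epochs × 20 s per condition, 32 channels, K = 4) —
group-template recovery above 0.95 mean $|$corr$|$ (observed ≈ 0.999),
duration recovery within 15% (observed ≈ 5%), coverage within 0.03
(observed ≈ 0.015), cluster-count selection at 4 in at least 80% of cohorts.
Directional end-to-end validation uses 50 cohorts of 24 subjects (1 epoch ×
30 s per condition) and requires all four effect signs (fear: C down, D up;
trait: positive with C, negative with D) in at least 90% of cohorts.
Split-half consistency is demonstrated on 20 subjects with 3 × 45 s epochs,
where all class × parameter reliabilities exceed 0.7. TANOVA calibration
uses exact enumeration at n = 5 and 500 null datasets at 199 permutations
(the add-one estimator is exactly 0.05-calibrated there). Restart counts are
scaled to the task (50 by default; 10–30 in large simulation loops, where
the calibrated signal-to-noise makes the optimum easy to find and the
exhaustive-oracle block separately verifies optimum attainment).

## Known limitations

* The CV criterion's behavior on noise-only data (above) means cluster-count
  selection should be reported together with the GEV curve, never consumed
  blindly.
* Per-sample winner-takes-all labeling without temporal smoothing is noisy
  at GFP troughs on broadband data; duration estimates from real recordings
  are systematically shorter than template-level structure suggests. The
  censoring rules remove edge bias but not trough fragmentation.
* TANOVA tests grand-average topographic differences; it has no power
  against effects that average out across subjects.
* The EDF reader/writer covers continuous 16-bit single-record files only —
  enough for interchange and round-trip tests, not for annotated clinical
  recordings.
* Gender-nested ANOVA and mixed models with random intercepts are outside
  the scope of this package's statistics module.
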