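---
title: "Linking oscillatory power and phase to representational geometries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking oscillatory power and phase to representational geometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscirsa)
```

## The analysis in one paragraph

Large-scale oscillatory brain signals (MEG) and local activation patterns
(fMRI regions such as V1 and IT) can be compared on a common footing by
representational similarity analysis (RSA): each measurement is reduced to a
representational dissimilarity matrix (RDM) over the same stimulus
conditions, and geometries are compared by correlating vectorized RDMs.
`oscirsa` implements this program for time-frequency (TF) decomposed
multichannel recordings: at every TF coordinate it builds one RDM from
oscillatory *power* patterns and one from oscillatory *phase* patterns,
relates each to two reference RDMs by partial correlation (isolating the
unique match to each reference), tests the subject-wise maps against zero
with FDR control, clusters the full stack of RDMs to find co-varying
oscillatory components, and positions each cluster on two complementary
scales: a cortical-level score between the low- and high-level reference
geometries, and a complexity score from a layered feature hierarchy.

Because real recordings of this kind are not redistributable, the package
ships a synthetic-data generator with *planted*, analytically known
structure, so that every stage has a ground-truth recovery test.

## Time-frequency features

The TF transform follows the multitaper convention: at frequency $f$ the
sliding window spans `window_cycles`$/f$ seconds (default 2 cycles) and the
spectral half-bandwidth is `smoothing`$\times f$ (default 0.4). The
time-bandwidth product is therefore constant over frequency,
$2TW - 1 = 2\cdot 2\cdot 0.4 - 1 = 0.6 < 1$, so the taper count rule
$K = \max(1, \lfloor 2TW - 1\rfloor)$ yields a single Slepian taper at every
frequency; the rule only engages extra tapers for longer windows. Two
conventions had to be fixed where the verbal description is ambiguous:

* *Smoothing denotes the half-bandwidth.* "0.4 × frequency" could denote
  half- or full bandwidth; we take it as the half-bandwidth $W$. Under the
  default parameters the choice does not change the taper count (both give
  $K = 1$), only the concentration of the single taper.
* *Phase is referenced to absolute time zero.* The window at $(f, t)$ is
  demodulated with $e^{-2\pi i f t_n}$ over absolute sample times, so a
  planted $\cos(2\pi f t + \phi)$ yields measured phase $\phi$ regardless of
  the window center.

The default grid has 50 log-spaced frequencies from 3 to 100 Hz and 66 time
points from $-0.6$ to $0.7$ s in 20 ms steps. Coordinates whose window
overruns the epoch are *masked*, never zero-padded: padding invents data and
biases onset latencies. Masks propagate through patterns, RDM stack, RSA
maps, and clustering.

Power patterns convert each trial to decibels, $10\log_{10}(|c|^2 +
\varepsilon)$ with floor $\varepsilon = 10^{-20}$ (squared-amplitude units,
configurable), *before* averaging across trials — the order matters and is
tested. Phase patterns normalize each trial coefficient to unit length,
average across trials, renormalize the resultant, and concatenate real and
imaginary parts over sensors (612 features for 306 sensors). Exactly zero
coefficients are excluded from the resultant rather than propagating NaN;
an all-zero resultant marks the coordinate degenerate.

## RDMs and their comparison

An RDM entry is $1 - $ Pearson correlation between two condition pattern
vectors; entries live in $[0, 2]$, the matrix is symmetric with zero
diagonal. Vectorization takes the strictly-lower-triangle entries in
row-major order (4186 values for 92 conditions); every module and the text
serialization share this order. Pearson is a normalization-free ratio, so
RDMs are invariant to per-condition affine rescaling of patterns — the
property that makes decibel offsets and global gains harmless.

## Partial-correlation RSA and group statistics

The two reference RDMs are themselves correlated (the generator's default
coupling is $r \approx 0.3$), so plain correlations would credit shared
geometry to both references. At each coordinate we therefore compute the
partial correlation of the TF RDM with each reference controlling the
other. Group inference is a per-coordinate one-sample $t$ test of the
subject-wise partial correlations against zero on the raw $r$ scale (a
Fisher-z option exists but is off by default, for fidelity to the original
procedure), two-sided, with Benjamini–Hochberg FDR at $\alpha = 0.05$
applied *per map* (per signal kind × reference target), not pooled across
the 2×2 family; pooling is a one-liner for users who want it. Latency
interpretation uses a corrected time axis $t + (``window\_cycles''/f)/2$,
since the window smears responses by half its duration; band profiles
(e.g. alpha 8–13 Hz) average map rows inside a closed frequency interval
and report the mean correction of the contributing frequencies.

## Clustering the RDM stack

All power and phase RDM vectors (for a full grid, $46 \times 66 \times 2 =
6072$ points in 4186 dimensions) enter a correlation-distance k-means:
vectors are row-centered and unit-normalized, assignment minimizes
$1 - $ Pearson, centroids are renormalized means, empty clusters are
re-seeded from the farthest point, and the best of 5 random restarts by
residual sum of distances (RSS) is kept, deterministically per seed. In the
multi-subject pipeline the stack entering the clustering is the
subject-averaged RDM stack.

**Model selection.** The elbow criterion is defined through the discrete
second derivative $d_2(k) = \mathrm{RSS}(k{+}1) - 2\,\mathrm{RSS}(k) +
\mathrm{RSS}(k{-}1)$ on the centered grid $k = 2..K{-}1$. For an RSS curve
with a kink at the true family count $k_0$ (steep decline before, marginal
gains after), $d_2$ peaks exactly *at* $k_0$ — and on smooth convex curves
small-$k$ diminishing returns create a secondary early local maximum. The
package therefore selects the *global* positive curvature maximum and
returns that $k$ (`rule = "at"`, the point at which adding another cluster
first yields only a marginal gain). The literal alternative reading "the
point just before the maximum" (`rule = "before"`, $k_m - 1$) is kept
behind a flag; on planted 7-family stacks only the default rule recovers 7
as the modal choice over seeds. A curve without positive curvature (e.g.
exactly linear) raises an explicit "no elbow" error rather than guessing.

Clusters are summarized by distance-to-centroid TF maps per signal kind and
ranked by ascending mean member-to-centroid distance (tightest, most
stereotyped cluster first).

## Level and complexity scores

For each centroid, partial correlations $R_{low}$ and $R_{high}$ against
the two references are combined into the cortical-level scale

$$L = \sigma\!\left(\frac{R_{high} - R_{low}}{R_{high} + R_{low}}\right),$$

with $\sigma$ the logistic sigmoid. Two caveats are implemented literally
rather than patched: (1) for non-negative inputs the ratio lies in
$[-1, 1]$, so the attainable range is $[\sigma(-1), \sigma(1)] \approx
[0.269, 0.731]$, not the nominal $(0, 1)$ — 0.5 still means "equally
similar to both"; (2) when $R_{high} + R_{low} \le 0$ the scale is
undefined and the package raises an error (reported as `NA` with a warning
in batch scoring) instead of clamping.

Significance uses a surrogate test: the centroid vector's entries are
shuffled uniformly (`scheme = "entries"`, the literal reading), the partial
correlation recomputed, and the one-sided add-one-corrected p value
reported, $p = (\#\{r_{surr} \ge r_{obs}\} + 1)/(n_{iter} + 1)$ with
$n_{iter} = 10^5$ by default. A label-permutation scheme (permuting
condition rows/columns jointly, which preserves RDM structure and is
statistically stricter) is available behind a flag.

The complexity score compares a centroid (Spearman) with the RDM of every
layer of one or more layered feature hierarchies after *centering*:
subtracting, per layer, the mean feature vector of an independent image
set. Centering matters because feature spaces trained on a different image
distribution place the analysis images in a remote corner: pairwise
correlation distances are then dominated by the common offset and compress
toward zero (the package's `centroid_origin_distance()` diagnoses this).
The best-matching layer index is normalized as
$(\mathrm{argmax} - 1)/(n_{layers} - 1)$, so the endpoints hit exactly 0
and 1; ties resolve to the smallest layer. Scores are averaged across
hierarchies (the default emulation uses seven hierarchies of depths 5, 13,
12, 16, 17, 14, 8).

## What the generator emulates — and what it does not

`generator_spec()` defaults mirror the emulated study: 92 conditions, 306
sensors, 20 trials per condition, 500 Hz sampling over $[-0.6, 1.2)$ s, 1/f
background noise. Planted components are condition-coded sinusoids:

* **Power coding**: per-sensor amplitudes are log-linear in a
  correlation-preserving sensor embedding of a latent condition geometry
  (default gain: 6 dB standard deviation across sensors — a strong but
  plausible narrowband modulation), with the oscillation phase drawn
  uniformly per condition × trial and *shared across sensors*, as for a
  coherent source. Phase patterns therefore carry no condition information,
  making the power/phase dissociation testable.
* **Phase coding**: per-sensor phase offsets are linear in the embedded
  geometry (default spread 1.2 rad, within $(-\pi, \pi]$) at fixed unit
  amplitude, so power patterns carry no condition information.

The embedding preserves pairwise Pearson structure exactly, so the planted
RDM equals the latent geometry's RDM and noiseless recovery through the dB
power path is exact to machine precision. Phase recovery is bounded by the
negative-frequency leakage of a real-valued carrier, of relative size
$|H(2f)|/|H(0)|\sim 10^{-2}$ for 2-cycle windows: measured phases deviate
by $\sim 0.01$ rad, so phase-RDM recovery is asserted at 0.05 in entries
(RDM correlation > 0.999), not at machine precision. For power coding the
leakage factor is shared across sensors within a condition and cancels in
the RDM.

Reference RDM pairs are built from two latent pattern matrices sharing a
common component with mixing weight $w$; the expected correlation between
the vectorized RDMs is $w^2$, so $w = \sqrt{0.3}$ yields the documented
coupling (measured mean over 50 seeds at 92 conditions: $\approx 0.29$,
seed-to-seed SD $\approx 0.02$). Multi-subject studies redraw noise with
subject-specific seeds and jitter the shared component geometry (default
relative SD 0.2), giving the between-subject variability that paired group
statistics require. Layered feature sets interpolate *linearly in the RDM*
from the low to the high geometry across layers (an exact property of the
correlation-preserving embedding), carry a planted mean offset (default 5
feature-SD units) so that centering matters, and draw the centering set
from the same distribution over fresh latent images (default 4 per
analysis image, i.e. 368 for 92).

Not emulated: head geometry and forward models, sensor noise covariance,
session effects within the trial count, eye/muscle artifacts, and any
actual network inference — feature matrices are consumed as input. Passing
recovery tests on this generator demonstrates that the *pipeline* is
correct and sensitive under its stated assumptions; it does not certify
effect sizes or latencies in real recordings.

## Numerical choices

* Pearson computations use the sample-normalized ratio (normalization
  cancels), with results clamped to the mathematically valid range.
* RDM symmetry is enforced by averaging with the transpose; entries are
  clipped to $[0, 2]$ against rounding.
* The dB floor is $10^{-20}$ in squared-amplitude units; silent channels
  floor at $-200$ dB instead of $-\infty$.
* k-means ties in assignment resolve to the first (lowest-index) centroid;
  elbow ties to the smallest $k$; argmax ties to the smallest layer.
* All serialized floating point uses 17 significant digits, so text
  round-trips are exact; binary epoch arrays round-trip bit-identically.
* Every random draw flows from an explicit seed through a deterministic
  stream-splitting helper; no function disturbs the session RNG.

## Problem sizes in the test suite

The shipped tests exercise the full pipeline at reduced scale, chosen to
keep the suite fast while leaving every planted effect comfortably
detectable: recordings of 8–24 conditions, 6–32 sensors, 4–12 trials at
250 Hz; grids of 4–12 frequencies and 5–20 time points; 5–10 subjects;
family-recovery runs with 7 × 15 RDM vectors over 20 seeds; null
calibration over 50 seeds; surrogate calibration with 200 repeats of 400
iterations. Structural checks (4186-dimensional vectors, 612-dimensional
phase patterns, 66 time points, 6072 stack rows, 368 centering images) run
at the full default dimensions, which are cheap in isolation.

## Known limitations

* The elbow criterion needs a genuine kink; on featureless convex RSS
  curves it errors rather than returning an arbitrary $k$.
* The level scale is undefined when both partial correlations are
  non-positive; such clusters (typically noise clusters) are reported with
  `NA` level.
* Band profiles apply one mean latency correction per band; frequencies
  within a band differ in their individual corrections by up to the band's
  window-duration spread.
* The full grid clusters whatever unmasked coordinates it is given; if a
  published analysis used a reduced frequency set (e.g. 46 of 50), that
  reduction must be expressed through the grid configuration — the package
  does not guess a reduction rule.
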