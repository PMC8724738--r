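---
title: "Counting molecules in single RNA-protein complexes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules in single RNA-protein complexes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smstoich)
```

# Overview

`smstoich` infers the number of protein molecules bound to individual
surface-immobilized RNA molecules from sequential multi-colour TIRF
movies. The pipeline is: composite-image spot detection, sub-pixel
Gaussian localization, chromatic registration, cross-channel
colocalization, background-corrected trace extraction, Bayesian
photobleaching step counting, and conversion of step-count histograms
into stoichiometry estimates under a labelled-fraction/dimerization
model. A companion module scores positional enrichment of eCLIP
read-pair 3′ termini along short reference RNAs. Every stage can be
exercised against synthetic data with known ground truth; this vignette
records the models, the tunable parameters, and the design decisions
taken where the procedure left genuine freedom.

# Spot detection

## Composite images

Each channel's frames are reduced to two composite images: the per-pixel
mean and the per-pixel maximum. The mean composite has the best
signal-to-noise for molecules that survive a substantial part of the
acquisition; the max composite recovers molecules that bleach early
(their mean-image contrast decays as bleach-time/frames, but their peak
frame is preserved).

Both composites are scaled to [0, 1] **by division with the image
maximum** (recorded, so normalized amplitudes can be mapped back to
camera counts). We deliberately do not subtract the image minimum: the
global minimum is an extreme-value statistic of the noise, and
subtracting it pins the background arbitrarily close to zero. That has
two bad consequences: the max/mean detection ratio (below) then fires on
pure noise, and the baseline windows of the fit validity rules lose
their meaning. With division-only scaling the ratio criterion is
identical on normalized and raw counts (it is scale-invariant), and the
fitted baseline *B* is interpretable as the background fraction of the
peak — consistent with the channel windows of 0.4 (Cy5) and 0.53
(mEGFP).

## Candidate criterion

A 19 × 19 px window is a candidate region when its maximum pixel is at
least 1.119 × its mean pixel intensity, evaluated on either composite
(detection on both composites makes the total fluorophore yield
unimportant; a molecule needs only one bright stretch). Operationally,
candidates are seeded at strict 8-neighbour local maxima that are
themselves the peak satisfying the criterion of their own centred
window; this avoids seeding on noise pixels that merely share a window
with a bright spot. The box is then shrunk by 2 px per step, staying
centred on its seeding peak, until exactly one *intensity peak* remains
inside; a peak counts only if it satisfies the same max/mean ratio
within the current box, so strict-inequality noise wiggles at background
level do not block termination. Boxes that would shrink below 9 × 9 px
are rejected; surviving candidates closer than 4 px are merged, keeping
the brighter peak (double counting would corrupt colocalization
percentages). Shrinking stays centred on the seeding peak rather than
re-centring on the brightest pixel of the current box: re-centring drags
the candidate of the dimmer member of a close pair onto its brighter
neighbour and halves recall on paired spots.

The max composite is smoothed with a 3 × 3 mean filter before peak
analysis. A per-pixel maximum over hundreds of frames is an order
statistic with a long upper tail; without smoothing its speckle produces
spurious local maxima at background level.

## Localization and validity

The marginal intensity profiles through the peak (the box row and the
box column, mean composite) are each fitted with
\(G(x) = B + A\,e^{-(x-\mu)^2/2\sigma^2}\), *x* measured from the box
centre, by Levenberg–Marquardt least squares from three starts (the raw
interface `minpack.lm::nls.lm` is used because constructing an `nls`
object fails on exactly symmetric zero-residual profiles). The
amplitude is a free parameter by default; a config switch pins it to the
fixed-amplitude parameterization \(1/2\pi\) for compatibility with the
historical form of the fit. A fit is valid when both dimensions satisfy
the channel's σ and B windows and \(|\mu| < \text{box} - 2.5\). The µ
bound is implemented literally against the final box size, and the
bound, windows and ratio are all exposed as arguments. Non-convergent
fits return an invalid record with a reason code, never an error. The
561 nm (mCherry) channel uses the mEGFP windows by default, its own
windows being unspecified.

# Chromatic registration

The apparent position of a spot depends on wavelength. The correction
model assumes the divergence of a source channel from the 633 nm
reference grows linearly with distance from a centre of zero divergence:
per dimension

\[ x_t = x + \frac{x - x_c}{SF_x}. \]

The flattened typography of this formula admits either a multiplicative
or divisive role for the scaling factor; we read it as the fraction
shown. The choice is observationally neutral because the calibration
fit absorbs the parameterization — only the sign/magnitude conventions
of the reported \(SF\) differ. Calibration from dual-labelled emitter
pairs is linear least squares per dimension (residual
\(x + a x - b - x_\mathrm{ref}\) with \(a = 1/SF\), \(b = x_c/SF\));
degenerate geometries error, and an exactly-zero divergence gradient is
represented by a very large \(SF\) (no correction). Each source channel
carries its own transform; 561 nm is never corrected with the 488 nm
calibration.

# Colocalization

Two spots of different wavelengths are colocalized when their corrected
separation is ≤ 2 px. Matching is greedy one-to-one in increasing
separation, with ties broken by peak intensity then index: the matching
discipline is not dictated by the procedure itself, and one-to-one
matching prevents a single bright spot from inflating counts. Three-way
complexes are the intersection of the two pairwise matchings on the RNA
spot id. The random-background colocalization probability is estimated
per image by translating the other channel's spot list by ±10 px
(toroidal wrap) and averaging the resulting colocalization rates;
translation controls are robust to non-uniform spot density, and the
analytic expectation \(1 - e^{-\rho \pi r^2}\) is retained as a
cross-check in the tests. Background is reported but never subtracted.

# Step counting

## Trace extraction

For each colocalized spot the per-frame intensity is the mean of the
3 × 3 box centred on the spot's nearest pixel minus the mean of the ring
of pixels at **Chebyshev distance exactly 5** (the ring reading of
"pixels five pixels away"; it is config-exposed). Spots closer than
5 px to an image edge are marked edge-clipped and excluded.

## Bayesian change-point detection

Traces are piecewise-constant signals in Gaussian noise of unknown
variance. For a (sub-)trace of length *N*, the marginal posterior of a
single mean shift at position *m* (flat priors on the two means,
Jeffreys prior on the noise variance, variance integrated out) is

\[ p(m \mid D) \propto [m(N-m)]^{-1/2}\, \mathrm{RSS}(m)^{-(N-2)/2}, \]

and the no-change model has evidence
\(\propto N^{-1/2} \mathrm{RSS}_0^{-(N-1)/2}\). The detector accepts
the most probable position when the log posterior odds of the one-change
model (evidence averaged over positions) exceed a threshold, then
recurses on the left and right sub-traces. The numeric threshold of the
original analysis is not recoverable; the default is 8 on the log-odds
scale with a minimum segment of 3 frames, both exposed. Because the
flat mean priors leave a residual scale dependence in the odds, the
trace is standardized internally before detection, which makes the
output *exactly* invariant to affine intensity rescaling.

Binary segmentation fixes each boundary before later splits exist, which
can leave change points a frame or two off the joint optimum; a
coordinate-descent refinement pass re-optimizes each boundary by exact
RSS with its neighbours fixed. With refinement the recursive result's
RSS is within 5% of the exhaustive two-change optimum in ≥ 95% of
simulated 60-frame traces.

## Plateau counting and re-activation

Plateau levels are segment means. Transitions smaller in magnitude than
the within-plateau noise SD are treated as plateau-estimation jitter in
both directions. An upward transition larger than the noise SD is a
re-activation event: its gained intensity is discounted, i.e. the
matching later downward step is not counted. The fluorophore count is
the number of counted downward steps; classes are 1–5, ">5", or "X" when
no consistent assignment exists (no counted step, or a first plateau
already at the final background level — a pre-bleached molecule). The
photon count is the summed corrected intensity from the first frame to
the final change point. By-eye verification of change points is
replaced by an automated review queue (near-threshold odds,
re-activations, class "X"); the pipeline proceeds unaided.

## Photon-count validation

If step classes are assigned correctly, complexes assigned two molecules
should emit about twice the photons of those assigned one.
Pseudo-double complexes are formed by adding the one-molecule photon
counts to a seeded fixed-point-free permutation of themselves; the
two-molecule class is compared to singles and to pseudo-doubles by
two-tailed Mann–Whitney tests. One caveat the synthetic studies expose:
conditioning on the *assigned* class selects against two-molecule
complexes whose fluorophores bleach nearly simultaneously (their steps
merge), and since merging is more likely when both bleach early, the
surviving two-step photon sums are biased up by a few percent. At
per-experiment sample sizes (tens of complexes) the rank test is
appropriately insensitive to this; very large samples can detect it.

# Stoichiometry inference

## The label/dimerization model

A site occupied by one protein *unit* shows 0, 1 or 2 bleaching steps:
the unit is an intrinsic dimer with probability *d* (else a monomer),
and each protein copy carries a fluorescent tag independently with
probability *f*:

\[ P(0) = (1-d)(1-f) + d(1-f)^2,\quad
   P(1) = (1-d)f + 2df(1-f),\quad
   P(2) = df^2. \]

For *n* units the observed class is the convolution of *n* unit
distributions, conditioned on at least one visible label (spots with
zero labelled copies are recorded as not colocalized). These
distributions are verified exactly against exhaustive enumeration over
all unit/label configurations.

*f* comes from quantitative Western blotting (e.g. tagged:endogenous
90:10 → f = 0.9). *d* is estimated from molecules recorded without
added RNA: the expected two-step:one-step ratio is
\(R = df/((1-d) + 2d(1-f))\), inverted as \(\hat d = R/(f + R(2f-1))\),
with a profile-binomial-likelihood confidence interval. For counts of
32 two-step vs 129 one-step molecules at f = 0.9 this gives
\(\hat d \approx 0.226\).

## Occupancy mixture

An observed histogram over classes 1–4 is modelled as
\(E_k = S[(1-\pi_2) q_1(k) + \pi_2 q_2(k)]\), with \(q_n\) the
unconditional class probabilities above, \(\pi_2\) the fraction of
occupied sites carrying two molecules, and *S* the effective accessible
total (occupancy × accessible molecules, including invisible zero-label
sites). Both parameters are free; χ² is minimized by bounded
multistart optimization from \(\pi_2 \in \{0, 0.5, 1\}\), ties resolved
toward the smaller \(\pi_2\). The *reported* χ² follows the convention
of including only classes with expected counts ≥ 5, but the objective is
minimized over all modelled classes (with a small floor) to keep it
continuous in the parameters. Classes ">5" and "X" are excluded from
the mixture — they are attributed to the distinct super-stoichiometric
background population. Dark or misfolded fluorophores are assumed
absent by default (the conservative choice: assuming a dark fraction
inflates inferred occupancy); an optional dark-fraction multiplier on
*f* supports sensitivity analysis.

## Background models

The background population is fitted with zero-truncated Poisson or
geometric distributions over classes 1–5 plus the aggregated ≥ 6 tail,
by χ² minimization. Significance uses categories with expected counts
≥ 4 and, as printed in the source convention, N − 2 (Poisson) or N − 3
(geometric) degrees of freedom. Both families have one parameter, so
the standard convention would be N − 2 in both cases; the printed
convention is kept for reported p-values and a `dfOffset` override is
provided (the acceptance tests verify p-value uniformity under the
standard convention and acceptance behaviour under the printed one).

The robustness of a protein histogram to diffraction-limited spots
containing two RNA molecules is checked by excluding complexes whose RNA
bleached in ≥ 2 steps and comparing retained vs excluded class
distributions by a χ² contingency test.

# The eCLIP positional statistic

Inputs are per-position read-pair coverage and fragment 3′-terminus
counts on a short reference RNA (1-based), per experiment, with a
size-matched control; BED read-pair spans (0-based half-open) are
converted internally, counting fragment 3′ ends on the reference strand.
Counts are normalized to percentages of all aligned pairs; enrichment is
the signal percentage over the control percentage with a one-read-pair
pseudocount on each percentage scale (logs must stay finite; the
original pipeline is silent on zeros). The statistic

\[ v_i = \log(\text{terminus pct}_i + \epsilon) - \log(\text{enr}_i) \]

isolates terminus excess beyond coverage enrichment. Per cell, the
normal cumulative probabilities of \(v\) under the position-wise
(across experiments) and experiment-wise (across positions)
distributions are multiplied and square-rooted; a zero SD makes that
factor 0.5 (with a warning). Larger terminus excess gives larger Φ —
the "enriched" tail is the upper tail; the orientation can be flipped by
negating `v` if a run needs the opposite convention. Per-protein scores
collapse experiments by the geometric mean (power 1/2 for 2 experiments,
1/4 for 4), which is monotone in each experiment and idempotent.

# The synthetic-data module

The generator provides ground truth for every stage. Movies: emitters
are isotropic 2D Gaussians (σ = 1.3 px by default; pixel size and PSF
width are not dictated by the procedure, so these are implementer
choices exposed in the config) rendered into a sequential channel plan
(defaults 633 nm × 50, 561 nm × 250, 488 nm × 250 frames at 20 s⁻¹),
each fluorophore bleaching after an exponential lifetime (default mean
50 frames), with Poisson shot noise on signal + baseline and Gaussian
read noise. Study conditions were fixed once: baseline 120
counts/frame, amplitude 300 counts/frame/fluorophore (per-frame peak
SNR ≈ 13), read noise 10; SNR-10 benchmarks use amplitude 280. Emitter
positions, when not supplied, are drawn with an 8 px hard-core minimum
separation, emulating surface immobilization at proper dilution;
sub-diffraction doubles are exercised separately (supplied positions,
and the RNA-dimer exclusion check) rather than in the detection
benchmark, which measures detection, not optical resolution.
Non-reference-channel emitters are rendered at the position whose
chromatic correction maps back onto the reference-frame truth. Every
simulator takes a mandatory seed and is a pure function of
(configuration, seed).

Trace simulation bypasses imaging: per-fluorophore unit steps plus
Gaussian noise, with bleach lifetimes doubly truncated to
[5, frames − 5] so each ground-truth fluorophore has a measurable
initial plateau and bleaches within the trace (acquisitions run until
complete bleaching; molecules bleaching before a level could be measured
are the pipeline's "X" class and are not ground truth for recovery).

eCLIP simulation: control counts are Poisson around a smooth unimodal
coverage profile; a spiked position multiplies the coverage *and the
per-pair 3′-terminus rate* by the fold (terminus counts therefore scale
with the fold squared). This is the reading under which a spike is
detectable at all: if terminus counts were multiplied by the same fold
as coverage, the fold would cancel exactly in
\(v = \log(\text{term}) - \log(\text{enr})\).

What the generator does **not** emulate: camera gain and EM excess
noise, stage drift (the class of instrument modelled has nanometre-scale
feedback), astigmatic/3D PSFs, fluorophore blinking by default (the
mEGFP dark-state dwell of 1–2 s is short relative to acquisitions; an
optional dark-state stress test can be layered on the trace generator),
non-exponential photobleaching kinetics, and non-specific surface
binding. Passing tests therefore certify the analysis chain against
this generative model, not the full physics of any particular
microscope.

# Problem sizes and numerical choices

The test-suite and acceptance benchmarks use: 100-emitter fields of
320 × 320 px at 50 frames for detection; 50 bead pairs at 0.1 px
localization noise for registration; 500 traces per fluorophore count
N ∈ {1, 2, 3} at 250 frames and SNR 5 for step recovery; 150 colocalized
spots per replicate (200 replicates) for occupancy-mixture recovery; 500
molecules per replicate for background model selection; 164 nt
references (the U1 snRNA length) with 4 experiments for the eCLIP
statistic; and two 256 × 256 fields of 60 complexes with label fractions
0.58/0.57 for the three-colour end-to-end run. These sizes were chosen
as the smallest at which the binomial/Monte-Carlo error of each measured
quantity is comfortably below the margin being asserted.

Numerical details worth knowing: composite normalization records its
scale factor and flags flat images; RSS computations floor at machine
precision so noiseless traces recurse correctly; the occupancy χ² floor
is 10⁻⁹; the derangement for pseudo-doubles resamples until
fixed-point-free; all derived seeds stay below 2³¹.

# Known limitations

- Two fluorophores bleaching within about two frames of each other merge
  into one detected step; without per-fluorophore brightness calibration
  (an explicit non-goal) this bounds exact-N recovery at roughly the
  Laplace tail probability of near-simultaneous bleaching.
- The detection benchmark's recall target presumes resolvable emitters;
  fields dominated by sub-diffraction pairs will show lower recall by
  construction.
- The χ² mixture fit reports no significance (the free scale and mixture
  fraction invalidate the nominal dof), matching the source convention.
- The eCLIP statistic is specialized to short references; it is not a
  peak caller and does not model transcriptome-wide background.
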