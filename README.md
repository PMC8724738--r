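# smstoich

Single-molecule photobleaching stoichiometry for multi-colour TIRF data.

## The problem

How many copies of a protein sit on one RNA molecule? Single-molecule
total-internal-reflection fluorescence (TIRF) microscopy answers this by
immobilizing RNA–protein complexes on a coverslip, locating each
Cy5-labelled RNA as a diffraction-limited spot, asking which RNA spots
carry a fluorescent protein (mEGFP or mCherry fusion) in another spectral
channel, and then counting the discrete bleaching steps of that protein's
fluorescence: each irreversible intensity drop is one fluorophore, so the
step count estimates the number of protein molecules in the complex.

Raw step counts under-count molecules (only a fraction *f* of the protein
pool carries the tag, measured by quantitative Western blotting) and
over-count them (a fraction *d* of free protein units are intrinsic
homodimers, estimated from two-step bleaching in the absence of added
RNA). `smstoich` implements the full chain from movie to corrected
stoichiometry, plus a positional eCLIP enrichment statistic for mapping
protein cross-link sites along short reference RNAs such as U1 snRNA.

## What the package computes

- **detect** — per-channel mean/max composite images; spot candidates by
  the box criterion (window max ≥ 1.119 × window mean on a 19 px box,
  shrunk until one intensity peak remains, rejected below 9 px);
  sub-pixel localization by per-dimension 1D Gaussian fits
  `G(x) = B + A exp(−(x−µ)²/2σ²)` with channel-specific validity windows
  (Cy5: 0.9 ≤ σ ≤ 3.5, 0 ≤ B ≤ 0.4; mEGFP: 0.3 ≤ σ ≤ 4.7, 0 ≤ B ≤ 0.53;
  |µ| < box − 2.5).
- **register** — linear chromatic correction per dimension,
  `x_t = x + (x − x_c)/SF_x`, calibrated by least squares from
  dual-labelled emitters.
- **coloc** — greedy one-to-one matching of corrected spots at ≤ 2 px
  separation; three-way intersection; translation-control estimate of the
  random-background colocalization probability.
- **steps** — background-corrected traces (3×3 centre box minus the ring
  of pixels 5 px away); recursive Bayesian change-point detection
  (posterior over a single mean shift ∝ [m(N−m)]^(−1/2) RSS(m)^(−(N−2)/2),
  noise variance integrated out; recursion while the log posterior odds
  exceed a threshold); plateau counting with re-activation discounting;
  photon-count validation via pseudo-double complexes and two-tailed
  Mann–Whitney tests.
- **stoich** — binomial error bars; expected step distributions under the
  label-fraction/dimerization model (per unit: P(0) = (1−d)(1−f) + d(1−f)²,
  P(1) = (1−d)f + 2df(1−f), P(2) = df², convolved and conditioned on
  visibility); dimer fraction from free-protein 2:1 step ratios; χ²
  mixture estimation of the one- vs two-molecule occupancy fraction;
  zero-truncated Poisson/geometric background fits.
- **eclip** — per-position percent normalization, size-matched-control
  enrichment, the 3′-terminus statistic
  `v = log(terminus% + ε) − log(enrichment)`, position-wise ×
  experiment-wise normal probabilities combined as √(Φ_pos·Φ_exp), and
  geometric-mean collapse across experiments.
- **simulate** — synthetic movies (Gaussian PSF emitters, exponential
  bleaching, Poisson + Gaussian noise, chromatic distortion), traces,
  step-count histograms and eCLIP count tables, all with ground truth and
  mandatory seeds.

## Worked example

```r
library(smstoich)

cfg <- simConfig(seed = 11, dim = c(256L, 256L),
                 plan = channelPlan(c("cy5", "gfp"), c(633, 488),
                                    c(30L, 150L)))
complexes <- data.frame(cy5 = rep(1L, 40), gfp = rep(1L, 40))
sim <- simulateMovie(cfg, complexes)

rna  <- detectSpots(sim$stack, "cy5")
prot <- detectSpots(sim$stack, "gfp")
cc <- colocalize(rna, prot, maxSep = 2)

results <- lapply(seq_len(nrow(cc$complexes)), function(k) {
  i <- cc$complexes$otherId[k]
  tr <- extractTrace(sim$stack, prot$x[i], prot$y[i], "gfp")
  analyseTrace(tr$values)
})
buildStepHistogram(results, totalRna = cc$nRef, condition = "demo")
#> StepHistogram 'demo': 40 RNA spots, 40 colocalized (100.0%)
#>  1  2  3  4  5 >5  X
#> 38  0  0  0  0  0  2
```

Every simulated RNA carried exactly one labelled protein; 38 of the 40
colocalized complexes bleach in a single step and two fall into the
undetermined class "X" (fluorophores that bleached before a stable initial
level was recorded). Correcting observed 2:1 step ratios for tagging and
dimerization:

```r
estimateDimerFraction(129, 32, f = 0.9)$d
#> [1] 0.2258292
```

i.e. free-protein counts of 32 two-step vs 129 one-step molecules at 90%
tagging imply that ~22.6% of free protein units are dimers.

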