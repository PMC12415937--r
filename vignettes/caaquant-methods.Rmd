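---
title: "Quantifying vascular amyloid-beta: image-processing rules and hierarchical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular amyloid-beta: image-processing rules and hierarchical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caaquant)
```

## The measurement problem

In cerebral amyloid angiopathy (CAA), amyloid-beta accumulates in the
walls of cerebral arterioles, along the intramural periarterial drainage
(IPAD) routes that normally clear it. Experiments that probe this process
inject fluorescent amyloid into mouse hippocampus and image the tissue
with three-channel confocal microscopy: Collagen IV marks the basement
membrane of *all* vessels, alpha-smooth-muscle actin (SMA) marks the
smooth-muscle coat that only arterioles possess, and a third channel
carries the labelled amyloid. Two quantities are measured per animal:

* **coverage** — the percentage of each vessel's wall area occupied by
  amyloid fluorescence, a proportion with a large point mass at exactly
  zero (many vessels carry no amyloid at all); and
* **aggregate size** — the pixel area of each detected amyloid deposit,
  classified as *intramural* (inside an arteriole wall) or *extramural*
  (in the surrounding tissue), a nonnegative, strongly right-skewed
  variable.

`caaquant` implements the full chain from calibrated image stacks to
group-level inference, together with a synthetic-data generator that
makes every stage testable against known ground truth.

## Vessel classification

Analysis operates on maximum z-projections of the calibrated stacks
(1024 x 1024 px covering 581.25 um x 581.25 um, i.e. 0.5676 um/pixel;
the package recomputes this with `compute_calibration()`).

An **arteriole wall** is an SMA connected component that

1. forms a *complete ring*: filling the component's holes adds at least
   `min_lumen_px` (default 1) enclosed pixels — the unstained lumen;
2. is *co-positive* for Collagen IV: at least `copositivity_fraction`
   (default 0.5) of its pixels fall on the Collagen IV mask; and
3. has a wall area (lumen excluded) of at least
   `min_arteriole_area_px = 150` px, about 48.3 um^2 — the rasterised
   wall area implied by the anatomical minimum arteriole diameter of
   10 um.

Components touching the image border cannot enclose a hole on the open
side and are therefore never classified as rings; this is deliberate,
since a truncated vessel's wall area would be unreliable anyway. The
co-positivity fraction of 0.5 makes the rule robust to a pixel of
registration jitter between channels while still demanding genuine
double staining.

**Capillaries** are what remains of the comprehensive Collagen IV mask
after the detected arteriole walls, dilated by `dilation_radius_px = 4`
px (disk element, an isotropic safety margin against edge effects), are
subtracted. Remaining components of at least `min_capillary_area_px =
29` px (about 9.6 um^2, from a typical 3.5-um capillary) are kept. By
construction no pixel is both arteriole wall and capillary.

Binarisation defaults to Otsu's histogram criterion per channel, with a
fixed-value override for controlled experiments; the method is exposed
because staining intensity varies between preparations. Connected
components use 8-connectivity by default (the convention of common
particle-analysis tools); a 4-connectivity switch exists and is
cross-checked in the tests against `EBImage::bwlabel`, which is
4-connected.

## Amyloid spot detection

Aggregates are detected in three stages, in this order:

1. **White top-hat** (`top_hat_radius_px = 10`, about 5.7 um): the image
   minus its morphological opening with a disk. This removes any
   structure wider than the disk — diffuse background and vessel-scale
   autofluorescence — exactly cancelling constant offsets. The default
   radius is chosen larger than expected aggregates but smaller than
   vessels.
2. **Mexican-hat filter** (`mexican_hat_sigma_px = 2`): convolution with
   a negated, scale-normalised Laplacian of Gaussian, a band-pass that
   turns blobs near the chosen scale into positive peaks and returns
   (up to boundary effects) zero on constant and linear-ramp images.
   The kernel is mean-corrected so its coefficients sum exactly to
   zero.
3. **Intensity thresholding** of the filtered response (Otsu default,
   fixed and quantile overrides), connected-component labelling, and
   per-component records of size, centroid and mean raw intensity.
   `min_size_px` defaults to 1: no minimum is imposed on aggregates.

Background removal precedes the band-pass because the top-hat's
nonlinearity is what actually discards large structures; the LoG alone
would only attenuate them. Detection is invariant to adding a constant
to the input — a property the test-suite asserts.

Each aggregate is assigned a compartment by a **strict pixel majority**:
intramural if more than half of its pixels lie on an arteriole wall
mask, extramural otherwise (an any-overlap variant is available). The
boundary case is genuinely ambiguous in tissue; the majority rule is the
documented choice and the tests pin its boundary behaviour (6 of 10
pixels on the wall: intramural; 5 of 10: extramural).

## Preprocessing rules

Two prespecified rules precede modelling:

* **Extreme outliers**: while the largest aggregate size in a
  compartment dataset exceeds 20 times the next-largest, it is removed
  (and logged). Iterating the printed rule makes it deterministic and
  idempotent; with a single extreme value it removes exactly that one.
* **Images without arterioles**: if segmentation finds no arteriole in
  an image, deposits there cannot be assigned a compartment reliably,
  so the image's arteriole-coverage rows and all its aggregate rows are
  excluded (and logged).

## The two mixed models

Both outcomes share the nesting structure: vessels/aggregates within
images within mice, with the experimental group as the only fixed
covariate. Both models carry nested Gaussian random intercepts
`(1 | mouse / image)` on the mean's linear predictor.

**Coverage** uses a zero-inflated Beta GLMM. A logistic component gives
the probability `pi` of exactly zero coverage (intercept-only by
default; the group term is available by option but is deliberately not
the default, because the zero process was not the scientific target).
Nonzero proportions follow a Beta distribution parameterised by its
mean `mu` (logit link) and precision `phi`, so the density is
`Beta(mu * phi, (1 - mu) * phi)`. Responses of exactly 1 are squeezed
by the standard transform `y' = (y (n - 1) + 0.5) / n` over the `n`
nonzero responses before fitting.

**Aggregate size** uses a Tweedie GLMM with power `p` in (1, 2) and log
link: a compound Poisson-gamma law with `Var(Y) = phi * mu^p`, positive
mass at zero and a continuous, right-skewed density on the positive
axis. The density is evaluated through its series expansion with
adaptive term selection around the dominant index; the zero mass is the
closed form `exp(-mu^(2-p) / (phi (2 - p)))`. The series implementation
is cross-checked in the tests against `mgcv::ldTweedie` and against a
one-million-draw compound Poisson-gamma simulation.

### Estimation

The marginal likelihood integrates the random intercepts out by a
**Laplace approximation** around the per-mouse joint mode. Because
mice are independent given the fixed effects, the integral factorises
by mouse; each mouse contributes a small (1 + images) dimensional inner
problem solved by damped Newton iterations to gradient tolerance 1e-8.
The Newton direction uses a positive-definite surrogate curvature
(per-observation second derivatives clipped at zero — the Beta
log-likelihood is not globally concave in its linear predictor), while
the Laplace log-determinant uses the true Hessian at the mode. With
both random-effect SDs at zero the "approximation" is exact and equals
the sum of per-observation log densities.

The outer optimisation is quasi-Newton (`nlminb`) over fixed effects,
log-dispersion, log random-effect SDs (unconstrained scale) and, for
the Tweedie, `p` mapped by a logistic transform onto (1, 2); `p` is
first profiled over a coarse grid and then refined jointly. Restarts
(default 3, seedable, jittered) guard against local optima. Standard
errors come from the observed-information inverse at the optimum; a
variance component that collapses to the boundary (log-SD at its lower
bound) is held fixed and the information is taken over the free
parameters — the practical convention for singular fits. Wald `z =
estimate / SE` with two-sided normal p-values completes inference; no
multiplicity correction is applied (each outcome is a single
prespecified contrast at alpha = 0.05).

Group summaries are **estimated marginal means**: the linear predictor
per group with random effects at zero, transformed to the response
scale, with delta-method 95% intervals computed on the link scale (log
of the overall mean `(1 - pi) * mu` for the zero-inflated model — the
default reported mean; the conditional Beta mean is available) so the
intervals respect the response range.

### Accuracy of the approximation, honestly stated

The test-suite compares the Laplace marginal likelihood against nested
adaptive Gauss-Hermite quadrature on tiny designs (2-3 mice, up to 2
images, up to 4 observations) and requires relative agreement within
1e-3; at the study's realistic variance scales (SDs of 0.2-0.4 on the
link scale) the approximation error is far below the Monte-Carlo noise
of any study-level quantity. The package's fits were also verified
against an independent implementation (`glmmTMB`) during development;
the suite retains that cross-check: fixed effects, SEs and marginal
log-likelihoods agree to numerical precision on common data.

Wald inference with 5 mice per group is known to run liberal: the
normal reference ignores the handful of cluster degrees of freedom, and
maximum likelihood biases the mouse-level SD downward with so few
clusters. This affects this package exactly as it does any
maximum-likelihood mixed-model fit. The package's own recovery
simulations quantify it — at the 2 x 5 x 5 x 10 design the group
effect is estimated with negligible bias, but empirical 95% interval
coverage sits near 0.90 and the type-I error of the Wald test near
0.10-0.12 rather than 0.05; doubling the number of mice moves both
markedly toward nominal. The recovery checks therefore accept interval
coverage in [0.90, 0.98] rather than demanding 0.95 sharp, and
conclusions that hinge on error control at exactly 0.05 with five
animals per group should be treated with corresponding caution.

## The synthetic-data generator

The generator serves two distinct purposes and keeps them separate:

* `simulate_glmm_data()` / `simulate_tabular_study()` draw tabular
  studies **exactly** from the two generative families at the study's
  design (2 groups x 5 mice x ~10 images), so the inference code can be
  tested for parameter recovery with no approximation gap in the data.
  Default generative effects sit near the magnitudes the field reports
  for this kind of experiment (about -0.24 on the coverage logit scale,
  about -0.56 on the intramural log-size scale); they are illustrative
  defaults, not reproductions of any dataset. Each of the four outcomes
  draws its own independent random effects — a simplification; real
  outcomes share animals and are correlated across outcomes.
* `synthetic_scene()` / `render_synthetic_image()` build image scenes
  with pixel-level ground truth: arterioles as annuli co-positive in
  both stain channels with unstained lumina (outer diameter 10-40 um,
  wall 2-5 um), capillaries as Collagen-IV-only smoothed-random-walk
  tubes of 3.5 um width, aggregates as Gaussian blobs whose recorded
  footprint is the half-maximum region, plus distractors that probe
  each classification rule: gap-rings (incomplete SMA rings), solid
  disks (no lumen), small complete rings (below the 150-px wall
  threshold) and sub-29-px Collagen specks. Structures are spread over
  z-planes with per-plane weights whose maximum is 1, so a noise-free
  maximum projection equals the 2D scene exactly; Gaussian and
  photon-like Poisson noise are added last, after ground truth is
  recorded.

What the rendered scenes do **not** emulate: optical point-spread
blurring, z-dependent attenuation, tissue autofluorescence texture,
vessel branching, and overlapping structures (placement is
rejection-sampled to keep components disjoint, so that ground-truth
counts are unambiguous). Passing the zero-noise recovery suite
therefore demonstrates that the implemented rules are correct and
self-consistent, not that they are robust to every real-world artefact;
the noise parameters exist precisely so users can probe robustness.

## Problem sizes used by the test-suite

The suite was sized to be thorough yet runnable on a single CPU:
segmentation recovery uses twenty 224 x 224 zero-noise scenes
(containing in total well over twenty qualifying arterioles and every
distractor type); density normalisation uses 50 random parameter draws
and a 1e6-draw simulation oracle; parameter recovery uses 200 simulated
studies per family at 2 x 5 x 5 x 10 for the effect setting and another
200 under the null for the type-I error (the acceptance script reports
the same quantities from 60 replicates per cell so its runtime stays
modest). Rendered-image defaults in `study_config()` remain at the
acquisition's native 1024 x 1024; the tests pass smaller shapes
explicitly.

## Numerical choices and edge cases

* Inner Newton tolerance 1e-8 (infinity-norm of the gradient), at most
  60 damped iterations with step halving; random-effect modes are
  warm-started across outer iterations of the same fit.
* Log-SDs are box-bounded in [-10, 3]; exp(-10) is numerically "no
  random effect", and an SD below 1e-8 removes the dimension exactly.
* Linear predictors are clamped at +/-30 before exponentiation.
* Tweedie series terms are summed outward from the dominant index until
  they fall 37 log-units below the running maximum (double-precision
  negligibility), with log-sum-exp accumulation.
* Degenerate inputs fail fast with messages: all-zero coverage (Beta
  component unidentified), negative sizes, responses outside [0, 1],
  `p` outside (1, 2), empty wall masks.
* Single-observation images are retained; identifiability of the image
  variance rests on the full hierarchy, and collapsing components are
  handled by the boundary convention above rather than by dropping
  data.

## Known limitations

* Coverage is computed on 2D projections; stacked vessels at different
  depths can merge, which projection-based analysis inherits by design.
* The intramural/extramural rule is pixel-majority on the projected
  wall mask; a deposit hugging the outer wall edge can flip category
  with one pixel of segmentation error.
* Wald small-sample liberality with few mice (see above); users needing
  exact small-sample error control should pair the fits with a
  permutation or parametric-bootstrap layer.
* The Tweedie power `p` is weakly identified in small datasets; the
  profile-then-refine scheme is robust but `p`'s own uncertainty is not
  propagated into the fixed-effect SEs beyond its curvature at the
  optimum.
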