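---
title: "Infusion-response phMRI: models, inference, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Infusion-response phMRI: models, inference, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pharmacological MRI (phMRI) measures the direct effect of a drug infusion on
BOLD activity, without any sensory task. The analysis differs from
task fMRI in three ways that shape every design choice in this package:

* the signal of interest is a *slow, one-shot* response locked to the
  infusion protocol, not a train of brief events — so there is no HRF
  convolution and no high-pass filter (a high-pass filter would remove the
  signal itself);
* the response onset varies across brain regions and subjects with local
  pharmacodynamics, so a single fixed regressor is biased;
* group inference compares two *within-subject* drug conditions from a
  randomized crossover, so all group models are paired.

`phmri` implements this pipeline end to end and ships a synthetic crossover
cohort with known ground truth, so every stage — preprocessing, single-subject
GLM, paired contrast, spatially regularized mixture inference, seed-based
connectivity, cluster reporting — is exercised by tests without any data
download.

## The infusion model

The expected response (the "infusion EV") is a ramped unit step on the
acquisition clock: 0 during a 5-minute baseline (the pretreatment infusion),
a linear ramp from 5 to 13 minutes while the drug is delivered in fractional
boluses, and a plateau of 1 thereafter:

$$
f(t) \;=\;
\begin{cases}
0 & t \le 300\,\mathrm{s}\\[2pt]
(t - 300)/480 & 300 < t < 780\,\mathrm{s}\\[2pt]
1 & t \ge 780\,\mathrm{s}
\end{cases}
$$

`build_infusion_ev()` samples $f$ at the frame times of the *analyzed*
series: after dropping the first `n_drop = 2` volumes the first retained
frame sits at $t = n_\mathrm{drop}\cdot TR$, which `drop_initial_volumes()`
tracks as the volume's time origin. The per-voxel statistic of interest is
the EV coefficient ("infusion amplitude") from an ordinary least-squares GLM
with Gaussian errors — no prewhitening, matching the modelling assumption of
a GLM with white Gaussian noise; residual autocorrelation is a known
limitation discussed below.

### Onset-jitter nuisance regressors

Because the true onset can shift by tens of seconds, the design includes a
small set of data-independent nuisance regressors that span onset
variation. The construction (the cited literature gives the idea but not a
recipe, so this concrete family is this package's documented choice):

1. build the family of ramps shifted by −60 … +60 s in 15 s steps;
2. residualize each member against the nominal EV and the intercept;
3. keep the top-`k` (default 3) left singular vectors.

The resulting columns are orthonormal and exactly orthogonal to the nominal
EV and intercept, so on data generated by the nominal ramp they cannot change
the fitted amplitude (a tested invariant). Under a +60 s true shift they
absorb the shift-shaped residual that would otherwise leak into the
amplitude through the drift and intercept columns: in the packaged
simulation the mean amplitude bias shrinks by an order of magnitude
(about −0.11 to about +0.01 on a true amplitude of 1; the acceptance script
recomputes both numbers). The first singular vector alone carries ~95% of
the family's residual variance.

### Covariates of no interest

Linear drift (mean-centered), WM and CSF mean timecourses (mean-centered)
and an intercept complete the design. Two details matter:

* **GM-eroded extraction masks.** `nuisance_extraction_masks()` removes a
  one-voxel 26-neighborhood dilation of the GM mask from the WM and CSF
  masks before timecourse extraction. Spatial smoothing bleeds GM signal
  into adjacent WM/CSF voxels; a covariate contaminated with the response
  re-enters every voxel's fit with opposite sign and biases the whole map.
  On the desk-scale phantom (where WM/CSF masks are small, so the
  contamination fraction is large) this artifact is dramatic — nominal null
  z maps with sd ≈ 2 instead of 1 — which is why the erosion is the default
  and not an option. Eroding nuisance masks away from gray matter is
  standard practice in connectivity pipelines for exactly this reason.
* **Extraction happens after smoothing** (configurable in principle; the
  pipeline extracts from the preprocessed volume). Whether a real study
  extracts pre- or post-smoothing is rarely reported; post-smoothing is the
  conservative choice given the erosion above.

A rank check runs on every assembled design and names the collinear columns
on failure; the condition number is reported.

### t-to-z

All t statistics are mapped to z by matched tail quantiles, computed on the
log scale (`pt(..., log.p = TRUE)` into `qnorm(..., log.p = TRUE)`) so the
far tails do not underflow, and clipped at |z| = 8 — far beyond any
inference boundary, but finite so that perfect fits on synthetic data do not
produce infinities. The transform is monotone and odd; both properties are
tested.

## Paired group contrast

Per voxel, the paired differences $d_i = A_i - B_i$ over the $n = 13$
subject pairs give $t = \bar d / (s_d/\sqrt n)$ with $n-1$ degrees of
freedom, transformed to z. Both contrast directions are returned and are
exact negations. This is a deliberate simplification of record: the original
analysis used a Bayesian mixed-effects variance model, but the design it
implements is a paired t-test design, and at 13 pairs with a single
within-subject statistic per condition the classical paired t is the
matching classical estimator. Voxels missing in any subject are dropped
from the group mask rather than imputed. A degenerate voxel
($s_d = 0$, $\bar d \ne 0$) is pinned at $z = \pm 8$ with a warning; an
identically-zero difference gives $z = 0$.

## Mixture-model inference with an MRF label prior

Instead of null-hypothesis thresholding, the group z map is modelled as a
3-class Gaussian mixture — deactivated, null, activated ($\mu_{-1} < \mu_0 <
\mu_{+1}$ enforced) — with a Markov random field soft-max prior on the class
labels: at voxel $v$,

$$
p(\ell_v = k \mid \ell_{\partial v}) \;\propto\; \pi_k\,
\exp\!\big(\beta\, m_k(v)\big),
$$

where $m_k(v)$ counts 6-connected in-mask neighbors with label $k$,
$\pi_k$ are global mixing proportions, and $\beta \ge 0$ is the coupling
strength. Three classes are required because both increased and decreased
responses are real outcomes of a drug contrast. The exact parameterization
of the soft-max prior (including whether $\pi_k$ enters) is not fixed by the
literature this follows; the form above is this package's documented choice.

Estimation is by **iterated conditional modes** (hard labels, not mean-field
EM — ICM is the named estimator):

(a) a raster-order label sweep assigns each voxel
$\arg\max_k\; \log\pi_k + \beta m_k(v) + \log N(z_v;\mu_k,\sigma_k^2)$,
using already-updated neighbors (ICM is order-dependent, so the fixed raster
order is part of the specification and makes the fit deterministic);
(b) class means, sds and mixing update by maximum likelihood from the hard
labels, with $\sigma_k$ floored at 0.05 and empty classes removed (the
collapse guard — on a pure-null map the tail classes lose their members and
the model gracefully degrades);
(c) $\beta$ updates by maximizing the Besag pseudo-likelihood of the label
field over $[0, 5]$ by bounded 1-D search.

The joint pseudo-posterior (likelihood plus field term with each edge
counted once) is recorded before and after every label sweep; each
single-site update can only increase it, so within a sweep it is
non-decreasing — asserted in the tests on every fit. Iteration stops when a
sweep changes no label or after `max_sweeps = 50`.

The **posterior probability map** of activation conditions on the converged
neighborhood labels and the data:
$\mathrm{PPM}_k(v) = p_k(v)\,N(z_v;\mu_k,\sigma_k^2) / \sum_j p_j(v) N(z_v;\mu_j,\sigma_j^2)$,
summed over positive-mean classes (and negative-mean classes for
deactivation). Detection uses the *strict* rule PPM > 0.5: a voxel at
exactly 0.5 is excluded. Conditioning on converged hard labels (rather than
marginalizing neighbors) is the simpler of the two defensible choices and is
documented as such.

With $\beta$ fixed at 0 the whole machinery reduces exactly to a non-spatial
hard-assignment Gaussian mixture; the tests verify label-for-label and
PPM-to-1e-12 agreement against an independently coded classification GMM.
With $\beta$ free, planted z≈6 blobs are recovered at Dice ≥ 0.9 and
spatial coupling strictly reduces isolated single-voxel detections relative
to $\beta = 0$.

## Seed-based partial-correlation connectivity

Only the final 5 minutes (120 frames at TR 2.5 s) enter connectivity: the
drug effect is in steady state there, so correlations are not driven by the
shared ramp. Per session, every brain voxel's partial correlation with the
seed mean timecourse is computed given intercept, within-window linear
drift, and WM/CSF timecourses — both series are residualized against the
nuisance matrix by least squares and the residuals correlated. An
independent precision-matrix formulation agrees to 1e-10 (tested on random
instances). $r$ is clipped at $1 - 10^{-7}$ and Fisher-z transformed
($\operatorname{atanh}$) for variance stabilization before the paired group
contrast; inference on the group z map reuses the mixture/MRF engine.

The null variance of $\operatorname{atanh}(r)$ follows the convention
$1/(n - q - 3)$, with $q$ the number of *non-intercept* nuisance regressors
(the intercept is the mean-centering already counted by the classical
$1/(n-3)$); simulation confirms this within 10%.

## The synthetic cohort

The phantom emulates the study conditions: 13 subjects, two conditions each
(crossover, always paired), TR 2.5 s, 600 volumes (25 min), 3.5 mm isotropic
voxels. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| grid | 20 × 20 × 10 (desk scale) | full ellipsoidal brain with three tissue shells at test-suite speed; 64 × 64 × 41 available by config |
| baseline | 1000 a.u. | amplitudes are absolute additive units, directly comparable to GLM output |
| noise sd | 1.0 per frame | per-frame effect size ≈ amplitude, a realistic per-TR BOLD regime where power comes from the 598 frames |
| planted amplitude | 1.5, condition A only | the "effect size ≈ 1.5" study condition |
| planted region | anterior GM patch, ≈ 136 voxels ≈ 5.8 cm³ | inside the 0.4–19 cm³ range of reported activation clusters; GM-only so the nuisance compartments stay response-free |
| onset jitter | uniform ± 60 s per session | matches the span of the SVD shift family |
| drift | per-session slope ~ N(0, 0.5 a.u./scan) | slow scanner drift for the drift column to absorb |
| WM/CSF nuisance | AR(1), lag-1 0.95, marginal sd 2, 20% leak into GM | realistic low-frequency physiological confounds that the covariates must actually remove |
| seed network | seed (28 vox) + target (84 vox) GM regions, shared latent, coupling 1.0 × noise sd, condition A, final 5 min only | connectivity present only where and when the method should find it |

Tissue masks are concentric ellipsoid shells (WM core, GM shell, CSF rim) —
a stand-in for segmentation that gives the pipeline the three compartments
it needs. Sessions are bit-reproducible: each (subject, condition) pair
derives its own RNG substream from the cohort seed, so sessions can be
generated in any order, or singly, with identical output.

What the phantom does **not** emulate: head motion, spin-history and
physiological (cardiac/respiratory) artifacts, temporally autocorrelated
voxel noise, spatial inhomogeneity of noise, registration error, and any
real anatomy. Passing tests therefore demonstrate the *statistical
machinery* — calibration, unbiasedness, recovery, determinism — not
robustness to acquisition artifacts.

## Numerical choices

* Smoothing: separable Gaussian, σ = FWHM/(2√(2 ln 2)) converted per axis
  to voxel units; kernel truncated at 4σ; whole-sample reflection at the
  boundary, which conserves each frame's spatial mean exactly (symmetric,
  doubly-stochastic convolution matrix).
* Grand-mean target 10000 (a convention; the factor cancels in every
  statistic). The grand mean is computed within the brain mask only —
  including background zeros would distort the multiplier.
* Mixture init: null class at the 10%-trimmed mean/sd of the z values;
  activated/deactivated at ±(2 + null sd) with sd 1 and mixing 0.05.
* ICM ties in the label argmax break to the lowest class index; the label
  sweep visits voxels in ascending linear index (raster) order.
* Cluster reporting uses 26-connectivity by default (a reporting
  convention, deliberately distinct from the MRF's 6-neighborhood, which is
  a model choice); peak = max |z|, ties to the lowest linear index;
  laterality from the peak's world x with a ±2 mm midline band ("B").
* Reported volumes are voxel count × voxel volume exactly; the reporting
  grid is whatever grid the maps live on (resampling to a standard 2-mm
  space is out of scope, so tables from the phantom are at 3.5 mm).

## Problem sizes

The test suite and the acceptance script run the full 13-subject crossover
at the 20 × 20 × 10 desk grid (about 25 s per end-to-end run), plus
calibration simulations of 200–5000 replicates; the complete pipeline on
one CPU stays well under the 15-minute design budget for `run_phmri_pipeline()`.

## Known limitations

* OLS without prewhitening: with temporally autocorrelated noise the
  single-subject se would be optimistic; group inference (which only uses
  per-subject amplitudes) is unaffected.
* FLAME-style mixed-effects variance weighting is intentionally replaced by
  the classical paired t.
* Spatial smoothing spreads planted signal into a one-voxel halo whose
  group statistics are genuinely suprathreshold; recovery Dice against the
  exact planted support therefore plateaus around 0.7–0.8 by construction,
  not by estimation error.
* Motion correction, brain extraction, registration, segmentation and
  ICA-based artifact removal are out of scope; inputs are assumed aligned
  in a common space, as the synthetic data is.
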