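---
title: "Methods: models, estimators and design choices in locipair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in locipair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(locipair)
```

`locipair` measures the 3D distance between the two fluorescent dots that a
lacO/LacI-EGFP insertion produces in an interphase plant nucleus, and asks
the questions that distance supports: is it longer than random placement
predicts, does it scale with nuclear volume, does it shorten after DNA
double-strand breaks and recover, and how often do the two dots merge into
one ("paired" loci). Because the original image data are not redistributable,
the package pairs every estimator with a generative model whose ground truth
is exact, so each stage can be validated end to end. This vignette records
the models, the tunable parameters, and the design decisions that were
genuinely open.

## The nucleus generator

A nucleus is an ellipsoid with semi-axes $(a_x, a_y, a_z)$ (µm) containing a
concentric spherical nucleolus of radius $r'$; the *nucleoplasm* is the
ellipsoid interior minus the nucleolus. The two loci are point sources at an
exact separation $s$: the first endpoint is uniform in the nucleoplasm, the
orientation uniform on the sphere, and the pair is accepted only if both
endpoints are inside the nucleoplasm (batched rejection; an explicitly
requested separation that cannot be placed is an error, a model-drawn one is
redrawn).

Defaults follow the biology of the two root zones:

* **meristematic**: sphere of radius 2.3 µm (matching the nucleus radius
  used by the geometric null), nucleolus 1.17 µm, separation mean 3.5 µm,
  SD 1.0 µm. The 3.5-µm meristematic separation is the published scale for
  this system and doubles as the generator's truth in the recovery checks.
* **elongation**: endoreplicated nuclei, modelled as a $4.6 \times 3.25
  \times 3.25$ µm ellipsoid (≈ 4× the meristematic volume — the shapes are
  not published, so an x-elongated ellipsoid of the right volume ratio is
  our choice), nucleolus 1.86 µm, separation mean 5.5 µm.

Separations are drawn from a normal truncated to $[0, 2\max(a)]$ (the
longest chord). Near the geometric maximum the placement step additionally
conditions on feasibility, so the effective distribution of meristematic
truths has a slightly lower mean (≈ 3.2 µm) than the nominal 3.5; the
distribution test therefore runs at parameters where truncation is
negligible and compares against the closed-form truncated-normal moments.

Each nucleus also receives a log-normal linear size factor (SD 0.08 on the
log scale) applied to the semi-axes, nucleolus and separation mean together.
This produces the distance–volume correlation observed across nuclei while
leaving the volume distribution independent of dose, and it is the only
source of volume variation in a panel.

**Rendering.** Voxels default to $0.1 \times 0.1$ µm lateral × 0.5 µm axial
(the axial step is the published acquisition setting; the lateral size is a
typical spinning-disk sampling, not published). The PSF is an anisotropic
Gaussian, $\sigma_{xy} = 0.125$ µm, $\sigma_z = 0.3$ µm — conventional for a
high-NA confocal at EGFP wavelengths; the optics of the original
acquisitions are not published, so these are package choices. Spots are rendered by per-axis integrals of the
Gaussian over voxel extents (differences of normal CDFs), so the rendered
sum equals the amplitude exactly up to window truncation — this is what the
intensity-conservation test asserts. Amplitude defaults to 2000 photons per
focus over a 10-photon background; with Poisson shot noise and 2-photon
read noise this gives a peak-voxel SNR near 10. The nucleus channel is the
filled ellipsoid at 50 photons over background. Positions are voxel-center
coordinates: 0-based index $i$ maps to $(i + 0.5)v$ µm.

**What the generator does not emulate:** aberrations, depth-dependent PSF
broadening, photobleaching, chromatin texture, multiple nuclei per field,
or mitotic figures. Tests passing on these synthetics validate the
estimators' geometry and statistics, not robustness to those optical
artifacts.

## Dose response and genotypes

The effect of an acute dose $D$ (Gy) observed $t$ hours later is a
saturating shortening with exponential recovery:

$$ s(D, t) = s_0 - A\,(1 - e^{-D/D_{1/2}})\, e^{-t/\tau} $$

with defaults $s_0 = 3.5$ µm, $A = 1.5$ µm, $D_{1/2} = 60$ Gy,
$\tau = 6$ h. Only monotone shortening and recovery by 24 h are published;
the functional form and constants are package choices, picked so that
≥ 100 Gy produces a clearly significant shortening at the study's sample
sizes and 24 h sits within 2% of baseline. The same saturating term scales
a pairing probability (maximum 0.3) with which a nucleus instead receives a
near-coincident pair (separation uniform below 0.2 µm). Genotypes are pure
generator switches — `shortening` and `pairing` on for the wild type, off
for the "rad54-like" configuration — the package makes no molecular claims.

## Spot detection and distance measurement

Detection smooths the foci channel with a Gaussian matched to the expected
spot, with sigmas converted per axis into voxel units so anisotropic
sampling is handled once. Candidates are strict 26-neighborhood local
maxima above `median + 6·MAD` of the smoothed stack; candidates within 3
spot-sigmas of a stronger one are suppressed (shoulder maxima), and the top
`max_candidates` survive. Each is refined by a least-squares fit of the same
integrated-Gaussian model used by the renderer, with fixed sigmas and five
free parameters (centre, amplitude, background), optimized by L-BFGS-B with
the centre boxed to the fit window. A fit that ends with vanishing
amplitude or fails to improve on its starting point falls back to the
intensity-weighted centroid — the degenerate local optimum this guards
against otherwise produces rare gross outliers. On defaults the mean
measured distance is within ±0.01 µm of truth at separations 1–3.5 µm with
per-measurement SD ≈ 0.01 µm.

Pairing follows the field's reading of overlapped dots: two detections
closer than the threshold, or a nucleus showing a single dot, count as
paired (distance 0); nuclei with no detections are excluded entirely. The
0.4-µm default threshold is ≈ 2× the lateral PSF sigma plus margin — the
scale below which two EGFP dots merge visually; it is configurable and
recorded in every output. Distance summaries exclude paired loci (they are
counted in the pairing frequency instead), and the pairing frequency treats
the root, not the nucleus, as the replication unit, warning below 30 nuclei
per root. Time series are measured per frame with no registration — the
distance is invariant to nuclear translation — and frames with no
measurable pair stay missing.

## Nucleus segmentation

Segmentation smooths the nucleus channel (sigmas in voxel units, 1.5
lateral / 0.6 axial, so the smoothing-induced surface bias shrinks with the
voxel size), thresholds by Otsu, then re-thresholds at the midpoint between
the foreground plateau (90th percentile of the Otsu class) and the
background median. The refinement matters: with a 0.5-µm axial step the
partial-height edge band is a large voxel fraction and plain Otsu lands
below the half-height contour, dilating volumes by ≈ 20%; the half-height
threshold brings sphere volumes within ~4% of $\tfrac{4}{3}\pi r^3$, and
the error at least halves when voxels are halved (the consistency test).
Holes are filled and the largest 6-connected component kept; components
touching the border beyond a 0.1% voxel fraction are flagged clipped and
excluded from volume statistics. Volume is voxel count × voxel volume, with
no marching-cubes correction — the resolution-dependent bias is documented
by the tests rather than corrected.

## The Monte Carlo shell null

The null model draws both loci independently and uniformly from a spherical
nucleoplasm shell: direction uniform, radius by inverse CDF of the $r^3$
law restricted to $(r'^3, r^3]$ — exact and branch-free; a brute-force
rejection sampler serves as an independent oracle in the tests. A nucleolus
at least as large as the nucleus makes the shell constraint $r' < r_x \le
r$ unsatisfiable, so the constructor rejects $r' \ge r$ with a message; of
the two published radii only one assignment is geometrically consistent,
and the defaults take the nucleus as the larger — $r = 2.3$ µm, nucleolus
$r' = 1.17$ µm. Two closed forms anchor the
sampler: the full-ball mean pairwise distance $36r/35$ and the thin-shell
(surface) limit $4r/3$. With the default geometry the null mean is
≈ 2.50 µm, well below the 3.5-µm measured scale.

`compare_to_null()` tests "measured longer than null" by resampling: draw
$|measured|$ distances from the null sample, record how often the resampled
mean reaches the measured mean, $p = (1 + k)/(B + 1)$ with $B = 1999$ by
default (a Welch test against the null sample is available by flag). The
choice avoids distributional assumptions on a model-vs-data comparison; its
calibration (uniform p under the null) is asserted by test. Both sample
sizes are always reported, since "n" is ambiguous in a model-vs-data
figure.

## Comet metrics

Comet images are 2D with migration along +x (real images must be
pre-rotated). Background is a per-column median smoothed by a rolling
median along x — the comet occupies a minority of every column, so the
median sees clean background; a low percentile would sit ≈ 0.84 SD below
the true level under noise and bias every intensity. The head is found on
the y-collapsed profile as the *leftmost* peak above 25% of the profile
maximum (the head leads; the global mode can sit in a bright tail), its
radius as the half-height radius of the radial profile, with a 2-px guard
band so the softened head edge is attributed to the head. The tail is
thresholded signal (`3·MAD` above background, the explicit stand-in for an
unpublished plugin internals) beyond the head edge. Tail DNA % is the tail
share of (head + tail) intensity; tail length is head centroid to the
farthest above-threshold tail pixel; the Olive moment is tail fraction ×
head-to-tail centroid separation.

Noise-free measurements recover the generated tail fraction within one
percentage point. Under shot noise the thresholded-mask definition loses
sub-threshold tail signal, attenuating tail % (e.g. ≈ 26 measured for a
generated 50% at default SNR) while preserving order — which is why comet
outputs are property-tested (monotonicity, scale invariance, verdict
logic) and never compared on an absolute scale. The recovery verdict is a
pure function of two test outcomes (earliest group above control; latest
group above control) and is truth-table tested.

## The study pipeline

`run_study()` generates everything from a master seed (per-item substreams,
all below $2^{31}$), measures it, and reports seeded significance verdicts
at the configured alpha: zone comparison, distance–volume Pearson
correlation (pooled zones), measured-vs-null, dose response with Holm
correction across doses (raw p also reported), volume invariance under
dose, 24-h recovery, genotype shortening and per-root pairing frequencies,
and the comet time course. Welch's t-test is the default two-sample test
(the published analysis does not name its tests, and distances and volumes
are near-unimodal under the generator, where Welch is robust to unequal
variance), with Mann-Whitney by flag. Identical
config and seed give byte-identical JSON reports; no timestamps are
embedded.

Default problem sizes — 25 nuclei per zone and per dose, 25 recovery
nuclei, 5 roots × 8 nuclei per genotype × dose, 20 comets per condition,
$2 \times 10^5$ null pairs — are chosen so the generated effects are
detected with high power while a full study runs in about two minutes on
one core; the per-root count is deliberately below the 30-nucleus per-root
design minimum the pairing-frequency stage enforces, and the pipeline
surfaces the corresponding warnings in its report notes. The acceptance script uses 100
stacks for parameter recovery, 200 for the pairing baseline, and $10^6$
null pairs.

## Known limitations

* The detector assumes exactly two true loci; a third bright object
  displaces a true focus from the top-two only if it outscores it, and is
  otherwise recorded in the candidate count for QC.
* Sub-resolution separations (below ≈ 0.4 µm laterally, worse axially)
  merge into one detection and are classified paired rather than measured —
  the intended reading of overlap, but it means the distance sample is
  left-truncated near zero.
* Volume estimates carry a small negative bias (≈ 3–4% at default voxels)
  from smoothing and curvature; comparisons between conditions are
  unaffected because the bias is common.
* The shell null is spherical only; an ellipsoidal nucleoplasm is an
  extension point, not implemented.
* Noisy comet tail % is attenuated by thresholding (see above); only
  noise-free values are accurate on an absolute scale.
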