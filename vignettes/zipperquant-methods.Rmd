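---
title: "Quantifying filopodia zippering, motility and filament mechanics: methods and design"
author: "ZipperQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying filopodia zippering, motility and filament mechanics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter choices
and numerical conventions. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

# The contact-density statistic

The central measurement is the number of filopodial contacts along a
cell–cell segment where the gap between the two cells stays constant,
divided by the physical length of the sampled profile:

$$\rho = \frac{n_\text{contacts}}{L} \quad [\text{contacts}/\mu m].$$

`extractProfile()` samples the image by bilinear interpolation at a spacing
of at most one pixel along the segment and averages over `widthPx` parallel
lines perpendicular to the path; positions are converted to micrometres with
the pixel size. Coordinates are 0-based `(row, col)`; physical units enter
only through `pixelSize`.

## Peak definition

A *contact* is a local maximum of the (optionally baseline-subtracted,
smoothed) profile whose **topographic prominence** — its height above the
higher of the two minima separating it from higher terrain on either side —
is at least `minProminenceFrac` (default 0.2) of the profile's dynamic range
`max(I) - min(I)`. Accepted peaks must be at least `minSeparationUm`
(default 0.3 µm) apart; on conflict the higher peak wins. Because the
threshold is *range-relative*, multiplying all intensities by a positive
constant changes nothing — the detector is invariant to illumination and
detector gain, which is the property a confocal-microscopy statistic needs
most.

A flat profile has zero dynamic range and zero contacts, not an error.

## Why the detector smooths first

`peakParams()` exposes a Gaussian pre-smoothing bandwidth `smoothUm`
(default 0.2 µm, i.e. roughly two-thirds of the point-spread-scale peak
width below). This stage is part of the detector's design, not a
convenience: with additive read noise of standard deviation $\sigma_n$, the
extreme prominence among the roughly $10^4$ noise samples of a batch of
profiles reaches $\approx 6\text{–}7\,\sigma_n$ (the max–min range of the
noise between true peaks). A range-relative threshold of $0.2\,A$ (peak
amplitude $A$) is crossed by pure noise once
$\sigma_n \gtrsim A/35$ — which an SNR-5 image ($\sigma_n = A/5$) exceeds by
an order of magnitude on raw samples. Perpendicular averaging over the
profile width and the 0.2 µm smoothing kernel together reduce the effective
noise by a factor $\approx 9$ while attenuating a PSF-scale peak by only
$\approx 17\%$, placing the noise extreme comfortably below threshold. The
width and smoothing scales were fixed from this calculus; the test suite
then verifies perfect precision and recall at SNR 5 over 100 scenes.

One inherent limitation follows from the same arithmetic: a profile that
truly contains *no* peaks but does contain noise has a dynamic range made
entirely of noise, and a range-relative detector will report spurious peaks
there. The procedure presumes regions selected because contacts are present
(as region selection in practice does); a zero-contact noisy profile needs
an absolute intensity floor, which the package deliberately does not invent.

## Baseline, gaps, bins and groups

* **Baseline.** A rolling-median baseline (window 5 µm) is available but
  **off by default**: background subtraction in the source imagery is a
  presentation step, not part of the counting procedure, and a
  range-relative prominence already absorbs smooth offsets.
* **Constant-gap segmentation.** `segmentConstantGap()` scans left to right
  and extends each segment while the running gap range stays within
  `tolGap` (default 0.5 µm — the data give no tolerance, and half a
  micrometre is below any biologically meaningful gap change at these pixel
  sizes). Segments are disjoint, ordered and maximal under this greedy rule,
  which the tests pin to an $O(n^2)$ oracle.
* **Binning.** Density-versus-gap summaries use the Freedman–Diaconis width
  $h = 2\,\mathrm{IQR}\,n^{-1/3}$ with type-7 (linear-interpolation)
  quartiles; a zero IQR falls back to a single flagged bin. Per-bin error
  bars are standard errors of the mean.
* **Group comparisons.** Boxplot summaries report mean, median and 5–95
  percentile whiskers under the linear-interpolation percentile convention
  (stated because whisker values depend on it: the 5th percentile of
  1..100 is 5.95). The default two-sample test is Mann–Whitney U —
  distribution-free, matching a boxplot presentation — with KS available.

## Perimeter filopodia

`perimeterProfile()` extracts the ordered boundary of a single-component
mask, samples the intensity along it and runs the same peak detector on the
**cyclic** profile: the profile is rotated so the array cut falls at the
global minimum, where circular and linear prominences coincide. The
perimeter is a chain-code length with corner-corrected step weights (0.980
per axial step, 1.406 per diagonal step, −0.091 per direction change),
which removes most of the staircase overestimate of a raw pixel-centre
polygon; on digitised disks of radius ≥ 8 px this lands within 4% of
$2\pi r$, verified in the tests.

# First-neighbor distances

Images are binarized (Otsu on the [0, 1]-rescaled image by default, the
threshold mapped back to intensity units and recorded; foreground is
strictly above threshold), then labeled. Labeling is an iterative
minimum-label propagation supporting both 4- and 8-connectivity;
8-connectivity is the default so that touching cells merge into one
"cluster" object, matching how such images are read in practice. The test
suite pins the labeling to an independent BFS flood-fill oracle on 1000
random masks.

Each object's first-neighbor distance is the centroid-to-centroid distance
to its nearest other object; distances are normalized by the **mean
equivalent-circle radius** of the analyzed field (the natural reading of
"average cell radius"; per-image averaging, since a global average is not
definable offline). Distribution comparisons use the exact-sup two-sample
KS statistic — with the exact p-value whenever the sample sizes permit
(R's convention, $nm < 10^4$) — and Gaussian-kernel KDEs with Silverman's
bandwidth on a shared grid, renormalized so the trapezoidal integral over
the grid is exactly 1.

**Edge handling.** The plain estimator ignores field borders, as the
procedure it reimplements does. For *calibration* against the homogeneous
Poisson closed form $E[d_{NN}] = 1/(2\sqrt{\lambda})$, border effects matter:
the naive estimator's bias (the Donnelly term, ≈ 0.0514 · perimeter/n)
exceeds three standard errors at any field size reachable with 50 fields.
`nnDistances()` therefore offers a periodic (torus) metric, unbiased for
homogeneous patterns, which the calibration uses; `edge = "none"` remains
the default for real images.

# Motility

`computeMSD()` implements the pure **ensemble** average: squared
displacement from each trajectory's first frame, averaged across
trajectories, with SEM across trajectories per lag. A time-averaged variant
sits behind `timeAverage = TRUE`, clearly non-default, for robustness
comparisons. The frame interval is the file's `dt` (20 min in the motivating
assay); trajectories are validated to uniform spacing and no interpolation is
attempted. Fits are ordinary least squares of MSD on lag (slope/4 = D,
intercept retained to absorb localization offsets) or of log MSD on log lag
(anomalous exponent).

"Explored area" is operationalized as the per-trajectory **maximum
displacement radius** from the starting point within a time horizon — the
radius of the dashed circle drawn around a trajectory's origin — because the
quantity is never defined numerically in the motivating work; the mean and
SEM over trajectories are reported.

The synthetic persistent walker draws steps with stationary per-component
variance $2D\,dt$ and AR(1) correlation $\exp(-dt/\tau_p)$ between
successive steps. With the *single-step* variance matched, positive step
correlations push the short-lag MSD **above** the $4Dt$ line of the
uncorrelated walk (superdiffusive onset) — the behaviour the persistent
generator is specified to exhibit. (An Ornstein–Uhlenbeck velocity process
matched on the *long-time* D would instead sit below $4Dt$; the choice is
deliberate and documented here.)

# Filament persistence length

Filament backbones are resampled at uniform arclength; tangent angles are
unwrapped segment angles at segment midpoints. Amplitudes use the free-end
cosine basis with the normalization fixed so the 2-D worm-like-chain law
takes exactly the inverse-square form:

$$a_n = \sqrt{\tfrac{2}{L}} \sum_k \theta(s_k)\cos\!\big(\tfrac{n\pi s_k}{L}\big)\,\Delta s,
\qquad \operatorname{var}(a_n) = \frac{1}{L_p\,q_n^2},\quad q_n = \frac{n\pi}{L}.$$

The 2-D convention $\operatorname{Var}[\theta(s{+}\Delta s)-\theta(s)] =
\Delta s / L_p$ is stated explicitly to avoid the factor-of-two ambiguity
between 2-D and 3-D tangent diffusion; the simulator and the analyzer share
no code for this law, so their agreement in the tests validates both.

Defaults and guards: modes 1–5 enter the fit (high modes are dominated by
localization noise, whose flat variance contribution grows relative to the
$q^{-2}$ signal; the tests demonstrate the resulting downward bias and its
removal by restricting modes); `nMax` may not exceed half the number of
tangent samples (aliasing); filaments are analyzed in equal-length batches
(5% tolerance) because $q_n = n\pi/L$ mixes across lengths — localization
noise inflates chordal lengths, so noisy batches may need a looser
tolerance, exposed as `lengthTol`. A fit returning a non-positive amplitude
coefficient reports `converged = FALSE` with `NA` for $L_p^*$ and residual
diagnostics rather than a fabricated value.

# Omics bookkeeping

Fold changes are **signed linear** values (+2 = twofold up, −3 = threefold
down; the interval (−1, 1) cannot occur), matching the ±2/3/5/8 cutoff
notation; log2 converters are provided. Threshold boundaries are inclusive
for the fold change (⩾ c, ⩽ −c) and strict for p (< 0.05). Set nesting
across increasing cutoffs is enforced by construction and re-checked against
exhaustive scans in the tests.

MS acceptance filters default to protein probability > 0.99, peptide
probability > 0.95 and ≥ 2 peptides, each applied only when the
corresponding column exists. The filter set is configurable because
published identification lists routinely retain curated single-peptide
entries — the packaged 56-protein table itself contains many — so a rigid
filter would misrepresent such tables rather than "clean" them.

Networks are undirected with a closed edge-type vocabulary (physical,
genetic, colocalization, shared_domain, pathway, predicted). Quantities that
depend on external interaction databases — the fraction of nodes with
physical edges in a published network, specific overlap counts, a particular
domain network's node/edge count — are *procedural* references: the package
reproduces the operations (filtering, counting, assembly from a
domain-interaction map, including self-interacting domains such as LIM–LIM),
not the database-dependent values.

# The synthetic generator: what it emulates, and what it does not

* **Contact scenes** render two rectangular cell bodies separated by a
  constant gap, with contacts as Gaussian bumps on the midline —
  full-width-at-half-maximum `peakWidthUm` (default 0.7 µm, a PSF-scale
  filopodium) along the profile and elongated across the gap (sd = gap/2),
  as a filopodium bridging two cells is. Ground-truth positions keep a
  separation of at least twice the FWHM, which also keeps them resolvable
  by any local-maximum detector. Noise is additive Gaussian read noise; no
  PSF convolution, photon (Poisson) statistics, uneven illumination or 3-D
  structure is modelled. Passing detection tests therefore demonstrates the
  *procedure's* correctness and noise robustness, not performance on real
  membranes, where background texture and out-of-focus light add structure
  the generator omits.
* **Trajectories** are Gaussian random walks (optionally step-correlated);
  real wound-healing motion includes collisions, confinement and drift.
* **Filaments** are exact 2-D worm-like chains with optional localization
  noise — the inverse model of the analyzer, which is precisely what makes
  them the right oracle for it.
* **Point patterns** are homogeneous Poisson disks; real monolayers are
  clustered and size-correlated.
* **DE tables** plant clean regulated sets with magnitudes clear of the
  cutoffs under test, so set recovery is exact by construction.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use 100 seeded scenes for
detection, 1000 trajectories × 100 steps for MSD calibration, 500 filaments
per persistence length in {5, 10, 25} µm at L = 5 µm, 50 Poisson fields of
500 × 500 µm at λ = 10⁻³ µm⁻², 1000 null replicates (n = 50 per group) for
KS calibration and 1000 random 64 × 64 masks for the labeling oracle —
sizes at which every calibrated quantity resolves well inside its 3-SE
acceptance band while the whole suite runs in minutes on one core.

Every generator takes an explicit integer seed and restores the caller's RNG
state; `runPipeline()` echoes its configuration and writes an md5 manifest,
and identical configurations produce hash-identical artifacts (checked in
the tests). One caveat on the KS type-I calibration: at n = 50 per group the
KS statistic is discrete (multiples of 1/50), so the achievable rejection
levels nearest 0.05 are ≈ 0.039 (exact p-values, used here) and ≈ 0.068;
the calibrated rate is therefore expected slightly below nominal.

# Known limitations

* No cell segmentation from raw images: masks and segment endpoints are
  inputs (or synthetic).
* No filament tracing from images: backbone coordinates are inputs.
* The peak detector cannot certify "zero contacts" on noisy profiles (see
  above).
* Absolute density values depend on detector parameters (prominence,
  separation, width) that the motivating procedure leaves unstated; the
  package documents its defaults and makes them configurable, claiming
  procedural fidelity rather than numeric reproduction of unpublished
  values.
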