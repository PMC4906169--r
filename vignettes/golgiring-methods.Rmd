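---
title: "Models and methods behind golgiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind golgiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgiring)
```

`golgiring` quantifies cellulose synthase complex (CSC) trafficking from
fluorescence and electron microscopy: the distribution of CesA cargo
within Golgi bodies (ring vs solid), object diameters, plasma-membrane
delivery rates from FRAP movies, migration speeds of membrane foci,
Manders co-localization, and the axial distribution of immuno-gold
particles. Because raw imaging data of this kind are rarely shareable, the
package treats validation as a first-class problem: every estimator has a
matched generator that simulates the same kind of data with known ground
truth, and the test suite is built around parameter recovery.

This vignette documents the models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic validation does
and does not demonstrate.

## Imaging model shared by all generators

All generators use a common optical/camera model (`imaging_params()`):

* **PSF**: isotropic Gaussian with FWHM 266 nm — the stated resolution
  limit of the emulated spinning-disc system. We deliberately do not model
  Airy rings or vectorial PSFs; at this resolution and SNR the Gaussian
  approximation is standard and differences are far below the noise.
* **Pixel size**: 133 nm/pixel, half the PSF FWHM, i.e. Nyquist sampling
  for a high-NA 100× system. The imaging system behind the emulation does
  not pin this number down, so it is configurable; every physical
  conversion takes it from configuration, never from TIFF tags (tag
  dialects are too unreliable to trust silently).
* **Noise**: Poisson noise on (signal + background) scaled by
  `photon_scale` (expected photons per intensity unit), plus additive
  Gaussian read noise — the standard EMCCD approximation. The default
  profile conditions (amplitude 100 a.u., background 10, `photon_scale`
  1, read noise 2) give a peak SNR near 10, a realistic mid-range value
  for live-cell spinning-disc data. Setting `photon_scale = 0` and
  `read_noise_sd = 0` turns generators exactly deterministic; noise never
  alters a ground-truth record.

Each generator takes an explicit integer seed and is bit-reproducible
given (spec, seed); seeding is local, so the caller's RNG state is left
untouched.

## Ring vs solid classification and the object diameter

A transect through a Golgi body's centre gives a 1-D profile sampled every
half pixel (66.5 nm). A ring of diameter D crosses the transect at two rim
points, modelled as Gaussians at ±D/2 with σ = FWHM/2√(2 ln 2) ≈ 113 nm
(the rim itself is sub-resolution, so its apparent width is the PSF's). A
solid body is a single such Gaussian.

`find_profile_peaks()` detects local maxima by topographic prominence.
The baseline is the mean of the outer 10% of samples; peaks must have
prominence of at least 20% of (max − baseline) and pairwise separation of
at least 200 nm. These two thresholds suppress, respectively, noise bumps
(at SNR 10 the noise is ~10% of the peak) and shoulder artefacts closer
than the resolution limit. One peak classifies the object as solid, two as
a ring; zero or three-plus peaks are "rejected" — the scheme only defines
the one- and two-peak cases, and population fractions are reported over
classified objects, matching how scored percentages are reported in
practice.

`fit_double_gaussian()` then fits

$$I(x) = b + A_1 e^{-(x-\mu_1)^2/2\sigma_1^2} + A_2 e^{-(x-\mu_2)^2/2\sigma_2^2}$$

by bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`,
cost tolerance 1e-8, at most 500 iterations). For rings the separation is
free (7 parameters). For solids the two components cannot be resolved, so
the separation is **fixed to the resolution limit R = 266 nm** by
reparameterizing with the common centre c: μ1 = c − R/2, μ2 = c + R/2
(6 parameters). The constraint therefore holds exactly by construction,
not approximately through a penalty. A baseline term is included even
though an idealized two-Gaussian description omits it: real profiles sit
on nonzero cytoplasmic background, and absorbing it into the amplitudes
would bias the widths.

Initialization uses the detected peaks (positions → μ, heights − baseline
→ A, σ = R/2.3548, outer-10% mean → b); with one peak the centres start at
the peak ± R/2. Bounds keep σ between one sample step and half the
window, μ inside the window, and A ≥ 0. Non-convergence is reported via a
flag, never by dropping the object. On noiseless double-Gaussian input the
fit recovers all seven parameters to better than 1e-4 relative error (an
exact-recovery oracle in the test suite).

The **object diameter** is defined as the separation plus the width of
each component:

$$D = (\mu_2 - \mu_1) + w_1 + w_2 .$$

"Width" is taken as the FWHM (2√(2 ln 2)·σ) by default — the conventional
meaning of a peak's width — with 2σ selectable (`width_definition =
"two_sigma"`); the identity D = separation + w1 + w2 holds exactly for
every returned result. Under this convention a generated ring of true
diameter D yields an expected recovered diameter of D + 2 × 266 nm (each
rim contributes one PSF FWHM of broadening); the recovery test asserts the
population mean against that expectation within 5%.

Transects can be drawn automatically: `segment_objects()` smooths,
thresholds (Otsu by default), labels connected components, and returns
intensity-weighted centroids plus the major-axis orientation from second
central moments; `extract_cross_section()` samples the image by bilinear
interpolation along that axis (pixel centres at integer indices). Manual
centroids/orientations are equally accepted, mirroring interactive
transect drawing.

## FRAP insertion events and the delivery rate

After photobleaching the plasma-membrane focal plane, newly delivered CesA
foci appear over a 10-min movie at 5-s intervals. `generate_frap_movie()`
draws insertion times from a homogeneous Poisson process with intensity
(rate × field area), uniform positions, and post-insertion straight-line
motion at the condition's migration speed; foci persist to the end of the
movie. One-frame "decoy" flashes (default density 1 per μm² per hour in
the presets) emulate transient non-delivery events — vesicles passing
through the focal plane — and exist precisely so the persistence criterion
has something to reject.

`detect_insertion_events()` scores a focus detection at frame t as an
insertion iff:

1. no detection lay within `r_excl` = 500 nm in the `k_before` = 2
   preceding frames (the neighbourhood must be devoid of particles before
   delivery), and
2. the particle can be followed (nearest detection within `d_max` =
   400 nm per step) for at least `k_after` = 4 subsequent frames — the
   characteristic tracking behaviour of a delivered complex; a one-frame
   flash fails this by construction.

Only the central subregion (movie cropped by 20% per side, 36% of the
area) is scored, to exclude complexes migrating in from outside the
bleached region. The exclusion radius, window lengths and margin are
declared operational choices — the qualitative criteria they implement do
not come with numbers — and all are configurable.

**Exposure correction.** Because delivered foci persist, criterion (1)
progressively masks the field: at the wild-type rate, ~25% of the central
area is within 500 nm of an existing particle by mid-movie, and a naive
n/(A·T) estimate is biased downward by the same amount (and worse at
higher rates, destroying linearity). The scorer therefore reports the
*effective* exposure Σ_t A_eff(t)·Δt, where A_eff(t) is the central-area
fraction not masked at frame t (computed on the pixel grid from the
detections in the k_before preceding frames), and the first k_before and
last k_after frames — where the criteria cannot be evaluated — are
excluded from the duration. `delivery_rate()` is then the exact
arithmetic n / (area × hours). With this correction the estimator is
unbiased (50-movie check) and linear in the true rate across 1–8
events·μm⁻²·h⁻¹ (slope within 1 ± 0.1).

A single 10-min, 400-μm² movie at the wild-type rate contains ~80 scored
events, so its rate estimate carries ~10% Poisson error (~17% for the
mutant); recovery checks therefore average a handful of seeded movies,
as cell-level replicates are pooled in practice.

## Foci tracking and migration speed

`detect_foci()` filters each frame with a zero-DC negative
Laplacian-of-Gaussian kernel at the PSF scale and takes strict local
maxima above a threshold, with sub-pixel refinement by separable quadratic
interpolation (≤ 0.25 px error on clean spots). For movies, the threshold
is set globally (a fraction of the maximum response over all frames) so
sensitivity does not drift with content.

`link_trajectories()` uses greedy nearest-neighbour assignment ordered by
distance (ties by lower track id), per-step distance ≤ 400 nm, gap
closing over one missed frame, and discards tracks shorter than five
detections. Global assignment (Hungarian/JV) would matter at high
densities; at the densities simulated here (≤ 0.05 foci/μm²) greedy
linking recovers ≥ 95% of tracks without identity swaps and is fully
deterministic.

`trajectory_speed()` offers two definitions, because the reference
implementations in commercial trackers are unspecified:

* **slope** (default): project positions onto the track's principal axis
  and take |slope| of projected position vs time. Localization noise adds
  zero-mean error to the projections and leaves the regression slope
  unbiased — the kymograph-slope analogue.
* **stepwise**: mean frame-to-frame displacement per time. At 5-s frames
  a 255 nm/min focus moves ~21 nm per step, while 50-nm localization
  noise contributes ~88 nm of expected step length; the stepwise mean is
  therefore biased upward several-fold under these conditions. It is
  provided for comparison, and the bias is demonstrated in the test
  suite.

Generated speeds are drawn from a normal distribution truncated at zero —
the natural reading of a reported mean ± SD on a nonnegative quantity.
Truncation shifts the realized mean slightly upward (≈ +2.8% at
255 ± 128 nm/min, ≈ +4% at 191 ± 92), which is visible in recovery runs
and is a property of the generative model, not estimator bias.

## Manders coefficients and the gold-periphery statistic

`manders()` computes thresholded Manders coefficients: M1 is the fraction
of channel-A intensity, summed over pixels where A exceeds its threshold,
that lies on pixels where B also exceeds its threshold; M2 swaps the
roles. Thresholds default to per-channel Otsu because manually chosen
thresholds are irreproducible; manual values are accepted for parity with
interactive workflows. A channel with no above-threshold signal yields NA
with a warning — never a silent 0. The coefficients are bounded in [0,1],
symmetric under channel swap, and invariant to positive rescaling of a
channel with its threshold; `generate_coloc_pair()` places a known
fraction of spots at identical positions in both channels so that, with
equal-intensity spots and no noise, M1 = M2 = overlap fraction.

`gold_relative_distance()` projects immuno-gold particle positions onto
the Golgi long axis (given endpoints, or the principal axis of an outline
polygon) and reports |s − L/2| / L ∈ [0, 0.5]. The "centre" is the
midpoint of the long axis — TEM sections of Golgi are strongly elongated,
making the axial midpoint the natural centre; a centroid-based centre
would differ only for asymmetric outlines. Particles projecting more than
5% of L outside the axis raise an error (they indicate a wrong outline)
rather than being clipped silently. For uniform positions the expected
relative distance is E|U − ½| = ¼, which the generator and statistic
reproduce to ±0.01 at n = 10⁴. `summarize_distribution()` reports median,
type-7 (linear-interpolation) quartiles — stated explicitly for
reproducibility — 1.5×IQR whiskers, and a kernel density, i.e. the
ingredients of a violin/box plot.

## Group comparison

`compare_groups()` reproduces the two-stage testing procedure used for
all pairwise comparisons: a two-sided F-test on the variance ratio
decides (at α = 0.05) between the pooled-variance Student t-test and
Welch's unequal-variance t-test, and the chosen two-tailed test is
applied. The implementation delegates to `stats::t.test()`/`var.test()`;
the test suite checks it against hand-coded textbook formulas to 1e-10 on
random samples.

## Presets and problem sizes

`preset()` pins the generator parameters to the reported population
values for the two genotypes: solid fractions 0.08 (n = 870) and 0.54
(n = 820) with ring diameters 800 ± 150 nm; delivery rates 4.8 and 2.2
foci·μm⁻²·h⁻¹ with the 5-s/10-min protocol over a 400-μm² field; speeds
255 ± 128 and 191 ± 92 nm/min over 30-frame tracks with 50-nm
localization noise. Where the emulated study reports no value (ring
diameter spread, noise levels, decoy density, track length), the preset
fixes one realistic value, documented here, and the tests use it
unchanged.

Validation problem sizes were chosen to keep the full suite to a few
minutes on one CPU while leaving Monte-Carlo error well inside each
tolerance: 200 seeds for Poisson-count checks, 50 movies for estimator
bias, 500 tracks for speed recovery, 10⁴ particles for the uniform-gold
mean.

## Limitations

* The generators emulate idealized data: Gaussian PSF, constant
  background, no photobleaching decay, no focal drift, straight-line
  motion, and isotropic localization noise. Passing recovery tests shows
  the estimators are correct under these conditions; it does not certify
  performance on real movies with drift, uneven illumination or
  microtubule-guided curved trajectories.
* Ring rendering assumes an infinitesimally thin rim (rim width below
  resolution); genuinely thick toroidal cargo would broaden the fitted
  widths beyond the PSF term.
* The classifier's rejected class (0 or ≥ 3 peaks) is excluded from
  fractions; under heavy noise this discards data rather than guessing.
* Greedy linking is adequate only at low foci density; crossing tracks at
  high density would need global assignment, which is out of scope.
* 3-D (z-stack) morphometry and deconvolution are out of scope; all
  measurements are 2-D.
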