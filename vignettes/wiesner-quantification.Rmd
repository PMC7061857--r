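---
title: "Quantitative Wiesner-stain imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative Wiesner-stain imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

The Wiesner test (phloroglucinol/HCl) stains coniferaldehyde residues in
lignified cell walls a deep purple. Under a Beer–Lambert reading of
brightfield micrographs, the stain-specific signal at each pixel is the
difference in optical density between a stained and an unstained frame of
the same section,

$$\Delta A = \log_{10}\frac{255}{\mathrm{pv}_{\text{stained}}}
           - \log_{10}\frac{255}{\mathrm{pv}_{\text{unstained}}},$$

with pixel values on the 8-bit scale and the grey intensity taken as the
mean of the RGB channels before the logarithm. `lignoquant` implements this
reading end to end — paired-image registration, absorbance-difference maps,
per-cell-type point sampling, cell-wall layer profiling, cell-to-cell
cooperativity networks, genotype statistics, spectral colorimetry, and
gel-permeation polymer metrics — together with a synthetic-section
generator that provides ground truth for every stage.

## The optical model and its assumptions

The model treats the stained pixel as the product of transmittances:
an achromatic wall baseline (unstained walls are visible — wall material
refracts and absorbs light), an optional residual background pigment, and
the stain itself, a single optical-density direction in RGB space set by
the chromophore hue (~310°, magenta-purple). Assumptions worth keeping in
mind:

* **Linearity.** Absorbance adds along the light path; there is no
  scattering model. This matches the subtraction logic of the difference
  map but ignores section-thickness effects beyond a scalar.
* **Luminance collapse.** Quantification happens on the grey intensity.
  The generator scales the chromatic stain vector so that the *grey*
  absorbance of a rendered pixel equals the encoded truth exactly, which
  makes `difference_map()` the exact inverse of `render_pair()` up to 8-bit
  quantisation.
* **Scalar background adjustment.** A non-lignified reference region
  (phloem in real sections, the empty background in synthetic ones)
  defines a single offset subtracted from the whole map. Lamp drift
  between frames is removed by this; spatially varying illumination is
  deliberately out of scope.

## What the generator emulates — and what it does not

`section_spec()`/`render_pair()` draw annular cells on a jittered lattice;
tangent rings share boundary pixels, which serve as the compound middle
lamella and define adjacency. Defaults, with units and reasons:

| parameter | default | why |
|---|---|---|
| pixel pitch | 0.179 µm/px | makes a 12-px circular point 0.7 µm across, the sampling design used for herbaceous sections |
| poplar pitch | 0.5 µm/px | wood is imaged at lower magnification; keeps three 50-µm development bins inside one field |
| `unstained_od` | 0.15 | unstained walls are clearly visible in brightfield; also gives registration its landmarks; cancels exactly in the subtraction |
| `wall_texture_cv` | 5 % | real walls are optically heterogeneous; the texture also dithers 8-bit quantisation so that mean absorbance survives rounding (without it, a uniform A = 2 wall quantises to a ~0.07 bias; with it, < 0.002) |
| `noise_sd` | 0 (2 in the study conditions) | i.i.d. Gaussian sensor noise on 8-bit values, clipped to [0, 255] — the simplest model that exposes the quantisation floor |
| stain hue | 310° | the purple chromophore |
| wild-type type scale | MX = XF = 1, IF = LP = 0.5, PX = 0.25 | the herbaceous wild-type contrast pattern |
| poplar type scale | vessel = 1, ray = 0.75, fiber = 0.5 | the wood wild-type contrast pattern, plus a mild developmental gradient (0.85→1.15 with cambium distance) |

The generator does **not** attempt photorealism: no vignetting, no
chromatic aberration, no polarisation, no 3-D sectioning, no morphological
realism beyond adjacency. Passing tests therefore show that the *analysis*
is correct under the stated optical model and noise; they cannot certify
camera calibration or segmentation quality on real micrographs (cell-type
labels are inputs here, as they were manual annotations originally).

## Registration

Stained and unstained frames differ *because of the stain*, so raw
intensity metrics are invalid between them. Both the rigid and the elastic
stages therefore match **gradient magnitude** images (edges move with the
tissue; their position does not depend on staining): phase correlation over
a coarse rotation grid initialises a Nelder–Mead refinement of
(dx, dy, θ) on a normalised-correlation cost. On clean synthetic pairs the
recovery error is ≤ 0.03 px and ≤ 0.01°; at 5 grey levels of sensor noise
it stays below 0.1 px — comfortably inside what the 12-px point sampling
can tolerate. The elastic stage estimates a smooth displacement field by
per-block Lucas–Kanade flow on a 10 × 10 control grid (28-px blocks),
inverse-distance-fills textureless blocks, smooths, and composes up to
three match–warp–re-match iterations with an early stop once increments
fall below 0.3 px. On a 2-px sinusoidal warp the corrected residual sits
at the bilinear-interpolation floor (~0.33× the uncorrected one).

## Wall layers

The double wall between two cells is split by a mixed scheme: CML = the
central 500 nm, S1 = the adjacent 500 nm on each side (absolute bands),
S2 = 0.1–0.35 and 0.65–0.9, S3 = 0.02–0.1 and 0.9–0.98 of the
range-normalised width. The scheme mixes absolute and fractional claims,
so overlaps are resolved by precedence: absolute bands (the more specific
claim) beat fractional ranges, S3 beats S2 at range edges, and the
mid-zone between the S2 ranges but outside the absolute bands is labelled
S1 by contiguity. Only the outermost 2 % on each side may stay
unassigned, so coverage is ≥ 96 % on walls ≥ 3 µm wide. Transects are
sampled at half-pixel spacing (Nyquist-safe for 500-nm bands at ~0.18-µm
pixels) and rejected when the two single-wall widths differ by more than
20 % — the operational form of "equal width on both sides".

The profile generator lays truth down with the same scheme, then applies a
0.15-µm Gaussian optical blur (a 0.75 NA objective at 550 nm) and additive
noise. The blur matters: it smears the narrow CML band into S1, so an
encoded +25 % CML change reads back as ~+22 %. That attenuation is a
property of the measurement physics, not a bug; the layer-recovery checks
carry an 8-point tolerance for exactly this reason.

## Cell-to-cell cooperativity

For a directed pair B → A, measurements of A's walls adjacent to B and
adjacent to A itself are averaged per sample unit (genotype × replicate;
replicate-level units maximise n, genotype is retained as a column).
Then

$$\Delta r = r(\bar{A}_{\text{adj }B},\ \bar{B}) -
             r(\bar{A}_{\text{self}},\ \bar{B}),$$

two dependent Pearson correlations sharing B's series. Significance uses
Williams' t (the Steiger form) with n − 3 degrees of freedom, the
between-series correlation estimated empirically from the two A-series.
Simulated level at n = 30 over 2000 null replicates: 0.050. The relative
impact is the per-genotype fold change mean(A adj-B)/mean(A adj-self),
averaged across genotypes. Edges with zero variance are reported as
undefined, not dropped. Per the original analysis design there is **no**
cross-edge multiplicity correction; with six directed edges at α = 0.05
that leaves a ~20 % chance of at least one false-positive edge per
network, so single-edge claims are reliable but whole-network sparsity is
not — a known property of the design, not of this implementation.

## Statistics

Tukey-HSD letters (one-way ANOVA, insert-and-absorb letter assignment) are
computed on replicate means; pixel-level pooling is reserved for the layer
panels, which instead use pairwise Kruskal–Wallis with Holm adjustment —
pixel distributions within layers are skewed and enormous, so rank tests
are the defensible choice there. Hierarchical clustering of genotypes uses
each trait's difference from the wild type, range-normalised per column,
Euclidean distance, and average linkage (unstated upstream; average
linkage is the common default for trait profiles and is recorded in the
output metadata). PCA is column-centred but not variance-scaled — inputs
already share ΔA units. Data ellipses are bivariate-normal quantile
ellipses at 95 %.

## Colorimetry

Hue of an absorbance spectrum: transmittance 10^−A is integrated against
the CIE 1931 2° observer — implemented as the published analytic
multi-lobe Gaussian fits, accurate to ~1 %, keeping the package free of
embedded spectral tables — under an equal-energy illuminant with von Kries
white-point normalisation; after normalisation the hue of smooth absorbers
is nearly illuminant-independent (a flat spectrum maps exactly to white),
and a measured illuminant SPD can be supplied as a vector. sRGB conversion
clips out of gamut before HSV, as any 8-bit camera pipeline does.
Saturation below 0.05 is declared achromatic — hue is meaningless near the
grey axis. Colour deconvolution fixes the primary stain vector (from its
hue at reference saturation 0.8, value 0.5) and constructs the
complementary vector orthogonal to it within the plane spanned by the
primary and the image's mean OD direction. The complement is kept exactly
orthogonal even when a component is negative, because a strictly positive
primary admits no non-negative orthogonal vector: clamping (available via
`clamp_negative = TRUE`) would silently break the unmixing identity.

## Polymer metrics

`gpc_metrics()` computes Mp, Mn = ΣNM/ΣN, Mw = ΣNM²/ΣNM and PDI = Mw/Mn
from a number-weighted distribution; a signal-weighted (RID) trace is
converted by N ∝ signal/M, and the mode must be stated because the wrong
one silently biases Mn. `condensation_fraction()` reproduces the canonical
back-calculation: a weight-average shift from 1595 to 2431 Da with 160-Da
residues and 125-Da adducts gives 67 %. Note the caveat this inherits: the
arithmetic applies number-average logic to weight-average masses; the
function reproduces the printed calculation and this paragraph documents
the approximation.

## Numerical choices and degenerate inputs

* `pixel_to_absorbance(0)` clips to pixel value 1 (A ≈ 2.407) rather than
  diverging.
* Distance-to-cambium bins are half-open on the left ([0, 50), [50, 100),
  [100, ∞) µm) — the printed bins share endpoints and need a convention.
* Circular points are the `area_px` pixels nearest the centre with a
  deterministic tie-break; placement within wall masks is seeded-random
  and non-overlapping (the original placement was manual; seeding keeps
  the same intent reproducible).
* A single global seed fans out to every stage through
  `derive_seed(seed, stage)`, so one integer reproduces the whole run;
  the pipeline manifest records the MD5 of every output.
* Letters displays sort groups by decreasing mean with the label as
  tie-break, making them independent of input order.

## Problem sizes

The shipped checks run five sections per scenario with 50 points of 12 px
(herbaceous) or 20 points of 5 px (wood) per cell type, 50 wall profiles
per layer scenario, 2000 replicates for test-level simulations and 20
seeded runs for power checks — sizes chosen so the whole suite documents
the method's behaviour in minutes on a laptop while keeping every
Monte-Carlo margin well away from its threshold.

## Known limitations

Labels are inputs — no automatic cell-type classification. Illumination is
assumed flat apart from a scalar drift. The cooperativity model is the
printed correlation construction, not a transport model; the reading of
"correlation between two cell types when adjacent to themselves" follows
one consistent interpretation (both correlations taken against the source
type's series, differing only in the target's context) among the two the
phrasing admits. Real-tissue hues and correlation panels depend on the
original micrographs and are checked here only as range and property
assertions on synthetic data.
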