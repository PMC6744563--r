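---
title: "msiclust: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msiclust: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiclust)
```

## What the package computes

msiclust analyses MALDI imaging mass spectrometry (IMS) datasets — one
centroided positive-mode spectrum per pixel of a tissue raster — without any
anatomical supervision. The pipeline has six stages:

1. **Average spectrum and peak picking.** All pixel spectra are binned
   (default 0.001 Da) and averaged; peaks are local maxima of the average
   spectrum with signal-to-noise ≥ 10, and maxima closer than 0.2 Da are
   merged keeping the more intense.
2. **Ion images.** For each picked peak, the per-pixel maximum intensity in
   the interval ±0.004 Da around the peak centre.
3. **Screening.** Ion images are kept as biomolecule distributions when
   their mean intensity inside a tissue ROI exceeds the outside mean by a
   configurable enrichment factor (default 2); images brighter off tissue
   are off-tissue artefacts, images with near-equal means are homogeneous
   artefacts (matrix and chemical background).
4. **Spatial PCA.** The pixels × images stack, one column per ion image, is
   centred and scaled to unit variance; the top 5 principal components are
   computed. The score maps are spatial images (grey matter, fibre tracts
   and homogeneous background typically dominate the first components in
   brain sections); the contribution of component $k$ is
   $\lambda_k / \sum_j \lambda_j \times 100$, with
   $\sum_j \lambda_j = p$ for a correlation matrix of $p$ images.
5. **Similarity grouping.** Pairwise cosine similarity
   $s_{ij} = x_i^\top x_j / (\lVert x_i\rVert \lVert x_j\rVert)$ over ROI
   pixels; average-linkage (UPGMA) hierarchical clustering on $1 - s$;
   molecule groups are the dendrogram clusters cut at distance
   $1 - 0.5 = 0.5$ with at least 7 members (diagonal blocks of the
   reordered heat map), plus off-diagonal groups joining tight sub-blocks
   of different clusters whose mean cross-similarity exceeds 0.5.
6. **Annotation.** Picked m/z values are matched against a
   glycerophospholipid library over the adducts [M+H]⁺, [M+NH4]⁺, [M+Na]⁺
   and [M+K]⁺ within 10 ppm, and isotopologue series spaced ≈ 1.0034 Da
   are detected and scored against theoretical isotope envelopes.

## Annotation arithmetic

Lipid shorthand (e.g. `PS(39:0)`: a phosphatidylserine with 39 acyl
carbons, 0 double bonds) is expanded by diacyl head-group rules —
PS(c:d) = C(c+6) H(2c+10−2d) N O10 P and analogously for PA, PC, PE, PG,
PI — and summed over monoisotopic atomic masses:

```{r}
round_half_up(monoisotopic_mass("PS(39:0)"), 4)
round_half_up(adduct_mz(monoisotopic_mass("PS(39:0)"), "[M+H]+"), 4)
```

Three deliberate conventions deserve explanation:

* **Adduct masses add neutral atoms.** The default (`"neutral"`) convention
  adds the monoisotopic mass of H, NH4, Na or K without subtracting the
  electron mass. This is how four-decimal adduct masses are conventionally
  printed in FT-ICR lipid tables; the physically exact cation m/z
  (`convention = "electron"`, 0.00055 Da lighter) is available for users
  who need it.
* **Two isotope models.** The `"carbon"` envelope model is a carbon-only
  binomial with ¹³C fractional abundance 1.07%: the k-th isotopologue has
  relative abundance $\binom{n_C}{k} r^k$, $r = 0.0107/0.9893$, spaced at
  the printed 1.0034 Da. It is the model under which phospholipid
  envelopes round to integer triples such as 100/49/12. The `"full"` model
  convolves the complete natural-isotope tables of C, H, N, O, P, S, Na
  and K and aggregates to nominal-mass centroids; it is validated in the
  tests against exhaustive enumeration of all isotope placements for small
  molecules.
* **ppm against printed precision.** `assignment_table()` rounds
  theoretical m/z to 4 decimals *before* computing the ppm delta, and it
  computes isotopologue masses with the exact ¹³C shift (1.0033548 Da)
  rather than the display value. Both choices reproduce published
  assignment tables to the printed digit; raw `ppm_error()` is available
  when full precision is wanted.

The 10 ppm matching threshold is applied per candidate. Observed ions can
legitimately sit slightly beyond the threshold when they are isotopologues
of an accepted monoisotopic hit; callers following that convention filter
`assign_candidates()` on `isotopologue == 0` and propagate the series.

## Peak picking details

The literature rarely defines the noise term of an S/N threshold. msiclust
uses 1.4826 × the median absolute deviation of the spectrum's intensities
after discarding the top 5% — a robust floor estimate that ignores the
sparse true peaks, making picking invariant to uniform intensity scaling.
A zero estimate (e.g. an isolated spike over an empty baseline) disables
the threshold rather than dividing by zero. Whether a stated "width" is a
merge radius or an integration width is ambiguous in most vendor software;
msiclust implements it as a merge radius (closer maxima collapse to the
most intense, ties to lower m/z) and keeps the interval ±0.004 Da as the
separate ion-image integration window.

## The phantom: what it emulates and what it does not

Real IMS reference datasets are rarely deposited, so every stage is
validated against a synthetic *brain phantom*: an elliptical tissue area on
a rectangular raster (default 64 × 48 pixels at a nominal 50 µm pitch)
partitioned into grey matter, a fibre-tract band, a cerebellar-cortex
disc, a brainstem disc and an off-tissue margin. A ground-truth manifest
assigns each planted molecule a spatial archetype, 1–2 adducts and a base
intensity; rendering emits one peak per isotopologue per adduct per pixel
with intensity `base × template(pixel) × envelope fraction`, multiplied by
mean-one log-normal noise (default sdlog 0.25), plus Poisson spurious
peaks (default 3 per spectrum, exponential intensity with mean 2) at
uniform random m/z in 700–900. All randomness derives from one seed and
rendering is bit-reproducible.

Design choices worth knowing:

* **Disjoint archetype supports.** The ten molecule-group archetypes are
  rendered on mutually disjoint sub-regions (grey matter split into six
  anterior→posterior bands; the fibre tract into two halves; cerebellar
  cortex; brainstem), each modulated by a smooth ±20% left-right gradient.
  In real data some groups overlap spatially (e.g. genuinely homogeneous
  molecules overlap every region); such overlapping distributions have
  cosine similarity well above 0.5 with region-confined ones and are *not*
  separable by a 0.5 threshold — no clustering method could recover them
  as distinct groups. The phantom therefore plants distributions that are
  identifiable by construction: recovery tests demonstrate that the
  pipeline finds structure that is present, not that every real mixture is
  resolvable. Homogeneous-everywhere signal is still exercised through the
  `artefact_homogeneous` archetype, which the screening stage must remove.
* **Centroided rendering.** Spectra are emitted as peak lists, matching
  FT-ICR peak-picked output; profile-mode rendering (peak shape, mass
  jitter) is out of scope, so mass-accuracy aspects of picking are tested
  only through binning (≤ 0.0005 Da quantisation).
* **Noise defaults** were chosen once for testability: spurious peaks are
  sparse enough that the average spectrum's noise floor sits orders of
  magnitude below planted peaks, while still producing junk local maxima
  that exercise S/N thresholding and screening. No attempt is made to
  model matrix-cluster chemical noise.

## Recovery experiments

The test suite and `scripts/acceptance.R` run three seeded experiments on
the 64 × 48 phantom:

* **PCA recovery.** Three archetypes planted with unequal multiplicities
  (20/12/6 molecules at low noise). Unequal block sizes separate the top
  three eigenvalues, so each score image aligns with one spatial template
  (|r| ≥ 0.9). With equal blocks the leading eigenspace is nearly
  degenerate and score images mix templates — a property of PCA, not a
  defect of the implementation.
* **Clustering recovery.** Ten archetypes × 6 molecules under default
  noise; recovered diagonal groups are compared with the manifest by the
  adjusted Rand index (≥ 0.9 required; typically 1.0). Picked peaks are
  mapped back to planted molecules within 0.005 Da, and matches with
  another molecule's peak within 0.01 Da are excluded as isobaric — the
  same exclusion an analyst applies to ambiguous ions.
* **Screening.** Forty tissue molecules plus 13 homogeneous and 13
  off-tissue artefacts; all artefact-derived images must be discarded and
  at most 5% of biomolecule images may be lost.

Experiment species are drawn from the bundled library with
`select_spaced_species()`, which enforces ≥ 0.5 Da between isotopologue
footprints so that peak merging (0.2 Da) and window sharing (±0.004 Da)
cannot conflate molecules — recovery then measures the pipeline, not
accidental isobaric collisions.

## Numerical choices and degenerate inputs

* PCA uses a deterministic SVD (no randomised solver); component signs are
  fixed by making the largest-magnitude loading entry positive, so results
  are bit-reproducible. Constant (zero-variance) images abort with the
  offending image's label.
* Group extraction cuts the dendrogram by walking the merge list rather
  than `cutree()` on heights, because tied average-linkage heights can be
  non-monotone by floating-point epsilon.
* The cosine matrix clamps values to ≤ 1 against rounding overshoot;
  zero-norm images are an error naming the image.
* The minimum group size default is 7 *inclusive*: published group tables
  include 7-member groups even where the accompanying prose says "more
  than seven", and the inclusive reading matches the data. The knob is
  exposed.
* Empty spectra, empty phantoms and empty group lists are valid inputs
  throughout (an empty occupancy table reports a grouped total of 0).

## Problem sizes

Tests and the acceptance script run the full pipeline on a 64 × 48 grid
with up to 100 molecules (≈ 3,000 spectra, ≈ 200 picked peaks), which
completes in a few seconds on one CPU; the recovery experiments use 38–66
molecules each. These sizes were chosen to exercise every code path at
comfortable margins; nothing in the implementation is specific to them,
and `run_pipeline()` accepts arbitrarily larger grids.

## Known limitations

* The screening surrogate is a mean-enrichment rule standing in for what
  is, in practice, manual curation; its threshold (default 2) is reported
  in every `screen_report` for audit.
* Annotation is restricted to diacyl glycerophospholipids under four
  positive adducts; ether lipids, MS/MS-based identification and
  negative-ion mode are out of scope.
* imzML support covers continuous and processed mode with uncompressed
  32/64-bit float arrays; vendor raw formats are not read.
* The phantom does not model profile peak shapes, mass-axis jitter or
  matrix-cluster noise; conclusions about real-data mass accuracy and
  chemical background must come from real data.
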