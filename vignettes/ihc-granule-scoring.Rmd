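---
title: "Methods: nuclear granule scoring and vessel density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear granule scoring and vessel density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcscore)
```

## The measurement problem

Nuclear localisation of the hypoxia-inducible transcription factor
subunits HIF1&alpha; and HIF2&alpha; indicates stabilised,
transcriptionally active protein. In chromogenic immunohistochemistry
(AEC chromogen over a hematoxylin counterstain) the stabilised protein
appears as discrete red-brown granules inside epithelial nuclei. The
quantity of interest per tissue specimen is its *immunoreactivity*: the
percentage of counted epithelial cells whose nuclei carry a granule
load above a positivity criterion. Cohorts of pterygium specimens
(primary and recurrent) and healthy conjunctival controls are then
compared on these percentages.

`ihcscore` implements that measurement chain end to end, together with a
second, independent image pipeline that measures vessel-pixel density in
colour photographs, and the statistics used to compare groups.

## Scoring model

**Focus stacking.** Granules sit at different depths in a 4 µm section,
so a single focal plane misses some of them. Micrographs taken at
several focus levels are collapsed into one all-in-focus image by
per-pixel *plane selection*: each pixel takes its value from the plane
maximising the local variance of a 3×3 Laplacian response within a 9×9
window (`fuse_stack()`). Selection rather than averaging is deliberate —
the downstream task is counting discrete granules, and any blending
would dilute granule contrast. Ties resolve to the lowest plane index,
and the chosen plane per pixel is kept as a provenance map. Planes are
assumed coarsely aligned; no registration is attempted.

**Detection.** Nuclei are detected on a counterstain score (blue minus
red channel): threshold (default 0.12), hole filling (granules puncture
the nuclear mask), morphological opening, then a watershed on the
distance map to separate touching nuclei, and an area filter
(15–120 µm²). Granules are detected inside each nucleus mask on the
chromogen score (red minus blue): connected components above a
threshold of 0.06, which is the midpoint between the nuclear-background
and granule-core values of that score, so the detected contour is the
50% coverage contour of a granule disk and the equivalent circular
diameter `2*sqrt(area/pi)` is measured without systematic bias.
Components below 0.6 µm equivalent diameter are discarded as pixel
noise.

**Classification.** Granule diameters of 1.2–1.6 µm count as *small*
and above 1.6 up to 2.2 µm as *large*; 1.6 µm itself is small. Each
nucleus receives one of five patterns: few small (1), numerous small
(2), few large (3), numerous large (4), no granules (5). Patterns
collapse into four categories — 5 and 1 share category 1; 2, 3, 4 map
to categories 2, 3, 4 — and a nucleus is *positive* if its category is
2–4. Specimen immunoreactivity is 100 × positives / counted non-goblet
nuclei. Goblet cells are excluded from both numerator and denominator.

Three boundary decisions in this taxonomy are genuinely open and are
fixed as follows, each overridable in configuration:

* *Few vs numerous*: no count threshold is standard; we use
  `few_max = 4` (at most four granules is "few").
* *Mixed loads*: the taxonomy defines pure patterns only; a nucleus with
  both sizes is classified by its large granules (large dominates),
  which is the least surprising completion.
* *Out-of-range sizes*: below 1.2 µm is treated as noise; above 2.2 µm
  is flagged `over_range` and ignored by default (strict reading of the
  defined classes), with `over_range_as_large = TRUE` available.
* *Diameter definition*: "diameter" is read as equivalent circular
  diameter, not longest axis — an interpretation, since granules are
  rendered and detected as near-circular blobs.

Reporting conventions mirror standard practice in this literature:
positive-specimen fractions round half-up to integers
(`positive_fraction(28, 55)` is 51), and marker ratios are given at two
significant figures (`mean_ratio(38, 11)` is 3.5). Statistics run on the
exact (unrounded) per-specimen percentages.

## Group comparison

Specimen positivity percentages are summarised per group as mean ±
sample SD, and all group pairs are compared with Tamhane's T2 procedure
(`tamhane_t2()`): a Welch t statistic per pair,

$$t_{ij} = \frac{\bar x_i - \bar x_j}{\sqrt{s_i^2/n_i + s_j^2/n_j}},$$

with Welch–Satterthwaite degrees of freedom, and the Šidák family-wise
adjustment $p_\text{adj} = 1 - (1-p)^m$ over the $m = k(k-1)/2$ pairs.
Šidák rather than Bonferroni is what defines T2 as opposed to Tamhane's
other procedures. The procedure needs no equal-variance or equal-n
assumption, which matters here: group sizes such as 55/6/20 with SDs of
20/36/30 are exactly the regime it was designed for. The significance
flag is strict (`p_adj < alpha`); a pair with zero standard error is
degenerate and reports p = 1 for equal means, p = 0 otherwise.
Correlation checks between measures use Pearson and Spearman
(`marker_correlation()`); the method choice is ours, as none is standard
for this kind of null check.

Per-category marker comparisons (HIF2&alpha; vs HIF1&alpha; within
category 2, 3 or 4) are two-group comparisons of the same form; we treat
them as separate comparisons rather than one joint model, since only
pairwise results are of interest.

## Vessel density

Red vessels on a pale conjunctival background are segmented by:
green-channel extraction with polarity inversion (red structures absorb
green, so vessels become bright), high-pass filtering as an unsharp
residual (image minus a Gaussian blur, σ = 20 px), linear contrast
stretch, an h-dome morphological reconstruction, a second stretch, and
an Otsu threshold computed from ROI pixels only. The vessel fraction is
vessel pixels over ROI pixels.

The h-dome transform extracts connected peak regions of height at most
*h*: `image - reconstruct_dilate(image - h, image)`, computed by
greyscale reconstruction-by-dilation (fast-hybrid algorithm, in C++).
Two numerical properties matter downstream: the dome is bounded by
\[0, h\] and is invariant to constant offsets. The dome height default
is `h = 0.5` of the post-stretch range: vessels form one connected
network of varying brightness, and the reconstruction climbs along the
network, so any dome of height *h* keeps only the top *h* slice of the
network — *h* must exceed the brightness variation along the vessels
or dimmer segments are clipped. With the background already flattened
by the high-pass step, a generous *h* costs nothing in specificity.
Both contrast steps are plain linear stretches to full range; where the
processing chain leaves freedom in their form, the simplest choice is
taken and exposed.

A vessel-free image would have its noise stretched to full range and
bisected by Otsu, so the pipeline declares an image vessel-free
(fraction 0) when the high-pass image's dynamic range inside the ROI is
below `min_contrast = 0.15`; this noise floor is documented behaviour,
not an error.

## What the synthetic data emulates

The generator (`generate_cohort()`, `generate_vessel_image()`) exists so
that every stage can be validated against known truth without any
external image. It emulates, per specimen, one epithelial field at
0.25 µm/pixel (about 400× magnification) with 25–35 cells:

* counterstained nuclei (radius 3–5.2 µm) as blue-violet blobs;
* intranuclear chromogen granules as red-brown disks, each sharp in
  exactly one of three focus planes and defocus-blurred elsewhere
  (Gaussian, σ = 2.5 px per plane step), giving the focus-stacking step
  a real signal;
* goblet cells (10% of cells) as larger, faintly stained, granule-free
  blobs that stay below the counterstain threshold, plus an explicit
  truth flag;
* a faint uniform cytoplasmic wash and Gaussian pixel noise
  (SD 0.02).

Per-specimen true positivity is drawn from a truncated normal on
\[0, 100\] with the group's mean and dispersion — matching mean ± SD
reporting without asserting a distribution the data do not constrain.
Note that truncation shifts the distribution mean away from the nominal
location parameter (location 11, SD 20 truncates to a mean near 20.7);
recovery tests therefore compare against the analytic truncated mean or
the cohort's realized ground truth, never the nominal location. Each
non-goblet nucleus is then positive with that probability, positive
nuclei drawing pattern 2, 3 or 4 uniformly and negative nuclei pattern
1 or 5. The stored truth (pattern, category, per-specimen positivity)
is recomputed from the granules actually placed, so truth is consistent
with the classification rules by construction, and realized positivity
equals the category bookkeeping exactly.

Two rendering choices are *detectability by design* and should be kept
in mind when interpreting passing tests. True granule diameters are
drawn with a margin inside their class (small from 1.25–1.55 µm, large
from 1.7–2.2 µm): at 0.25 µm/pixel an equivalent diameter is measured
to about ±0.05 µm, so truth exactly at the hard 1.2 µm boundary would
be lost to the sub-threshold cut at a rate no classifier could control.
Likewise granules are placed without contact (wider separation in
"few" nuclei), and nuclei that must hold "numerous" granules are drawn
larger. Real tissue offers no such guarantees — overlapping granules,
stromal background, section artefacts and uneven staining are all
outside what these tests demonstrate. Passing the synthetic suite shows
the chain is correct and unbiased under its stated model, not that it
matches a pathologist on real slides.

Vessel images are jittered random-walk strokes (width 3–6 px) stamped
onto a pale background until the vessel mask covers the requested ROI
fraction; stamping stops pixel-by-pixel at the target, so the realized
fraction is exact to well under the ±2 percentage-point contract.
Targets above 0.6 are refused as unreachable for curvilinear strokes.

## Problem sizes and reproducibility

Everything is deterministic given seeds: specimen images in
`(seed, specimen index)`, vessel images in their seed. The validation
suite runs, among others: full enumeration of all granule
configurations up to 20 small and 20 large; 50 random 32×32 images
against a pure-R geodesic-dilation fixpoint oracle for the h-dome; a
2,000-replicate null simulation (equal means, SDs 20/36/30,
n = 55/6/20) bounding the family-wise error at 0.06; 500
distribution-scale replicates of the cohort draw establishing ≥ 80%
power for the primary-vs-control comparison; and one full 81-specimen
image cohort scored end to end, with group means recovered within three
standard errors. Module tests use reduced cohorts (about 7 specimens,
192 px fields, 8–10 cells) so the default suite stays fast; the sizes
above are the package's chosen validation scale.

## Known limitations

* The fusion step claims equivalence to focus-stacking tools only at the
  level "granules from all focus levels appear in one image", not
  bit-level reproduction of any particular software.
* Epithelium-vs-stroma segmentation is out of scope; fields are assumed
  purely epithelial. Cytoplasmic staining is deliberately not
  quantified.
* Goblet-cell exclusion relies on their weak counterstain or on an
  annotation table; strongly counterstained goblet cells in real tissue
  would need annotation.
* One field per specimen is the default (a per-specimen field count is
  not standardised); scoring multiple fields and pooling records is
  possible through the API.
* The h-dome of a connected structure is a *relative* top slice; with a
  small `h` it is not a vessel segmenter. The default documented above
  reflects that.
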