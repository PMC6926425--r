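---
title: "Scoring arrayed CRISPR screens: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring arrayed CRISPR screens: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayscreen)
```

## The analysis problem

In an arrayed CRISPR knockout screen every well of a multi-well plate
receives one known guide RNA, so phenotypes can be read well by well —
here by two readouts: an ATP-dependent luminescence viability assay, and
fluorescence microscopy of knockout phenotypes (marker loss, nuclear
enlargement, Golgi fragmentation). Each plate also carries four kinds of
control wells:

* **mock** — no-transfection wells defining 100% viability,
* **blank** — empty wells defining the instrument background,
* **scrambled** — non-targeting guides, the "no effect" distribution,
* **positive controls** — guides against an essential gene (POLR2A is
  the canonical choice); its knockout kills most cells and defines the
  "lethal" distribution.

`arrayscreen` implements the full desk-side analysis: normalization of
raw luminescence into relative viability, a likelihood-ratio LOD score
per gene knockout with control-based quality control, image
quantification for the microscopy readouts, and a protein-turnover
"targetability" classifier. A seeded synthetic-data generator emulates
plates, screens, microscopy fields and turnover tables with known
ground truth, so every stage is testable without laboratory data.

## Viability normalization

Raw luminescence is processed per plate:

1. **Background**: the mean raw luminescence of the plate's blank wells
   (an explicit override is accepted; with neither, background falls
   back to 0 with a warning). The assay does not define how background
   should be measured, so designating blank wells keeps the estimate
   auditable.
2. **Relative viability**: for each well,
   `v = max(0, raw − background) / mean(raw − background over reference wells)`,
   where the reference is either the mock or the scrambled wells of the
   *same plate*. Per-plate referencing absorbs plate-to-plate assay
   drift; no spatial (edge-effect) correction is attempted because the
   screens this models did not use one.

Negative background-subtracted values are clamped to 0 and flagged
`clamped_negative` — viability cannot be negative, and the flag
preserves the information for QC. Wells present in the plate map but
missing from the readout are kept with `NA` and flagged, not errored:
real plates have failed wells. Two invariants follow directly from the
construction and are asserted in the tests: reference wells average to
exactly 1, and a global rescaling of all raw values leaves every
normalized viability unchanged.

Replicate wells are summarized per guide by the mean and the sample
(n−1) standard deviation — control sets are small, so the unbiased
estimator matters.

## The LOD score

The score of a guide compares two hypotheses for its mean normalized
viability $x$: that it behaves like the positive (lethal) control, or
like the scrambled (neutral) control. Both control sets are modelled as
normal distributions fitted by sample mean and standard deviation,
$\mathcal{N}(\mu_+, \sigma_+)$ and $\mathcal{N}(\mu_-, \sigma_-)$, and

$$\mathrm{LOD}(x) \;=\; \log_{10}
\frac{\varphi(x;\,\mu_+, \sigma_+)}{\varphi(x;\,\mu_-, \sigma_-)},$$

with $\varphi$ the normal density. A LOD of 3 means the lethal model is
1,000 times more likely — the classical linkage-analysis significance
value — and hits are called at LOD ≥ 3 (inclusive; a likelihood ratio
of exactly 1,000 is significant). No multiple-testing correction is
applied on top: the LOD threshold is the sole calling rule.

With equal control variances $\sigma$ the score has a closed form,

$$\mathrm{LOD}(x) = \frac{(x-\mu_-)^2 - (x-\mu_+)^2}
{2\sigma^2 \ln 10},$$

which is linear in $x$, antisymmetric under swapping the control roles,
and strictly decreasing in viability when $\mu_+ < \mu_-$. These
properties are asserted numerically in the test suite and make the
density form the package default. A second variant replaces the
densities with lower-tail cumulative probabilities
(`method = "cdf_tail"`); it scores how deep into the lethal tail a
value lies and is provided because screening workflows sometimes frame
the score through the cumulative distribution. Both probabilities are
floored at `1e-300` before the ratio so extreme values yield large
finite scores rather than infinities; the floor never affects rankings.

Guides are scored on their per-guide mean normalized viability (one
score per gene knockout); a per-well score can be obtained by passing
per-well values instead.

### Control quality control

High LOD scores are only attainable when the control distributions are
narrow and well separated, which doubles as a screen QC rule. The
fitted `control_model` carries the separation
$(\mu_- - \mu_+)/\text{pooled sd}$ and one-sample Kolmogorov–Smirnov
p-values of each control set against its fitted normal. `screen_qc()`
fails a screen when separation < 3 pooled standard deviations (default)
or when either KS p-value falls below α = 0.01. The KS test is run with
estimated parameters and without a Lilliefors correction, which makes
it conservative; it is reported as a diagnostic, not an inferential
claim, and the tests verify that genuinely normal controls are flagged
at well under the nominal rate.

Replicate concordance (Pearson and Spearman correlation of per-guide
means across two replicate experiments) is computed on the shared guide
set and emitted as a paired table for the replicate-vs-replicate
scatter.

## Image phenotyping

Nuclei are segmented from the nuclear-stain channel by median filtering
(radius 2 px default), Otsu's global threshold, hole filling, and a
watershed on the distance transform to split touching nuclei; objects
outside the area bounds (default 50 px to ∞) or touching the image
border are discarded. "Automated thresholding" is fixed to Otsu's
method — the standard default of CellProfiler/KNIME-era workflows — and
the threshold is computed on the min–max rescaled channel, so
segmentation is invariant to affine intensity rescaling. Watershed
seeds come from distance-transform maxima with a minimum height
tolerance (1 px default); seed ordering is deterministic, so repeated
runs produce identical label maps. EBImage provides all the image
primitives.

Per-object measurements (area in px and µm², mean and total intensity
in both channels) support the three phenotype readouts this package
models: marker loss as reduced mean nuclear intensity, nuclear
enlargement as increased per-nucleus area, and Golgi fragmentation via
punctate signal quantification.

For punctate (Golgi-type) signal, cell regions are built by assigning
every pixel within `cell_dilation_px` (default 25) of a nucleus to its
nearest nucleus — a Voronoi-like partition that cannot produce
overlapping cells, implemented with EBImage's seeded propagation.
Puncta are isolated with a white top-hat filter (disc radius 5 px
default; structures larger than the element are treated as local
background) and thresholded with Otsu's method. The thresholded
fragment mask keeps only the bright core of a roughly Gaussian punctum
— about half its integrated intensity — so the mask is grown by a small
halo (`halo_px`, default 2) before summation to capture the faint rim.
The per-cell value is the raw-signal sum over its fragments minus
(fragment pixel count × median signal outside all cell regions); the
median makes the background estimate robust to stray fragments, and
together with the top-hat it renders the measurement invariant to
uniform background shifts, which the tests assert. The top-hat radius
and dilation distance are not dictated by any published protocol; the
defaults suit the synthetic image scale (nuclei of ~12 px radius) and
are exposed as parameters. Mean nuclear marker intensities are reported
without background subtraction by default.

Group comparisons between a target condition and scrambled controls use
the two-sided Mann–Whitney U test (the package-wide default, matching
common screening practice) or the Kolmogorov–Smirnov test for
distribution-shape phenotypes such as nuclear size, with the effect
size reported as the target median normalized to the scrambled median.

Manual curation of high-content data (removing mitotic, out-of-focus
and stain-artifact objects) is replaced by a deterministic surrogate:
rule-based filters on border contact, object solidity, and mean nuclear
intensity above a pixel percentile. This is a surrogate for, not a
reproduction of, interactive QC.

## Protein turnover and targetability

Arrayed screens observe phenotypes within ~3–5 days of transfection, so
a knockout phenotype only appears once pre-existing protein has
decayed. Exponentially degraded (ED) proteins follow
$R(t) = e^{-kt}$ with half-life $\ln 2 / k$; non-exponentially degraded
(NED) proteins show two-phase kinetics modelled here as a fast/slow
two-pool mixture

$$R(t) = \alpha e^{-k_\mathrm{fast} t} + (1-\alpha) e^{-k_\mathrm{slow} t},$$

strictly decreasing from 1 to 0, so $R(t) = 1/2$ has a unique root,
found by bisection between the pure-pool half-lives to 1e-6 h. The
two-pool mixture is a declared parameterization choice: published
turnover datasets report NED kinetics in more than one framework, and
this module deliberately accepts precomputed per-protein parameters
rather than fitting pulse-chase data, so results on an external dataset
depend on how its parameters map onto the mixture form. Proteins with
half-life strictly greater than 120 h are classed `hard_to_target`
(exactly 120 h is still targetable); the threshold reflects the
practical upper limit for phenotype emergence in a 5-day arrayed
screen.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* **Plates/screens**: 96-well layout with 8 mocks, 8 scrambled, 8
  positive-control and 4 blank wells, 45 single-guide gene wells, two
  replicate plates per cell line, and two cell lines. Positive controls
  are planted at relative viability 0.15 (an 85% viability loss, the
  scale of an essential-gene control), planted lethal genes at 0.2,
  neutral genes at 1.0, with multiplicative log-normal well noise at 5%
  CV — log-normal because luminescence is positive and its noise scales
  with signal. Five lethal genes are shared between the lines and one
  is specific to each, emulating a shared-essential plus
  oncogene-addiction structure.
* **Images**: anti-aliased disks for nuclei (radius 12 ± 1.5 px in a
  256-px field by default), optional touching pairs at 0.8 × summed
  radii to exercise the watershed split, a marker channel that either
  repeats the nuclear footprint or scatters Gaussian puncta of known
  integrated intensity just outside each nucleus, plus additive
  Gaussian and optional Poisson noise. Ground-truth masks and
  per-object intensities are emitted with every field.
* **Turnover tables**: log-normal intended half-lives (median 30 h,
  sdlog 1 — a realistic mammalian proteome scale), a configurable ED
  fraction, and NED parameters rescaled so the mixture half-life equals
  the intended one exactly.

Every generator is a pure function of its parameters and seed (the
caller's RNG stream is saved and restored), and reruns are
bit-identical.

What the generators deliberately do not emulate: transfection
efficiency gradients, spatial plate effects, cell-growth kinetics,
illumination inhomogeneity, out-of-focus blur, or segmentation-hostile
clumping beyond pairwise touching. Passing tests therefore demonstrate
the correctness of the computations under clean, known conditions — not
robustness to every pathology of real plates and micrographs.

## Numerical choices and degenerate inputs

* Probability floor 1e-300 in the LOD ratio (keeps scores finite
  without affecting order).
* Control fits require ≥ 3 finite values per set and positive sample
  sd; violations raise typed errors rather than propagating NaN.
* Background-subtracted negatives clamp to 0 with a flag; a plate
  without the chosen reference type is an error naming the plate.
* The 2-state half-life bisection runs to 1e-6 h on a bracket that
  always contains the root; α = 1, α = 0 and equal-rate inputs
  short-circuit to the exact 1-state formula.
* Constant images raise a no-foreground error; a constant top-hat
  response yields zero fragments rather than an error, since an empty
  signal channel is a legitimate knockout phenotype.
* Well names are canonicalized to zero-padded form ("A1" → "A01") on
  input; coordinates are 0-based internally.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script validate on: 200 seeded
replications of the two-cell-line 45-gene screen for hit recovery; 100
seeded control fits for the KS diagnostic size; five 256-px fields (12
nuclei each) plus one touching-pair field for segmentation recovery;
eight 400-px fields per arm (~200 objects) for the area and intensity
phenotype comparisons; 1,000 null comparisons for the type-I rate; and
a 1,000-protein synthetic proteome for the targetability summary.
These sizes give stable estimates for every property checked while
keeping the whole suite fast enough to run routinely.

## Known limitations

* The LOD model assumes normally distributed control viabilities; the
  KS diagnostic flags gross violations but a failing screen is reported,
  not repaired.
* Per-guide scoring inherits the usual caveat of arrayed screens: one
  guide per gene conflates guide efficacy with gene essentiality.
* The image pipeline is 2-D single-plane and does not model
  illumination correction; it is not intended to reproduce any specific
  commercial analysis pixel for pixel.
* The targetability fraction depends on the half-life parameterization
  supplied; with the synthetic log-normal proteome it is a property of
  the generator, not a biological estimate.
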