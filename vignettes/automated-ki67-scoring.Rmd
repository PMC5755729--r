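---
title: "Automated Ki67 scoring with emergent hot spots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated Ki67 scoring with emergent hot spots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67score)
library(dplyr)
```

## The problem

The Ki67 index — the percentage of tumor nuclei staining positive for
the proliferation marker Ki67 — carries real prognostic weight in
early-stage, hormone-receptor-positive breast cancer, but manual
scoring is notoriously irreproducible. The dominant source of
disagreement is *selection bias*: two observers scoring the same slide
choose different fields, and when "hot spots" (locally
hyper-proliferative regions) are scored, each observer picks their own
hot spot.

This package removes the choice. The entire annotated tumor region is
analyzed: it is partitioned into 500 × 500 µm tiles, every nucleus in
every tile is detected and classified, and the hot spots *emerge* as
the top-scoring tiles rather than being selected by eye. Two indices
are reported per slide:

* **hot-spot Ki67 index** — the unweighted mean percent-positive of
  the top five tiles among those containing at least 500 cells;
* **whole-slide Ki67 index** — the unweighted (macro) mean of the
  per-tile percentages over all tiles, with no minimum-cell rule.

Downstream, the package provides the statistics used to validate such
an assay (Pearson's r with two-tailed p, Lin's concordance correlation
coefficient), Oncotype DX risk-group assignment (low < 18,
intermediate 18–30, high ≥ 31 on the 0–100 Recurrence Score), and a
random-forest harness that asks how well Recurrence Scores — and hence
risk groups — can be predicted from clinico-pathological variables
including the automated Ki67 index.

## Imaging model

Brightfield IHC obeys the Beer–Lambert law: transmitted intensity
falls off exponentially with stain amount, so per channel we work in
optical density,

$$\mathrm{OD}_c = -\log_{10}\!\big(\max(I_c, 1)/255\big),$$

where the one-intensity-unit guard keeps the transform finite at
$I = 0$ (capping OD near 2.407). OD is additive across chromogens, so
a pixel's OD vector is a non-negative mixture of a hematoxylin
direction (blue nuclear counterstain), a DAB direction (brown Ki67
chromogen) and a residual. We default to the published
Ruifrok–Johnston H-DAB vectors, normalized to unit length, with the
residual their normalized cross product; the basis is configurable for
scanners with different stain appearance. Unmixing is one 3 × 3 solve
per pixel; physically impossible negative concentrations are clamped
to zero after the solve (the unclamped solution is exact, which is
what the round-trip tests exercise).

Nucleus detection then runs on the combined nuclear map (hematoxylin +
DAB concentration): Gaussian smoothing at 1 px, a fixed concentration
threshold of 0.15, connected components, optional distance-transform
watershed to split touching nuclei, and a minimum-area filter of
10 µm² (converted to pixels through the image scale). A nucleus is
called Ki67-positive when its mean DAB concentration strictly exceeds
0.2; the strict inequality sends ties to negative, a conservative,
deterministic rule. None of these four values is dictated by the
science — commercial platforms keep their equivalents proprietary —
so they are declared defaults, chosen to separate the simulator's two
stain classes by a wide margin, and every one is a `detection_params()`
field.

Nuclei are *points* downstream: the centroid alone decides membership
in the region and in a tile. This prevents double counting across tile
borders and makes the per-tile counts an exact partition.

## Tiling and the two indices

The tile grid is anchored at the top-left corner of the region's
bounding box (the anchor must be fixed somewhere for reproducibility;
the bounding box is the only canonical point available). Tile boxes
are half-open so each centroid falls in exactly one tile; a tile is
kept iff its closed box intersects the region polygon, so partial edge
tiles are scored — they contain tumor — though they rarely reach 500
cells and therefore rarely qualify as hot spots.

Ranking for the hot-spot index sorts qualifying tiles by
percent-positive, breaking ties by larger cell count and then grid
order; repeated runs are byte-identical. Two degenerate situations the
500-cell rule creates on small tumors are handled explicitly: with
fewer than five qualifying tiles, all qualifying tiles are averaged
(and the number used is reported); with none, the index is undefined
and flagged with a warning rather than silently zeroed. Zero-cell
tiles are excluded from the whole-slide macro mean — their percentage
is 0/0 — because treating them as 0% would deflate scores wherever the
annotation includes stroma-rich, cell-poor tiles.

Boundary rule, stated once and used everywhere: a centroid on the
region boundary (including a hole's rim) counts as inside.

## Agreement statistics and risk groups

Pearson's r comes with the two-tailed p-value from the t transform on
n − 2 degrees of freedom. Lin's concordance correlation coefficient is

$$\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

computed with population (1/n) moments; the sample (1/(n−1))
convention differs only by a factor that cancels at the invariant
level (|CCC| ≤ |r| either way), and the population form matches the
direct-summation definition our oracle tests use. CCC penalizes
location and scale shifts that leave r untouched, which is exactly why
it accompanies r in method-agreement work.

Risk groups partition the Recurrence Score range: low < 18,
intermediate 18–30, high ≥ 31. Scores are integers in practice, so the
printed conventions "18–30" and "≥ 31" leave the open interval
(30, 31) unassigned for fractional inputs; we assign it to
intermediate so that the map is total. The confusion summary uses the
asymmetric conventions of low-versus-high evaluation: a correct
low-risk call is the true positive, a correct high-risk call the true
negative, and any pair where *either* the actual or the predicted
group is intermediate is excluded before tallying. Metrics with a zero
denominator are reported as missing and named, never as 0 or 100 — on
small test halves specificity frequently has a near-empty denominator,
which is also why its dispersion across rounds is large.

Reported cohort percentages round half away from zero at one decimal,
the convention of printed clinico-pathological tables.

## The random-forest harness

The harness regresses the Recurrence Score on 13 chart variables (age,
tumor size, grade, nuclear grade, differentiation, mitotic score,
ER/PgR staining intensity and Allred scores, the Ki67 index in either
variant, and two additional chart fields), optionally extended with
the three RT-PCR expression scores from Oncotype DX reports (ER, PgR,
HER2) for a 16-variable set. The predictor list is configuration, not
code: real chart exports differ, so `predictor_set()` is a default,
not a contract.

Forest settings follow the established tuning for this problem:
1000 trees, `m_try` 15 with the expression scores and 12 without,
bootstrap draws of 40 records per tree (with replacement), minimum
node size 5, no depth cap. Ordinal predictors (grades, scores, Allred)
enter as integers.

Each cross-validation round splits the cohort 50/50 without
replacement (the training half receives the extra record when n is
odd), fits on one half, predicts the other, converts predicted and
actual scores to risk groups, and evaluates the confusion summary
above. Variable importance is the permutation form:

$$\%\mathrm{IncMSE}_v = 100 \cdot \frac{\mathrm{MSE}_{\mathrm{perm}(v)} - \mathrm{MSE}_{\mathrm{base}}}{\mathrm{MSE}_{\mathrm{base}}},$$

computed on the held-out half with a seeded permutation of column v.
Two design choices deserve a note. First, the quantity is defined as a
*relative* MSE increase: the name is a percentage, and the relative
form preserves ranking semantics while staying comparable across
rounds with different error scales; the classic alternative
(tree-level out-of-bag averaging inside the forest) requires
tree-level bookkeeping and measures the same thing more noisily.
Second, importance is evaluated on the held-out half rather than
in-bag, keeping it honest about generalization. If a model fits its
evaluation set perfectly (baseline MSE exactly zero, which happens on
degenerate constant cohorts), the relative form is undefined and the
absolute increase is reported with a flag instead.

Aggregates are means ± standard deviations over rounds; a round whose
evaluation is empty (no low/high pairs survive the intermediate
exclusion) is recorded and excluded, and a metric undefined in a round
is excluded from that metric's aggregate only, with the count of
defined rounds reported. Everything derives from one master seed, so
identical seeds give byte-identical reports.

## What the simulators emulate — and what they do not

`simulate_slide()` draws nucleus centers from an inhomogeneous Poisson
process — a base intensity plus circular hot spots with a density
multiplier — thinned to a hard-core minimum separation, labels each
nucleus Bernoulli-positive (`p_hot` inside a hot spot, `p0` outside),
and renders randomly oriented ellipses by Beer–Lambert forward
synthesis through the same H-DAB basis the analyzer inverts, plus
Gaussian OD noise. The closed loop (render and analyze through one
basis) is deliberate: it isolates segmentation and scoring errors from
stain-estimation errors, and a perturbed basis can be passed to probe
the latter separately.

The hard-core separation defaults to 2× the maximum nucleus radius.
A tighter core (for example 1.5×) produces visibly touching nuclei
whose watershed splits occasionally fail, which turns the
detection-count oracle from exact into approximate; at 2× two maximal
ellipses can at most touch, so the ground-truth count is recovered
essentially exactly and label accuracy exceeds 99%.

Default study conditions: a 2 × 2 mm region at a candidate intensity
of 3600 nuclei/mm² (about 9300 nuclei after thinning, ~580 cells per
tile, so all sixteen 500 µm tiles clear the 500-cell rule), background
positivity 15%, and one hot spot of radius 360 µm at 1.5× density and
85% positivity. The per-tile cell counts deliberately sit just above
the qualification threshold so the rule is exercised rather than
vacuous. Smaller canvases are used throughout the test suite to keep
runtimes modest; the recovery checks run five full-size slides.

What the slide simulator does *not* emulate: chromatin texture,
staining artifacts, folds, out-of-focus regions, scanner-to-scanner
stain variation, or clustered/overlapping nuclei beyond the hard core.
Passing the recovery tests therefore shows the tiling, counting and
scoring machinery is correct *given* detectable nuclei; it does not
certify segmentation performance on real tissue, where detection
parameters would need tuning against annotated fields.

`simulate_cohort()` generates records whose dependence structure
mirrors clinical experience qualitatively: Ki67 is log-normal with a
mean rising in tumor grade and mitotic score and falling in ER/PgR
Allred scores, and the Recurrence Score is a linear combination
dominated by Ki67 plus Gaussian noise, truncated to [0, 100]. The
default coefficients give roughly 60/28/12 percent
low/intermediate/high — close to the skew of Oncotype DX-tested
cohorts — and a Ki67–RS correlation near 0.9. Ordinal marginals
roughly follow the frequencies seen in such cohorts; no claim of
distributional fidelity is made. The `single_signal` variant (uniform
Ki67, Recurrence Score a noise-free multiple of it, all other
predictors independent) is the cleanest parameter-recovery setting for
the harness and is what the acceptance checks use.

## Numerical choices and degenerate inputs

* Intensities are rounded to integers before the OD transform,
  matching 8-bit storage; white (255) maps exactly to OD 0.
* The stain solve refuses a singular basis; the residual construction
  makes the default basis well conditioned.
* Tile side = `round(tile_size_um / mpp)` pixels; anisotropic pixels
  are rejected at construction.
* Empty detection sets, zero-cell tiles, all-intermediate evaluations,
  zero-variance series, and zero-density simulations each have an
  explicit, tested behavior (empty result, undefined-with-flag, or a
  named error) — never a silent zero.
* Problem sizes in the validation suite: five full-size simulated
  slides for index recovery; 10⁴ concentration pairs for the stain
  round trip; 1000 random tile tables for hot-spot dominance; 200
  pair sets and 500 label vectors for the statistics oracles; and 100
  cross-validation rounds (scaled down from the 1000 used for
  reporting) at n = 200 for the harness.

## Known limitations

* Segmentation is classical (threshold + watershed); heavily
  overlapping nuclei in real tissue will merge, and the detection
  defaults are simulator-calibrated, not tissue-calibrated.
* Pyramidal whole-slide containers (SVS/NDPI) are out of scope; inputs
  are flat PNG/TIFF with a known scale.
* H&E-to-IHC annotation registration is assumed done: annotations are
  taken in the Ki67 image's pixel space.
* The confusion conventions evaluate only the low/high extremes, as is
  standard for this prediction task; intermediate-risk performance is
  deliberately not summarized.
* Lin's CCC is reported without a confidence interval.

## Reproducing a full run

```{r, eval = FALSE}
sim <- simulate_slide(slide_spec(seed = 1))
score <- score_slide(sim$image, sim$region)
glance(score)                 # both indices and tile counts
glance(truth_indices(sim))    # the ground-truth oracle
autoplot(score)               # tile heatmap with hot spots outlined

co <- simulate_cohort(cohort_spec(n = 328, seed = 1))
cv <- cross_validate(complete_cases(co), predictor_set("hotspot"),
                     forest_params(), n_rounds = 100, seed = 1)
glance(cv)
plot_importance(cv)
```
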