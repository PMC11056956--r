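---
title: "Methods: models, parameters and design choices in adenoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in adenoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adenoquant)
```

`adenoquant` packages the quantitative readouts of a tamoxifen-induced
murine adenomyosis fertility workup. This vignette records the models and
procedures each module implements, the parameters that matter, the
numerical conventions, and the design decisions that were genuinely open —
in enough detail that every result the test suite asserts can be traced to
a definition.

## PGR immunofluorescence quantification

A uterine section is represented as three co-registered 8-bit channels:
red (PGR immunostain), green (αSMA, smooth muscle), blue (DAPI, all
nuclei). Three manually drawn ROI polygon sets decompose the studied
region into luminal epithelium, glands, and stroma; gland pixels exclude
epithelium, stroma is the remainder, so the three masks are pairwise
disjoint and their union is exactly the studied region (an invariant the
suite checks on every phantom).

**Binarization.** Red and blue are binarized independently with Otsu's
method: the integer threshold in [0, 255] maximizing between-class
variance of the 256-bin histogram. Conventions, fixed for determinism:

* one threshold per channel per image, computed over the whole studied
  region and applied to all compartments — this keeps compartment ratios
  comparable within an image and follows the per-image description of the
  workflow;
* foreground is *strictly greater* than the threshold;
* ties are broken toward the lowest maximizing threshold.

The readout per compartment is `area(red) / area(blue)` in pixels. Areas
are pixel counts because the ratio is scale-free; µm² would require the
pixel size, which is carried as optional metadata only. The green channel
is deliberately not quantified — it delineates the myometrium visually.

**Rasterization convention.** Polygons are filled by the even-odd rule; a
pixel belongs to a polygon iff its centre is inside, with a half-open
boundary (left/top edges included). This makes abutting polygons partition
pixels exactly. One consequence worth knowing: the rule is not equivariant
under 90° rotation when polygon edges pass exactly through pixel centres
(an integer-coordinate rectangle shifts by one row when rotated). The
rotation-invariance property is therefore exercised with ROIs on
half-integer coordinates, where masks rotate exactly.

## Depth-of-invasion grading

The myometrial wall is the region between the endometrial–myometrial
interface (inner boundary) and the serosal edge (outer boundary). Every
wall pixel gets a normalized depth

d(p) = dist(p, inner) / (dist(p, inner) + dist(p, outer)),

computed with exact point-to-segment distances to the polygon outlines
(0 on the inner boundary, 1 on the outer; on concentric circles this is
the closed form (r − r_in)/(r_out − r_in), which the suite checks to
within the 1-px discretization of the wall). The deepest pixel of any
ectopic focus sets the grade: grade I for 0 < d ≤ 1/3, II for
1/3 < d ≤ 2/3, III above — closed upper bounds mirroring the
"inner third" / "two-thirds" wording, and a max-depth rule because the
Bird scale grades by deepest involvement (whether the source scale uses
the deepest point or the focus centroid is not documented; the deepest
point is the package's documented choice). A focus entirely outside the
wall is ignored with a warning; with no (in-wall) foci the grade is 0 and
`invasion_present` is `FALSE`. For 1-month uteri, whose wall is too thin
to tertile, only `invasion_present` is meaningful.

Cohort summaries report per-grade percentages rounded half-up to two
decimals — the convention behind every printed percentage this package
reproduces (base R's round-half-even cannot produce 91.18 from 62/68).

## Estrous cytology

A smear carries counts of nucleated epithelial cells, cornified
epithelial cells, and leukocytes. The classifier applies three rules in
fixed precedence:

1. **metestrus** if the cornified fraction and the leukocyte fraction are
   both ≥ `m_lo` (default 0.25) — the sloughing stage mixes the two;
2. else **diestrus** if the leukocyte fraction is ≥ `d_hi` (default
   0.60) — "very high density";
3. else the **majority** cell type decides (nucleated → proestrus,
   cornified → estrus, leukocyte → diestrus).

The verbal staging descriptions are qualitative; `m_lo` and `d_hi` are
the package's quantitative defaults and are exposed as configuration. On
degenerate compositions (one dominant type per stage) the classifier
recovers simulator truth with 100 % accuracy, which is what the defaults
are required to guarantee; real smears are noisier than anything this
establishes.

**Cyclicity metrics.** Stage percentages use observed (callable) days as
the denominator; failed smears are gaps. "Number of cycles in a window"
is not operationally defined in the staging literature this package
follows, so it is fixed here as a deterministic scan: a cycle is counted
at each *entry* into estrus (an estrus day whose previous called day is
not estrus, the first called day included) that is followed, before the
next entry, by at least one metestrus or diestrus day. Gaps neither
create an entry nor complete a cycle. The count is invariant to
leading/trailing diestrus padding (property-tested).

## Folliculometry

Ovaries are sectioned at 5 µm with one section in ten stained, so
consecutive stained sections are 50 µm apart and a 400 µm span covers
`floor(400 / (5 × 10)) = 8` stained sections. Follicle types (primordial,
primary, secondary-or-more, corpus luteum) are assigned upstream; this
module consumes annotation tables. Density is the *pooled* estimator —
total count of a type divided by total sectioned surface — rather than a
mean of per-section densities: it matches "follicles per mm² after
calculating the ovarian surface" and has lower variance. Fewer than six
quantified sections flags the result without suppressing it. Corpora
lutea are counted raw (no Abercrombie-type volumetric correction, by
design) with identity-based deduplication across adjacent sections within
the 8-section span; annotations without an identity are each counted
once, reproducing plain unadjusted counting.

## Expression analysis

**qPCR.** Duplicate wells collapse to their arithmetic mean; a replicate
range above 0.5 cycles (configurable) flags the pair. The per-sample
reference Ct is the arithmetic mean of the two housekeeper Cts (Rplp0 and
Gapdh) — equivalent to geometric-mean normalization on the linear scale,
the standard multi-reference convention; the source protocol names the
genes but not the combination rule. ΔCt = Ct_target − Ct_ref;
ΔΔCt subtracts the *mean control-group* ΔCt (a group baseline, not a
single calibrator, because group-level fold changes are what the figures
plot); fold = 2^−ΔΔCt with amplification efficiency fixed at 2. Two
algebraic consequences are asserted as tests: the geometric mean of
control folds is exactly 1, and folds are invariant to adding a constant
to every Ct.

Parameter recovery: noiseless simulated tables return the programmed fold
exactly. With 0.2-cycle Gaussian well noise at n = 8/group the
per-experiment sampling sd of the log2 group fold is ≈ 0.09, so single
experiments scatter beyond ±10 % about one time in nine; the recovery
property is therefore stated for the mean over 20 replicate simulated
experiments, which is well inside ±10 %.

**Densitometry.** Band intensities are divided by the HSP70 loading
control, then by the control-group mean of that normalized value, per
protein — fold change versus control, matching the blot quantification
convention.

## Fertility statistics

Breeding records hold one row per litter; dams that never delivered are
carried with an NA month so group denominators survive filtering.
`mean_litter_size` reports both the pooled estimator (total pups / total
litters — the protocol's stated definition) and the mean of per-dam
ratios, since printed group means do not disambiguate the two.

**Mann–Whitney.** When both groups have ≤ 8 observations (configurable)
and the pooled sample is tie-free, the two-sided p is exact: U is
computed for every C(n+m, n) label assignment and p is the doubled
smaller tail, capped at 1 — a standard deterministic choice where the
protocol specifies only "Mann–Whitney". Otherwise mid-rank U with the
tie-corrected normal approximation and continuity correction is used
(identical samples are fully tied, so they take this path and return
p = 1). The exact path is verified against `stats::wilcox.test`'s exact
p on random tie-free samples, and its type-I error is confirmed
conservative by simulation.

**Two-way ANOVA.** Cumulative pups over months are analysed as an
ordinary two-factor layout with interaction via `stats::aov`, mirroring
the stated method; the repeated-measures structure of per-dam series is
deliberately not modelled, and that caveat travels with the function. A
term with zero sum of squares reports F = 0 (with zero residual variance
the ratio is otherwise undefined).

## Synthetic data: what it emulates, and what it does not

The generators define the verification conditions for every stage.

* **Fluorescence phantoms**: a rectangular studied region with an
  epithelial band, two circular glands, stroma, and a green muscle band
  outside. Nuclei are identical non-overlapping disks (rejection-sampled,
  centre distance > 2r) placed fully inside their compartment, so the
  blue area per compartment is exactly n × 29 px (radius 3) and painting
  round(f·n) disks red makes the true ratio exactly round(f·n)/n. Noise
  adds independent uniform integers in [0, noise·255] to every pixel.
  Defaults (160 × 160 px, radius 3, 30/30/90 nuclei, signal 220) keep
  every compartment well-populated while placement stays fast. These are
  geometric phantoms: no histology texture, no uneven illumination, no
  touching nuclei — passing them validates the arithmetic of the
  pipeline, not segmentation robustness on real micrographs.
* **Cycle simulations**: the canonical mouse cycle (P 1 d, E 2 d, M 1 d,
  D 2 d — 6 days/cycle, within the species' 4–6-day range) with the
  adenomyosis condition emulated by multiplying the estrus duration
  (factor 3 in examples, matching the prolonged-estrus phenotype).
  Per-stage expected cell fractions (defaults: P 80/15/5, E 5/90/5,
  M 10/45/45, D 10/15/75) were chosen to be consistent with the staging
  rules at their defaults; daily counts are multinomial draws of 100
  cells. Durations are deterministic integers by default; geometric
  jitter sits behind a flag because no stochastic model is documented.
* **Ct tables**: case-group target Cts are shifted by −log2(fold), so
  programmed folds are recovered exactly without noise.
* **Cohort fixtures**: integer counts are *reconstructed* from printed
  percentages by smallest-denominator search
  (`reconstruct_counts_from_percentages`): the smallest n whose counts
  re-round (half-up, two decimals) to every printed value. The grade
  shares 1.47/2.94/4.41/91.18 % resolve to n = 68 with counts
  (1, 2, 3, 62); the delivering share 33.33 % of a 6-dam group resolves
  to 2 dams. The study ledger reports 55 treated mice at the 3-month
  timepoint while the shares imply 68; the fixture follows the
  percentages and the discrepancy is surfaced, not resolved. Breeding
  fixture litter sizes are deterministic values whose pooled totals
  (220/17, 19/3) re-round to the printed means 12.94 and 6.33.
* **Synthetic transcripts**: the packaged reference sequences for the
  primer assays are constructed stand-ins (random filler around the
  printed primer strings at the printed product sizes, split points at
  typical 20–22-nt primer lengths) and are labelled synthetic wherever
  they appear. They validate the split/match machinery offline; resolving
  the real accessions requires their sequences.

All generators are bit-reproducible under a fixed seed (`withr::with_seed`).

## Numerical conventions and degenerate inputs

* Percentages print half-up at two decimals; `round_half_up` guards the
  binary representation with a 1e-9 epsilon.
* Otsu on a constant region, an all-zero smear, an empty cohort or group,
  zero section area, or non-positive intensities raise errors rather than
  propagate NaN; an empty compartment yields zero areas and a flagged
  undefined ratio.
* The exact Mann–Whitney enumeration cutoff (n ≤ 8) bounds C(16, 8) =
  12 870 assignments, a few milliseconds.
* Problem sizes in the tests (160-px phantoms with 100–150 nuclei, 20
  noise replicates, 1 000 histograms, 2 000 null simulations at n = 5/5,
  500 ANOVA permutations) were chosen so each property is measured with
  comfortable margins while the full suite stays within a coffee break.

## Known limitations

* No pixel-level segmentation anywhere: ROIs, smear counts, follicle
  annotations and band intensities are inputs; the package quantifies,
  it does not detect.
* The phantom noise model (uniform background offsets) is far cleaner
  than real autofluorescence; Otsu separability on phantoms does not
  imply separability on real sections.
* Grading consumes supplied boundary polygons; mis-drawn boundaries
  propagate directly into d and the grade.
* The ANOVA mirrors the stated analysis, including its disregard of
  within-dam correlation.
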