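---
title: "Methods: compartment-specific striato-pallido-thalamic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-specific striato-pallido-thalamic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The striatum is built from two interdigitated compartments of medium spiny
neurons — striosome (patch) and matrix — with distinct embryology,
connectivity, and disease vulnerability. In diffusion MRI the compartments
cannot be seen directly, but voxels can be *inferred* to be striosome-like
or matrix-like from the balance of their connectivity to cortical regions
whose compartment preference is known from animal tract tracing.
`striothal` implements the downstream analysis chain that starts from such
paired connectivity probability maps:

1. **Striatal parcellation** — convert a pair of classification-targets
   probability maps into a voxelwise striosome fraction
   $f(v) = P_{str}(v) / (P_{str}(v) + P_{mat}(v))$ and select equal-volume
   striosome-like and matrix-like masks.
2. **Bundle metrics** — normalize compartment-seeded streamline density
   fields to their maximum inside the globus pallidus interna (GPi, the
   obligatory waypoint), localize intra-pallidal peaks, align hemispheres,
   and quantify overlap by Dice coefficients of amplitude-ranked cores.
3. **Thalamic bias** — renormalize thalamus-seeded probability pairs, trim
   partial-volume edge voxels, count suprathreshold voxels per nucleus, and
   express each nucleus's bias as the matrix fraction
   $N_{mat} / (N_{str} + N_{mat})$.
4. **Statistics** — pooled and paired t-tests with Bonferroni families,
   two-factor location ANOVAs with simple main effects, and an exact
   binomial sign-consistency statistic for hemispheric laterality.

Because the upstream tractography (FSL `probtrackx2` and friends) is
well-established external tooling, the package replaces it with a synthetic
cohort generator whose phantoms have *known* ground truth, so every stage
can be validated by parameter recovery rather than by eye.

## The synthetic cohort

Each subject phantom contains mirror-symmetric ellipsoidal caudate,
putamen, GPi, and thalamus per hemisphere on a fixed 96 x 114 x 84 mm field
of view (so 1.5 mm and 2.0 mm cohorts share physical geometry), with a
+/- 3 % seeded size jitter per subject. The thalamus is partitioned into 20
contiguous parcels (Voronoi assignment after Lloyd relaxation in
ellipsoid-normalized coordinates), named for the 20 thalamic nuclei the
analysis quantifies.

**Striosome character.** On each hemisphere's striatum the generator plants
$g(v) = \mathrm{logistic}(w_m m + w_r r + w_v d + \varepsilon)$, where
$(m, r, d)$ are bounding-box-normalized medial/rostral/ventral coordinates
and $\varepsilon \sim N(0, \sigma)$. The default weights $(2, 2, 2)$ enrich
striosome character medially, rostrally, and ventrally — the gradient
described in human and animal histology. Bounding-box normalization (rather
than mm) keeps the statistical structure identical across voxel
resolutions, since resolution is a cohort covariate, not a biological one.

**Striatal probability pair.** $P_{str} = \mathrm{clip}(g + \varepsilon_1)$,
$P_{mat} = \mathrm{clip}(1 - g + \varepsilon_2)$ with independent Gaussian
noise on the probability scale. Noiseless pairs invert exactly through the
bias map (the parcellation recovers $g$ to machine precision).

**Thalamic probability pair.** For a voxel in nucleus $n$, hemisphere $h$,
the matrix share is drawn as

$$s = \mathrm{clip}\big(\beta_n + \delta\,[h = \text{left}] + U + Z\big),
\qquad U \sim \mathrm{Unif}(-w, w),\; Z \sim N(0, \sigma),$$

and the pair is $(1 - s, s)$ scaled by an edge-attenuation ramp. Two design
choices deserve explanation:

* *The uniform dispersion $U$ (default half-width $w = 0.55$).* The
  nucleus-level quantity is a **count-based** fraction: voxels with share
  $\ge 0.55$ count as matrix-favoring, $\le 0.45$ as striosome-favoring,
  and the 0.45–0.55 band counts for neither. For
  $U \sim \mathrm{Unif}(-w, w)$ the counts satisfy
  $P(s \ge 0.55) = (w - 0.55 + \beta)/2w$ and
  $P(s \le 0.45) = (w - 0.55 + 1 - \beta)/2w$, so the expected count
  fraction is $(w - 0.55 + \beta) / (2w - 0.1)$ — which equals $\beta$
  *identically* precisely when $w = 0.55$. The default is therefore the
  unique calibration under which the suprathreshold-count pipeline is an
  unbiased estimator of the planted per-nucleus bias; it also gives each
  nucleus a realistic spread of voxel shares rather than a delta function.
  Clipping to $[0, 1]$ never changes a voxel's counted side, so the
  identity survives clipping exactly; the Gaussian component perturbs it
  only near extreme $\beta$ (worst-case bias about 0.01 at $\beta = 0.08$
  with $\sigma = 0.1$).
* *Edge attenuation.* A linear ramp from 0.2 at the boundary shell to 1 in
  the interior (depth 1 voxel by default). Boundary voxels then sum to
  0.2 < 0.5 and are trimmed downstream, the first interior shell sums to
  0.6 and exercises renormalization, and deep voxels sum to exactly 1 —
  so both the trimming rule and the renormalization rule are genuinely
  exercised on every phantom.

The default bias table assigns the 16 combined-hemisphere nuclei their
group-mean matrix fractions (AV 0.29 … VPL 0.71) and the four
hemisphere-split nuclei (CeM, MDl, Reu, VAmc) the midpoint of their
left/right means. Hemispheric asymmetry is a single additive left offset
$\delta$ (default 0.05) applied uniformly to all nuclei — the simplest
mechanism producing the observed near-universal left > right direction
without per-nucleus parameters. Note that with $\delta > 0$ the *pooled*
two-hemisphere truth for a nucleus is $\beta + \delta/2$, and recovery is
assessed against that planted pooled value.

**Bundle densities.** Each compartment's density is a smooth corridor
(Gaussian profile around a seed-to-GPi-to-thalamus polyline) plus a
dominant Gaussian peak planted at the GPi centroid plus a per-compartment
offset (defaults $\mp(0.8, -1.6, 1.6)$ mm, striosome more lateral, rostral,
and ventral; planted peak separation 4.8 mm). Corridor endpoints are
displaced by twice the peak offset so the two bundles transit distinct
corridors, not merely distinct peaks. The matrix bundle's amplitude is
`fold_factor` (default 5.7) times the striosome bundle's, and per-seed
streamline totals are Poisson draws around 2,291 (matrix) and 401
(striosome) streamlines per seed voxel. Multiplicative log-normal noise
(sd 0.02) keeps fields strictly positive while preserving exact linearity
in amplitude.

**What the phantoms do not model.** No diffusion signal, fiber ODFs, or
streamline propagation; no registration error beyond the edge-attenuation
proxy; no anatomically realistic nucleus shapes; no inter-subject
correlation structure. Passing tests therefore demonstrate that the
*analysis chain* is correct and well-calibrated under its stated
assumptions — not that the biological conclusions would survive real
tractography confounds.

## Analysis parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sd_k` | 1.5 | mask selection: scores above mean + k sd |
| `fixed_n` | 83 @ 2.0 mm, 180 @ 1.5 mm | equal-volume mask size (voxels) |
| `trim` | 0.5 | minimum pair sum before a thalamic voxel is kept |
| `supra` | 0.55 | suprathreshold share for bias counting |
| `seed_region_supra` | 0.87 | substantial-bias criterion for seed-region profiling |
| `qc_fraction` | 0.10 | subject-hemisphere volume cutoff vs per-side mean |
| `stringencies` | 0.25, 0.5, 0.9 | bundle core fractions for Dice overlap |
| `alpha` | 0.05 | family-wise alpha (Bonferroni divided) |
| jitter `max_shift` | 3 | imprecise-mask displacement per axis (voxels) |

The minimum nucleus volume is four diffusion-space voxels, inclusive:
13.5 mm^3 at 1.5 mm and 32 mm^3 at 2.0 mm.

## Numerical and procedural choices

* **Bias as a bounded fraction.** The compartment ratio is computed as
  $P_{str}/(P_{str}+P_{mat})$ rather than a raw ratio: same ranking,
  bounded in [0, 1], and the 0.55/0.87 thresholds apply directly.
* **Deterministic tie-breaking.** Fixed-N selection, stringency cores, and
  peak localization break ties by ascending linear voxel index; sd-mode
  selection uses a strict inequality so an all-equal map selects nothing.
  Ties are measure-zero on real data but common on synthetic fields.
* **Equal-volume guarantee.** If a voxel would qualify for both
  compartments (pathological flat map), it goes to the compartment where
  its rank is better (ties to striosome) and the other compartment takes
  its next-ranked voxel; overlap is asserted zero.
* **Jitter resamples out-of-bounds offsets** rather than clipping, which
  would bias displacements toward the boundary; after deduplication the
  jittered mask may shrink, and the achieved size is reported, not
  enforced. The mean per-voxel Euclidean displacement of uniform
  $\{-3..3\}^3$ offsets is 3.33 voxels by enumeration — that is the
  implemented scheme's expectation, and the oracle tests exactly that.
* **QC order.** The 10 % volume rule runs first in a single pass (the
  per-side mean is computed once over all subjects, not iterated), then
  the zero-compartment rule.
* **Split-nucleus rule.** A nucleus is reported per-hemisphere only when
  the hemispheric difference is significant *and* exactly one hemisphere is
  itself significantly biased while the other is neutral; nuclei that
  differ in magnitude but share a significant direction stay combined.
* **Classification test.** The default is the literal two-sample
  equal-variance t between the matrix-fraction sample and its complementary
  striosome-fraction sample; the statistically equivalent one-sample test
  against 0.5 is provided as an option.
* **Zero-variance conventions.** Degenerate samples (noiseless fixtures)
  give t = 0, p = 1 for equal means and |t| = Inf, p = 0 otherwise, rather
  than erroring; a zero-residual ANOVA reports F = 0, p = 1 for null
  effects.
* **Simple main effects** use the full model's pooled residual mean square
  and a Scheffé-type simultaneous critical value
  $F^* = (a-1) F_{\alpha;\,a-1,\,df_{res}}$ — a conservative bound chosen
  because it is reproducible from first principles.
* **Laterality ties** (left mean exactly equal to right) drop the nucleus
  from $n$: the fair-coin null has no atom at zero.
* **Hemisphere alignment** decomposes into reflection about the
  mid-sagittal plane plus centroid-matching translations that place each
  GPi centroid at the two-hemisphere mean; the location ANOVA uses
  medial-positive x so the compartment effect does not cancel across
  hemispheres.
* **Exact binomial mass** is $C(n,k)/2^n$ with integer numerators
  ($n \le 64$), rendered as "1 in $\mathrm{round}(2^n / C(n,k))$"; 18 of 20
  gives 1 in 5,519. The exact-k mass (not the tail) reproduces that printed
  rendering; the tail variant is available.

## Problem sizes used in validation

The packaged validation runs use: a 20-subject cohort at 1.5 mm for
parameter recovery (pooled per-nucleus error stays within +/- 0.05 of the
planted pooled truth, observed about 0.02); twenty replicate 20-subject
cohorts for the laterality operating characteristic (left > right in at
least 18 of 20 nuclei in at least 95 % of cohorts at delta = 0.05); two
hundred 4-subject cohorts at 2.0 mm with delta = 0 for the null
calibration (the left-greater count k is compared to Binomial(20, 1/2) by
chi-square with pooled tails); and 2–6-subject cohorts for end-to-end
determinism and bundle metrics. These sizes were chosen as the smallest
cohorts at which the binomial arithmetic above predicts comfortable margins
for the stated operating characteristics.

## Known limitations

* Nucleus-level recovery is count-based and therefore exact only under the
  calibrated dispersion; a user who narrows `share_dispersion` should
  expect count fractions to saturate toward 0/1 for strongly biased nuclei
  (this is a property of suprathreshold counting itself, not of the
  implementation).
* With the default left asymmetry, near-neutral nuclei (|beta - 0.5| <
  0.03) sit close to the classification boundary once pooled across
  hemispheres; their verdicts legitimately vary with cohort draw.
* The hemisphere-alignment transform is one reading of an ambiguous
  convention (reflect about the mid-sagittal plane, then match centroids);
  alternatives differ by a translation and do not affect RMS separations.
* The sd-mode / fixed-N duality is deliberate: fixed-N defaults (83/180)
  are used everywhere volumes must match exactly, while sd mode is
  provided for per-subject thresholding.
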