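---
title: "Methods: from microperimetry to V1 statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from microperimetry to V1 statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vf2cortex)
```

This vignette documents the models, numerical choices and open design
decisions behind `vf2cortex`. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Retinal ROI model

**PRL center and BCEA.** Fixation behavior is modeled as bivariate normal.
The PRL center is the sample mean; the bivariate contour ellipse area at
probability content $P$ is

$$\mathrm{BCEA}(P) = \chi^2_2(P)\,\pi\,\sigma_H \sigma_V \sqrt{1-\rho^2},
\qquad \chi^2_2(P) = -2\ln(1-P).$$

Two choices deserve note. First, $\chi^2_2(0.63)$ is evaluated exactly
($-2\ln 0.37 \approx 1.9889$), not rounded to 2; microperimeter vendors are
not explicit about which constant they use and the exact quantile is the
defensible reading. Second, $\sigma_H$, $\sigma_V$, $\rho$ use the $n-1$
sample denominator, consistent with the other sample statistics the
pipeline reports. Collinear clouds yield a flagged zero-area result rather
than a crash.

**Coverage-level rule.** The 95% ellipse replaces the 63% one when PRL
eccentricity exceeds a threshold (default 7°, configurable; ties take
0.63). The intent is to counteract cortical magnification: an eccentric ROI
of fixed angular size maps to few vertices, so more eccentric PRLs get the
larger ellipse. The threshold is a free parameter because the underlying
study protocol described the rule only qualitatively; it is recorded in the
ROI summary.

**Binocular fusion and trimming.** The two eyes' sensitivity maps are
translated so their foveae coincide; loci are paired by nearest neighbor
within 0.5° and fused with `seen = seen_L | seen_R`,
`threshold = max(threshold_L, threshold_R)` — "usable vision in at least
one eye" needs nothing stronger than the max. Raster cells of the ROI whose
*nearest* fused locus is unseen are removed (bilateral scotoma); the
operation is idempotent because removal never changes which locus is
nearest to a surviving cell.

**URL placement.** Candidates are the reflection across the vertical
meridian, the reflection across the horizontal meridian, and rotations
about the fovea in $360/n$-degree steps (default $n = 72$, i.e. 5°; the
identity is excluded). All candidates are isometries about the fovea, so
URL eccentricity, shape, area, and any prior trimming are preserved
exactly — the candidate is stored as an orthogonal transform applied to the
PRL's raster, not as a re-rasterization. Scoring maximizes the count of
seen fused loci inside the ROI; ties fall back to the summed thresholds,
then to the documented preference order (vertical flip, horizontal flip,
smallest rotation). The candidate family is a design decision — the manual
procedure it replaces ("rotate or flip in an image editor") was never
enumerated — so the chosen transform and all score ties are logged in the
provenance record.

## 2. Surface model and ROI transfer

**Synthetic retinotopy.** The generator builds a structured ring-by-spoke
sheet per hemisphere instead of triangulating random points: ring
eccentricities sit at quantiles of the radial density
$p(e) \propto M(e)^2\, 2\pi e$ with $M(e) = A/(e+e_0)$ (defaults
$A = 17.3$ mm, $e_0 = 0.75^\circ$, standard human V1 values), so annulus
vertex counts follow the cortical-magnification law by construction, and
the quad-grid triangulation gives exact adjacency and guaranteed
connectivity. Sub-ring jitter (seeded) makes every vertex's eccentricity
unique, which keeps quantile band limits well-defined. Two extra spoke
columns beyond each vertical-meridian edge are flagged non-V1; they stand
in for the V1/V2 border and exercise the pruning rule. The polar-angle
convention (`atan2(y, x)` in degrees, 0 at the right horizontal meridian)
is recorded in the surface metadata.

Note one analytic property of these defaults: integrating
$M(e)^2 2\pi e\,de$ gives normalized mass 0.150 below 2° and 0.178 beyond
45° — the central *annulus count* does not exceed the peripheral one, only
the per-area density does (by more than three orders of magnitude). The
test suite asserts the integral law itself (counts within 5% at 20,000
vertices) and the density ratio.

**Vertex matching.** A V1 vertex joins a field ROI when the raster cell
nearest to its field Cartesian position is inside the mask. Matching in
Cartesian field coordinates, not in raw $(e, \theta)$ pairs, is deliberate:
Euclidean distance on $(e, \theta)$ is anisotropic and degenerate at the
fovea, and "closest eccentricity and polar angle" can only sensibly mean
proximity in the visual field. For a regular raster the nearest cell is
found by clamped rounding, which resolves knife-edge ties toward the lower
cell index deterministically.

**Dilation.** One-ring mesh neighborhoods are the dilation step (the
standard choice on triangulated surfaces); after each ring non-V1 vertices
are pruned, and iteration stops when the combined count reaches the minimum
(default 50). When an ROI spans both hemispheres only the larger portion
grows (ties to the left hemisphere, logged). Dilation is monotone and
idempotent once the minimum is met; the test suite checks ring counts
against an independent breadth-first-search oracle.

**LPZ and bands.** The LPZ is the 100 lowest-eccentricity V1 vertices per
hemisphere (ties at the cutoff broken by vertex id). Eccentricity bands
use half-open intervals $[lo, hi)$ with the last interval closed — a
partition with no double counting. In quantile mode, limits are midpoints
between order statistics at equal-count chunk boundaries of the pooled
hemispheres, giving band sizes equal to within one vertex while applying
identical limits to both hemispheres. The fixed eight-band limits
0, 2.0, 4.3, 6.8, 9.3, 15.7, 26.6, 45.4, 90° are shipped as
`eccentricity_band_limits()`.

**Vertex exclusion.** A validity mask (non-finite or non-positive metric
values) is applied before every aggregation; excluded vertices leave both
the numerator and the count. The upstream study referenced per-vertex
exclusion criteria only by a dangling section reference, so this default
mask is our decision and is documented here rather than attributed.

## 3. Metrics

Thickness is normalized per vertex by the mean over *all* valid vertices of
its hemisphere (not V1 only — the quantity is "mean hemispheric
thickness"), making the per-hemisphere mean of normalized thickness exactly
1 and the measure invariant to global rescaling. ROI values are unweighted
vertex means, pooling hemispheres for split ROIs; no area weighting is
applied because none is defensible without the source meshes' per-vertex
areas.

## 4. The synthetic cohort as a stated world

Defaults are chosen once, from the observed cohort where available, and not
tuned:

| parameter | default | basis |
| --- | --- | --- |
| PRL eccentricity | $\mathcal N(9.7^\circ, 4.2^\circ)$, clamped to ≤ 19° | observed cohort mean/SD/max |
| scotoma radius | 5° | dense central scotomas, PRLs just outside |
| ages | early onset $\mathcal N(47.8, 20.8)$, late $\mathcal N(70.9, 11.4)$ | observed cohort |
| acuity (logMAR) | EO $\mathcal N(1.12, 0.21)$, LO $\mathcal N(0.73, 0.40)$ | observed cohort |
| sensitivity grid | 65 loci: center + rings 2, 6, 10, 14, 18° (8,16,16,16,8) | see below |
| vertex noise SD | 0.08 normalized units | gives ROI-mean SDs of ~0.02, matching plausible group-level F's |
| participant SD | 0.02 | regional between-participant variation |
| diagnosis effect | −0.03 | large standardized effect, as reported upstream |

The ring radii deviate from a first-draft layout ending at 9°: with the PRL
placement distribution above, nearly half of all synthetic PRLs would fall
beyond such a grid and URL placement would have no seen locus in any
candidate. A grid reaching 18° covers the eccentricity range where PRLs are
actually observed; the layout (not the 65-locus count) is a stand-in and is
parameterized.

**Effect-knob convention.** Every effect knob is injected as a sum-to-zero
cell deflection of half its magnitude: `effect_diagnosis = e` deflects MD
cells by $+e/2$ and controls by $-e/2$, so the MD−control difference is
exactly $e$ (the noiseless case is asserted in the tests);
`effect_onset_x_diagnosis = e` deflects cells by
$(e/2)\,s_{diag}\,s_{onset}$, so the early−late difference within an arm is
$e$ and the difference-of-differences is $2e$. This is the orthogonal
parameterization in which "an interaction of $d$ SD units" has the
conventional power behavior (analytic power $\approx 0.98$ for $d = 1.5$ at
8 per cell); the alternative reading — knob = difference-of-differences —
was rejected because it is internally inconsistent with the pinned
diagnosis semantics and would make any standard power target unreachable
at these sample sizes.

**Normalization-aware injection.** Thickness deflections (group effects and
the participant-level offset) are applied to V1 vertices with an exact
compensating offset spread over the non-V1 vertices of the same hemisphere.
In real data V1 is a tiny fraction of the hemisphere, so hemispheric-mean
normalization leaves V1 effects intact; the synthetic sheet is almost
entirely V1, and without compensation normalization would cancel the
injected effects nearly completely. The compensation emulates the real
denominator's insensitivity; it is not a claim that extrastriate cortex
thickens.

**RNG discipline.** All generators take explicit seeds, save and restore
`.Random.seed`, and scramble the seed with a multiplicative hash.
Participant-level sub-seeds are drawn from a master RNG stream rather than
derived arithmetically: Mersenne–Twister streams initialized from seeds
with a constant difference are measurably correlated (we observed pairwise
correlations near −0.05 through identical vertex-subset means, enough to
push a nominal 5% test to 7–8%), and matched participants would otherwise
always sit a constant seed-distance apart.

**What a green test establishes — and what it does not.** The generator
reproduces the statistical *structure* the analysis assumes (Gaussian,
homoscedastic vertex noise; exact retinotopy; a thickness gradient
decreasing with eccentricity; a 2×2 matched between design), not real
data's spatial autocorrelation, lesion-shape irregularity, registration
error, or heavy-tailed artifacts. Green calibration and power tests certify
the inference machinery under the assumed model, not robustness to model
violations.

## 5. Statistics

The mixed ANOVA uses the classical split-plot decomposition via a
multivariate linear model on the participant × within-level matrix:
between-participant effects are tested on participant means against the
participant stratum; the within main effect and its interactions on
orthonormal within contrasts against the participant × within stratum.
Sums of squares are Type III (term deletion from the full model under
sum-to-zero contrasts) because the cells are unbalanced in realistic
cohorts; the SS type is recorded in every result. Covariates enter the
design matrix of both strata additively — which reproduces the
degrees-of-freedom bookkeeping of standard ANCOVA software — with their F
tests reported in the between stratum; eccentricity is log-transformed then
centered (a 1° step near the fovea is a large cortical distance, so log
eccentricity is the better linear proxy), ROI size is centered untransformed.

Sphericity: Mauchly's $W$ from the eigenvalues of the orthonormalized
residual covariance, with Box's second-order $\chi^2$ correction;
Greenhouse–Geisser $\hat\varepsilon$; Huynh–Feldt
$\tilde\varepsilon = ((d_e+1)\,d\,\hat\varepsilon - 2)\,/\,
(d\,(d_e - d\,\hat\varepsilon))$ with $d = k-1$ and error df
$d_e = N - g$ — the Lecoutre-corrected split-plot form, which reduces to
the classic one-group formula and matches base R's `anova.mlm`. The HF
correction rescales within-effect dfs whenever Mauchly rejects at 0.05
(configurable); $\varepsilon$ is reported regardless. With only two within
levels sphericity holds trivially and no correction is attempted; when the
residual covariance is rank-deficient (fewer error df than contrasts) the
diagnostics are reported as `NA` rather than fabricated.

Welch (not pooled) t-tests are used for two-sample comparisons — the
fractional dfs reproduce the published demographic tests exactly — with
the subtraction order an explicit, recorded argument. Post-hocs are Welch
tests per ROI under a single Benjamini–Hochberg family (step-up, monotone,
capped at 1), significant at $q = 0.05$.

**Calibration experiment.** `simulate_rejection_rates()` fixes one cohort
geometry (surface + per-participant ROIs through the full pipeline) and
regenerates metric noise each repetition. Geometry is fixed because it does
not affect the error calibration of the test and regenerating meshes
thousands of times would dominate runtime; PRL eccentricity is held fixed
(`prl_sd_deg = 0`, angles random) because with heterogeneous PRL positions
the matched design shares ROI-position variance between the groups and the
*unpaired* ANOVA becomes conservative (diagnosis rejection near 0 in our
measurements). That conservatism is a property of the matched design — it
is precisely why the ANCOVA with eccentricity and size covariates exists —
not an error of the test.

## 6. Known limitations

- The mesh is a flattened sheet: no 3-D embedding, no geodesic distances in
  millimeters, no gyral folding.
- One within factor; no REML mixed-effects reformulation (explicitly out of
  scope), so missing within-levels abort rather than being modeled.
- The URL search samples a finite candidate set; a continuous optimum could
  in principle score marginally higher between 5° steps.
- Binocular fusion assumes the two eyes' grids are congruent up to the
  pairing tolerance; no torsional alignment.
- The published neuroimaging F statistics depend on the study's MRI data,
  which is not deposited; nothing in this package claims to reproduce them,
  and the acceptance targets are limited to the demographic/ophthalmic
  statistics computable from the published table plus property-based
  contracts.
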