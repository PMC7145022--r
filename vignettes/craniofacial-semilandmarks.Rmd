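---
title: "Craniofacial shape analysis with TPS warping and sliding semi-landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Craniofacial shape analysis with TPS warping and sliding semi-landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Overview

`craniomorph` implements a complete landmark-based pipeline for 3D
soft-tissue craniofacial morphometrics: a 500-point template (20 fixed
anatomical anchor landmarks plus 480 surface semi-landmarks) is
transferred from a template head onto each target surface mesh by
thin-plate-spline (TPS) warping, the semi-landmarks are made
geometrically homologous by bending-energy-minimizing sliding, and the
resulting shape data feed the standard statistical battery of the field:
generalized Procrustes analysis (GPA), hierarchical Procrustes ANOVA
with digitization error, principal components ("relative warps") with
parallel-analysis retention, Euclidean distance matrix analysis (EDMA),
allometric regression, MANOVA slope/intercept tests, canonical variate
analysis (CVA) and cross-validated discriminant classification (DA).

Real head-scan collections of this kind are license-restricted, so the
package ships a synthetic head generator that reproduces the *structure*
of such a study — a 2 ethnicity x 2 sex x 5 age-class design with known
group effects, allometry, individual variation and digitization error —
making every stage testable against ground truth. The `analysis/`
scripts replay the full study on the synthetic population; the package
functions in `R/` carry all the computation.

## The thin-plate spline engine

A TPS in three dimensions interpolates a smooth map $h:\mathbb{R}^3 \to
\mathbb{R}^3$ through $M$ control-point pairs while minimizing the
integrated squared second derivatives (the bending energy). The map
decomposes into a radial non-affine part and an affine part,

$$h(p) = \Psi(p)\,K + p\,\Gamma,$$

with $\Psi_w(p) = \lVert p - s_w\rVert$ the 3D radial kernel (in 3D the
correct kernel is the plain Euclidean distance, not the planar
$r^2\log r$), $K$ the $M\times 4$ non-affine coefficients and $\Gamma$
a $4\times 4$ homogeneous affine transform; points carry a trailing 1.
`fit_tps()` solves the bordered linear system whose constraint block
forces the homogeneous source coordinates to annihilate $K$, so affine
maps live entirely in $\Gamma$ and cost zero energy.

Two numerical choices deserve a note:

* **Energy sign.** The kernel $U(r) = r$ is *conditionally negative
  definite*, so the closed-form energy quadratic form carries a global
  sign flip: `bending_energy` $= -\mathrm{trace}(K_{xyz}'\,\Psi\,
  K_{xyz}) \ge 0$, exactly zero iff the map is affine. The energy is
  always evaluated in this closed form, never by numerical quadrature —
  exact and $O(M^2)$.
* **Smoothing sign.** For the same reason, the smoothing regularization
  $\beta \ge 0$ enters as $\Psi - \beta I$ on the kernel block (the
  familiar "$+\beta I$" belongs to the positive-kernel convention).
  Stationarity of the penalized least-squares objective gives exactly
  this system, and with it the bending energy is monotone non-increasing
  in $\beta$ — a property the test suite asserts. The default is
  $\beta = 0$ (pure interpolation).

The warp direction convention is fixed once: the spline always maps the
*template* (source) onto the *target* (destination), everywhere in the
pipeline. Near-duplicate control points (closer than $10^{-9}$ mm) are
rejected rather than jittered, because silent jitter corrupts
correspondence; coplanar or too-few controls raise a rank error.

## Template construction

The template is a synthetic head (see below) carrying the 20 standard
anchor notations (enl, exl, exr, enr, me, g, n, pr, all, alr, chl, chr,
ls, li, pg, gn, tl, tr, op, ve). `generate_template_semilandmarks()`
spreads `n = 480` surface semi-landmarks from the pronasale — the most
robust and prominent facial point — by random placement followed by
iterative tangent-plane repulsion with closest-point re-projection
(a Lloyd-style uniformization constrained to the surface). Anchors act
as fixed repulsors; the first semi-landmark is initialized on the
pronasale, where the spreading starts, and then relaxes with the rest.
(Pinning it there permanently would duplicate the `pr` anchor and make
the template's bending-energy matrix singular, so it stays fixed only in
the degenerate `n = 1` case.)

The spacing radius (default 1.5 mm) is a *lower bound* on admissible
spacing; the relaxation radius itself adapts to the surface area,
$r_{\mathrm{int}} = \max(\mathrm{radius},\ 1.7\sqrt{A/(n + 20)})$, so
the points spread uniformly even when the surface is much larger than
$n$ disks of the nominal radius. The relaxation is deterministic given
its seed; 40 sweeps are ample at these sizes.

## Transfer and sliding

For each digitized record, `transfer_template()` fits the TPS on the 20
anchor pairs (the anchors establish the warping field), maps the 480
template semi-landmarks through it, and projects every warped point
onto the closest point of the target triangulation (exact
point-to-triangle minimization with barycentric clamping, implemented
in C++ and verified against an independent per-triangle oracle).
Projections that travel farther than 10 x the spacing radius are
flagged with a warning — the threshold is a repository convention, since
no quantitative acceptance threshold is standard.

`slide_semilandmarks()` then relaxes the semi-landmarks in six cycles.
Each cycle:

1. computes tangent frames at the current semi-landmarks (vertex
   normals are area-weighted and interpolated barycentrically);
2. solves, in one dense symmetric system, for the tangent-plane
   displacements of all semi-landmarks jointly that minimize the TPS
   bending energy between the target configuration and the template —
   the classical minimum-bending-energy semi-landmark formulation.
   Anchors never move;
3. scales the displacements by the cycle's step fraction, which decays
   geometrically from 1.00 to 0.05 (ratio $0.05^{1/5} \approx 0.549$;
   the endpoints are fixed, the geometric shape of the decay is a
   repository choice among exponential schedules);
4. re-projects onto the target surface.

Because the energy is exactly quadratic in the positions, the tangent
step never increases it; the re-projection onto the curved surface can,
slightly. A **monotone safeguard** therefore accepts a cycle only if the
projected configuration does not end above the previous cycle's energy
(relative tolerance $10^{-9}$); otherwise the configuration is kept and
the trace records the unchanged energy. This makes the per-cycle energy
sequence non-increasing by construction, which is also what the trace
semantics promise. Convergence is by fixed cycle count (six); an
optional relative-tolerance early stop exists but is off by default.

The sliding trace records the initial energy $E_i$, the per-cycle
energies down to the final $E_f$, and the step fractions. (The
"homologous warping after six energy-reducing cycles" is bookkeeping:
the deliverable is the final configuration plus this energy record.)

## Superimposition and shape statistics

`gpa()` removes translation, scale (all configurations to unit centroid
size) and rotation (orthogonal Procrustes to the iterated consensus,
**rotations only** — reflections are disallowed so anatomical left and
right cannot flip). The consensus is initialized from the raw mean of
the centered, scaled configurations (falling back to the first specimen
if rotations scatter the mean toward zero), which makes GPA an exact
fixed point on already-aligned input. Downstream linear statistics
operate on tangent-space coordinates: the vectorized deviations from
the consensus with their component along the consensus direction
projected out.

* **Procrustes distance** is computed between unit-size configurations
  after a fresh pairwise optimal rotation. Permutation tests on group
  mean-shape distances use the add-one convention,
  $p = (\#\{d^\ast \ge d\} + 1)/(n_{\mathrm{perm}} + 1)$, so $p$ is
  never exactly zero; the default is 10,000 permutations.
* **Procrustes ANOVA** decomposes the summed squared Procrustes
  deviations hierarchically in the fixed order ethnicity, sex, age,
  individual, digitizing error (sequential sums of squares on the
  tangent coordinates, each partition freshly superimposed). Degrees of
  freedom per main effect are $(\mathrm{levels}-1)(3K-7)$ — 53 for the
  20-anchor partition, 1433 for 480 semi-landmarks, 1493 for all 500,
  and 212 for the five-level age effect on anchors. Individual df are
  $(n_{\mathrm{ind}} - 1 - \sum(\mathrm{levels}-1))(3K-7)$ and error df
  are (number of extra digitizations) $\times (3K-7)$; the error and
  individual df conventions of the original software are not derivable
  from its stated design, so the package documents its own ladder and
  treats only the main-effect df as fixed points. F ratios follow the
  hierarchy: effects over the individual mean square, individual over
  the error mean square. With unbalanced replication the main-effect
  F is only approximately centered at 1 under the null (the classic
  unbalanced nested-ANOVA coefficient mismatch); the calibration tests
  therefore use balanced designs.
* **PCA / relative warps** come from the singular value decomposition
  of the centered tangent coordinates; component signs are fixed so the
  largest-magnitude loading is positive. Retention is by parallel
  analysis: each coordinate column is permuted independently across
  specimens (100 randomizations, 95th percentile per rank). The
  advertised "300 computed / 180 retained" style of fixed counts is not
  reproducible from a rank argument, so retention is data-driven with
  an explicit override.
* **EDMA** reports inter-anchor segment lengths on group mean shapes
  rescaled to millimetres by the group's mean centroid size, and their
  base-10 logarithms — base 10 matches the magnitude of anthropometric
  lengths (a 160 mm cranial length has log 2.2).
* **Allometry** is the multivariate regression of tangent coordinates
  on centroid size; predicted and residual components are percentages
  of total variation and significance is by permuting size against
  shape. The pooled within-group correction estimates a common slope on
  group-centered data (groups of size 1 are excluded with a warning)
  and returns residuals plus group means as "size-corrected" shapes.
* **MANOVA** uses `stats::manova()` with Wilks' lambda and Rao's F
  approximation on retained PC scores: the group x size interaction of
  the full model tests slope parallelism, and the group effect of the
  reduced (no-interaction) model tests intercepts. The variance cutoff
  (default 99.98%) is capped so residual degrees of freedom remain.
* **CVA / DA.** CVA solves the within$^{-1}$ x between eigenproblem
  (PCA preprocessing is applied automatically, with a message, when the
  within-scatter is singular) and scales axes to unit pooled
  within-group variance. Classification is linear discriminant analysis
  with pooled covariance (`MASS::lda`), evaluated by leave-one-out
  cross-validation — deterministic and the convention of the usual
  desktop tools; "cross-validated" without qualification is ambiguous.
  Classification operates on individual specimens (averaging specimens
  into group means before DA would make cross-validation meaningless)
  and on retained PC scores rather than raw coordinates, keeping the
  pooled covariance full-rank; the feature count is additionally capped
  below the smallest group size. Mahalanobis distances are computed
  internally by the CVA machinery but not reported.

The pipeline analyses full configurations; no object-symmetry
decomposition is performed (a symmetric/asymmetric split is sometimes
alluded to in this literature without a protocol; the divergence is
deliberate and documented here).

## The synthetic study population

`population_spec()` + `sample_population()` emulate the structure of a
restricted head-scan study: 2 ethnicities x 2 sexes x 5 age classes
(`<13`, `13-19`, `20-29`, `30-49`, `50>`), default cell counts equal to
the real study's cell proportions scaled to a 120-specimen desk total
(`n_per_cell = "full"` restores the original 292), and 30 randomly
chosen specimens digitized twice for the error assessment.

The base head is a smoothly deformed ellipsoid (semi-axes 78 x 95 x 88
mm) with Gaussian feature bumps (nose, chin, brow, mouth inset, cheeks)
on a latitude/longitude triangulation of ~2.2k vertices — deliberately
desk-scale; real scans have ~180k vertices, and resolution is a knob.
Anchors are placed *by construction* on the continuous surface and
snapped to the triangulation; through every deformation they (and the
ground-truth semi-landmarks) are carried by barycentric coordinates, so
they always lie exactly on the deformed mesh.

Per specimen the template is deformed by

* its cell's **fixed effect fields** — ethnicity: cranial
  widening/roundness; sex: nose and mouth protrusion; age: chin and
  forehead protrusion — each a smooth scalar Gaussian bump field applied
  **along the local surface normal** and normalized to unit *peak*
  displacement. A factor amplitude is therefore the millimetre gap
  between the extreme groups at the feature's centre (defaults:
  ethnicity 3, sex 6, age 3 mm), tapering away from it. Group effects
  are localized while individual variation is surface-wide; that is
  what produces the study-typical variance ordering digitization error
  << factor strata << individual stratum;
* a random smooth **individual field**: a low-frequency scalar
  radial-basis offset (14 kernels, 70 mm width) along the surface
  normal, unit RMS over the surface, scaled by `individual_sd`
  (default 1 mm), with kernel centres biased toward the face where real
  between-individual variation concentrates;
* an **allometric field** coupled to the specimen's standardized log
  size, dominated (weight 0.75) by a trace-free linear anisotropic
  scaling — faces elongate and narrow relative to the neurocranium as
  size increases — plus a smooth jaw/cheek bump component (weight
  0.25), peak-normalized, default amplitude 0.8 mm per SD of log size;
* a global size factor (log-normal, SD 0.05, with small deterministic
  age trends and a male size offset).

Normal-direction fields are a deliberate modelling decision, twice
over. Physically, between-individual surface variation *is* a smooth
offset of the skin surface; a tangential displacement field would slide
material points along an unchanged surface, injecting "variation" that
no surface-based landmarking could or should recover. And the
affine-dominated allometry reflects the classical picture of craniofacial
growth allometry as relative elongation; being in the TPS null space it
is transported exactly by the anchor warp and is invariant under
sliding, so the generator's injected allometric percentage is a
well-posed recovery target for the pipeline. Purely localized
high-frequency deformation below the resolving scale of 20 anchors
would be partly unrecoverable by *any* method anchored on those points
— passing recovery tests here therefore shows the pipeline recovers
smooth, anchor-resolvable structure, not that it could resolve
arbitrarily fine variation in real scans.

Digitization noise is i.i.d. Gaussian per coordinate (default 0.1 mm)
applied to the **anchor landmarks at each digitization event**; the
semi-landmark "digitization error" then arises mechanistically, as in
the real protocol, from re-running the warp on the re-digitized
anchors. All randomness flows from the single spec seed through R's
default Mersenne-Twister generator; populations are bit-reproducible.

`ground_truth()` reports per-specimen effect codes and sizes, plus the
injected allometric percentage *by construction*: the true landmark
configurations (no digitization noise, no warping; the generator applies
no rotations) are centered, scaled to unit centroid size and regressed
on centroid size.

## What the synthetic data do not emulate

No texture, no latex-cap artifacts, no scanner holes or noise, no
bilateral asymmetry structure, no real covariance between facial
features, and a mesh three orders of magnitude coarser than a scan.
Tests passing on this population show the pipeline's mathematics and
statistics are correct under its assumptions (smooth, landmark-resolvable
variation; correct anchor correspondence); they do not certify
performance on raw 3dMD scans, automatic anchor detection (anchors are
digitized manually in the emulated protocol), or populations whose
variation is concentrated below the anchor resolving scale.

## Problem sizes and budgets

The test-suite experiments are sized for a desk machine: the acceptance
battery uses the full 480-semi-landmark template on the ~2.2k-vertex
head, a 120-specimen default population (plus 30 re-digitizations) for
end-to-end recovery, 200 null replicates with 499 permutations for the
type-I calibration of the permutation and MANOVA tests, and 100 random
configurations for TPS exactness. The `analysis/` scripts run the same
defaults with 10,000 permutations. The degrees-of-freedom checks are
design quantities and independent of sample size.

## Known limitations

* Sliding relaxes tangential placement toward the minimum-bending-energy
  configuration, which is systematically *smoother* than material-point
  homology; localized group differences are therefore mildly attenuated
  relative to an idealized material correspondence. This is intrinsic to
  the minimum-bending-energy criterion, not a defect of the solver.
* The closest-point projection scans all triangles (no spatial index);
  fine for desk-scale meshes, quadratic-ish for scan-scale ones.
* The Procrustes ANOVA F ratios are the standard Goodall-style
  approximations; with strong anisotropy of landmark covariance or
  heavy unbalance they are approximate, as in the desktop tools they
  mirror.
* OBJ support covers `v`/`f` records (fan triangulation of polygons);
  PLY covers ASCII and binary-little-endian with `x`,`y`,`z` vertex
  properties. Landmark files are plain CSV (`label,x,y,z`, mm,
  dot-decimal); semi-landmarks get generated labels `s0001...`.
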