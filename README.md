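# craniomorph

Geometric-morphometric analysis of 3D soft-tissue craniofacial shape in
R: thin-plate-spline (TPS) multi-point warping with sliding
semi-landmarks, and the downstream statistical battery used to study
shape variation across ethnicity, sex and age groups.

**Who it is for.** Researchers in craniofacial anthropometry, forensic
facial analysis and geometric morphometrics who need a fully scripted,
testable version of the classic desktop workflow (template warping +
GPA + Procrustes ANOVA + PCA/EDMA/CVA/DA) — and anyone who needs a
synthetic 3D head population with known ground truth to validate such a
pipeline, since real head-scan collections are license-restricted.

## The method

A 500-point template — 20 fixed anatomical **anchor landmarks** (enl,
exl, exr, enr, me, g, n, pr, all, alr, chl, chr, ls, li, pg, gn, tl,
tr, op, ve) plus 480 surface **semi-landmarks** spread from the
pronasale at a 1.5 mm spacing radius — is transferred onto each target
head mesh and made homologous:

1. **TPS warp.** The 3D thin-plate spline `h(p) = Ψ(p) K + p Γ`, with
   radial kernel `Ψ_w(p) = ‖p − s_w‖`, is fitted on the 20 anchor pairs
   by solving the bordered system; at smoothing β = 0 it interpolates
   the anchors exactly, and its bending energy (the integrated squared
   second derivatives) is evaluated in closed form from the non-affine
   coefficients.
2. **Projection.** Warped semi-landmarks are projected onto the closest
   point of the target triangulation (exact point-to-triangle
   minimization, in C++).
3. **Sliding.** Six cycles of bending-energy-minimizing relaxation: per
   cycle the tangent-plane displacements of all semi-landmarks that
   minimize the TPS bending energy against the template are solved as
   one dense symmetric system, scaled by a step fraction decaying
   geometrically 1.00 → 0.05, and re-projected onto the surface.
   Anchors never move.
4. **Statistics.** Generalized Procrustes analysis (unit centroid size,
   rotations only), hierarchical Procrustes ANOVA with digitization
   error (main-effect df = (levels − 1)(3K − 7)), PCA with
   parallel-analysis retention, EDMA log10 inter-anchor distances on
   group means, multivariate regression of shape on centroid size with
   permutation tests, pooled within-group size correction, MANOVA
   (Wilks' Λ) slope/intercept tests, CVA, and leave-one-out
   discriminant classification.

A synthetic head generator (`make_head_mesh()`, `population_spec()`,
`sample_population()`, `ground_truth()`) emulates the structure of a
292-specimen study — 2 ethnicities × 2 sexes × 5 age classes with 30
re-digitized specimens — with known group effects, allometry,
individual variation and digitization noise, so every stage is testable
against ground truth. See the methods vignette
(`vignettes/craniofacial-semilandmarks.Rmd`) for the model, parameter
meanings and design decisions.

## Worked example

```r
library(craniomorph)

## template: synthetic head + 20 anchors + 480 sliding semi-landmarks
base <- make_head_mesh()
tmpl <- generate_template_semilandmarks(base$mesh, base$anchors,
                                        n = 480, radius = 1.5, seed = 7)
tmpl
#> <template_model> 20 anchors + 480 semi-landmarks (seed 'pr', radius 1.5 mm)

## a small synthetic study population (2 x 2 x 5 design, 8 re-digitized)
spec <- population_spec(seed = 42, n_redigitized = 8)
spec$counts[] <- 1; spec$counts[1, 1, ] <- 2; spec$counts[2, 2, ] <- 2
pop <- sample_population(spec, template = tmpl)
pop
#> <synthetic_population> 30 individuals, 8 re-digitizations

## warp the template onto one specimen and slide the semi-landmarks
tr <- slide_semilandmarks(tmpl, pop$meshes[["S001"]],
                          pop$anchors[["S001"]])
tr
#> <sliding_trace> 6 cycles; E_i = 0.9186 -> E_f = 0.8674
round(tr$step_fractions, 3)
#> [1] 1.000 0.549 0.302 0.166 0.091 0.050

## homologous configurations for every record -> Procrustes ANOVA
configs <- lapply(seq_len(nrow(pop$meta)), function(i) {
  ind <- ifelse(is.na(pop$meta$replicate_of[i]), pop$meta$id[i],
                pop$meta$replicate_of[i])
  slide_semilandmarks(tmpl, pop$meshes[[ind]],
                      pop$anchors[[pop$meta$id[i]]])$landmarks
})
arr <- aperm(simplify2array(lapply(configs, function(l) l$points)),
             c(3, 1, 2))
procrustes_anova(arr, pop$meta, partition = "anchors", anchor_count = 20)
#>             effect var_pct       SS       MS   DF     F         p
#> 1        ethnicity  18.688 2.58e-03 4.86e-05   53 22.97 2.44e-146
#> 2              sex  52.739 7.27e-03 1.37e-04   53 64.82  0.00e+00
#> 3        age_class   9.480 1.31e-03 6.17e-06  212  2.91  1.35e-30
#> 4       individual  18.712 2.58e-03 2.12e-06 1219 17.05 3.81e-164
#> 5 digitizing_error   0.382 5.27e-05 1.24e-07  424    NA        NA
#> 6            Total 100.000 1.38e-02       NA 1961    NA        NA
```

Reading the table: the bending energy drops from 0.919 to 0.867 as the
semi-landmarks relax; the step fractions follow the configured
exponential decay. In the ANOVA, all three group effects are highly
significant, digitizing error is a negligible 0.4% of the total shape
variance, and the main-effect degrees of freedom are the design
quantities (levels − 1) × (3 × 20 − 7): 53 for the two-level factors
and 212 for the five age classes. (At this demonstration size, 30
individuals, the factor percentages are noisy; the full 120-specimen
default population in `analysis/` gives the study-typical ordering with
the individual stratum dominant.)

## The analysis workflow

The numbered scripts under `analysis/` replay the complete study on the
default 120-specimen synthetic population (run from the repository
root, in order):

| script | stage |
|---|---|
| `analysis/01_simulate.R` | template + synthetic population + ground truth |
| `analysis/02_warp.R` | TPS transfer + six-cycle sliding for all 150 records |
| `analysis/03_align_anova.R` | GPA + Procrustes ANOVA (anchors / semi-landmarks / all) |
| `analysis/04_ordination_edma.R` | PCA + parallel analysis + EDMA distance tables |
| `analysis/05_allometry_manova.R` | allometric regressions, size correction, MANOVA |
| `analysis/06_classify.R` | permutation distances, CVA, LOO discriminant analysis |

Tables land under `results/tables/`, heavy intermediates under
`results/cache/`. Everything is deterministic in the seed set in
`analysis/00_common.R`.

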