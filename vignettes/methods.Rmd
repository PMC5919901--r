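---
title: "Reconstructing brains from endocasts: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing brains from endocasts: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A fossil cranium preserves no brain, only the shape of the endocranial
cavity — the endocast. The inference this package implements runs in three
steps. First, a large living cohort with both brains and endocasts defines
a population-average endocast and the population-average brain enclosed in
it, via iterative diffeomorphic registration. Second, the deformation that
carries a fossil endocast onto the average endocast is estimated; because
the deformation model is a diffeomorphism, its inverse transports the
average brain — and an anatomical parcellation of it — back into the
fossil cavity, yielding regional volume estimates for an animal that died
tens of millennia ago. Third, the resulting specimen-by-region volume
tables and homologous surface meshes feed standard morphometric statistics:
ICV-adjusted ANOVA with Ryan's pairwise procedure, vertex-wise Hotelling
$T^2$ maps, cerebellar laterality analysis, and cognition regressions on a
living reference cohort.

Real MRI and fossil CT data cannot ship with a package. Every input is
therefore produced by a synthetic phantom generator with exactly known
ground truth, and the validation protocols (leave-one-out reconstruction,
parcel accuracy, cross-cohort transfer) are run against that truth. All
phantom objects are labelled synthetic in their documentation; nothing in
`inst/` or `results/` is derived from real specimens.

## Deformation model

Deformations are parameterized by a stationary velocity field $v$ on the
voxel grid, in voxel units. The map is its group exponential,
$\varphi = \exp(v)$, computed by scaling and squaring:
$\varphi = (\mathrm{id} + v/2^N)^{\circ N}$ with $N = 6$ by default, and
$\varphi^{-1} = \exp(-v)$. Registration minimizes

$$E(v) = \sum_x \left(M(\exp(v)(x)) - F(x)\right)^2
  + \lambda\,\mathrm{LE}(v), \qquad
\mathrm{LE}(v) = \frac{\mu}{4}\sum_{ij}\lVert D_i v_j + D_j v_i\rVert^2
  + \frac{\lambda_L}{2}\lVert \operatorname{div} v\rVert^2,$$

a mean-squared-difference match with a linear-elastic (strain + divergence)
penalty, discretized by central differences with replicated edges. The
optimizer is steepest descent with Armijo step halving on the exact
objective, coarse-to-fine over 3 levels; the match-term gradient uses the
standard first-order approximation that treats $d\exp(v)/dv$ as the
identity (as in log-domain demons), which costs nothing in correctness
because every step is accepted only if the true objective decreases.
Gauss–Newton schemes converge in fewer iterations but each iteration is
far heavier; at the $48^3$ desk scale used throughout, Armijo descent with
a smoothed (FWHM 4 voxels) descent direction is the better trade and keeps
the code transparent.

Two interpolation paths coexist deliberately. Image warps are trilinear
(labels: nearest neighbour, rounding half away from zero, background 0
outside the grid). Displacement-field resampling inside `exp_velocity()`
and `compose_deformation()` defaults to Catmull–Rom tricubic, because the
truncation error of trilinear interpolation on curved displacement fields
dominates the inverse-consistency error; the optimizer's internal
exponentials use the linear path for speed, a split many registration
toolkits make. Within one voxel of the grid boundary the cubic stencil
would extrapolate, so it falls back to trilinear there.

Edge handling is by clamping, which means flow trajectories that exit the
grid are not invertible; all flow-field invariants (inverse composition
within 0.05 voxels, positive Jacobians, agreement with a dense Euler
integration oracle within 0.02 voxels) are therefore stated and tested
outside a 3-voxel boundary clamp zone, mirroring the explicit clamp-zone
qualifier in the exponential's contract. Registration operates on binary
masks smoothed with a Gaussian of FWHM 2 voxels — fossil "images" are
cavity masks, and the smoothing gives the matching term a capture range.

Registration direction: fossils are registered *to* the average endocast
(fossil moving), and the average brain is pulled back through
$\exp(-v)$ composed with the inverse of the affine pre-alignment
(centroids, principal axes without reflection, isotropic scale from the
cube-rooted mass ratio). Estimating the opposite direction and inverting
is equivalent up to the inversion error, which the inverse-consistency
bound controls.

## The phantom generator

The canonical phantom is a deterministic arrangement of ellipsoids on a
$48^3$ grid (1 mm voxels): two cerebral hemispheres, two cerebellar lobes
and a midline vermis, each with a WM core (62% linear scale) and GM shell,
inside a CSF-filled cavity; it is mirror-symmetric about the mid-sagittal
plane by construction. Its atlas has 25 regions — 12 per hemisphere plus
the vermis — grouped into the 13 lobe groups used by every downstream
statistic, and 14 named landmarks ray-cast onto the endocast surface.

Specimens are pull-backs of the canonical phantom through
$\exp(v_{\text{group}} + v_{\text{indiv}})$:

* **Group effects** are radial velocity fields realizing *volumetric*
  scale factors (linear factor $s^{1/3}$) over a smooth weight that is ~1
  across the target region and decays outside; lateralized effects are
  gated at the mid-sagittal plane with a ~3-voxel logistic ramp. A scale
  descriptor of 0.85 therefore means "85% of the canonical volume", the
  reading consistent with the expected cohort-mean bracket and with the
  few-percent cerebellar deficits under study. The NT-like default is
  cerebellum ×0.85 with the right half ×0.92.
* **Individual variation** is Gaussian-smoothed white-noise velocity
  (FWHM 8 voxels), RMS-scaled to `variation_sd` = 0.8 voxels by default —
  enough to produce regional volume CVs of a few percent, comparable to
  human inter-individual variability, while keeping every specimen
  diffeomorphic to the canonical anatomy (positive Jacobians are tested).

Because nearest-neighbour label transport is the identity for sub-half-
voxel displacements, a pure group effect with zero individual variation is
quantized away at desk resolution; with the default individual variation
the rounding is dithered and cohort-mean effects converge to the
generative factor (the 0.85 cerebellar factor realizes as 0.86 ± 0.07 over
specimens). This is a deliberate property of hard-label volumetry, which
the volumetric evaluation inherits from the voxel-counting accuracy
protocol.

T1-like images use fixed class intensities (CSF 0.2, GM 0.6, WM 1.0) plus
Gaussian noise (SD 0.05). The generator does not emulate cortical folding,
MRI bias fields or CT artifacts; passing tests show the pipeline's
geometric and statistical machinery is correct, not that it is robust to
real-scanner physics.

## Segmentation

Tissue probability maps do not exist for phantoms, so segmentation is an
EM Gaussian mixture on intensities within the head mask (k-means
initialization, deterministic given a seed), with classes reported in
CSF < GM < WM mean order regardless of initialization. An optional
one-parameter Potts-style smoothing of the posteriors is applied after
convergence so the exact-EM monotone log-likelihood guarantee is
preserved; its default weight is 0. Masks binarize summed posteriors at
0.5 (majority rule, stated explicitly because no binarization rule is
canonical); ICV integrates the *soft* fractions, matching the definition
of ICV as total GM+WM+CSF volume — both soft and hard modes exist because
the choice is not settled, and they agree within the partial-volume mass.

## Endocast restoration

Missing regions are filled by warping an intact reference endocast through
an interpolating 3-D thin-plate spline fitted on the surviving landmark
pairs. The kernel is the 3-D biharmonic $U(r) = r$ (the mathematically
correct choice in three dimensions; $r^2\log r$ is the 2-D kernel). The
spline maps each landmark exactly, reproduces affine relations with zero
bending energy, and its bending energy is rigid-motion invariant — all
asserted as exact tests. Only voxels inside the hole mask are replaced;
residual cavities of up to 2 voxels are closed morphologically. Landmark
correspondences are fixed (supplied by the generator): semi-landmark
sliding is a separate optimization that this package does not implement.
The refit loop defaults to 2 iterations; with fixed correspondences
further iterations are idempotent, and the chained restorations used for
heavily damaged specimens are expressed as successive `restore_endocast()`
calls.

## Surface morphometry

The template brain mesh (marching tetrahedra on the Kuhn 6-tetrahedra
cube subdivision — conforming across cubes, hence closed and orientable,
with outward normals; ~5,000 vertices at desk scale where the full-scale
analysis used ~50,000) is propagated through each specimen's inverse warp,
giving homologous meshes. Generalized Procrustes superimposition removes
translation, rotation (Kabsch, reflections excluded) and scale; size
normalization is to unit centroid size, the geometric-morphometrics
default, stated here because no normalization is canonical.

Per vertex, the two-sample Hotelling statistic on 3-D displacement vectors
is
$T^2 = \frac{n_a n_b}{n_a + n_b}\, \bar d^\top S_p^{-1} \bar d$, with
parametric $p$ from $F = T^2 (n-4) / (3(n-2))$. The pooled $3\times3$
covariances are inverted in closed form across all vertices; vertices with
numerically singular covariance get a $10^{-8}\cdot\mathrm{trace}$ ridge
and are flagged. Family-wise error control uses the permutation
distribution of the maximum vertex statistic — exact under exchangeability
of group labels, with full enumeration whenever the number of distinct
relabelings is small. Random-field-theory correction was rejected: RFT
for $T^2$ fields on irregular meshes needs smoothness-estimation machinery
whose assumptions the desk-scale meshes would strain, while the
permutation test's only assumption is exchangeability. Pairwise contrasts
are primary (mirroring the three group-pair maps); an omnibus Pillai-trace
MANOVA per vertex is provided as a secondary route.

## Group statistics

Volumetrics are carried in mm³ and reported in cc. Group summaries use
$n-1$ standard deviations, and the cerebellum/cerebrum ratio is the mean
of per-specimen ratios, not the ratio of means. ICV adjustment is two-step
residualization (pool all specimens, fit volume on ICV, keep residual plus
grand mean) rather than a joint ANCOVA — this is what reproduces the
published error degrees of freedom of $N - k$ (1190 at $N = 1193$,
$k = 3$) and makes adjusted volumes exactly orthogonal to ICV.

"Ryan's method" is implemented as the sequentially rejective pairwise
procedure: order the $k$ group means; a pair spanning $r$ ranks is tested
with a pooled-variance $t$ at nominal level $2\alpha / (k(r-1))$, and a
pair is declared significant only if every enclosing pair is. The exact
schedule the original analyses used is not recoverable, so the schedule
lives in one small function that can be swapped.

The laterality analysis treats side as a within-specimen factor: the
group × side interaction is the one-way ANOVA of the per-specimen L−R
differences; simple main effects of side within a group use the pooled
difference variance (error df $N - k$); between-group contrasts per side
use the $2N$-observation cell-model error (df $2N - 2k$ = 2380 at full
cohort). Symmetrized and mirrored atlas variants are averaged per
specimen/side before analysis. Detection of the prespecified "right
smaller than left" effect is assessed one-sided, since the hypothesis is
directional by construction. The symmetrized atlas itself is built by
registering a template constructed from images plus their mid-sagittal
mirror copies (flips are about the grid's centre plane, exact on
even-sized grids) and pulling the atlas into that frame; the mirrored
variant swaps left/right region identities by table lookup.

Cognition regressions fit `volume ~ score + ICV + age + sex` per task
(t on $n-5$ df; 1090 at $n = 1095$) with Bonferroni over the seven tasks.
The synthetic cognition generator was deliberately written in the same
direction as this analysis model — volume linear in confounds plus
$\sum_t \beta_t \cdot \text{score}_t$ with exogenous scores — so the
generative slopes are exactly recoverable at zero noise and the coverage
and null-error-rate simulations are meaningful; a generator in the
reverse regression direction would make "recovering $\beta$" ill-defined.

## Validation protocols and problem sizes

All stochastic conditions are fixed choices of the phantom system, stated
here once: cohorts default to $48^3$ grids with `variation_sd` 0.8;
the leave-one-out benchmark runs 8 specimens at $32^3$ with a lightened
registration schedule (iterations 20/14/7, one outer template pass, three
single-subject donors per fold, spread over the cohort); known-warp recovery and reconstruction
fidelity run at $48^3$; FWE calibration uses 20 null replicates of 10 + 10
sphere-mesh specimens with 500 permutations; the cognition simulations use
$n = 150$ with 100 replicates. Registration fidelity is checked against a
256-step forward-Euler flow oracle; reconstruction accuracy against the
generative warp (Dice ≥ 0.95); the template-versus-single-subject contrast
by a paired sign test over regions, the desk-scale analogue of the
published accuracy contrast between population-template and
individual-donor reconstructions.

## Known limitations

The phantom's smooth ellipsoidal anatomy makes registration easier than
real gyrified brains; accuracy numbers here bound the method's geometric
machinery, not its performance on real endocasts. Hard-label volumetry
quantizes sub-half-voxel effects at desk resolution. The affine
pre-alignment assumes unimodal, roughly convex masks (principal-axis
pairing falls back to centroid + scale when the moment tensor is
degenerate). Semi-landmark sliding, fragment reassembly of broken crania,
CT artifact handling and real atlas distributions are out of scope.
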