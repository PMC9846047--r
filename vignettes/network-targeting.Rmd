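---
title: "Network-targeted TMS coil placement: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-targeted TMS coil placement: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netarget)
```

## The model

Repetitive transcranial magnetic stimulation (rTMS) modulates not only the
cortex under the coil but the whole functional network connected to it.
`netarget` implements a targeting model built on that observation. For a
coil placement described by a scalp position $s$ and a handle orientation
$\theta$, the model composes four maps over the $N$ gray-matter voxels of a
reference grid:

1. **Local effect** $E_l(s,\theta)$: the induced electric field is
   thresholded at a percentage of its robust peak; the suprathreshold
   voxels carry signed weights $+w_i$ for excitatory (high-frequency,
   $> 5$ Hz) protocols and $-w_i$ for inhibitory ($\le 1$ Hz) protocols,
   zero elsewhere. By default $w_i$ is the field magnitude at voxel $i$;
   frequencies in $(1, 5]$ Hz have no accepted polarity and are rejected.
2. **Stimulation network**
   $E_n(s,\theta) = C\,E_l(s,\theta) / \lVert E_l(s,\theta)\rVert_1$, where
   $C$ is the voxel-wise signed resting-state functional connectome. With
   the 1-norm taken over absolute weights this is the weight-averaged
   combination of the seed maps of the stimulated voxels; excitatory and
   inhibitory protocols give exactly negated networks, and with a
   correlation-valued $C$ every entry stays in $[-1, 1]$.
3. **Pathological network** $P = I_{pt} - I_{hc}$: the patient-minus-control
   activity contrast of a disorder, supplied either as two state maps or as
   a coordinate-based meta-analysis foci table (signed spheres of a given
   radius around each reported peak, combined additively so overlapping
   hyper- and hypoactive foci cancel).
4. **Network targeting accuracy**
   $\mathrm{NTA}(s,\theta) = -\,\mathrm{corr}\langle E_n(s,\theta),\,P\rangle$,
   the spatial anti-correlation between the stimulation network and the
   pathological network, hypothesized to predict clinical improvement.
   Stimulation that excites what the disorder suppresses (and vice versa)
   scores high.

The package provides the full parameter space machinery around this chain:
a continuous proportional coordinate (CPC) system on the scalp, exhaustive
grid search over placements, cohort-level validation statistics with two
permutation nulls, and a synthetic-study generator that exercises every
step without external data.

## Scalp coordinates and the coil frame

Positions are expressed in CPC coordinates $(p_{NZ}, p_{AL}) \in [0,1]^2$
anchored to four fiducials: nasion (NZ), inion (IZ), and the left and right
preauricular points (AL, AR). The construction is by plane slicing, chosen
because exact triangle–plane intersection is deterministic and free of the
staircase bias of vertex-path shortest paths:

* the *sagittal curve* is the surface cut by the plane through NZ, IZ and
  the midpoint of AL–AR (for a perfectly symmetric head, where that
  midpoint falls on the NZ–IZ line, the plane is spanned instead by the
  landmark-derived up direction); $p_{NZ}$ is arc-length fraction from NZ;
* the *coronal curve* through the sagittal point at $p_{NZ}$ is the surface
  cut by the plane through AL, AR and that point; $p_{AL}$ is arc-length
  fraction from AL.

Every coronal curve passes through AL and AR, so those are poles of the
coordinate system: at $p_{AL} \in \{0, 1\}$ the $p_{NZ}$ coordinate is
undefined (`cpcInverse` returns `NA` there), and $p_{NZ} \in \{0,1\}$
collapses to NZ/IZ. Grid steps near the poles correspond to tiny physical
distances; search spaces should stay in the open interior.

The coil frame at a position takes its outward normal from the
area-weighted face normals of the containing triangle's 1-ring. The
0° reference direction lies in the tangent plane, perpendicular to the
intersection of the tangent plane with the AL–AR plane through the
position, pointing backward (toward IZ). The handle angle $\theta \in
(-180°, 180°]$ rotates that direction about the outward normal;
anticlockwise rotation viewed from outside the head is positive. Both
conventions are covered by rotation-matrix oracle tests.

`restorePlacement` inverts a cortical target in MNI mm to the scalp
position whose inward normal best points at it, the standard way published
stimulation sites are projected back to the scalp; ties in alignment are
broken by Euclidean distance (which also disambiguates the antipodal
patch, whose inward normal points at the target through the head), then by
distance to the landmark centroid, then by vertex order.

## The simplified E-field

Realistic finite-element field solutions can be supplied as volumes (any
function `(frame, grid) -> BrainMap` plugs in). For desk-scale work the
package ships an analytic stand-in:

$$E(\mathbf{x}) = \text{peak} \cdot
  \exp\!\left(-\tfrac{r^2}{2\sigma^2}\right) \cdot
  \exp\!\left(-\tfrac{d}{\lambda}\right)$$

with $r$ the tangential distance from the coil axis, $d$ the depth below
the scalp along the inward normal, $\sigma = 12$ mm (a figure-8 focality
of a few centimetres FWHM), $\lambda = 18$ mm (fields fall to roughly a
third over the first two centimetres of depth), and peak $100$ V/m (a
typical motor-threshold field). An `anisotropy` ratio below 1 narrows the
footprint across the handle, which is what makes NTA orientation-sensitive
for the stand-in; 1 gives the exactly axisymmetric form above. The
stand-in uses the field magnitude, not the component normal to the
cortical surface — no cortical geometry is modeled at this scale.

Thresholding is relative to a *robust peak*, the 99.9th percentile of the
strictly positive gray-matter magnitudes, so a single spiked voxel in an
imported FEM solution cannot silently shift the support. The threshold
percentage (75–99 is the range the sensitivity sweep covers) and a
uniform-weight mode are exposed as options.

## Connectome backends

The connectome is either a dense symmetric $N \times N$ matrix with unit
diagonal or a column-standardized time-series table; the lazy backend
evaluates $C v$ as $X^\top (X v)/(T-1)$ and agrees with the dense product
to $10^{-8}$ by contract (and test). $C$ stores raw Pearson $r$, keeping
the $[-1,1]$ bound that the convexity property of $E_n$ relies on; users
with Fisher-z matrices can supply them as dense input unchanged, since the
operator algebra is agnostic to the scale.

## Grid search, ANOVA, sensitivity

`gridSearch` evaluates every position × orientation combination with no
early stopping; failed placements (e.g. empty suprathreshold support)
become `NA` cells excluded from the argmax, whose ties break
lexicographically. The two-way position × orientation ANOVA across
subjects uses the balanced fixed-effects sums-of-squares decomposition in
closed form (verified against `aov` and a brute-force oracle); grids with
missing cells are rejected rather than imputed, and a zero error variance
is a degeneracy error. Sensitivity sweeps rebuild the chain across
E-field thresholds (75–99%) and foci radii (4–16 mm, default 10 mm — the
midpoint of that range) and report correlations between the resulting NTA
vectors.

## Cohort statistics

`efficacyCorrelation` reports the Pearson correlation between NTA and
clinical improvement with a one-tailed p-value ($t$ transform, $n-2$ df);
the directional hypothesis is always that higher NTA predicts larger
improvement. Two permutation nulls accompany it, both with the $+1$
correction $p = (1 + \#\{r^* \ge r_{obs}\})/(1 + n_{perm})$ and a fixed
seed:

* **Outcome reassignment** permutes the outcome column.
* **Random networks** relocates every pathological focus to a uniformly
  sampled gray-matter voxel (count, signs and weights preserved), rebuilds
  $P$, recomputes each subject's NTA at their fixed placement, and
  recomputes the cohort correlation. Only the pathological map is
  randomized; the connectome is left intact. A relocation hook is exposed
  for testing (forcing the identity relocation returns $p = 1$ exactly).

`partialCorrelation` controls sex (binary indicator) or age by
residualizing both variables on the covariate with an intercept, with
$n-3$ df; no interaction terms.

## The synthetic study

The generator emulates every input at desk scale, deterministically under
one seed:

* **Head**: a subdivided icosphere scaled to an ellipsoid (default nominal
  radius 90 mm, axis ratios 0.85/1/0.95 — a slightly elongated head), with
  the fiducials at analytic positions on the $z = 0$ plane.
* **Gray-matter shell**: voxels whose ellipsoidal radius lies 12–24 mm
  beneath the scalp (a scalp-to-cortex clearance of about 12 mm and a
  roughly centimetre-thick ribbon), on an isotropic grid (6–7 mm in the
  shipped studies, roughly 2,000 voxels).
* **Connectome**: $K$ spatially contiguous networks (angular sectors,
  sector 1 centered anteriorly) driven by block-correlated factors, plus a
  spatially local component (squared-exponential kernel smoothing of white
  noise) and i.i.d. voxel noise. The local kernel is a deterministic
  function of the grid, so every realization shares one spatial
  covariance; realizations differ only in their time courses. The planted
  studies use a local-dominant split (within-network 0.35, between
  $-0.15$, local 0.45 at 14 mm): in real resting-state data nearby voxels
  correlate far more strongly than a network's average, and it is this
  local structure that makes coil *position within* a network
  identifiable. With a purely block-structured connectome every placement
  inside a network yields the same expected stimulation network, and
  worse, the correlation denominator collapses wherever the E-field
  support straddles a network boundary, amplifying noise into spurious
  NTA peaks there.
* **Pathology**: a compact cluster of hypoactive ($-1$) foci on the target
  network and a hyperactive ($+1$) cluster on its anti-correlated partner
  — the frontal-limbic motif in miniature. Clusters are drawn from the
  superior cap (polar angle under 50°) and the angular core of their
  sector, implementing the reachability precondition: near the
  preauricular poles CPC grid steps shrink to nothing, and near a network
  boundary the denominator artifact above biases the optimum, so a
  planted-recovery question is only well-posed for interior targets.
* **Cohort**: per-subject connectome realizations, placements jittered
  uniformly (±0.18 CPC) around the target's scalp projection, and outcomes
  $\beta \cdot \mathrm{NTA} + \varepsilon$. The noise scale is set from a
  target population correlation (0.9 by default) unless given explicitly;
  linearity is the simplest form consistent with a monotone
  NTA–outcome association.

The planted-recovery study runs on a *spherical* head: there the
normal-aligned scalp projection of a cortical cluster coincides with the
nearest scalp point, so the model's noise-free optimum sits exactly at the
projected truth; on an ellipsoid the two notions separate by design, which
is a property of the geometry, not an error of the search.

### What passing tests do and do not show

The generator's networks are contiguous sectors with exchangeable voxels,
its E-field is an analytic kernel, and its outcomes are linear-Gaussian in
true NTA. Tests passing on these studies demonstrate the internal
consistency of the chain — algebraic identities, oracle agreement,
geometric convergence, recovery of a planted optimum, calibrated nulls —
not that NTA predicts outcomes in real patients, which requires clinical
cohorts, individual head models and a measured group connectome.

## Numerical choices and problem sizes

Curves are chained from exact triangle–plane intersections with on-plane
vertices nudged by $10^{-9}$; the inverse CPC map solves for the coronal
plane containing the query by bisection to $10^{-10}$ and tolerates
off-surface queries up to two mean edge lengths. Correlations of
degenerate (constant) maps are errors, never silently dropped. The shipped
test and acceptance studies use level-3 icospheres (1,280 faces; level 4
for geometry tolerances), 7 mm shells (~1,900 voxels), 200-timepoint
connectomes, 20-subject recovery runs over 60 positions × 12 orientations,
200 replicates × 1,000 permutations for null calibration (the validation
workflow default is $10^5$ permutations), and 50 replicates for power —
sizes chosen so the full suite reproduces the behavioral claims in
minutes on one core while keeping every Monte-Carlo band comfortably
non-degenerate.

## Known limitations

* The stand-in E-field has no tissue conductivity, gyrification or coil
  inductance; import FEM volumes where realism matters.
* Group connectome construction across many subjects (including the
  Fisher-z averaging question) is out of scope; the package consumes one
  supplied operator.
* The random-network null relocates foci only; nulls that randomize the
  connectome are not implemented, and reports label the null accordingly.
* Surface-based (vertex-wise) analysis, nonlinear spatial normalization,
  mesh registration and automatic fiducial detection are out of scope.
* Mesh I/O is ASCII PLY (plus TSV landmarks); STL/GIfTI readers are not
  bundled.
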