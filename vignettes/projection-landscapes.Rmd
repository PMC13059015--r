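---
title: "Projecting reaction-path optimizations onto invariant 2D landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting reaction-path optimizations onto invariant 2D landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathscape)
```

## The problem

Double-ended saddle-search methods (nudged elastic band, string methods)
produce long optimization histories: hundreds to thousands of molecular
geometries with energies and forces, of which only the final converged path
is usually inspected. The standard one-dimensional diagnostics — energy
against image index, or against the cumulative displacement
$s_i = \sum_j |R_j - R_{j-1}|$ — collapse all geometric information onto a
single history-dependent axis. They cannot show whether two saddle
estimates from different methods sit in the same basin, whether the
optimizer wandered through alternative pathways before converging, or
whether a machine-learned potential's saddle is geometrically close to a
higher-level reference.

pathscape reconstructs a two-dimensional, coordinate-free view of such
histories. Every sampled geometry $X$ is mapped to

$$(r, p) = \big(d(X, R),\; d(X, P)\big),$$

its permutation- and rotation-invariant RMSD distances from the reactant
$R$ and product $P$. Because the references are fixed, these coordinates
are comparable across methods, potentials, and runs — no descriptors, no
training, no presupposed reaction coordinate.

## The invariant metric

The distance is the root-mean-square deviation after jointly optimizing a
proper rotation $Q \in SO(3)$ and a within-element atom permutation $\Pi$:

$$d(X, X_\mathrm{ref}) = \min_{Q,\Pi}
  \sqrt{\tfrac{1}{N}\,\lVert X - Q\,\Pi X_\mathrm{ref}\rVert_F^2}.$$

`matchStructures()` solves this with a multi-start alternating scheme:
candidate initial rotations come from aligned atom-triplet local frames
(near neighbors within the `kmax` adjacency cutoff, default 3.5 Å, which
covers covalent adjacency), from principal-axes alignments, and from a
fixed octahedral rotation set; each start then alternates minimum-cost
bipartite assignment (squared-distance cost, per element block) with a
Kabsch rotation until the assignment stabilizes. Reflections are excluded
by flipping the smallest singular vector whenever the Kabsch determinant
is negative, so $Q$ is always a proper rotation. Ties between equally
optimal permutations resolve to the lexicographically lowest one, making
results deterministic. The default of 64 triplet starts was chosen so the
matcher attains the exhaustive permutation-enumeration minimum on random
small clouds, the hardest case we test; near-matching structures, the
practical workload, converge in far fewer starts.

## Reaction progress coordinates

The raw $(r, p)$ plane contains an unphysical corner where both distances
are small. A rigid rotation fixes this: with the first and last converged
path images at $(r_0, p_0)$ and $(r_N, p_N)$, the unit tangent
$(\hat s_r, \hat s_p)$ points between them, the normal is
$(\hat d_r, \hat d_p) = (-\hat s_p, \hat s_r)$, and

$$s_i = (r_i - r_0)\hat s_r + (p_i - p_0)\hat s_p, \qquad
  d_i = (r_i - r_0)\hat d_r + (p_i - p_0)\hat d_p.$$

$s$ measures progress along the reaction, $d$ the perpendicular deviation,
both in Å. The map is parameter-free, exact at the endpoints — the
reactant goes to $(0,0)$ and the product to $(L,0)$ — an isometry, and
directly invertible (`rotateFromProgress()`). The frame is anchored to the
final converged path, not to raw optimizer samples, because endpoints are
fixed during a band optimization. Coincident projected endpoints are a
hard error: they indicate identical references, a user input mistake. The
sign of $d$ follows the normal convention above with no re-flipping, so
output is reproducible.

## One-dimensional profiles

For the conventional panels, the per-image energies are interpolated with
a piecewise cubic Hermite polynomial whose node derivatives are
*prescribed* by the tangential force: $dE/ds|_{s_i} = -F_{\parallel,i}$.
`buildProfile()` reproduces node energies and node slopes exactly (they
are data, not estimates); this is why the evaluator is written here rather
than delegated to a monotone PCHIP fit, which would estimate its own
slopes.

## Synthetic 2D gradients

Forces live in $3N$ dimensions, but the Jacobian of the invariant RMSD is
not analytically available (the optimal permutation changes discontinuously),
so full force vectors cannot be projected. Instead the tangential component
is combined with the in-plane path tangent. The projected coordinates are
first stabilized with a Savitzky–Golay filter (window 5, polynomial order
2 — the smallest window that kills image-to-image jitter while reproducing
locally quadratic paths exactly); series shorter than the window pass
through unsmoothed with a warning. Tangents are central differences with
respect to the in-plane arc length, normalized to unit length, with
repeated points inheriting the previous tangent; then

$$\nabla_r E = -F_\parallel \tau_r, \qquad \nabla_p E = -F_\parallel \tau_p,$$

so the projected gradient magnitude equals $|F_\parallel|$. Gradients are
computed per path snapshot, never across optimizer steps, because a
tangent only has meaning along one path.

One property of this construction deserves emphasis. The $(r,p)$ map does
not preserve arc length: a straight segment between the two references
stretches by $\sqrt{2}$ (both distances change at unit rate), while for
per-atom-normalized RMSD coordinates on real systems the plane arc is
shorter than the $3N$ Frobenius arc by roughly $\sqrt{N}$. A force
recorded per unit of one arc is therefore inconsistent, by exactly that
stretch factor, with energy slopes measured in the other. The construction
above is a deliberate heuristic: it anchors gradient *direction* to the
local path geometry and gradient *magnitude* to $|F_\parallel|$. The
surface is a qualitative guide near the data, not a quantitative PES
surrogate, and the synthetic-data generator (below) makes the
inconsistency measurable.

## The gradient-enhanced Gaussian process

Energies and projected gradients jointly feed a GP with derivative
observations. The observation vector interleaves channels per point,
$y_\mathrm{full} = [E_1, \nabla_x E_1, \nabla_y E_1, E_2, \dots]$, and the
covariance combines kernel values, first derivatives and mixed second
derivatives in matching blocks. The default kernel is the inverse
multiquadric

$$k(x, x') = \frac{a}{\sqrt{c^2 + \lVert x - x'\rVert^2}},$$

whose derivative blocks have closed forms
($\partial k/\partial x_i = -(x_i - x_i')(c^2+r^2)^{-3/2}$ and
$\partial^2 k/\partial x_i \partial x_j' = \delta_{ij}(c^2+r^2)^{-3/2}
- 3 (x_i-x_i')(x_j-x_j')(c^2+r^2)^{-5/2}$, times $a$). Complete
monotonicity makes it strictly positive definite in every dimension, and
its polynomial tails ($1/r$, $1/r^2$, $1/r^3$ for value, gradient,
Hessian) keep long-range basin structure visible from sparse path data
while conditioning better than exponential kernels. Squared-exponential
and Matérn-5/2 alternatives are available with analytic derivative blocks;
the thin-plate kernel $r^2\log r$ is only conditionally positive definite
and its second derivative diverges at coincident points, so the `tps`
surface type fits energies only and reports no posterior variance — a
documented design choice.

Parameters and defaults:

* `c` (Å) — kernel scale; optimized, bounds $[10^{-3}, 10^2]$.
* `amplitude` (eV) — output scale. The printed kernel has none, but eV
  energies against Å distances need scale freedom; it is optimized
  alongside `c` and recorded as this implementation's extension.
* `noise` $\sigma^2$ (eV²) — one observation-noise scale shared by energy
  and gradient channels, bounds $[10^{-10}, 1]$.
* Energies are centered at the reactant level before fitting, so the GP
  prior mean (and hence the far-field surface) sits at the reactant
  energy.

Hyperparameters are learned by maximizing the marginal likelihood on the
final-path subset only (n of order 20, against full histories of hundreds
to thousands) with bounded L-BFGS-B in log-space from four deterministic
starts, then reused for the full fit. This cuts the cost from $O(N^3)$ to
$O(n^3)$ and isolates scale learning from transient optimization
dynamics. If the optimizer stalls (typically a likelihood ridge on
near-noiseless tiny subsets, where the amplitude runs to a bound), the
best iterate is returned with a warning. Cholesky factorizations escalate
jitter multiplicatively from $10^{-10}$ to at most $10^{-6}$ of the mean
diagonal before raising a conditioning error.

## Nyström acceleration

For histories beyond roughly $10^3$ gradient-augmented observations the
full solve is cubic and becomes prohibitive. `fitNystrom()` approximates
the augmented kernel matrix through $M$ inducing points,
$\tilde K_{NN} \approx K_{NM} K_{MM}^{-1} K_{MN}$, with predictive weights

$$\alpha_M = L^{-\top}\!\big(S^{-1} V y_\mathrm{full}\big), \qquad
  S = V V^\top + \sigma^2 I,\; V = L^{-1} K_{MN},$$

at $O(NM^2)$ cost. $L$ here is the (jitter-stabilized) Cholesky factor of
$K_{MM}$ itself; keeping $\sigma^2$ out of this factor makes the $M = N$
case reduce exactly to the full GP, which is the natural correctness
anchor for the approximation. Inducing points default to all final-path
images padded with evenly strided history points up to a budget of 300.
The predictive variance uses the subset-of-regressors form from the same
factorization; like all such approximations it understates uncertainty
far from the inducing set, so its contours should be read near the data
only.

## Reliability contours and the figure

The posterior standard deviation is small near sampled structures and
grows with distance, delineating data-supported regions from
extrapolation. `renderLandscape()` draws the mean surface (perceptually
uniform colormap), dashed std contours at 25/50/75% of the maximum grid
std (a scale-free default; the levels are configurable), all samples as
dots shaded early-to-late, the converged path as open circles, external
references as stars, and optional critical-point markers (reactant,
product, saddle estimate and highest-energy image; the last two coincide
unless a climbing image is marked). The grid defaults to 120×120 cells
with a 10% margin. Every plotted layer is also written as a TSV sidecar
with fixed formatting, so reruns with the same seed are byte-identical and
no data exists only as pixels.

## The synthetic-data generator

`doubleWellLandscape()` builds an analytic 2D double well with reactant at
energy 0, saddle at `barrier` and product at `asymmetry`, exactly: along
the well axis $E'(x) = (x^3 - x)(\alpha x + \beta)$ with
$\alpha = -15a/4$, $\beta = 4b - 2a$ places stationary values $0, b, a$ at
$x = -1, 0, 1$; a harmonic term (default 2 eV/Å²) closes the second
dimension. The defaults (0.4 eV barrier, product 0.8 eV below the
reactant) mirror a typical exothermic cycloaddition.

`liftTo3N()` embeds the plane into molecular coordinates: a seeded,
well-separated base geometry plus two displacement modes that carry no net
translation or rotation and whose $3\times 3$ cross-products are
symmetric. Those constraints make the optimal superposition between any
two lifted frames exactly the identity, so the invariant RMSD between
lifted points equals the planar distance to machine precision — the
projection stage can be tested against exact ground truth. Frames can be
decorated with seeded rigid transforms and within-element permutations to
exercise invariance end to end.

`synthesizeNebHistory()` relaxes a straight chain of images (default 15)
toward the minimum-energy path by perpendicular gradient descent with
equal-arc-length redistribution over 200 sweeps, injecting positional
jitter (default 0.02 Å) for the first 80% of the run so the recorded
final path is converged. It is deliberately not a faithful band
optimization — no springs — because path optimization itself is out of
scope; it only needs plausible histories with known truth.

Because of the arc-stretch property discussed above, the generator records
the tangential force per unit of *projected* arc by default
(`forceConvention = "projected"`), which makes the synthetic gradients
exactly consistent with the projected energies: end-to-end checks then
measure implementation error, and the default fixture recovers the 0.4 eV
barrier to well within 0.01 eV. Choosing
`forceConvention = "configuration"` records the force per $3N$ Frobenius
arc — what a real band driver reports — and exposes the method's intrinsic
projection bias (the fitted barrier then integrates toward
$\sqrt{2} \times$ the true value on this maximally straight fixture).
Real data sit between these extremes, which is one more reason to read the
surface qualitatively.

What passing the synthetic tests does *not* show about real data: the
fixture explores exactly two internal directions, its images lie close to
a plane the projection represents losslessly, and its forces are exact.
Real histories explore $3N-6$ directions, multiple structures can share
one $(r,p)$ point (the surface then shows a conditional average), and the
orthogonal curvature of the true PES is invisible to the tangential-force
construction.

## Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on data generated in
code: 1000 random pairs for kernel derivative checks, 50-point covariances
for definiteness, up-to-15-point GPs against an explicit-inverse oracle,
100 random ≤6-atom clouds against exhaustive permutation enumeration,
double-well histories of 15 images × 21 recorded sweeps (315 frames) for
the end-to-end checks, and 10 replicate draws for hyperparameter recovery.
These sizes were chosen to make every oracle exact or exhaustive while the
whole suite stays comfortably interactive.

## Known limitations

* The $(r,p)$ map is lossy and anisotropic; apparent off-path features can
  be projection artifacts. The variance contours mark where to stop
  trusting the surface.
* Only the tangential force enters; orthogonal curvature cannot be
  recovered, and minimum-energy-path orthogonality has no analogue in the
  projection.
* The thin-plate surface type carries no uncertainty estimate.
* Matching is non-convex; the multi-start scheme is exhaustive-verified
  only for small systems, and pathological near-symmetric clusters may
  need more starts (`nStarts`).
* Periodic systems, velocities and binary trajectory formats are out of
  scope; coordinates are raw Cartesian Å, energies eV, with no unit layer.
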